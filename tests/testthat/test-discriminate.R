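test_that("two separated 1-D classes give the midpoint decision boundary", {
  set.seed(61)
  x <- matrix(c(rnorm(50, 0), rnorm(50, 10)), ncol = 1,
              dimnames = list(NULL, "t"))
  y <- rep(c("lo", "hi"), each = 50)
  fit <- fit_lda(x, y)
  # scan for the posterior crossover
  grid <- matrix(seq(2, 8, by = 0.01), ncol = 1, dimnames = list(NULL, "t"))
  post <- predict(fit, grid)$posterior
  boundary <- unname(grid[which.min(abs(post[, "lo"] - 0.5)), 1])
  expect_equal(boundary, 5, tolerance = 0.5)
})

test_that("degenerate trait inputs are screened or stabilized", {
  set.seed(62)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  y <- rep(c("p", "q"), 20)
  # duplicate column: pooled covariance singular, ridge kicks in
  Xdup <- cbind(X, a2 = X[, "a"])
  fit <- fit_lda(Xdup, y)
  expect_gt(fit$ridge_applied, 0)
  pr <- predict(fit, Xdup)
  expect_length(pr$class, 40L)
  # constant column: dropped and recorded
  Xc <- cbind(X, k = rep(2, 40))
  fit2 <- fit_lda(Xc, y)
  expect_equal(fit2$dropped, "k")
  expect_error(fit_lda(matrix(1, 10, 2), rep(c("p", "q"), 5)), "constant")
  # singleton class named in the error
  expect_error(fit_lda(X, c(rep("p", 39), "solo")), "solo")
})

test_that("prediction agrees with MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(63)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3), n, 3),
             matrix(rnorm(n * 3, mean = 1.2), n, 3),
             matrix(rnorm(n * 3, mean = c(0, 2, 0)), n, 3))
  colnames(X) <- c("u", "v", "w")
  y <- rep(c("a", "b", "c"), each = n)
  ours <- predict(fit_lda(X, y), X)
  mf <- MASS::lda(X, grouping = y)
  mp <- predict(mf, as.data.frame(X))
  expect_equal(as.character(ours$class), as.character(mp$class))
  expect_equal(ours$posterior, mp$posterior, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("LOO predictions match MASS's built-in leave-one-out CV", {
  skip_if_not_installed("MASS")
  set.seed(64)
  X <- rbind(matrix(rnorm(40 * 2), 40, 2),
             matrix(rnorm(40 * 2, mean = 1.5), 40, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("a", "b"), each = 40)
  loo <- loo_predict(X, y)
  mcv <- MASS::lda(X, grouping = y, CV = TRUE)
  expect_equal(as.character(loo$class), as.character(mcv$class))
  expect_equal(loo$posterior, mcv$posterior, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("LOO accuracy is high for separated classes, chance for permuted", {
  set.seed(65)
  X <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(30 * 2, mean = 10), 30, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("a", "b"), each = 30)
  expect_gte(loo_predict(X, y)$accuracy, 0.98)
  # permuted labels over 4 balanced classes: chance = 1/4
  n <- 200
  Xp <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  accs <- replicate(20, {
    yp <- sample(rep(c("a", "b", "c", "d"), each = n / 4))
    loo_predict(Xp, yp)$accuracy
  })
  expect_equal(mean(accs), 0.25, tolerance = 0.08)
  # smallest valid input: 2 classes x 2 samples
  X2 <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
               dimnames = list(NULL, c("u", "v")))
  loo2 <- loo_predict(X2, c("a", "a", "b", "b"))
  expect_length(loo2$class, 4L)
})

test_that("accuracy is invariant to affine rescaling of a trait column", {
  set.seed(66)
  X <- rbind(matrix(rnorm(30 * 3), 30, 3),
             matrix(rnorm(30 * 3, mean = 1), 30, 3))
  colnames(X) <- c("u", "v", "w")
  y <- rep(c("a", "b"), each = 30)
  base <- loo_predict(X, y)
  Xs <- X
  Xs[, "v"] <- 1000 * Xs[, "v"] - 37
  rescaled <- loo_predict(Xs, y)
  expect_identical(as.character(base$class), as.character(rescaled$class))
  expect_equal(base$accuracy, rescaled$accuracy, tolerance = 1e-6)
})

test_that("confusion matrices row-normalize and handle novel predictions", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(cm$proportions["A", ], c(A = 0.5, B = 0.5))
  expect_equal(cm$proportions["B", ], c(A = 0, B = 1))
  perfect <- confusion_matrix(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(perfect$proportions, diag(3), ignore_attr = TRUE)
  # predicted label absent from actual set gets a column; rows still sum 1
  cm2 <- confusion_matrix(c("A", "A", "B", "B"), c("A", "C", "B", "B"))
  expect_true("C" %in% colnames(cm2$proportions))
  expect_equal(unname(rowSums(cm2$proportions)[c("A", "B")]), c(1, 1))
  expect_error(confusion_matrix(c("A", "B"), c("A")), "length")
})

test_that("node rank correlation follows its definition", {
  expect_equal(node_rank_rho(1:8, 1:8)$rho, 1)
  expect_equal(node_rank_rho(1:8, 8:1)$rho, -1)
  expect_error(node_rank_rho(1:8, rep(3, 8)), "constant")
  expect_error(node_rank_rho(1:3, 1:3), "5")
  set.seed(67)
  a <- sample(1:10, 40, replace = TRUE)
  b <- a + sample(-2:2, 40, replace = TRUE)
  got <- node_rank_rho(a, b)
  ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                          exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("feature-set comparison resolves ties and constructed contrasts", {
  set.seed(68)
  # identical informative traits in both sets: tie broken toward Both
  X <- rbind(matrix(rnorm(20 * 2), 20, 2),
             matrix(rnorm(20 * 2, mean = 4), 20, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("a", "b"), each = 20)
  X2 <- X; colnames(X2) <- c("u2", "v2")
  cmp <- feature_set_comparison(X, X2, y)
  expect_equal(cmp$landmark, cmp$efd)
  expect_true(all(cmp$max == "Both"))
  # species differing only in vein width: landmarks see it, outlines do not
  specs <- lapply(1:2, function(i) {
    species_spec(paste0("s", i), "A",
                 leaf_params(vein_half_width = c(0.15, 0.45)[i]),
                 sds = c(vein_half_width = 0.03,
                         midvein_len = 0.3, distal_lobe_len = 0.3))
  })
  ds <- synth_dataset(specs, 3L, 5L, asym_sd = 0.02, seed = 68L)
  g <- gpa(ds$table)
  lmt <- gpa_trait_matrix(g)
  eft <- efd_trait_matrix(ds$outlines, 10, ds$table$records$leaf_id)
  cmp2 <- feature_set_comparison(lmt, eft, ds$table$records$species)
  expect_true(all(cmp2$landmark > cmp2$efd))
  # singleton group excluded with a warning
  expect_warning(
    cmp3 <- feature_set_comparison(X, X2, y,
                                   group = c("g1", rep(c("p", "q"), c(19, 20)))),
    "single")
  expect_false("g1" %in% cmp3$group)
})
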