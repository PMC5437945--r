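test_that("covariance PCA recovers a known variance split", {
  set.seed(41)
  n <- 1e4
  X <- cbind(a = rnorm(n, sd = 2), b = rnorm(n, sd = 1))
  mod <- fit_pca(X)
  expect_equal(mod$variance_fraction[1], 0.8, tolerance = 0.02)
  # agreement with a direct eigen-decomposition of the sample covariance
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(mod$eigenvalues, ev$values, tolerance = 1e-8)
  expect_equal(sum(mod$variance_fraction), 1, tolerance = 1e-9)
})

test_that("PCA matches a brute-force covariance eigen solver", {
  set.seed(42)
  X <- matrix(rnorm(50 * 7), 50, 7,
              dimnames = list(NULL, paste0("t", 1:7)))
  X[, 3] <- X[, 1] * 0.5 + rnorm(50, sd = 0.1)
  mod <- fit_pca(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  expect_equal(mod$eigenvalues, ev$values, tolerance = 1e-8)
  for (j in 1:7) {
    # loadings match up to sign
    expect_equal(abs(sum(mod$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # orthonormal loadings
  expect_equal(crossprod(mod$loadings), diag(7), tolerance = 1e-9,
               ignore_attr = TRUE)
  # full-rank reconstruction returns the centered data
  rec <- mod$scores %*% t(mod$loadings)
  expect_equal(rec, scale(X, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-|entry| loading positive
  for (j in 1:7)
    expect_gt(mod$loadings[which.max(abs(mod$loadings[, j])), j], 0)
})

test_that("constant columns are dropped and degenerate input is handled", {
  set.seed(43)
  X <- cbind(a = rnorm(20), b = rnorm(20), c = rep(3, 20))
  mod <- fit_pca(X)
  expect_equal(mod$kept, c("a", "b"))
  expect_equal(mod$dropped, c(c = 3))
  # all samples identical: zero-component model
  same <- matrix(5, 10, 3, dimnames = list(NULL, c("x", "y", "z")))
  mod0 <- fit_pca(same)
  expect_equal(ncol(mod0$scores), 0L)
  expect_length(mod0$eigenvalues, 0L)
  expect_error(fit_pca(X[1:2, ]), "3 samples")
})

test_that("landmark PCA scores are rotation-invariant up to sign", {
  ds <- synth_dataset(default_species_specs()[1:3], 2L, 5L, seed = 51L)
  g <- gpa(ds$table)
  traits <- gpa_trait_matrix(g)
  mod1 <- fit_pca(traits)
  # rotate every aligned configuration by the same angle before PCA
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot <- g$aligned
  for (i in seq_len(dim(rot)[3])) rot[, , i] <- rot[, , i] %*% R
  g2 <- g; g2$aligned <- rot
  mod2 <- fit_pca(gpa_trait_matrix(g2))
  for (j in 1:4) {
    r <- stats::cor(mod1$scores[, j], mod2$scores[, j])
    expect_equal(abs(r), 1, tolerance = 1e-6)
  }
  expect_equal(mod1$eigenvalues, mod2$eigenvalues, tolerance = 1e-8)
})

test_that("eigenleaf landmarks obey the mean and linearity contracts", {
  ds <- synth_dataset(default_species_specs()[1:3], 2L, 5L, seed = 52L)
  g <- gpa(ds$table)
  mod <- fit_pca(gpa_trait_matrix(g))
  mean_leaf <- eigenleaf_landmarks(mod, 1, 0)
  expect_equal(as.numeric(mean_leaf),
               as.numeric(cbind(mod$center[paste0("x", 1:15)],
                                mod$center[paste0("y", 1:15)])),
               tolerance = 1e-12)
  up <- eigenleaf_landmarks(mod, 2, 1.5)
  down <- eigenleaf_landmarks(mod, 2, -1.5)
  expect_equal((up + down) / 2, mean_leaf, tolerance = 1e-10)
  expect_error(eigenleaf_landmarks(mod, 99, 1), "range")
})

test_that("sinus-depth-only variation localizes to the sinus landmarks", {
  # species identical except distal sinus depth; no noise elsewhere
  specs <- lapply(1:2, function(i) {
    p <- leaf_params(distal_sinus_depth = c(0.15, 0.55)[i])
    species_spec(paste0("s", i), "A", p,
                 sds = c(distal_sinus_depth = 0.02))
  })
  ds <- synth_dataset(specs, 3L, 5L, asym_sd = 0, seed = 53L)
  g <- gpa(ds$table)
  mod <- fit_pca(gpa_trait_matrix(g))
  up <- eigenleaf_landmarks(mod, 1, 1.5)
  down <- eigenleaf_landmarks(mod, 1, -1.5)
  move <- sqrt(rowSums((up - down)^2))
  sinus <- c(10, 12)
  # superimposition spreads a little compensation to every landmark, so
  # "nearly nowhere else" means clear dominance, not exact zero
  expect_gt(min(move[sinus]), 2 * max(move[-sinus]))
})

test_that("asymmetry-only variation loads on the B/C coefficient block", {
  specs <- lapply(1:2, function(i) {
    species_spec(paste0("s", i), "A", leaf_params(), sds = numeric(0))
  })
  ds <- synth_dataset(specs, 3L, 5L, asym_sd = 0.03, seed = 54L)
  traits <- efd_trait_matrix(ds$outlines, 20, ds$table$records$leaf_id)
  mod <- fit_pca(traits)
  ld <- abs(mod$loadings[, 1])
  bc <- grepl("^[BC]", names(ld))
  expect_gt(mean(ld[bc]), 10 * mean(ld[!bc]))
})

test_that("eigenleaf contours reconstruct the displaced coefficients", {
  ds <- synth_dataset(default_species_specs()[1:3], 2L, 5L, seed = 55L)
  traits <- efd_trait_matrix(ds$outlines, 12, ds$table$records$leaf_id)
  mod <- fit_pca(traits)
  ct0 <- eigenleaf_contour(mod, 1, 0, n_points = 240)
  mean_co <- traits_to_efd(mod$center, 12)
  expect_equal(ct0, reconstruct_contour(mean_co, 12, 240),
               tolerance = 1e-10)
  # the normalized invariants survive the round trip through the model
  v <- leafmorph:::pca_trait_vector(mod, 1, 1)
  expect_equal(unname(v["A1"]), 1)
  expect_equal(unname(v["B1"]), 0)
  expect_equal(unname(v["C1"]), 0)
  # +/- m eigenleaf coefficient vectors average to the center
  vp <- leafmorph:::pca_trait_vector(mod, 2, 1)
  vm <- leafmorph:::pca_trait_vector(mod, 2, -1)
  expect_equal((vp + vm) / 2, mod$center, tolerance = 1e-10)
  expect_error(eigenleaf_contour(mod, 99, 1), "range")
})
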