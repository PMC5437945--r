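test_that("boundary tracing enumerates the square's boundary counterclockwise", {
  mask <- matrix(FALSE, 8, 8)
  mask[3:6, 2:5] <- TRUE
  ct <- trace_boundary(mask)
  expect_equal(nrow(ct), 12L)        # 4x4 block has 12 boundary pixels
  expect_gt(leafmorph:::.signed_area(ct), 0)
  # all traced points are boundary pixels of the block
  expect_true(all(ct[, 1] %in% 2:5 & ct[, 2] %in% (8 - 6):(8 - 3) + 0))
  expect_error(trace_boundary(matrix(FALSE, 4, 4)), "empty")
  tiny <- matrix(FALSE, 4, 4); tiny[2, 2] <- TRUE
  expect_error(trace_boundary(tiny), "small")
  two <- matrix(FALSE, 8, 8); two[2:4, 2:4] <- TRUE; two[6:8, 6:8] <- TRUE
  expect_error(trace_boundary(two), "one foreground")
})

test_that("tracing commutes with rotating the mask", {
  mask <- matrix(FALSE, 10, 12)
  mask[3:7, 4:9] <- TRUE
  mask[3, 4] <- FALSE  # break symmetry
  ct <- trace_boundary(mask)
  rot <- t(mask[nrow(mask):1, ])   # 90-degree rotation
  ct_rot <- trace_boundary(rot)
  # pixel (r, c) of the mask maps to (c, nr + 1 - r) of the rotated mask;
  # in math coordinates that sends contour point (x, y) to (y + 1, nc - x)
  expected <- cbind(ct[, 2] + 1, ncol(mask) - ct[, 1])
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(ct_rot), key(expected))
  expect_equal(nrow(ct_rot), nrow(ct))
})

test_that("EFD of a circle is a pure first harmonic", {
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  R <- 2.5
  circ <- cbind(4 + R * cos(th), -7 + R * sin(th))
  co <- efd_coefficients(circ, 8)
  m <- unclass(co)
  expect_equal(m[1, "A"], c(A = R), tolerance = 1e-3)
  expect_equal(m[1, "D"], c(D = R), tolerance = 1e-3)
  expect_lt(max(abs(m[1, c("B", "C")])), 1e-3 * R)
  expect_lt(max(abs(m[-1, ])), 1e-3 * R)
  expect_equal(attr(co, "A0"), 4, tolerance = 1e-6)
  expect_equal(attr(co, "C0"), -7, tolerance = 1e-6)
})

test_that("EFD of a constant-speed ellipse is exact", {
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  ell <- cbind(2 * cos(th), sin(th))
  m <- unclass(efd_coefficients(ell, 4, chain_code = TRUE))
  expect_equal(m[1, "A"], c(A = 2), tolerance = 1e-3)
  expect_equal(m[1, "D"], c(D = 1), tolerance = 1e-3)
  expect_lt(max(abs(m[cbind(c(1, 1, 2, 3, 4), c(2, 3, 1, 1, 1))])), 1e-3)
})

test_that("forward transform matches the adaptive-quadrature oracle", {
  set.seed(31)
  for (rep in 1:3) {
    poly <- rand_polygon(20)
    m <- unclass(efd_coefficients(poly, 6))
    oracle <- quad_efd(poly, 6)
    expect_equal(m, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
  # unit square traversed as a polygon
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(unclass(efd_coefficients(sq, 5)), quad_efd(sq, 5),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("normalization yields the canonical frame and similarity invariance", {
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  ell <- cbind(2 * cos(th), sin(th))
  moved <- apply_similarity(ell, angle = 37 * pi / 180, scale = 5,
                            shift = c(11, -4))
  nf <- normalize_efd(efd_coefficients(moved, 6, chain_code = TRUE))
  m <- unclass(nf$coeffs)
  expect_equal(m[1, "A"], c(A = 1))
  expect_equal(m[1, "B"], c(B = 0))
  expect_equal(m[1, "C"], c(C = 0))
  expect_equal(abs(m[1, "D"]), c(D = 0.5), tolerance = 1e-6)
  expect_gt(nf$info$scale, 0)
  # circle: |D1| = 1
  circ <- cbind(cos(th), sin(th))
  mc <- unclass(normalize_efd(efd_coefficients(circ, 4))$coeffs)
  expect_equal(abs(mc[1, "D"]), c(D = 1), tolerance = 1e-3)
})

test_that("normalized coefficients are invariant under the similarity group", {
  set.seed(33)
  for (rep in 1:5) {
    poly <- resample_contour(rand_polygon(15), 300)
    ref <- unclass(normalize_efd(efd_coefficients(poly, 10))$coeffs)
    k <- nrow(poly)
    shift_idx <- c((k %/% 3):k, 1:(k %/% 3 - 1))
    variants <- list(
      apply_similarity(poly, angle = runif(1, 0, 2 * pi)),
      apply_similarity(poly, scale = runif(1, 0.1, 20)),
      apply_similarity(poly, shift = rnorm(2, 0, 50)),
      poly[shift_idx, ],
      apply_similarity(poly[shift_idx, ], angle = runif(1, 0, 2 * pi),
                       scale = runif(1, 0.5, 2), shift = rnorm(2)))
    for (v in variants) {
      got <- unclass(normalize_efd(efd_coefficients(v, 10))$coeffs)
      expect_lt(max(abs(got - ref)), 1e-8)
    }
  }
})

test_that("mirror reflection negates B and C and preserves A and D", {
  set.seed(34)
  for (rep in 1:3) {
    poly <- resample_contour(rand_polygon(12), 256)
    m <- unclass(normalize_efd(efd_coefficients(poly, 8))$coeffs)
    mir <- poly %*% diag(c(1, -1))
    mir <- mir[nrow(mir):1, ]       # restore counterclockwise traversal
    mm <- unclass(normalize_efd(efd_coefficients(mir, 8))$coeffs)
    expect_lt(max(abs(mm[, c("A", "D")] - m[, c("A", "D")])), 1e-8)
    expect_lt(max(abs(mm[, c("B", "C")] + m[, c("B", "C")])), 1e-8)
  }
})

test_that("degenerate first harmonics are rejected", {
  co <- efd_coeffs(matrix(c(0, 0, 0, 0, 1e-3, 0, 0, 0), 2, 4, byrow = TRUE),
                   T = 1)
  expect_error(normalize_efd(co), "degenerate")
  nf <- normalize_efd(efd_coefficients(rand_polygon(10), 4))
  expect_error(normalize_efd(nf$coeffs), "already")
})

test_that("reconstruction inverts the transform and converges", {
  # single-harmonic reconstruction is the first-harmonic ellipse
  co <- efd_coeffs(matrix(c(1, 0, 0, 0.5), 1, 4), normalized = TRUE)
  ct <- reconstruct_contour(co, 1, 360)
  expect_equal(max(ct[, 1]), 1, tolerance = 1e-6)
  expect_equal(max(ct[, 2]), 0.5, tolerance = 1e-6)
  # RMS error of a synthetic leaf outline is non-increasing in n_use
  leaf <- synth_leaf(leaf_params())$outline
  co40 <- efd_coefficients(leaf, 40)
  rms <- vapply(1:20, function(nu) {
    rec <- reconstruct_contour(co40, nu, nrow(leaf))
    sqrt(mean(dist_to_polygon(leaf, rec)^2))
  }, 0)
  expect_true(all(diff(rms) <= 1e-9))
  # 40 harmonics reconstruct a smooth contour to < 0.5% of perimeter
  rec40 <- reconstruct_contour(co40, 40, nrow(leaf))
  per <- attr(co40, "T")
  expect_lt(sqrt(mean(dist_to_polygon(leaf, rec40)^2)), 0.005 * per)
  expect_error(reconstruct_contour(co40, 41), "exceeds")
})

test_that("mean coefficients average per entry with guards", {
  set.seed(36)
  g1 <- normalize_efd(efd_coefficients(rand_polygon(12), 6))$coeffs
  expect_equal(mean_coefficients(list(g1)), g1, tolerance = 1e-12,
               ignore_attr = TRUE)
  g2 <- g1; g2[1, "D"] <- 0.4; g3 <- g1; g3[1, "D"] <- 0.6
  mn <- mean_coefficients(list(g2, g3))
  expect_equal(mn[1, "D"], c(D = 0.5))
  # mirror cancellation: mean of a leaf and its mirror has B = C = 0
  gm <- g1
  gm[, c("B", "C")] <- -gm[, c("B", "C")]
  cancel <- mean_coefficients(list(g1, gm))
  expect_true(all(abs(unclass(cancel)[, c("B", "C")]) < 1e-15))
  raw <- efd_coefficients(rand_polygon(12), 6)
  expect_error(mean_coefficients(list(g1, raw)), "normalized")
  expect_error(mean_coefficients(list()), "empty")
})

test_that("harmonic contributions amplify exactly one rank", {
  set.seed(37)
  leaves <- lapply(1:4, function(i)
    synth_leaf(leaf_params(distal_sinus_depth = 0.2 + 0.1 * i))$outline)
  mn <- mean_coefficients(lapply(leaves, function(o)
    normalize_efd(efd_coefficients(o, 12))$coeffs))
  plain <- reconstruct_contour(mn, 12, 240)
  expect_equal(harmonic_contribution(mn, 3, 1, 240), plain)
  # amplification 0 equals omitting the rank
  dropped <- mn; dropped[3, ] <- 0
  expect_equal(harmonic_contribution(mn, 3, 0, 240),
               reconstruct_contour(dropped, 12, 240))
  # stronger amplification moves the contour further from plain
  d2 <- hausdorff(harmonic_contribution(mn, 2, 2, 240), plain)
  d5 <- hausdorff(harmonic_contribution(mn, 2, 5, 240), plain)
  expect_gt(d5, d2)
  expect_error(harmonic_contribution(mn, 13, 2), "range")
})

test_that("mask-to-coefficients path is consistent with the contour path", {
  # a filled disk through the full mask pipeline
  nr <- 64
  xy <- expand.grid(r = 1:nr, c = 1:nr)
  mask <- matrix((xy$r - 32)^2 + (xy$c - 32)^2 < 24^2, nr, nr)
  co <- efd_coefficients(mask, 8)
  m <- unclass(normalize_efd(co)$coeffs)
  expect_equal(abs(m[1, "D"]), c(D = 1), tolerance = 0.02)
  expect_lt(max(abs(m[2:8, ])), 0.01)
})
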