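#' Trace the outer boundary of a binary mask
#'
#' Moore-neighbour tracing of the single 8-connected foreground component.
#' The trace starts at the top-most, then left-most boundary pixel and is
#' returned counterclockwise in math coordinates (x = column, y = height -
#' row), one point per boundary pixel center.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @return A closed contour: `k x 2` matrix (first point not repeated).
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) stop("empty mask")
  lab <- label_components(mask)
  if (max(lab) != 1L) stop("mask must contain exactly one foreground component")
  if (sum(mask) < 4L) stop("foreground component too small (< 4 pixels)")
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && mask[r, c]
  # start pixel: minimal row, then minimal column
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[idx[, 1] == r0, 2])
  # Moore neighbourhood in clockwise order starting from W (row, col offsets)
  moore <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                  ncol = 2, byrow = TRUE)
  path_r <- integer(0); path_c <- integer(0)
  cur <- c(r0, c0)
  backtrack <- 1L  # entered from the West (scan direction)
  repeat {
    path_r <- c(path_r, cur[1]); path_c <- c(path_c, cur[2])
    found <- FALSE
    start_dir <- backtrack
    for (k in 0:7) {
      dir <- ((start_dir - 1L + k) %% 8L) + 1L
      rr <- cur[1] + moore[dir, 1]; cc <- cur[2] + moore[dir, 2]
      if (inside(rr, cc)) {
        # next backtrack: direction pointing back at the previous free cell,
        # i.e. one step counterclockwise... take the neighbour before `dir`
        prev <- ((dir - 2L) %% 8L) + 1L
        # backtrack index = position of the cell we came from relative to new pixel
        br <- cur[1] + moore[prev, 1] - rr
        bc <- cur[2] + moore[prev, 2] - cc
        backtrack <- which(moore[, 1] == br & moore[, 2] == bc)
        cur <- c(rr, cc)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated-ish pixel: cannot happen for >=4 px blobs
    if (cur[1] == r0 && cur[2] == c0) break
    if (length(path_r) > 4L * sum(mask)) stop("boundary trace failed to close")
  }
  pts <- cbind(x = path_c, y = nr - path_r)
  pts <- pts[!duplicated(pts) | seq_len(nrow(pts)) == 1L, , drop = FALSE]
  # clockwise pixel order becomes counterclockwise after the y flip; enforce
  if (.signed_area(pts) < 0) pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
  storage.mode(pts) <- "double"
  pts
}

.signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Resample a closed contour to equally spaced points
#'
#' Linear interpolation along arc length; stabilises Fourier coefficients
#' across image resolutions.
#'
#' @param contour `k x 2` matrix, closed (first point not repeated).
#' @param n Number of output points.
#' @return `n x 2` matrix.
#' @export
resample_contour <- function(contour, n = 500L) {
  pts <- .clean_contour(contour)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  t_cum <- c(0, cumsum(seg))
  total <- t_cum[length(t_cum)]
  tt <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  x <- stats::approx(t_cum, closed[, 1], xout = tt)$y
  y <- stats::approx(t_cum, closed[, 2], xout = tt)$y
  cbind(x = x, y = y)
}

.clean_contour <- function(contour) {
  pts <- as.matrix(contour)
  if (ncol(pts) != 2L) stop("contour must be a k x 2 matrix")
  if (!all(is.finite(pts))) stop("non-finite contour coordinates")
  if (nrow(pts) > 1L && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  # drop zero-length segments (consecutive duplicates)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3L) stop("contour has fewer than 3 distinct points")
  pts
}

#' Elliptical Fourier coefficients of a closed contour
#'
#' Harmonic decomposition of the arc-length traversal `(x(t), y(t))` of a
#' closed polygon, with per-segment `dt` equal to segment length. For each
#' rank n the four coefficients are
#' \deqn{A_n = \frac{T}{2 n^2 \pi^2} \sum_p \frac{\Delta x_p}{\Delta t_p}
#'   \left[\cos\frac{2\pi n t_p}{T} - \cos\frac{2\pi n t_{p-1}}{T}\right]}
#' and analogously `B_n` with sine, `C_n`, `D_n` with `\Delta y_p`. The DC
#' offsets `A0`, `C0` are the arc-length means of `x(t)` and `y(t)`.
#'
#' @param contour `k x 2` closed polygon (first point not repeated), or a
#'   logical mask (traced and resampled first).
#' @param n_harmonics Number of harmonic ranks.
#' @param chain_code If `TRUE`, treat every segment as unit time
#'   (`dt = 1`), the convention of chain-code programs on 4-connected
#'   codes; default uses true segment lengths.
#' @return An `efd_coeffs` object: `n_harmonics x 4` matrix (columns
#'   A, B, C, D) with attributes `A0`, `C0`, `T` (perimeter) and
#'   `normalized = FALSE`.
#' @export
efd_coefficients <- function(contour, n_harmonics = 20L, chain_code = FALSE) {
  if (is.logical(contour)) contour <- resample_contour(trace_boundary(contour))
  pts <- .clean_contour(contour)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  closed <- rbind(pts, pts[1, ])
  dxy <- diff(closed)
  dt <- if (chain_code) rep(1, nrow(dxy)) else sqrt(rowSums(dxy^2))
  if (any(dt <= 0)) stop("zero-length contour segment")
  tp <- cumsum(dt)
  Tt <- tp[length(tp)]
  t0 <- c(0, tp[-length(tp)])
  n <- seq_len(n_harmonics)
  ang1 <- outer(tp, n) * (2 * pi / Tt)   # K x N
  ang0 <- outer(t0, n) * (2 * pi / Tt)
  dcos <- cos(ang1) - cos(ang0)
  dsin <- sin(ang1) - sin(ang0)
  fac <- Tt / (2 * n^2 * pi^2)
  vx <- dxy[, 1] / dt
  vy <- dxy[, 2] / dt
  A <- fac * colSums(vx * dcos)
  B <- fac * colSums(vx * dsin)
  C <- fac * colSums(vy * dcos)
  D <- fac * colSums(vy * dsin)
  # DC terms: arc-length average of the piecewise-linear x(t), y(t)
  xm <- (closed[-1, 1] + closed[-nrow(closed), 1]) / 2
  ym <- (closed[-1, 2] + closed[-nrow(closed), 2]) / 2
  dt_true <- sqrt(rowSums(dxy^2))
  A0 <- sum(xm * dt_true) / sum(dt_true)
  C0 <- sum(ym * dt_true) / sum(dt_true)
  m <- cbind(A = A, B = B, C = C, D = D)
  efd_coeffs(m, A0 = A0, C0 = C0, T = Tt, normalized = FALSE)
}

#' Construct an `efd_coeffs` object
#'
#' @param m `n_harmonics x 4` matrix, columns A, B, C, D.
#' @param A0,C0 DC offsets.
#' @param T Perimeter (traversal period).
#' @param normalized Whether the coefficients are in the canonical
#'   normalized frame (`A1 = 1`, `B1 = C1 = 0`).
#' @export
efd_coeffs <- function(m, A0 = 0, C0 = 0, T = 1, normalized = FALSE) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 4L, all(is.finite(m)))
  colnames(m) <- c("A", "B", "C", "D")
  structure(m, A0 = A0, C0 = C0, T = T, normalized = normalized,
            class = c("efd_coeffs", "matrix", "array"))
}

#' @export
print.efd_coeffs <- function(x, ...) {
  cat("efd_coeffs:", nrow(x), "harmonics,",
      if (attr(x, "normalized")) "normalized" else "raw", "\n")
  print(utils::head(unclass(x), 4L))
  if (nrow(x) > 4L) cat("  ...\n")
  invisible(x)
}

#' Normalize elliptical Fourier coefficients
#'
#' Removes the start point, orientation, scale and (via the forward
#' transform) translation, using the first-harmonic ellipse: the start-point
#' phase \eqn{\theta_1 = \tfrac12 \mathrm{atan2}(2(A_1 B_1 + C_1 D_1),
#' A_1^2 + C_1^2 - B_1^2 - D_1^2)} rotates each rank-n pair by
#' \eqn{n\theta_1}; the orientation \eqn{\psi_1 = \mathrm{atan2}(C_1^*,
#' A_1^*)} is removed by a spatial rotation; the scale
#' \eqn{E = \sqrt{A_1^{*2} + C_1^{*2}}} divides every coefficient. The
#' residual 180-degree ambiguity (shifting the start half a period while
#' rotating the shape 180 degrees flips every even-rank block and nothing
#' else, leaving `A1 = 1` intact) is resolved by requiring the
#' largest-magnitude even-rank `A`/`D` entry to be positive --
#' a mirror-invariant rule, so reflection still cleanly negates `B`/`C`;
#' the
#' sign of `D1` (first-harmonic chirality) is retained. The result has
#' `A1 = 1`, `B1 = C1 = 0` and is invariant to rotation, translation,
#' scaling and cyclic start-point shifts of the input contour.
#'
#' @param coeffs Unnormalized `efd_coeffs`.
#' @return List: `coeffs` (normalized `efd_coeffs`, offsets zeroed) and
#'   `info` (list `theta1`, `psi1`, `scale`).
#' @export
normalize_efd <- function(coeffs) {
  stopifnot(inherits(coeffs, "efd_coeffs"))
  if (isTRUE(attr(coeffs, "normalized")))
    stop("coefficients are already normalized")
  m <- unclass(coeffs)
  A1 <- m[1, 1]; B1 <- m[1, 2]; C1 <- m[1, 3]; D1 <- m[1, 4]
  E0 <- sqrt(A1^2 + B1^2 + C1^2 + D1^2)
  if (E0 < 1e-12 * max(attr(coeffs, "T"), 1))
    stop("degenerate first harmonic; cannot normalize")
  theta <- 0.5 * atan2(2 * (A1 * B1 + C1 * D1),
                       A1^2 + C1^2 - B1^2 - D1^2)
  # the two candidates differ exactly by a sign flip of every even-rank
  # block (start shifted half a period + 180-degree spatial rotation)
  cands <- lapply(c(0, pi), function(flip)
    c(list(theta = theta + flip), .apply_normalization(m, theta + flip)))
  if (cands[[1]]$E < 1e-12 * max(attr(coeffs, "T"), 1))
    stop("degenerate first harmonic; cannot normalize")
  pick <- .pick_even_rank_sign(cands[[1]]$m / cands[[1]]$E)
  out <- cands[[if (pick >= 0) 1L else 2L]]
  th <- out$theta
  E <- out$E
  mn <- out$m / E
  if (abs(mn[1, 2]) > 1e-8 || abs(mn[1, 3]) > 1e-8)
    stop("normalization failed to zero B1/C1 (internal error)")
  # clamp the exact invariants of the canonical frame
  mn[1, 1] <- 1
  mn[1, 2] <- 0
  mn[1, 3] <- 0
  list(coeffs = efd_coeffs(mn, A0 = 0, C0 = 0, T = attr(coeffs, "T"),
                           normalized = TRUE),
       info = list(theta1 = th, psi1 = out$psi, scale = E))
}

# sign of the largest-magnitude even-rank A/D entry (the most stable
# anchor under perturbation; falls back to B/C, then +1 if all vanish).
# A/D are mirror-invariant, so the choice commutes with reflection.
.pick_even_rank_sign <- function(mn, tol = 1e-9) {
  if (nrow(mn) < 2L) return(1)
  even <- seq(2L, nrow(mn), by = 2L)
  for (cols in list(c(1L, 4L), c(2L, 3L))) {
    vals <- as.numeric(mn[even, cols, drop = FALSE])
    k <- which.max(abs(vals))
    if (length(k) && abs(vals[k]) > tol) return(sign(vals[k]))
  }
  1
}

.apply_normalization <- function(m, theta) {
  n_h <- nrow(m)
  out <- m
  for (n in seq_len(n_h)) {
    rot <- matrix(c(cos(n * theta), -sin(n * theta),
                    sin(n * theta),  cos(n * theta)), 2, 2, byrow = TRUE)
    blk <- matrix(m[n, ], 2, 2, byrow = TRUE)   # [A B; C D]
    out[n, ] <- as.numeric(t(blk %*% rot))
  }
  psi <- atan2(out[1, 3], out[1, 1])
  spin <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2,
                 byrow = TRUE)
  for (n in seq_len(n_h)) {
    blk <- matrix(out[n, ], 2, 2, byrow = TRUE)
    out[n, ] <- as.numeric(t(spin %*% blk))
  }
  list(m = out, psi = psi, E = sqrt(out[1, 1]^2 + out[1, 3]^2))
}

#' Reconstruct a contour from Fourier coefficients
#'
#' Evaluates the truncated series
#' \deqn{x(t) = A_0 + \sum_{n \le n_{use}} A_n \cos(2\pi n t/T) +
#'   B_n \sin(2\pi n t/T)} (and analogously `y(t)` with `C`, `D`) at
#' uniformly spaced `t`.
#'
#' @param coeffs `efd_coeffs`.
#' @param n_use Ranks to use (default all).
#' @param n_points Samples along the contour.
#' @return `n_points x 2` matrix (closed contour, first point not
#'   repeated).
#' @export
reconstruct_contour <- function(coeffs, n_use = nrow(coeffs),
                                n_points = 360L) {
  stopifnot(inherits(coeffs, "efd_coeffs"))
  if (n_use > nrow(coeffs)) stop("n_use exceeds available harmonics")
  if (n_use < 1L) stop("n_use must be >= 1")
  m <- unclass(coeffs)[seq_len(n_use), , drop = FALSE]
  tt <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  n <- seq_len(n_use)
  ang <- 2 * pi * outer(tt, n)     # n_points x n_use
  x <- attr(coeffs, "A0") + cos(ang) %*% m[, 1] + sin(ang) %*% m[, 2]
  y <- attr(coeffs, "C0") + cos(ang) %*% m[, 3] + sin(ang) %*% m[, 4]
  cbind(x = as.numeric(x), y = as.numeric(y))
}

#' Mean of a group of normalized coefficient sets
#'
#' Arithmetic mean per coefficient; the standard way to compute an
#' averaged outline for a species or group.
#'
#' @param group List of normalized `efd_coeffs` with equal harmonic count.
#' @return Normalized `efd_coeffs`.
#' @export
mean_coefficients <- function(group) {
  if (!length(group)) stop("empty group")
  if (!all(vapply(group, inherits, TRUE, "efd_coeffs")))
    stop("group must contain efd_coeffs objects")
  norm <- vapply(group, function(g) isTRUE(attr(g, "normalized")), TRUE)
  if (!all(norm)) stop("all coefficients must be normalized (mixed states)")
  nh <- vapply(group, nrow, 0L)
  if (length(unique(nh)) > 1L) stop("harmonic counts differ across group")
  acc <- Reduce(`+`, lapply(group, unclass)) / length(group)
  efd_coeffs(acc, A0 = 0, C0 = 0,
             T = mean(vapply(group, attr, 0, "T")), normalized = TRUE)
}

#' Amplified harmonic contribution to shape
#'
#' Reconstructs a contour with a single harmonic rank's coefficients
#' multiplied by an amplification factor, the standard visualisation of
#' what each rank contributes to shape (low ranks: lobing; high ranks:
#' serration-scale detail).
#'
#' @param coeffs `efd_coeffs` (typically a group mean).
#' @param rank Harmonic rank to amplify.
#' @param amplification Multiplier (1 = plain reconstruction, 0 = omit the
#'   rank).
#' @param n_points Samples along the contour.
#' @return `n_points x 2` contour.
#' @export
harmonic_contribution <- function(coeffs, rank, amplification = 1,
                                  n_points = 360L) {
  stopifnot(inherits(coeffs, "efd_coeffs"))
  if (rank < 1L || rank > nrow(coeffs)) stop("rank out of range")
  m <- unclass(coeffs)
  m[rank, ] <- m[rank, ] * amplification
  reconstruct_contour(
    efd_coeffs(m, A0 = attr(coeffs, "A0"), C0 = attr(coeffs, "C0"),
               T = attr(coeffs, "T"), normalized = attr(coeffs, "normalized")),
    n_use = nrow(m), n_points = n_points)
}

#' Normalized EFD trait matrix for a set of contours
#'
#' Runs the forward transform and normalization on every contour and
#' flattens the coefficients into a samples x traits matrix with columns
#' `A1..A20, B1..B20, C1..C20, D1..D20` (for 20 harmonics), the input
#' expected by [fit_pca()], [fit_lda()] and [spearman_matrix()].
#'
#' @param contours List of `k x 2` contours.
#' @param n_harmonics Harmonic ranks.
#' @param ids Optional row names.
#' @return Numeric matrix.
#' @export
efd_trait_matrix <- function(contours, n_harmonics = 20L, ids = NULL) {
  rows <- lapply(contours, function(ct) {
    nf <- normalize_efd(efd_coefficients(ct, n_harmonics = n_harmonics))
    as.numeric(unclass(nf$coeffs))
  })
  out <- do.call(rbind, rows)
  nh <- seq_len(n_harmonics)
  colnames(out) <- c(paste0("A", nh), paste0("B", nh),
                     paste0("C", nh), paste0("D", nh))
  rownames(out) <- ids
  out
}

#' Convert between efd_coeffs and NEF records
#'
#' @param traits Row of an [efd_trait_matrix()] or a `nef` coefficient
#'   matrix.
#' @param n_harmonics Harmonic count.
#' @return `efd_coeffs` (assumed normalized).
#' @export
traits_to_efd <- function(traits, n_harmonics = length(traits) %/% 4L) {
  m <- matrix(as.numeric(traits), nrow = n_harmonics, ncol = 4L)
  efd_coeffs(m, normalized = TRUE)
}

#' @rdname traits_to_efd
#' @param coeffs_list List of normalized `efd_coeffs`.
#' @param ids Specimen ids.
#' @export
efd_to_nef <- function(coeffs_list, ids) {
  stopifnot(length(coeffs_list) == length(ids))
  structure(list(ids = as.character(ids),
                 coeffs = lapply(coeffs_list, function(m) {
                   mm <- unclass(m)
                   attributes(mm) <- list(dim = dim(mm),
                                          dimnames = list(NULL, c("A", "B", "C", "D")))
                   mm
                 }),
                 n_harmonics = nrow(coeffs_list[[1]])),
            class = "nef")
}
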