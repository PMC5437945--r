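#' Covariance PCA of a trait matrix
#'
#' Column-centered, covariance-based principal component analysis, the
#' standard decomposition for Procrustes coordinates and for normalized
#' harmonic coefficients (traits share units within each block, so no
#' correlation scaling). Constant columns -- e.g. the normalized
#' invariants `A1`, `B1`, `C1` -- are dropped and recorded so they can be
#' restored on reconstruction. Component signs follow the convention that
#' each loading's largest-magnitude entry is positive.
#'
#' @param traits Samples x traits numeric matrix with unique column names.
#' @param drop_constant Drop near-zero-variance columns (var < 1e-12
#'   relative to the largest column variance).
#' @return A `pca_model`: `center` (trait means over all input columns),
#'   `loadings` (kept traits x components), `eigenvalues`, `scores`,
#'   `variance_fraction`, `kept`, `dropped` (named constants).
#' @export
fit_pca <- function(traits, drop_constant = TRUE) {
  X <- as.matrix(traits)
  if (is.null(colnames(X))) colnames(X) <- paste0("t", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("trait names must be unique")
  if (!all(is.finite(X))) stop("non-finite trait values")
  if (nrow(X) < 3L) stop("PCA needs at least 3 samples")
  v <- apply(X, 2L, stats::var)
  const <- v < 1e-12 * max(v, .Machine$double.eps)
  dropped <- colMeans(X[, const, drop = FALSE])
  if (drop_constant) {
    Xk <- X[, !const, drop = FALSE]
  } else {
    Xk <- X
    dropped <- numeric(0)
  }
  if (ncol(Xk) < 1L) {
    # all samples identical: documented degenerate case
    return(structure(list(center = colMeans(X),
                          loadings = matrix(0, 0, 0), eigenvalues = numeric(0),
                          scores = matrix(0, nrow(X), 0),
                          variance_fraction = numeric(0),
                          kept = character(0), dropped = dropped),
                     class = "pca_model"))
  }
  pc <- stats::prcomp(Xk, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  load <- pc$rotation
  scores <- pc$x
  # sign convention: largest-|entry| of each loading positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(center = colMeans(X), loadings = load, eigenvalues = eig,
                 scores = scores, variance_fraction = eig / sum(eig),
                 kept = colnames(Xk), dropped = dropped),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(4L, length(x$variance_fraction))
  cat("pca_model:", nrow(x$scores), "samples,", length(x$kept), "traits\n")
  if (k)
    cat("  variance explained (PC1..PC", k, "): ",
        paste(sprintf("%.1f%%", 100 * x$variance_fraction[seq_len(k)]),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Trait vector along a principal component
#'
#' Mean plus `sd_multiplier` standard deviations (sqrt of the component's
#' eigenvalue) along the component's loading, with dropped constant traits
#' restored — the generic step behind both eigenleaf representations.
#'
#' @param model A `pca_model`.
#' @param pc Component index.
#' @param sd_multiplier Displacement in SD units.
#' @return Named trait vector in the original column order.
#' @keywords internal
pca_trait_vector <- function(model, pc, sd_multiplier) {
  stopifnot(inherits(model, "pca_model"))
  if (pc < 1L || pc > ncol(model$loadings)) stop("pc out of range")
  v <- model$center
  delta <- sd_multiplier * sqrt(model$eigenvalues[pc]) * model$loadings[, pc]
  v[model$kept] <- v[model$kept] + delta
  v
}

#' Eigenleaf as a landmark configuration
#'
#' Theoretical leaf shape at a stated displacement along a principal
#' component of Procrustes-aligned coordinates.
#'
#' @param model `pca_model` fitted on a 30-trait `x1..x15, y1..y15` matrix.
#' @param pc Component index.
#' @param sd_multiplier Displacement in SD units (0 gives the mean shape).
#' @return `15 x 2` landmark matrix.
#' @export
eigenleaf_landmarks <- function(model, pc, sd_multiplier) {
  v <- pca_trait_vector(model, pc, sd_multiplier)
  nms <- names(v)
  p <- length(v) / 2L
  if (!setequal(nms, c(paste0("x", 1:p), paste0("y", 1:p))))
    stop("model was not fitted on landmark traits (x1..y15)")
  cbind(x = v[paste0("x", 1:p)], y = v[paste0("y", 1:p)])
}

#' Eigenleaf as a contour
#'
#' Theoretical leaf outline at a stated displacement along a principal
#' component of normalized harmonic coefficients: the displaced trait
#' vector is reassembled into `efd_coeffs` (constant columns restored at
#' their constant values) and reconstructed.
#'
#' @param model `pca_model` fitted on an `A1..D<n>` coefficient matrix.
#' @param pc Component index.
#' @param sd_multiplier Displacement in SD units.
#' @param n_points Contour samples.
#' @return `n_points x 2` contour.
#' @export
eigenleaf_contour <- function(model, pc, sd_multiplier, n_points = 360L) {
  v <- pca_trait_vector(model, pc, sd_multiplier)
  nh <- length(v) / 4L
  need <- c(paste0("A", 1:nh), paste0("B", 1:nh),
            paste0("C", 1:nh), paste0("D", 1:nh))
  if (!setequal(names(v), need))
    stop("model was not fitted on harmonic-coefficient traits (A1..D_n)")
  m <- cbind(A = v[paste0("A", 1:nh)], B = v[paste0("B", 1:nh)],
             C = v[paste0("C", 1:nh)], D = v[paste0("D", 1:nh)])
  reconstruct_contour(efd_coeffs(m, normalized = TRUE), n_use = nh,
                      n_points = n_points)
}
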