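#' Centroid size of a landmark configuration
#'
#' The size measure removed by Procrustes superimposition: the square root
#' of the summed squared distances of the landmarks from their centroid.
#'
#' @param config Numeric `p x 2` matrix of landmarks.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  config <- .as_config(config)
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs < .Machine$double.eps * 1e3)
    stop("degenerate configuration: all landmarks coincident")
  cs
}

.as_config <- function(config) {
  config <- as.matrix(config)
  if (ncol(config) != 2L) stop("configuration must have 2 columns (x, y)")
  if (!all(is.finite(config))) stop("non-finite landmark coordinates")
  config
}

.center_unit <- function(config) {
  config <- scale(config, scale = FALSE)
  attr(config, "scaled:center") <- NULL
  config / sqrt(sum(config^2))
}

#' Optimal superimposition of one configuration onto another
#'
#' Centers both configurations, scales each to unit centroid size, and
#' finds the orthogonal map (rotation, or rotation + reflection when
#' `allow_reflection`) and scale minimising the summed squared distance of
#' the transformed second configuration to the first. The minimised
#' root-sum-of-squares between the unit-size shapes is the full Procrustes
#' distance.
#'
#' @param A,B `p x 2` landmark matrices (same p).
#' @param allow_reflection Permit an orientation-reversing map.
#' @return List: `rotation` (2 x 2 orthogonal), `scale`, `translation`
#'   (applied as `scale * B %*% rotation + translation` on the raw `B`),
#'   `distance` (full Procrustes distance), `B_aligned` (unit-size aligned
#'   copy of B in A's frame).
#' @export
align_pair <- function(A, B, allow_reflection = TRUE) {
  A <- .as_config(A); B <- .as_config(B)
  if (nrow(A) != nrow(B)) stop("configurations differ in landmark count")
  csA <- centroid_size(A); csB <- centroid_size(B)
  Ac <- .center_unit(A); Bc <- .center_unit(B)
  M <- crossprod(Bc, Ac)
  sv <- svd(M)
  d <- sv$d
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    # constrain to a proper rotation: flip the smallest singular direction
    sgn <- diag(c(1, -1))
    R <- sv$u %*% sgn %*% t(sv$v)
    d[2] <- -d[2]
  } else if (allow_reflection && det(R) < 0 && abs(d[2]) < 1e-12) {
    # tie: reflection gains nothing; prefer determinant +1
    sgn <- diag(c(1, -1))
    R2 <- sv$u %*% sgn %*% t(sv$v)
    if (det(R2) > 0) R <- R2
  }
  beta <- sum(d)                     # optimal scale for unit-size shapes
  dist2 <- max(0, 1 - beta^2)
  Baligned <- beta * (Bc %*% R)
  cA <- colMeans(A)
  scale_raw <- beta * csA / csB
  translation <- cA - scale_raw * (colMeans(B) %*% R)
  list(rotation = R, scale = scale_raw, translation = as.numeric(translation),
       distance = sqrt(dist2), B_aligned = Baligned)
}

#' Generalized Procrustes analysis
#'
#' Iterative full-Procrustes superimposition of a set of landmark
#' configurations: every configuration is centered and scaled to unit
#' centroid size, then repeatedly rotated (reflection permitted by default)
#' and rescaled onto the current mean shape; the mean is re-estimated and
#' re-unit-sized until it stops moving.
#'
#' @param lt A [landmark_table()], or a `p x 2 x n` array, or a list of
#'   `p x 2` matrices.
#' @param allow_reflection Permit orientation-reversing superimposition.
#' @param tol Convergence tolerance on the Frobenius movement of the mean.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @return A `gpa` object: `aligned` (`p x 2 x n` array), `mean_shape`
#'   (`p x 2`, centroid at the origin, unit centroid size),
#'   `centroid_sizes`, `residual_distances` (full Procrustes distance of
#'   each aligned shape to the mean), `iterations`, `converged`,
#'   `objective_trace` (summed squared deviations from the mean after each
#'   iteration), and the `records` carried over from a landmark table
#'   input.
#' @export
gpa <- function(lt, allow_reflection = TRUE, tol = 1e-10, max_iter = 200L) {
  records <- NULL
  if (inherits(lt, "landmark_table")) {
    records <- lt$records
    arr <- lt$coords
  } else if (is.list(lt) && !is.array(lt)) {
    arr <- array(unlist(lapply(lt, .as_config)),
                 c(nrow(lt[[1]]), 2L, length(lt)))
  } else {
    arr <- lt
  }
  stopifnot(length(dim(arr)) == 3L, dim(arr)[2] == 2L)
  n <- dim(arr)[3]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  sizes <- apply(arr, 3L, centroid_size)
  aligned <- array(apply(arr, 3L, function(m) .center_unit(.as_config(m))),
                   dim(arr))
  mean_shape <- aligned[, , 1]
  iterations <- 0L; converged <- FALSE
  objective_trace <- numeric(0)
  repeat {
    iterations <- iterations + 1L
    for (i in seq_len(n)) {
      fit <- align_pair(mean_shape, aligned[, , i],
                        allow_reflection = allow_reflection)
      aligned[, , i] <- fit$B_aligned
    }
    new_mean <- apply(aligned, c(1, 2), mean)
    new_mean <- .center_unit(new_mean)
    objective_trace <- c(objective_trace,
                         sum(sweep(aligned, c(1, 2), new_mean)^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
    if (iterations >= max_iter) break
  }
  resid <- apply(aligned, 3L, function(m)
    align_pair(mean_shape, m, allow_reflection = allow_reflection)$distance)
  dimnames(aligned) <- dimnames(arr)
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = sizes, residual_distances = resid,
                 iterations = iterations, converged = converged,
                 objective_trace = objective_trace, records = records),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat("gpa:", dim(x$aligned)[3], "configurations,",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  mean residual full-Procrustes distance:",
      signif(mean(x$residual_distances), 4), "\n")
  invisible(x)
}

#' Procrustes-aligned coordinates as a trait matrix
#'
#' Flattens the aligned configurations of a [gpa()] fit into a samples x
#' traits matrix with columns `x1..x15, y1..y15`, the input expected by
#' [fit_pca()], [fit_lda()] and [spearman_matrix()].
#'
#' @param g A `gpa` object.
#' @return Numeric matrix with named columns and leaf ids as row names.
#' @export
gpa_trait_matrix <- function(g) {
  stopifnot(inherits(g, "gpa"))
  p <- dim(g$aligned)[1]; n <- dim(g$aligned)[3]
  out <- t(apply(g$aligned, 3L, function(m) c(m[, 1], m[, 2])))
  colnames(out) <- c(paste0("x", seq_len(p)), paste0("y", seq_len(p)))
  rownames(out) <- dimnames(g$aligned)[[3]]
  out
}
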