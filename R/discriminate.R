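#' Fit a linear discriminant model
#'
#' Gaussian linear discriminant analysis with pooled within-class
#' covariance and observed class frequencies as priors. Near-constant
#' traits are screened out before fitting; if the pooled covariance is
#' numerically singular a ridge of `ridge * trace / dim` is added to its
#' diagonal (recorded in the fit).
#'
#' @param traits Samples x traits numeric matrix.
#' @param labels Class label per sample (coerced to factor).
#' @param ridge Relative ridge applied only on singularity.
#' @param compute_axes Whether to compute discriminant axes (skipped in
#'   tight cross-validation loops).
#' @param priors Optional named prior probabilities per class; default is
#'   the observed class frequencies of `labels`.
#' @param allow_singleton Permit classes with a single sample (they
#'   contribute a mean but no scatter); used by cross-validation folds
#'   where the held-out sample reduces its class to one member.
#' @return An `lda_model`: `labels` (levels), `priors`, `means` (class x
#'   trait), `cov_inv`, `kept`, `dropped`, `ridge_applied`, `axes`
#'   (discriminant directions).
#' @export
fit_lda <- function(traits, labels, ridge = 1e-8, compute_axes = TRUE,
                    priors = NULL, allow_singleton = FALSE) {
  X <- as.matrix(traits)
  if (is.null(colnames(X))) colnames(X) <- paste0("t", seq_len(ncol(X)))
  labels <- factor(labels)
  if (nrow(X) != length(labels)) stop("traits and labels differ in length")
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes")
  small <- names(tab)[tab < 2L]
  if (length(small) && !allow_singleton)
    stop("classes with fewer than 2 samples: ", paste(small, collapse = ", "))
  if (nrow(X) - length(tab) < 1L)
    stop("no residual degrees of freedom for the pooled covariance")
  v <- apply(X, 2L, stats::var)
  keep <- v >= 1e-12 * max(v, .Machine$double.eps)
  if (!any(keep)) stop("all traits are constant")
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  lv <- levels(labels)
  k <- length(lv)
  means <- matrix(0, k, p, dimnames = list(lv, colnames(X)))
  W <- matrix(0, p, p)
  for (g in lv) {
    Xg <- X[labels == g, , drop = FALSE]
    means[g, ] <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2L, means[g, ]))
  }
  W <- W / (nrow(X) - k)
  ridge_applied <- 0
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch) || kappa(ch, exact = FALSE) > 1e12) {
    ridge_applied <- ridge * sum(diag(W)) / p
    ch <- chol(W + diag(ridge_applied, p))
  }
  cov_inv <- chol2inv(ch)
  if (is.null(priors)) {
    priors <- as.numeric(tab[lv]) / length(labels)
    names(priors) <- lv
  } else {
    if (!all(lv %in% names(priors))) stop("priors must cover every class")
    priors <- priors[lv] / sum(priors[lv])
  }
  axes <- NULL
  if (compute_axes) {
    # discriminant axes: eigenvectors of W^-1 B (between-class scatter)
    gm <- colMeans(X)
    B <- crossprod(sweep(means, 2L, gm) * sqrt(as.numeric(tab[lv])))
    ev <- eigen(cov_inv %*% B, symmetric = FALSE)
    naxes <- min(k - 1L, p)
    axes <- Re(ev$vectors[, seq_len(naxes), drop = FALSE])
  }
  structure(list(labels = lv, priors = priors, means = means,
                 cov_inv = cov_inv, kept = colnames(X), dropped = dropped,
                 ridge_applied = ridge_applied, axes = axes),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("lda_model:", length(x$labels), "classes,", length(x$kept), "traits")
  if (x$ridge_applied > 0) cat(" (ridge-stabilized)")
  cat("\n")
  invisible(x)
}

#' Predict classes from a fitted linear discriminant model
#'
#' Maximum-posterior rule under equal-covariance Gaussians with the
#' fitted priors.
#'
#' @param object An `lda_model`.
#' @param newdata Samples x traits matrix (screened columns are selected
#'   by name when present).
#' @param ... Unused.
#' @return List: `class` (factor), `posterior` (samples x classes).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && all(object$kept %in% colnames(X)))
    X <- X[, object$kept, drop = FALSE]
  if (ncol(X) != length(object$kept))
    stop("newdata does not match the fitted traits")
  k <- length(object$labels)
  disc <- matrix(0, nrow(X), k)
  for (g in seq_len(k)) {
    mu <- object$means[g, ]
    d <- sweep(X, 2L, mu)
    disc[, g] <- -0.5 * rowSums((d %*% object$cov_inv) * d) +
      log(object$priors[g])
  }
  disc <- disc - apply(disc, 1L, max)
  post <- exp(disc)
  post <- post / rowSums(post)
  colnames(post) <- object$labels
  cls <- factor(object$labels[max.col(post, ties.method = "first")],
                levels = object$labels)
  list(class = cls, posterior = post)
}

#' Leave-one-out cross-validated prediction
#'
#' For every sample, a model fitted on all remaining samples predicts the
#' held-out one; each prediction comes from a model that never saw its
#' sample, compensating for unequal replication across classes. Priors
#' are the class frequencies of the full label vector (the convention of
#' the standard leave-one-out LDA implementation), so folds differ only
#' in their training rows.
#'
#' @param traits Samples x traits matrix.
#' @param labels Class per sample.
#' @param ridge Passed to [fit_lda()].
#' @return List: `class` (factor of LOO predictions), `posterior`,
#'   `accuracy` (overall proportion correct).
#' @export
loo_predict <- function(traits, labels, ridge = 1e-8) {
  X <- as.matrix(traits)
  labels <- factor(labels)
  n <- nrow(X)
  if (n != length(labels)) stop("traits and labels differ in length")
  lv <- levels(labels)
  full_priors <- table(labels) / n
  full_priors <- stats::setNames(as.numeric(full_priors), names(full_priors))
  preds <- character(n)
  post <- matrix(NA_real_, n, length(lv), dimnames = list(rownames(X), lv))
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_lda(X[-i, , drop = FALSE], labels[-i], ridge = ridge,
              compute_axes = FALSE, priors = full_priors,
              allow_singleton = TRUE),
      error = function(e)
        stop("LOO fold ", i, " (", rownames(X)[i] %||% i, "): ",
             conditionMessage(e), call. = FALSE))
    pr <- predict(fit, X[i, , drop = FALSE])
    preds[i] <- as.character(pr$class)
    post[i, colnames(pr$posterior)] <- pr$posterior[1, ]
  }
  cls <- factor(preds, levels = lv)
  list(class = cls, posterior = post,
       accuracy = mean(cls == labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion matrix of actual versus predicted labels
#'
#' @param actual,predicted Equal-length label vectors.
#' @return A `confusion_matrix`: `counts` and row-normalized `proportions`
#'   (rows = actual, columns = predicted; the union of observed labels on
#'   both axes).
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length")
  lv <- sort(unique(c(as.character(actual), as.character(predicted))))
  a <- factor(as.character(actual), levels = lv)
  p <- factor(as.character(predicted), levels = lv)
  counts <- table(actual = a, predicted = p)
  rs <- rowSums(counts)
  props <- sweep(unclass(counts), 1L, pmax(rs, 1L), "/")
  structure(list(counts = unclass(counts), proportions = props,
                 labels = lv),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat("confusion_matrix (row-normalized proportions):\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Spearman correlation of actual and predicted node positions
#'
#' Treats node position as ordinal: tie-corrected Spearman's rho between
#' actual and LOO-predicted node, with a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param actual,predicted Ordinal vectors (coercible to numeric).
#' @return List: `rho`, `p`, `n`.
#' @export
node_rank_rho <- function(actual, predicted) {
  a <- as.numeric(as.character(actual))
  b <- as.numeric(as.character(predicted))
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 5L) stop("need at least 5 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant vector: correlation undefined")
  rho <- stats::cor(a, b, method = "spearman")
  n <- length(a)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare feature sets by per-group LOO accuracy
#'
#' Runs leave-one-out LDA on the landmark traits, the harmonic traits,
#' and their column concatenation, then tabulates percent-correct per
#' group (e.g. per species, or per node) with the winning feature set.
#' Exact ties resolve Both > Landmark > EFD.
#'
#' @param landmark_traits,efd_traits Trait matrices over the same samples
#'   (matched by row names when present).
#' @param labels Class per sample (the prediction target).
#' @param group Grouping for the summary rows (default: the labels
#'   themselves).
#' @return A `feature_comparison` data frame: group, n, `landmark`,
#'   `efd`, `both` (percent correct), `max`.
#' @export
feature_set_comparison <- function(landmark_traits, efd_traits, labels,
                                   group = labels) {
  L <- as.matrix(landmark_traits)
  E <- as.matrix(efd_traits)
  if (nrow(L) != nrow(E)) stop("trait matrices differ in sample count")
  if (!is.null(rownames(L)) && !is.null(rownames(E))) {
    if (!setequal(rownames(L), rownames(E)))
      stop("sample ids differ between trait matrices")
    E <- E[rownames(L), , drop = FALSE]
  }
  labels <- factor(labels)
  group <- factor(group)
  sets <- list(landmark = L, efd = E, both = cbind(L, E))
  correct <- lapply(sets, function(X)
    loo_predict(X, labels)$class == labels)
  gtab <- table(group)
  singletons <- names(gtab)[gtab < 2L]
  if (length(singletons))
    warning("groups with a single sample excluded: ",
            paste(singletons, collapse = ", "))
  keep_groups <- names(gtab)[gtab >= 2L]
  rows <- lapply(keep_groups, function(g) {
    idx <- group == g
    acc <- vapply(correct, function(ok) 100 * mean(ok[idx]), 0)
    best <- c("both", "landmark", "efd")[
      which.max(acc[c("both", "landmark", "efd")])]
    data.frame(group = g, n = sum(idx),
               landmark = acc[["landmark"]], efd = acc[["efd"]],
               both = acc[["both"]],
               max = c(both = "Both", landmark = "Landmark",
                       efd = "EFD")[[best]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_comparison", class(out))
  out
}
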