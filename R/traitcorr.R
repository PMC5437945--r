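#' Pairwise Spearman correlation of traits
#'
#' Tie-corrected Spearman's rho between every pair of trait columns
#' (landmark coordinates and harmonic coefficients alike), with two-sided
#' p-values from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. Constant traits have
#' undefined correlations; their pairs are recorded as `NA` with a
#' warning.
#'
#' @param traits Samples x traits numeric matrix (>= 5 samples).
#' @return A `trait_corr`: `rho`, `p` (symmetric matrices), `n` (pairs
#'   used), `traits`.
#' @export
spearman_matrix <- function(traits) {
  X <- as.matrix(traits)
  if (is.null(colnames(X))) colnames(X) <- paste0("t", seq_len(ncol(X)))
  if (nrow(X) < 5L) stop("need at least 5 samples")
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const))
    warning("constant traits with undefined correlations: ",
            paste(colnames(X)[const], collapse = ", "))
  rho <- suppressWarnings(
    stats::cor(X, method = "spearman", use = "pairwise.complete.obs"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  diag(rho)[!const] <- 1
  n <- crossprod(!is.na(X))
  tstat <- rho * sqrt(pmax(n - 2, 0) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n - 2, 1))
  p[abs(rho) >= 1 - 1e-15] <- 0
  diag(p) <- 0
  p[is.na(rho)] <- NA_real_
  structure(list(rho = rho, p = p, n = n, traits = colnames(X)),
            class = "trait_corr")
}

#' @export
print.trait_corr <- function(x, ...) {
  cat("trait_corr:", length(x$traits), "traits\n")
  invisible(x)
}

#' Hierarchically cluster traits from their correlation structure
#'
#' Agglomerative clustering of traits on the dissimilarity
#' `d(i, j) = 1 - rho(i, j)` (signed; strongly anticorrelated traits are
#' maximally distant) or `1 - |rho|`. Traits with undefined correlations
#' are excluded first. Input columns are ordered lexicographically before
#' clustering so that the leaf order is deterministic under ties.
#'
#' @param corr A `trait_corr` from [spearman_matrix()].
#' @param linkage Linkage method for [stats::hclust()].
#' @param transform `"signed"` (`1 - rho`) or `"absolute"` (`1 - |rho|`).
#' @return A `trait_clustering`: `hclust` (the tree), `order` (trait
#'   names in dendrogram order), `distance`, `linkage`, `excluded`.
#' @export
cluster_traits <- function(corr, linkage = "complete",
                           transform = c("signed", "absolute")) {
  stopifnot(inherits(corr, "trait_corr"))
  transform <- match.arg(transform)
  rho <- corr$rho
  bad <- apply(is.na(rho), 1L, all) | is.na(diag(rho))
  keep <- sort(rownames(rho)[!bad])
  if (length(keep) < 2L) stop("need at least 2 traits with defined rho")
  rho <- rho[keep, keep]
  if (any(is.na(rho)))
    stop("undefined rho among clustered traits: ",
         paste(keep[apply(is.na(rho), 1L, any)], collapse = ", "))
  d <- if (transform == "signed") 1 - rho else 1 - abs(rho)
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  structure(list(hclust = hc, order = hc$labels[hc$order],
                 distance = paste0("1 - ",
                                   if (transform == "signed") "rho" else "|rho|"),
                 linkage = linkage,
                 excluded = rownames(corr$rho)[bad]),
            class = "trait_clustering")
}

#' @export
print.trait_clustering <- function(x, ...) {
  cat("trait_clustering:", length(x$order), "traits,", x$linkage,
      "linkage on", x$distance, "\n")
  invisible(x)
}

#' Write a trait clustering as Newick
#'
#' @param clustering A `trait_clustering`.
#' @param path Output path.
#' @export
write_clustering_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "trait_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Mean absolute correlation between two trait blocks
#'
#' Summary used to contrast the symmetric-shape block (A/D harmonic
#' coefficients) with the asymmetry block (B/C): when leaf asymmetry is
#' independent of everything else, B/C traits correlate with little
#' besides themselves.
#'
#' @param corr A `trait_corr`.
#' @param block1,block2 Character vectors of trait names.
#' @return Mean of `|rho|` over all (block1, block2) pairs with defined
#'   rho.
#' @export
block_mean_abs_rho <- function(corr, block1, block2) {
  stopifnot(inherits(corr, "trait_corr"))
  sub <- corr$rho[intersect(block1, corr$traits),
                  intersect(block2, corr$traits), drop = FALSE]
  if (identical(block1, block2)) sub[upper.tri(sub, diag = TRUE)] <- NA
  mean(abs(sub), na.rm = TRUE)
}
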