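#' Configuration for a full pipeline run
#'
#' Either a landmark table + outline source read from disk, or the
#' synthetic study template. The configuration is validated up front and
#' written verbatim into the run directory.
#'
#' @param landmark_path Optional path to a landmark table (with
#'   `landmark_dialect`); `NULL` to synthesize.
#' @param dialect A [landmark_dialect()] for `landmark_path`.
#' @param nef_path Optional path to pre-computed normalized coefficients
#'   (skips the forward transform).
#' @param synth List of synthesis settings (used when `landmark_path` is
#'   `NULL`): `separation`, `vines_per_species`, `nodes_per_vine`,
#'   `noise`, `asym_sd`.
#' @param n_harmonics Harmonic ranks for the EFD stage.
#' @param linkage,corr_transform Clustering options (see
#'   [cluster_traits()]).
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory (must not already exist).
#' @return A `run_config`.
#' @export
run_config <- function(landmark_path = NULL, dialect = landmark_dialect(),
                       nef_path = NULL,
                       synth = list(separation = 3, vines_per_species = 3L,
                                    nodes_per_vine = 10L, noise = 1,
                                    asym_sd = 0.03),
                       n_harmonics = 20L, linkage = "complete",
                       corr_transform = "signed", seed = 1L,
                       out_dir = tempfile("leafmorph_run_")) {
  if (!is.null(landmark_path) && !file.exists(landmark_path))
    stop("landmark_path does not exist: ", landmark_path)
  if (!is.null(nef_path) && !file.exists(nef_path))
    stop("nef_path does not exist: ", nef_path)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (dir.exists(out_dir)) stop("out_dir already exists: ", out_dir)
  structure(list(landmark_path = landmark_path, dialect = dialect,
                 nef_path = nef_path, synth = synth,
                 n_harmonics = as.integer(n_harmonics), linkage = linkage,
                 corr_transform = corr_transform, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full morphometric pipeline
#'
#' Ingest (or synthesize) leaves, superimpose landmarks by GPA, compute
#' normalized EFDs, fit both PCA morphospaces with eigenleaves, run
#' leave-one-out LDA for species and for node under each of the three
#' feature sets (landmark, EFD, both) with confusion matrices and
#' comparison tables, correlate all traits pairwise and cluster them,
#' and write every artifact plus a manifest into one immutable run
#' directory. Identical config + seed gives identical outputs.
#'
#' @param config A [run_config()].
#' @return The result list, invisibly; all artifacts are under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = out("run.log"), append = TRUE)
  # out_dir is implicit (the directory itself) and dropped so that two
  # runs with identical settings produce byte-identical artifacts
  jsonlite::write_json(config[!names(config) %in% c("dialect", "out_dir")],
                       out("config.json"), auto_unbox = TRUE, null = "null")
  set.seed(config$seed)

  ## stage 1: data
  if (is.null(config$landmark_path)) {
    sy <- config$synth
    specs <- default_species_specs(separation = sy$separation %||% 3)
    ds <- synth_dataset(specs,
                        vines_per_species = sy$vines_per_species %||% 3L,
                        nodes_per_vine = sy$nodes_per_vine %||% 10L,
                        noise = sy$noise %||% 1,
                        asym_sd = sy$asym_sd %||% 0.03,
                        seed = config$seed)
    lt <- ds$table; outlines <- ds$outlines
    utils::write.csv(ds$truth, out("ground_truth.csv"), row.names = FALSE)
    logf("synthesized %d leaves (%d species)", length(lt),
         length(unique(lt$records$species)))
  } else {
    lt <- read_landmark_table(config$landmark_path, config$dialect)
    outlines <- NULL
    logf("read %d leaves from %s", length(lt), config$landmark_path)
  }
  rec <- lt$records

  ## stage 2: GPA
  g <- gpa(lt)
  if (!g$converged) logf("WARNING: GPA did not converge")
  lm_traits <- gpa_trait_matrix(g)
  write_landmark_table(
    landmark_table(g$aligned, rec), out("procrustes_landmarks.csv"))
  logf("GPA: %d iterations, mean residual %.3g", g$iterations,
       mean(g$residual_distances))

  ## stage 3: EFDs
  if (!is.null(outlines)) {
    efd_traits <- efd_trait_matrix(outlines, n_harmonics = config$n_harmonics,
                                   ids = rec$leaf_id)
  } else if (!is.null(config$nef_path)) {
    nef <- read_nef(config$nef_path)
    efd_traits <- do.call(rbind, lapply(nef$coeffs, as.numeric))
    nh <- nef$n_harmonics
    colnames(efd_traits) <- c(paste0("A", 1:nh), paste0("B", 1:nh),
                              paste0("C", 1:nh), paste0("D", 1:nh))
    rownames(efd_traits) <- nef$ids
    efd_traits <- efd_traits[rec$leaf_id, , drop = FALSE]
  } else {
    stop("stage efd: no outlines and no nef_path")
  }
  nh <- config$n_harmonics
  coeff_list <- lapply(seq_len(nrow(efd_traits)), function(i)
    traits_to_efd(efd_traits[i, ], nh))
  write_nef(efd_to_nef(coeff_list, rec$leaf_id), out("normalized_efd.nef"))
  logf("EFD: %d harmonics, %d leaves", nh, nrow(efd_traits))

  ## stage 4: PCA morphospaces + eigenleaves
  pca_lm <- fit_pca(lm_traits)
  pca_efd <- fit_pca(efd_traits)
  if (length(pca_efd$kept) < 4L) {
    warning("only ", length(pca_efd$kept),
            " non-constant EFD traits after screening; ",
            "consider more harmonics")
    logf("WARNING: %d non-constant EFD traits", length(pca_efd$kept))
  }
  for (nm in c("lm", "efd")) {
    mod <- if (nm == "lm") pca_lm else pca_efd
    utils::write.csv(data.frame(pc = seq_along(mod$variance_fraction),
                                eigenvalue = mod$eigenvalues,
                                variance_fraction = mod$variance_fraction),
                     out(paste0("pca_", nm, "_variance.csv")),
                     row.names = FALSE)
    utils::write.csv(cbind(rec, mod$scores),
                     out(paste0("pca_", nm, "_scores.csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mod$loadings),
                     out(paste0("pca_", nm, "_loadings.csv")),
                     row.names = TRUE)
  }
  for (pc in seq_len(min(4L, ncol(pca_lm$loadings)))) {
    for (s in c(-1.5, 0, 1.5)) {
      utils::write.csv(as.data.frame(eigenleaf_landmarks(pca_lm, pc, s)),
                       out(sprintf("eigenleaf_landmarks_pc%d_%+.1fsd.csv",
                                   pc, s)), row.names = FALSE)
    }
  }
  for (pc in seq_len(min(4L, ncol(pca_efd$loadings)))) {
    for (s in c(-1, 0, 1)) {
      utils::write.csv(as.data.frame(eigenleaf_contour(pca_efd, pc, s)),
                       out(sprintf("eigenleaf_contour_pc%d_%+.1fsd.csv",
                                   pc, s)), row.names = FALSE)
    }
  }
  logf("PCA: landmark PC1-4 %.1f%%, EFD PC1-4 %.1f%%",
       100 * sum(pca_lm$variance_fraction[1:4]),
       100 * sum(pca_efd$variance_fraction[1:4]))

  ## stage 5: LOO-LDA, species and node, three feature sets
  sets <- list(landmark = lm_traits, efd = efd_traits,
               both = cbind(lm_traits, efd_traits))
  lda_summary <- list()
  for (target in c("species", "node")) {
    labels <- factor(rec[[target]])
    for (nm in names(sets)) {
      loo <- loo_predict(sets[[nm]], labels)
      cm <- confusion_matrix(labels, loo$class)
      utils::write.csv(cm$proportions,
                       out(sprintf("confusion_%s_%s.csv", target, nm)))
      entry <- list(accuracy = loo$accuracy)
      if (target == "node") {
        rr <- node_rank_rho(labels, loo$class)
        entry$rho <- rr$rho; entry$p <- rr$p
      }
      lda_summary[[target]][[nm]] <- entry
      logf("LOO-LDA %s/%s: accuracy %.3f", target, nm, loo$accuracy)
    }
    cmp <- feature_set_comparison(lm_traits, efd_traits, labels)
    utils::write.csv(cmp, out(sprintf("feature_comparison_%s.csv", target)),
                     row.names = FALSE)
  }

  ## stage 6: trait correlation + clustering
  both <- cbind(lm_traits, efd_traits)
  corr <- suppressWarnings(spearman_matrix(both))
  utils::write.csv(corr$rho, out("trait_rho.csv"))
  utils::write.csv(corr$p, out("trait_p.csv"))
  cl <- cluster_traits(corr, linkage = config$linkage,
                       transform = config$corr_transform)
  write_clustering_newick(cl, out("trait_clustering.nwk"))
  utils::write.csv(data.frame(order = cl$order),
                   out("trait_cluster_order.csv"), row.names = FALSE)
  logf("correlation: %d traits clustered, %d excluded",
       length(cl$order), length(cl$excluded))

  ## stage 7: replication summary + manifest
  repl <- stats::aggregate(node ~ vine + species, rec, max)
  names(repl)[3] <- "nodes_sampled"
  utils::write.csv(repl, out("replication_summary.csv"), row.names = FALSE)
  jsonlite::write_json(lda_summary, out("lda_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- data.frame(file = files,
                         md5 = as.character(tools::md5sum(out(files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(table = lt, gpa = g, lm_traits = lm_traits,
                 efd_traits = efd_traits, pca_landmark = pca_lm,
                 pca_efd = pca_efd, lda_summary = lda_summary,
                 corr = corr, clustering = cl, out_dir = config$out_dir))
}
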