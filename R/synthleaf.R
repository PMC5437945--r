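#' Parameters of a synthetic lobed leaf
#'
#' Generative parameters of a Passiflora-like, three-lobed leaf. The 15
#' homologous landmarks are derived from them: vein-base pairs at the
#' petiolar junction (1-2 for the midvein, 5-6 for the proximal veins),
#' distal vein bases on the midvein (3-4), lobe tips (7 and 15 proximal,
#' 9 and 13 distal, 11 the apex) at the stated lengths and angles, and
#' sinus points (8, 14 between proximal and distal lobes; 10, 12 between
#' distal lobes and apex) radially between adjacent tips at the stated
#' depth fraction.
#'
#' @param midvein_len Midvein length (length units; sets the leaf scale).
#' @param distal_lobe_len,proximal_lobe_len Lobe-tip radii.
#' @param distal_lobe_angle,proximal_lobe_angle Radians from the midvein,
#'   in `(0, pi/2)`; the proximal angle must exceed the distal one.
#' @param distal_sinus_depth,proximal_sinus_depth Sinus depth fractions in
#'   `[0, 1)`: 0 puts the sinus on the chord between adjacent tips' radii,
#'   values near 1 cut to the centroid.
#' @param vein_half_width Half the separation of each vein-base landmark
#'   pair; a vascular trait invisible to the blade outline.
#' @param asymmetry Dimensionless, in `(-1, 1)`; left-side lobe radii are
#'   scaled by `(1 + asymmetry)` and right-side radii by
#'   `1 / (1 + asymmetry)`, a balanced skew that is purely antisymmetric
#'   to first order (so it feeds the B/C harmonic coefficients, not the
#'   symmetric A/D shape). Negative values skew the other way; 0 is a
#'   perfectly symmetric leaf.
#' @param serration_amp Relative amplitude of a symmetric high-frequency
#'   margin ripple.
#' @param n_outline_points Outline samples (>= 64).
#' @return A `leaf_params` list.
#' @export
leaf_params <- function(midvein_len = 10, distal_lobe_len = 7,
                        proximal_lobe_len = 5, distal_lobe_angle = 0.55,
                        proximal_lobe_angle = 1.15,
                        distal_sinus_depth = 0.25,
                        proximal_sinus_depth = 0.2,
                        vein_half_width = 0.3, asymmetry = 0,
                        serration_amp = 0, n_outline_points = 500L) {
  p <- list(midvein_len = midvein_len, distal_lobe_len = distal_lobe_len,
            proximal_lobe_len = proximal_lobe_len,
            distal_lobe_angle = distal_lobe_angle,
            proximal_lobe_angle = proximal_lobe_angle,
            distal_sinus_depth = distal_sinus_depth,
            proximal_sinus_depth = proximal_sinus_depth,
            vein_half_width = vein_half_width, asymmetry = asymmetry,
            serration_amp = serration_amp,
            n_outline_points = as.integer(n_outline_points))
  validate_leaf_params(p)
  structure(p, class = "leaf_params")
}

validate_leaf_params <- function(p) {
  with(p, {
    if (any(c(midvein_len, distal_lobe_len, proximal_lobe_len,
              vein_half_width) <= 0))
      stop("lengths must be > 0")
    if (distal_sinus_depth < 0 || distal_sinus_depth >= 1 ||
        proximal_sinus_depth < 0 || proximal_sinus_depth >= 1)
      stop("sinus depths must be in [0, 1)")
    if (distal_lobe_angle <= 0 || distal_lobe_angle >= pi / 2 ||
        proximal_lobe_angle <= 0 || proximal_lobe_angle >= pi / 2)
      stop("lobe angles must be in (0, pi/2)")
    if (proximal_lobe_angle <= distal_lobe_angle)
      stop("proximal_lobe_angle must exceed distal_lobe_angle")
    if (asymmetry <= -1 || asymmetry >= 1)
      stop("asymmetry must lie in (-1, 1)")
    if (serration_amp < 0)
      stop("serration_amp must be >= 0")
    if (n_outline_points < 64L) stop("n_outline_points must be >= 64")
  })
  invisible(p)
}

# parameters that accept additive perturbation in the generator
.leaf_numeric_params <- c("midvein_len", "distal_lobe_len",
                          "proximal_lobe_len", "distal_lobe_angle",
                          "proximal_lobe_angle", "distal_sinus_depth",
                          "proximal_sinus_depth", "vein_half_width",
                          "asymmetry", "serration_amp")

#' Generate one synthetic leaf
#'
#' Builds the 15-landmark configuration and a matching closed outline from
#' a [leaf_params()] set. The outline is a periodic cubic interpolation
#' through the nine blade landmarks plus a basal closure point, with an
#' optional symmetric serration ripple; with `asymmetry = 0` it is
#' mirror-symmetric about the midvein, and asymmetry skews the two sides
#' in opposite directions so the perturbation is antisymmetric to first
#' order.
#'
#' @param params A `leaf_params`.
#' @param seed Unused by the deterministic construction but accepted so a
#'   per-leaf stream can thread through; the construction itself has no
#'   randomness.
#' @return List: `landmarks` (`15 x 2`), `outline`
#'   (`n_outline_points x 2`, counterclockwise, closed, first point not
#'   repeated).
#' @export
synth_leaf <- function(params, seed = NULL) {
  validate_leaf_params(params)
  p <- params
  L <- p$midvein_len; w <- p$vein_half_width
  asym_l <- 1 + p$asymmetry
  asym_r <- 1 / asym_l
  a_d <- p$distal_lobe_angle; a_p <- p$proximal_lobe_angle
  # blade points in polar form: angle phi from the +y (midvein) axis,
  # negative phi = left side; radius per point
  r_tip_d <- p$distal_lobe_len
  r_tip_p <- p$proximal_lobe_len
  phi_sin_pd <- (a_p + a_d) / 2          # sinus between proximal/distal tips
  phi_sin_da <- a_d / 2                   # sinus between distal tip and apex
  r_sin_pd <- (1 - p$proximal_sinus_depth) * (r_tip_p + r_tip_d) / 2
  r_sin_da <- (1 - p$distal_sinus_depth) * (r_tip_d + L) / 2
  blade <- rbind(
    c(-a_p, r_tip_p * asym_l),   # 7  proximal tip, left
    c(-phi_sin_pd, r_sin_pd * asym_l),  # 8
    c(-a_d, r_tip_d * asym_l),   # 9  distal tip, left
    c(-phi_sin_da, r_sin_da * asym_l),  # 10
    c(0, L),                     # 11 apex
    c(phi_sin_da, r_sin_da * asym_r),   # 12
    c(a_d, r_tip_d * asym_r),    # 13 distal tip, right
    c(phi_sin_pd, r_sin_pd * asym_r),   # 14
    c(a_p, r_tip_p * asym_r))    # 15 proximal tip, right
  pol2xy <- function(phi, r) cbind(r * sin(phi), r * cos(phi))
  blade_xy <- pol2xy(blade[, 1], blade[, 2])
  lm <- matrix(0, 15, 2)
  lm[1, ] <- c(-w, 0); lm[2, ] <- c(w, 0)
  lm[3, ] <- c(-w, 0.2 * L); lm[4, ] <- c(w, 0.2 * L)
  lm[5, ] <- c(-w, -w * sin(a_p)); lm[6, ] <- c(w, -w * sin(a_p))
  lm[7:15, ] <- blade_xy
  colnames(lm) <- c("x", "y")
  # outline knots counterclockwise: base -> right side up -> apex -> left
  # side down -> back to base
  base_pt <- c(0, -0.1 * L)
  knots <- rbind(base_pt, blade_xy[9:1, ])
  outline <- .periodic_spline_outline(knots, p$n_outline_points)
  if (p$serration_amp > 0) {
    phi <- atan2(outline[, 1], outline[, 2])
    outline <- outline * (1 + p$serration_amp * cos(24 * phi))
  }
  colnames(outline) <- c("x", "y")
  list(landmarks = lm, outline = outline)
}

.periodic_spline_outline <- function(knots, n_points) {
  closed <- rbind(knots, knots[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  tk <- c(0, cumsum(seg))
  total <- tk[length(tk)]
  tt <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- stats::spline(tk, closed[, 1], method = "periodic", xout = tt)$y
  y <- stats::spline(tk, closed[, 2], method = "periodic", xout = tt)$y
  cbind(x, y)
}

#' Species template for the synthetic generator
#'
#' @param species Species name.
#' @param class Class label (groups of species with similar shape).
#' @param mean_params A [leaf_params()] giving the species mean.
#' @param sds Named numeric vector of per-parameter SDs (subset of the
#'   numeric parameter names; unnamed parameters get SD 0).
#' @param gradient Named numeric vector of per-node additive shifts (the
#'   heteroblastic gradient), applied as `shift * (node - 1)`.
#' @return A `species_spec`.
#' @export
species_spec <- function(species, class, mean_params = leaf_params(),
                         sds = numeric(0), gradient = numeric(0)) {
  stopifnot(all(names(sds) %in% .leaf_numeric_params),
            all(names(gradient) %in% .leaf_numeric_params))
  if (length(sds) && any(sds < 0)) stop("SDs must be >= 0")
  structure(list(species = species, class = class,
                 mean_params = mean_params, sds = sds, gradient = gradient),
            class = "species_spec")
}

#' Default synthetic study template
#'
#' Eight species in four classes (two species per class), a monotone
#' heteroblastic gradient (deeper lobing and relatively longer distal
#' lobes at higher nodes, plus a slight vein-width trend), and leaf-level
#' asymmetry noise independent of species. `separation` is the minimum
#' pairwise distance between species mean parameters measured in
#' within-species SD units, where the per-parameter SD is the effective
#' within-species spread: sampling noise plus the variance the node
#' gradient induces across a vine (`nodes` nodes). The raw offset
#' patterns fix the directions in parameter space; they are rescaled as a
#' whole so the closest species pair sits exactly `separation` effective
#' SDs apart.
#'
#' @param separation Minimum between-species mean distance in effective
#'   within-species SD units (default 3).
#' @param nodes Nodes per vine assumed when computing the
#'   gradient-induced spread (default 10, the template's vine length).
#' @return List of eight [species_spec()] objects.
#' @export
default_species_specs <- function(separation = 3, nodes = 10L) {
  base <- leaf_params()
  # per-parameter sampling SDs (shared across species)
  sds <- c(midvein_len = 0.35, distal_lobe_len = 0.3,
           proximal_lobe_len = 0.25, distal_lobe_angle = 0.03,
           proximal_lobe_angle = 0.03, distal_sinus_depth = 0.03,
           proximal_sinus_depth = 0.03, vein_half_width = 0.02)
  gradient <- c(distal_sinus_depth = 0.012, distal_lobe_len = 0.06,
                proximal_sinus_depth = 0.006, vein_half_width = -0.004)
  # effective within-species SD: noise + gradient spread along the vine
  eff <- sds
  node_sd <- stats::sd(seq_len(max(nodes, 2L)))
  for (nm in names(gradient))
    eff[nm] <- sqrt(eff[nm]^2 + (gradient[[nm]] * node_sd)^2)
  # species offset directions in effective-SD units (unnamed params 0);
  # pairs within a class share the sign pattern but differ in magnitude
  offs <- list(
    sp1 = c(midvein_len =  1.0, distal_lobe_len = -0.6),
    sp2 = c(midvein_len =  1.4, distal_lobe_len = -0.2,
            proximal_lobe_angle = 1.1),
    sp3 = c(distal_sinus_depth =  1.0, distal_lobe_angle =  0.7),
    sp4 = c(distal_sinus_depth =  1.3, distal_lobe_angle = -0.4,
            proximal_lobe_len = 0.9),
    sp5 = c(proximal_lobe_len = -1.0, proximal_sinus_depth = 0.8),
    sp6 = c(proximal_lobe_len = -1.2, proximal_sinus_depth = 1.2,
            midvein_len = -0.8),
    sp7 = c(distal_lobe_len =  1.0, vein_half_width =  1.0,
            distal_sinus_depth = -0.6),
    sp8 = c(distal_lobe_len =  0.6, vein_half_width =  1.8,
            distal_sinus_depth = -1.2, distal_lobe_angle = 0.5))
  classes <- rep(c("A", "B", "C", "D"), each = 2)
  # rescale the whole pattern so the closest pair is `separation` SDs apart
  omat <- matrix(0, length(offs), length(eff),
                 dimnames = list(names(offs), names(eff)))
  for (i in seq_along(offs)) omat[i, names(offs[[i]])] <- offs[[i]]
  dmin <- min(stats::dist(omat))
  omat <- omat * (separation / dmin)
  specs <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    mp <- base
    for (nm in colnames(omat))
      mp[[nm]] <- mp[[nm]] + omat[i, nm] * eff[[nm]]
    specs[[i]] <- species_spec(paste0("sp", i), classes[i],
                               do.call(leaf_params, mp[.leaf_numeric_params]),
                               sds = sds, gradient = gradient)
  }
  specs
}

#' Generate a synthetic leaf dataset
#'
#' One leaf per node per vine per species. Per-leaf parameters are the
#' species mean plus the heteroblastic node gradient plus Gaussian noise
#' (per-parameter SDs scaled by `noise`), plus signed leaf-level
#' fluctuating asymmetry drawn as `N(0, asym_sd)` independent of species
#' (either side of a leaf may be the dominant one). A single integer seed
#' drives a per-leaf seed stream, so generation is deterministic and
#' insensitive to leaf order.
#'
#' @param specs List of [species_spec()].
#' @param vines_per_species Vines per species.
#' @param nodes_per_vine Nodes on each vine (single integer or range
#'   `c(min, max)`, sampled per vine; within `[2, 30]`).
#' @param noise Multiplier on the per-parameter SDs.
#' @param asym_sd SD of the signed leaf asymmetry.
#' @param seed Integer seed.
#' @return List: `table` (a [landmark_table()] with species/class/vine/node
#'   records), `outlines` (named list of contours), `truth` (data frame of
#'   sampled parameters per leaf).
#' @export
synth_dataset <- function(specs, vines_per_species = 3L,
                          nodes_per_vine = 10L, noise = 1,
                          asym_sd = 0.03, seed = 1L) {
  if (!length(specs)) stop("empty species spec list")
  if (length(specs) < 2L) stop("need at least 2 species")
  rng <- range(nodes_per_vine)
  if (rng[1] < 2L || rng[2] > 30L)
    stop("nodes_per_vine must lie within [2, 30]")
  set.seed(seed)
  layout <- list()
  for (s in seq_along(specs)) for (v in seq_len(vines_per_species)) {
    nn <- if (length(nodes_per_vine) > 1L)
      sample(seq(rng[1], rng[2]), 1L) else as.integer(nodes_per_vine)
    for (nd in seq_len(nn))
      layout[[length(layout) + 1L]] <- list(s = s, v = v, node = nd,
                                            nodes_on_vine = nn)
  }
  n <- length(layout)
  leaf_seeds <- sample.int(.Machine$integer.max - 1L, n)
  coords <- array(0, c(15L, 2L, n))
  outlines <- vector("list", n)
  recs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    li <- layout[[i]]
    sp <- specs[[li$s]]
    set.seed(leaf_seeds[i])
    p <- sp$mean_params
    for (nm in names(sp$gradient))
      p[[nm]] <- p[[nm]] + sp$gradient[[nm]] * (li$node - 1L)
    if (length(sp$sds) && noise > 0) {
      eps <- stats::rnorm(length(sp$sds), 0, noise * sp$sds)
      for (k in seq_along(sp$sds))
        p[[names(sp$sds)[k]]] <- p[[names(sp$sds)[k]]] + eps[k]
    }
    p$asymmetry <- p$asymmetry + stats::rnorm(1L, 0, asym_sd)
    p <- .clamp_params(p)
    leaf <- synth_leaf(do.call(leaf_params, unclass(p)))
    id <- sprintf("%s_v%d_n%02d", sp$species, li$v, li$node)
    coords[, , i] <- leaf$landmarks
    outlines[[i]] <- leaf$outline
    recs[[i]] <- data.frame(leaf_id = id, species = sp$species,
                            class = sp$class,
                            vine = sprintf("%s_v%d", sp$species, li$v),
                            node = li$node,
                            nodes_on_vine = li$nodes_on_vine,
                            stringsAsFactors = FALSE)
    truth[[i]] <- cbind(data.frame(leaf_id = id),
                        as.data.frame(p[.leaf_numeric_params]))
  }
  records <- do.call(rbind, recs)
  names(outlines) <- records$leaf_id
  list(table = landmark_table(coords, records), outlines = outlines,
       truth = do.call(rbind, truth))
}

.clamp_params <- function(p) {
  eps <- 1e-3
  pos <- c("midvein_len", "distal_lobe_len", "proximal_lobe_len",
           "vein_half_width")
  for (nm in pos) p[[nm]] <- max(p[[nm]], eps)
  p$distal_sinus_depth <- min(max(p$distal_sinus_depth, 0), 1 - eps)
  p$proximal_sinus_depth <- min(max(p$proximal_sinus_depth, 0), 1 - eps)
  p$distal_lobe_angle <- min(max(p$distal_lobe_angle, eps), pi / 2 - 2 * eps)
  p$proximal_lobe_angle <- min(max(p$proximal_lobe_angle,
                                   p$distal_lobe_angle + eps), pi / 2 - eps)
  p$asymmetry <- min(max(p$asymmetry, -0.9), 0.9)
  p$serration_amp <- max(p$serration_amp, 0)
  p
}
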