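# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Fourier coefficients of the arc-length parameterization of a closed
# polygon, by per-segment adaptive quadrature of x(t)cos / x(t)sin etc.
# (On each segment x(t) is linear, so integrate() is fully adaptive and
# independent of the closed-form line-integral implementation.)
quad_efd <- function(contour, n_harmonics, rel_tol = 1e-9) {
  pts <- rbind(contour, contour[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  tk <- c(0, cumsum(seg))
  Tt <- tk[length(tk)]
  interp <- function(t, col) {
    i <- findInterval(t, tk, rightmost.closed = TRUE)
    i <- pmin(i, length(seg))
    w <- (t - tk[i]) / seg[i]
    (1 - w) * pts[i, col] + w * pts[i + 1L, col]
  }
  out <- matrix(0, n_harmonics, 4L,
                dimnames = list(NULL, c("A", "B", "C", "D")))
  for (n in seq_len(n_harmonics)) {
    for (coef in 1:4) {
      col <- if (coef <= 2) 1L else 2L
      trig <- if (coef %% 2 == 1) cos else sin
      f <- function(t) interp(t, col) * trig(2 * pi * n * t / Tt)
      # integrate segment-wise: integrand is smooth within each segment
      val <- 0
      for (s in seq_along(seg)) {
        val <- val + stats::integrate(f, tk[s], tk[s + 1L],
                                      rel.tol = rel_tol,
                                      abs.tol = 1e-12)$value
      }
      out[n, coef] <- 2 / Tt * val
    }
  }
  out
}

# random star-shaped polygon around the origin (simple by construction)
rand_polygon <- function(k = 20L, rmin = 0.5, rmax = 1.5) {
  ang <- sort(stats::runif(k, 0, 2 * pi))
  r <- stats::runif(k, rmin, rmax)
  cbind(r * cos(ang), r * sin(ang))
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

apply_similarity <- function(pts, angle = 0, scale = 1, shift = c(0, 0),
                             reflect = FALSE) {
  m <- pts
  if (reflect) m <- m %*% diag(c(-1, 1))
  scale * m %*% rot2(angle) + matrix(shift, nrow(m), 2, byrow = TRUE)
}

# full-Procrustes distance between two configurations by brute-force grid
# over the rotation angle (and optionally reflection)
brute_procrustes_distance <- function(A, B, allow_reflection = TRUE,
                                      step = 1e-3) {
  cu <- function(m) {
    m <- scale(m, scale = FALSE)
    m / sqrt(sum(m^2))
  }
  A <- cu(A)
  best <- Inf
  angles <- seq(0, 2 * pi, by = step)
  for (refl in if (allow_reflection) c(FALSE, TRUE) else FALSE) {
    Br <- if (refl) B %*% diag(c(-1, 1)) else B
    Bc <- cu(Br)
    for (a in angles) {
      Brot <- Bc %*% rot2(a)
      # optimal scale for centered unit-size shapes: <A, Brot>
      beta <- sum(A * Brot)
      d2 <- 1 - max(beta, 0)^2
      if (d2 < best) best <- d2
    }
  }
  sqrt(max(best, 0))
}

# GPA mean for 2-3 small configurations by gridding rotations (and
# reflections) of shapes 2..m against shape 1, scale handled
# analytically, coarse-to-fine
brute_gpa_mean <- function(configs, coarse = 0.05, fine = 5e-4,
                           allow_reflection = TRUE) {
  cu <- function(m) {
    m <- scale(m, scale = FALSE)
    m / sqrt(sum(m^2))
  }
  configs <- lapply(configs, cu)
  m <- length(configs)
  mirror <- diag(c(-1, 1))
  rotated <- function(angles, refl) {
    shapes <- list(configs[[1]])
    for (j in 2:m) {
      s <- configs[[j]]
      if (refl[j - 1L]) s <- s %*% mirror
      shapes[[j]] <- s %*% rot2(angles[j - 1L])
    }
    shapes
  }
  # full-Procrustes objective with unit-norm mean and optimal per-shape
  # scale: sum_i (1 - <mu, s_i>^2), minimized over unit mu by the leading
  # left singular vector of the stacked shape vectors, giving m - sigma1^2
  objective <- function(angles, refl) {
    S <- vapply(rotated(angles, refl), as.numeric,
                numeric(2L * nrow(configs[[1]])))
    m - svd(S, nu = 0, nv = 0)$d[1]^2
  }
  grid_opt <- function(centers, width, step, refl) {
    grids <- lapply(centers, function(cc) seq(cc - width, cc + width, by = step))
    best <- NULL; bestv <- Inf
    combos <- expand.grid(grids)
    for (r in seq_len(nrow(combos))) {
      v <- objective(as.numeric(combos[r, ]), refl)
      if (v < bestv) { bestv <- v; best <- as.numeric(combos[r, ]) }
    }
    list(angles = best, value = bestv)
  }
  refl_opts <- if (allow_reflection) {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m - 1L)))
  } else {
    matrix(FALSE, 1L, m - 1L)
  }
  best <- NULL; bestv <- Inf; best_refl <- NULL
  for (rr in seq_len(nrow(refl_opts))) {
    refl <- refl_opts[rr, ]
    a <- grid_opt(rep(pi, m - 1L), pi, coarse, refl)
    a <- grid_opt(a$angles, 2 * coarse, coarse / 10, refl)
    a <- grid_opt(a$angles, coarse / 5, fine, refl)
    if (a$value < bestv) {
      bestv <- a$value; best <- a$angles; best_refl <- refl
    }
  }
  S <- vapply(rotated(best, best_refl), as.numeric,
              numeric(2L * nrow(configs[[1]])))
  mu <- matrix(svd(S)$u[, 1], nrow(configs[[1]]), 2L)
  mu <- scale(mu, scale = FALSE)
  mu / sqrt(sum(mu^2))
}

# Procrustes distance between two shapes modulo rotation/reflection/scale,
# used to compare mean shapes from different algorithms
shape_distance <- function(A, B) {
  leafmorph::align_pair(A, B, allow_reflection = TRUE)$distance
}

hausdorff <- function(P, Q) {
  dd <- function(X, Y) {
    max(apply(X, 1L, function(p) min(sqrt((Y[, 1] - p[1])^2 +
                                            (Y[, 2] - p[2])^2))))
  }
  max(dd(P, Q), dd(Q, P))
}

# distance from points to a closed polygon boundary (for containment with
# tolerance)
dist_to_polygon <- function(pts, poly) {
  closed <- rbind(poly, poly[1, ])
  apply(pts, 1L, function(p) {
    a <- closed[-nrow(closed), , drop = FALSE]
    b <- closed[-1, , drop = FALSE]
    ab <- b - a
    t <- pmin(pmax(rowSums(sweep(a, 2, p) * -ab) / rowSums(ab^2), 0), 1)
    proj <- a + ab * t
    min(sqrt((proj[, 1] - p[1])^2 + (proj[, 2] - p[2])^2))
  })
}
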