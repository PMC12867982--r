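# Positional fluctuation and solvent-accessible surface-area observables.

# Kabsch optimal rotation aligning moving (n x 3) onto fixed (n x 3),
# both pre-centred; returns the rotation matrix (proper, det +1)
kabsch_rotation <- function(moving, fixed, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(moving))
  A <- crossprod(moving * w, fixed)
  s <- svd(A)
  d <- sign(det(s$v %*% t(s$u)))
  # returns R with moving %*% R ~ fixed
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# superpose each frame of coords (p x 3 x f) onto ref using selection rows
superpose_frames <- function(coords, ref, sel, w_sel = NULL) {
  nf <- dim(coords)[3]
  out <- coords
  ref_c <- colMeans(ref[sel, , drop = FALSE])
  ref0 <- sweep(ref[sel, , drop = FALSE], 2, ref_c)
  for (f in seq_len(nf)) {
    mob <- coords[, , f]
    mc <- colMeans(mob[sel, , drop = FALSE])
    R <- kabsch_rotation(sweep(mob[sel, , drop = FALSE], 2, mc), ref0, w_sel)
    out[, , f] <- sweep(sweep(mob, 2, mc) %*% R, 2, ref_c, "+")
  }
  out
}

#' Per-residue root-mean-square fluctuations
#'
#' Each frame is superposed onto the weighted mean structure by optimal
#' least-squares (Kabsch) rotation using the `superpose_selection` particles,
#' iterating superposition and mean until the mean converges. RMSF is
#' \eqn{\sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}} per particle,
#' using frame weights.
#'
#' @param ensemble a [conformer_ensemble()] with >= 2 frames.
#' @param superpose_selection integer particle indices used for the fit
#'   (default: the five CA particles nearest the core attachment, i.e. the
#'   "core" end of the lid).
#' @param max_iter,tol mean-structure iteration controls.
#' @return a tibble `(index, role, residue, rmsf_A)`.
#' @export
rmsf <- function(ensemble, superpose_selection = NULL, max_iter = 10,
                 tol = 1e-6) {
  nf <- n_frames(ensemble)
  if (nf < 2) {
    stop_lidfold("rmsf needs at least 2 frames", "lidfold_invalid_config")
  }
  parts <- ensemble$particles
  sel <- superpose_selection %||% {
    ca <- which(parts$role == "CA")
    tail(ca, 5)
  }
  ref <- ensemble$coords[, , 1]
  if (max(apply(ref[sel, , drop = FALSE], 2, function(z) diff(range(z)))) <
      1e-9) {
    stop_lidfold("degenerate superpose selection (coincident particles)",
                 "lidfold_degenerate_selection")
  }
  w <- ensemble$weights
  coords <- ensemble$coords
  for (it in seq_len(max_iter)) {
    aligned <- superpose_frames(coords, ref, sel)
    mean_new <- apply(sweep(aligned, 3, w, "*"), c(1, 2), sum)
    if (max(abs(mean_new - ref)) < tol) {
      ref <- mean_new
      break
    }
    ref <- mean_new
  }
  aligned <- superpose_frames(coords, ref, sel)
  dev2 <- apply(aligned, 3, function(fr) rowSums((fr - ref)^2))
  msf <- as.vector(dev2 %*% w)
  tibble(index = parts$index, role = parts$role, residue = parts$residue,
         rmsf_A = sqrt(msf))
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Test points on each particle's solvent-expanded sphere (radius + probe)
#' are checked for occlusion by neighbouring expanded spheres; the SASA is
#' the unoccluded fraction times \eqn{4\pi(r+p)^2}.
#'
#' @param frame coordinate matrix `(n, 3)`.
#' @param radii numeric vector of particle radii (Angstrom), length n.
#' @param probe_radius solvent probe radius (default 1.4).
#' @param n_sphere_points test points per particle (>= 64).
#' @return numeric vector of per-particle SASA in Angstrom^2.
#' @export
sasa <- function(frame, radii, probe_radius = 1.4, n_sphere_points = 960) {
  n <- nrow(frame)
  if (length(radii) != n || anyNA(radii)) {
    stop_lidfold("a radius is required for every particle",
                 "lidfold_missing_radius")
  }
  if (n_sphere_points < 64) {
    stop_lidfold("n_sphere_points must be >= 64", "lidfold_invalid_config")
  }
  pts <- sphere_points(n_sphere_points)
  rext <- radii + probe_radius
  d2 <- as.matrix(dist(frame))^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    test <- sweep(pts * rext[i], 2, frame[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj <- sweep(test, 2, frame[j, ])
      free <- free & (rowSums(dj^2) > rext[j]^2)
      if (!any(free)) break
    }
    out[i] <- mean(free) * 4 * pi * rext[i]^2
  }
  out
}

# default bead radii by particle role
default_radii <- function(particles) {
  unname(c(CA = 2.2, ANC = 2.2, LIG = 2.0)[particles$role])
}

# ensemble-average hydrophobic SASA (optionally subsampled for speed)
mean_hydrophobic_sasa <- function(ensemble, hydrophobic, radii = NULL,
                                  probe_radius = 1.4, n_sphere_points = 240,
                                  max_frames = 250) {
  radii <- radii %||% default_radii(ensemble$particles)
  nf <- n_frames(ensemble)
  use <- if (nf > max_frames) {
    round(seq(1, nf, length.out = max_frames))
  } else {
    seq_len(nf)
  }
  vals <- vapply(use, function(f) {
    sum(sasa(ensemble$coords[, , f], radii, probe_radius,
             n_sphere_points)[hydrophobic])
  }, 1.0)
  list(values = vals, weights = ensemble$weights[use] /
         sum(ensemble$weights[use]))
}

#' Relative change in hydrophobic SASA between free and bound ensembles
#'
#' \eqn{100 (\langle SASA_h\rangle_{free} - \langle SASA_h\rangle_{bound}) /
#' \langle SASA_h\rangle_{free}} with a block-bootstrap uncertainty over
#' frames. Positive values mean burial upon binding.
#'
#' @param free_ens,bound_ens [conformer_ensemble()] objects sharing the
#'   hydrophobic classification.
#' @param hydrophobic integer particle indices of the hydrophobic class (they
#'   must resolve in both ensembles).
#' @param n_boot,n_blocks bootstrap replicates and contiguous blocks.
#' @param seed RNG seed for the bootstrap.
#' @param ... passed to the SASA evaluation (`radii`, `probe_radius`,
#'   `n_sphere_points`, `max_frames`).
#' @return a tibble `(percent_decrease, uncertainty)`.
#' @export
hydrophobic_sasa_change <- function(free_ens, bound_ens, hydrophobic,
                                    n_boot = 50, n_blocks = 10, seed = 1,
                                    ...) {
  np_f <- nrow(free_ens$particles)
  np_b <- nrow(bound_ens$particles)
  if (any(hydrophobic > min(np_f, np_b))) {
    stop_lidfold("hydrophobic classification inconsistent across ensembles",
                 "lidfold_topology_mismatch")
  }
  fs <- mean_hydrophobic_sasa(free_ens, hydrophobic, ...)
  bs <- mean_hydrophobic_sasa(bound_ens, hydrophobic, ...)
  m_free <- wmean(fs$values, fs$weights)
  if (m_free <= 0) {
    stop_lidfold("free-state hydrophobic SASA is zero",
                 "lidfold_degenerate_sasa")
  }
  m_bound <- wmean(bs$values, bs$weights)
  pct <- 100 * (m_free - m_bound) / m_free
  set.seed(derive_seed(seed, 0L))
  boot_mean <- function(s) {
    n <- length(s$values)
    nb <- min(n_blocks, n)
    blk <- block_index(n, nb)
    pick <- sample.int(nb, nb, replace = TRUE)
    rows <- unlist(lapply(pick, function(p) which(blk == p)))
    wmean(s$values[rows], s$weights[rows])
  }
  reps <- vapply(seq_len(n_boot), function(b) {
    bf <- boot_mean(fs)
    bb <- boot_mean(bs)
    100 * (bf - bb) / bf
  }, 1.0)
  tibble(percent_decrease = pct, uncertainty = sd(reps))
}
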