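# Metropolis sampling of the lid model and umbrella-window generation.

default_particle_table <- function(system) {
  n <- system$n_residues
  roles <- c(rep("CA", n), rep("ANC", 2),
             if (system$ligand_present) rep("LIG", 3))
  tibble(
    index = seq_along(roles),
    role = roles,
    residue = c(system$residue_start + seq_len(n) - 1L,
                rep(NA_integer_, length(roles) - n))
  )
}

#' Sample a conformational ensemble by Metropolis Monte Carlo
#'
#' One sweep = one single-torsion Metropolis proposal per pseudo-dihedral
#' (80 % local Gaussian steps, 20 % uniform jumps for ergodicity) plus, when a
#' ligand is present, five rigid-body translation/rotation proposals. The
#' acceptance rule is the standard Metropolis criterion
#' \eqn{\min\{1, e^{-\Delta U / k_BT}\}}, which satisfies detailed balance for
#' these symmetric proposals. Coordinates are rebuilt from torsions by serial
#' chain extension with fixed bond length and pseudo-bond angle.
#'
#' Identical `(system, n_sweeps, seed, bias)` yield identical ensembles.
#'
#' @param system a [lid_system()].
#' @param n_sweeps number of post-burn-in sweeps (>= 1).
#' @param seed integer seed (required; no default randomness).
#' @param bias optional harmonic bias on the two collective variables:
#'   a list with `center = c(extension_A, dihedral_deg)` and
#'   `k = c(k_ext, k_dih)` in kcal/mol/A^2 and kcal/mol/rad^2.
#' @param stride store one frame every `stride` sweeps.
#' @param burnin burn-in sweeps discarded before recording (default
#'   `n_sweeps %/% 5`).
#' @param init initial torsions: `"coil"`, `"helix"`, or a numeric vector.
#' @param cv a [cv_definition()] used for the bias and the recorded CV series.
#' @param step_deg torsion proposal width (degrees).
#' @return a [conformer_ensemble()] with torsions, coordinates, ligand poses
#'   (when present), uniform weights, and a `cv` tibble
#'   (`frame`, `extension_A`, `dihedral_deg`) in `$provenance$cv`.
#' @export
sample_ensemble <- function(system, n_sweeps, seed, bias = NULL, stride = 10,
                            burnin = NULL, init = "coil",
                            cv = cv_definition(system), step_deg = 30) {
  stopifnot(inherits(system, "lid_system"))
  if (n_sweeps < 1) {
    stop_lidfold("n_sweeps must be >= 1", "lidfold_invalid_config")
  }
  if (missing(seed)) {
    stop_lidfold("an explicit seed is required", "lidfold_invalid_config")
  }
  burnin <- burnin %||% (n_sweeps %/% 5L)
  nt <- n_torsions(system)
  init_tor <- if (is.character(init)) {
    switch(init,
      coil = rep(system$theta_c, nt),
      helix = rep(system$theta_h, nt),
      stop_lidfold("init must be 'coil', 'helix' or a numeric vector",
                   "lidfold_invalid_config")
    )
  } else {
    stopifnot(length(init) == nt)
    as.numeric(init)
  }
  has_bias <- !is.null(bias)
  bc <- if (has_bias) as.numeric(bias$center) else c(0, 0)
  bk <- if (has_bias) as.numeric(bias$k) else c(0, 0)
  if (has_bias && (length(bc) != 2 || length(bk) != 2 || any(bk < 0))) {
    stop_lidfold("bias needs center = c(ext, dih) and k = c(k_ext, k_dih) >= 0",
                 "lidfold_invalid_config")
  }

  set.seed(derive_seed(seed, 0L))
  raw <- mc_sample_chain(
    unclass(system), as.integer(n_sweeps), as.integer(stride),
    as.integer(burnin), has_bias, bc, bk,
    as.integer(cv$extension_groups$tip), as.integer(cv$extension_groups$base),
    init_tor, step_deg, 0.5, 15
  )
  particles <- default_particle_table(system)
  coords <- aperm(raw$coords, c(2, 1, 3)) # (particle, xyz, frame)
  cv_tbl <- tibble(
    frame = seq_len(nrow(raw$cv)),
    extension_A = raw$cv[, 1],
    dihedral_deg = raw$cv[, 2]
  )
  conformer_ensemble(
    coords, particles,
    torsions = raw$torsions,
    lig_pose = if (system$ligand_present) raw$lig_pose,
    system = system,
    provenance = list(
      seed = seed, n_sweeps = n_sweeps, stride = stride, burnin = burnin,
      bias = bias, cv = cv_tbl,
      acc_torsion = raw$acc_torsion, acc_ligand = raw$acc_ligand
    )
  )
}

#' Generate umbrella-sampling windows over the two collective variables
#'
#' Runs one biased [sample_ensemble()] per window centre with harmonic
#' restraints on lid extension and lid-core dihedral, and returns the
#' per-window CV series plus restraint metadata. Each window uses an
#' independent RNG stream derived from `(seed, window index)`.
#'
#' Windows whose samples never come within 3 standard deviations
#' (\eqn{\sigma = \sqrt{k_BT/k}}) of their centre on either axis are flagged
#' with `overlap_ok = FALSE` (poor overlap) and a warning.
#'
#' @param system a [lid_system()].
#' @param centers a data frame (or tibble) with columns `extension_A` and
#'   `dihedral_deg`, one row per window.
#' @param force_constants length-2: `c(k_ext, k_dih)` in kcal/mol/A^2 and
#'   kcal/mol/rad^2 (both > 0).
#' @param n_sweeps,seed,stride,burnin,init passed to [sample_ensemble()].
#' @param keep_ensembles store the full ensemble in each window (needed to
#'   reweight conformations afterwards), not just the CV series.
#' @return a list of `bias_window` objects.
#' @export
generate_bias_windows <- function(system, centers, force_constants, n_sweeps,
                                  seed, stride = 10, burnin = NULL,
                                  init = "coil", keep_ensembles = FALSE) {
  centers <- as_tibble(centers)
  if (nrow(centers) < 1) {
    stop_lidfold("at least one window centre is required",
                 "lidfold_invalid_config")
  }
  if (any(force_constants <= 0)) {
    stop_lidfold("force constants must be positive", "lidfold_invalid_config")
  }
  windows <- vector("list", nrow(centers))
  for (w in seq_len(nrow(centers))) {
    ctr <- c(centers$extension_A[w], centers$dihedral_deg[w])
    ens <- sample_ensemble(
      system, n_sweeps, seed = derive_seed(seed, w), stride = stride,
      burnin = burnin, init = init,
      bias = list(center = ctr, k = force_constants)
    )
    windows[[w]] <- bias_window(
      samples = ens$provenance$cv[, c("extension_A", "dihedral_deg")],
      center = ctr, force_constants = force_constants,
      temperature = system$temperature,
      ensemble = if (keep_ensembles) ens
    )
  }
  bad <- !vapply(windows, function(w) w$overlap_ok, TRUE)
  if (any(bad)) {
    warn(paste0("windows with poor overlap (no samples within 3 sigma of ",
                "centre): ", paste(which(bad), collapse = ", ")))
  }
  windows
}

#' A single harmonic-restraint window
#'
#' @param samples data frame with columns `extension_A`, `dihedral_deg`.
#' @param center length-2 `(extension_A, dihedral_deg)` restraint centre.
#' @param force_constants length-2 `(k_ext, k_dih)`, kcal/mol/A^2 and
#'   kcal/mol/rad^2; zero is allowed (unbiased window).
#' @param temperature Kelvin.
#' @param ensemble optional [conformer_ensemble()] the samples came from.
#' @param offset constant added to the window's bias energy (kcal/mol); the
#'   estimators are gauge-invariant to it, which the tests exploit.
#' @return an object of class `bias_window`.
#' @export
bias_window <- function(samples, center, force_constants, temperature = 300,
                        ensemble = NULL, offset = 0) {
  samples <- as_tibble(samples)
  stopifnot(nrow(samples) >= 1, all(force_constants >= 0),
            length(center) == 2, length(force_constants) == 2)
  kT <- kT_kcal(temperature)
  sig_ext <- if (force_constants[1] > 0) sqrt(kT / force_constants[1]) else Inf
  sig_dih <- if (force_constants[2] > 0) {
    sqrt(kT / force_constants[2]) * 180 / pi
  } else {
    Inf
  }
  near <- abs(samples$extension_A - center[1]) <= 3 * sig_ext &
    ang_diff(samples$dihedral_deg, center[2]) <= 3 * sig_dih
  structure(
    list(samples = samples, center = as.numeric(center),
         force_constants = as.numeric(force_constants),
         temperature = temperature, n_samples = nrow(samples),
         overlap_ok = any(near), ensemble = ensemble, offset = offset),
    class = "bias_window"
  )
}

#' @export
print.bias_window <- function(x, ...) {
  cat("<bias_window> centre (", round(x$center[1], 2), " A, ",
      round(x$center[2], 1), " deg), k = (", x$force_constants[1], ", ",
      x$force_constants[2], "), ", x$n_samples, " samples",
      if (!x$overlap_ok) " [POOR OVERLAP]", "\n", sep = "")
  invisible(x)
}

# harmonic bias energy (kcal/mol) of window w evaluated at CV points
bias_energy <- function(window, extension, dihedral) {
  (window$offset %||% 0) +
    0.5 * window$force_constants[1] * (extension - window$center[1])^2 +
    0.5 * window$force_constants[2] *
      (wrap_deg(dihedral - window$center[2]) * pi / 180)^2
}

#' Draw i.i.d. samples from a 2D density on the collective-variable plane
#'
#' Grid-discretised exact sampling used to build toy umbrella windows on
#' analytic potentials (the free-energy estimators are validated against
#' closed-form surfaces this way). The density is
#' \eqn{\exp[-(U + B)/k_BT]} for a potential function `U` and optional
#' harmonic bias `B`.
#'
#' @param potential function `(ext, dih) -> kcal/mol`, vectorised.
#' @param n number of samples.
#' @param seed integer seed.
#' @param ext_range numeric length-2 extension range (A).
#' @param center,force_constants optional harmonic bias (as in
#'   [bias_window()]).
#' @param temperature Kelvin.
#' @param n_grid grid resolution per axis.
#' @return a tibble `(extension_A, dihedral_deg)`.
#' @export
sample_cv_density <- function(potential, n, seed, ext_range = c(0, 40),
                              center = NULL, force_constants = c(0, 0),
                              temperature = 300, n_grid = 400) {
  set.seed(derive_seed(seed, 0L))
  kT <- kT_kcal(temperature)
  gx <- seq(ext_range[1], ext_range[2], length.out = n_grid)
  gy <- seq(-180, 180, length.out = n_grid + 1)[-1]
  u <- outer(gx, gy, potential)
  if (!is.null(center)) {
    b <- outer(
      gx, gy,
      function(x, y) {
        0.5 * force_constants[1] * (x - center[1])^2 +
          0.5 * force_constants[2] * (wrap_deg(y - center[2]) * pi / 180)^2
      }
    )
    u <- u + b
  }
  p <- exp(-(u - min(u)) / kT)
  p <- p / sum(p)
  idx <- sample.int(length(p), n, replace = TRUE, prob = as.vector(p))
  ix <- (idx - 1) %% n_grid + 1
  iy <- (idx - 1) %/% n_grid + 1
  dx <- gx[2] - gx[1]
  dy <- gy[2] - gy[1]
  tibble(
    extension_A = gx[ix] + runif(n, -dx / 2, dx / 2),
    dihedral_deg = wrap_deg(gy[iy] + runif(n, -dy / 2, dy / 2))
  )
}
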