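# Shared oracles and fixture constructors, all built in code.

# analytic 2D double-well over (extension, dihedral): -kT log of two
# Gaussian bumps, second basin offset by `dg` kcal/mol
toy_double_well <- function(temperature = 300, dg = 1.5) {
  kT <- lidfold::kT_kcal(temperature)
  dang <- function(y, c) {
    d <- (y - c) %% 360
    ifelse(d > 180, d - 360, d)
  }
  function(x, y) {
    g1 <- exp(-((x - 10)^2 / 8 + dang(y, -60)^2 / 1800))
    g2 <- exp(-((x - 20)^2 / 8 + dang(y, 60)^2 / 1800) - dg / kT)
    -kT * log(g1 + g2 + 1e-10)
  }
}

# i.i.d.-sampled umbrella windows on an analytic potential
toy_windows <- function(potential, n_grid_centers = c(5, 5), n = 1500,
                        k = c(0.2, 2), seed = 42, temperature = 300) {
  centers <- expand.grid(
    extension_A = seq(7, 23, length.out = n_grid_centers[1]),
    dihedral_deg = seq(-144, 144, length.out = n_grid_centers[2])
  )
  lapply(seq_len(nrow(centers)), function(i) {
    ctr <- c(centers$extension_A[i], centers$dihedral_deg[i])
    s <- sample_cv_density(potential, n, seed = derive_seed(seed, i),
                           ext_range = c(4, 26), center = ctr,
                           force_constants = k, temperature = temperature)
    bias_window(s, ctr, k, temperature)
  })
}

# RMSE between a surface and the analytic potential over sampled bins,
# after removing the arbitrary additive constant
fes_rmse <- function(fes, potential) {
  tb <- generics::tidy(fes)
  tb <- tb[tb$sampled & is.finite(tb$F_kcalmol), ]
  tru <- potential(tb$extension_A, tb$dihedral_deg)
  tru <- tru - min(tru)
  d <- tb$F_kcalmol - tru
  sqrt(mean((d - mean(d))^2))
}

# rms difference between two surfaces on jointly sampled bins (gauge removed)
fes_diff <- function(f1, f2) {
  both <- is.finite(f1$F) & is.finite(f2$F)
  d <- f1$F[both] - f2$F[both]
  sqrt(mean((d - mean(d))^2))
}

# a small conformer ensemble built directly from torsion sets
ensemble_from_torsions <- function(torsion_mat, system, weights = NULL) {
  nf <- nrow(torsion_mat)
  np <- system$n_residues + 2
  coords <- array(NA_real_, c(np, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- build_chain(torsion_mat[f, ], system)
  }
  parts <- tibble::tibble(
    index = seq_len(np),
    role = c(rep("CA", system$n_residues), "ANC", "ANC"),
    residue = c(system$residue_start + seq_len(system$n_residues) - 1L,
                NA_integer_, NA_integer_)
  )
  conformer_ensemble(coords, parts, weights = weights,
                     torsions = torsion_mat, system = system)
}

# random rigid motion applied to an (n x 3) coordinate matrix
apply_rigid_motion <- function(xyz, seed) {
  set.seed(seed)
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  sweep(xyz %*% R, 2, rnorm(3, 0, 10), "+")
}
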