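# The coarse-grained lid model: energy function, Metropolis sampling,
# umbrella windows, and serialization round trips.

test_that("system constructor enforces its invariants", {
  expect_error(lid_system(n_residues = 4), class = "lidfold_invalid_system")
  expect_error(lid_system(sigma_h = -1), class = "lidfold_invalid_system")
  expect_error(lid_system(contact_epsilon = -0.1),
               class = "lidfold_invalid_system")
  expect_error(lid_system(contact_residue_index = 40),
               class = "lidfold_invalid_system")
  expect_error(lid_system(bond_length = 0), class = "lidfold_invalid_system")
})

test_that("energy is finite everywhere and the contact term switches off", {
  sys_apo <- lid_system()
  sys_eps0 <- lid_system(ligand_present = TRUE, contact_epsilon = 0)
  set.seed(1)
  pose <- c(sys_eps0$anchor, 1, 0, 0, 0)
  for (i in 1:25) {
    tor <- runif(n_torsions(sys_apo), -180, 180)
    e_apo <- lid_energy(sys_apo, tor)
    expect_true(is.finite(e_apo))
    # eps = 0 with the ligand present and inside its box adds nothing
    e_holo <- lid_energy(sys_eps0, tor, pose)
    expect_equal(e_holo, e_apo, tolerance = 1e-12)
  }
})

test_that("uncoupled symmetric double well has 0.5 helix occupancy", {
  sys <- lid_system(delta_u_hc = 0, sigma_h = 30, sigma_c = 30,
                    coupling_j = 0)
  # tolerance reflects the quadrature grid step at the basin boundary
  expect_equal(torsion_marginal(sys)$helix_occupancy, 0.5, tolerance = 1e-4)
})

test_that("J = 0 sampling reproduces the quadrature marginal", {
  sys <- lid_system(coupling_j = 0)
  occ_q <- torsion_marginal(sys)$helix_occupancy
  ens <- sample_ensemble(sys, 60000, seed = 5, stride = 20)
  occ <- in_helix_basin(ens$torsions, sys)
  occ_mean <- mean(occ)
  # Monte-Carlo standard error from per-torsion block means
  blk <- vapply(1:6, function(b) {
    rows <- lidfold:::block_index(nrow(occ), 6) == b
    mean(occ[rows, ])
  }, 1.0)
  mcse <- sd(blk) / sqrt(6)
  expect_lt(abs(occ_mean - occ_q), 3 * max(mcse, 1e-3))
})

test_that("sampling is deterministic under a fixed seed", {
  sys <- lid_system(ligand_present = TRUE)
  e1 <- sample_ensemble(sys, 4000, seed = 9, stride = 20)
  e2 <- sample_ensemble(sys, 4000, seed = 9, stride = 20)
  expect_identical(e1$torsions, e2$torsions)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$lig_pose, e2$lig_pose)
  e3 <- sample_ensemble(sys, 4000, seed = 10, stride = 20)
  expect_false(identical(e1$torsions, e3$torsions))
})

test_that("the acceptance rule satisfies detailed balance", {
  # for symmetric proposals, A(x->y)/A(y->x) must equal exp(-dE/kT)
  sys <- lid_system()
  kT <- kT_kcal(sys$temperature)
  set.seed(3)
  for (i in 1:20) {
    tx <- runif(n_torsions(sys), -180, 180)
    ty <- tx
    j <- sample(n_torsions(sys), 1)
    ty[j] <- runif(1, -180, 180)
    dE <- lid_energy(sys, ty) - lid_energy(sys, tx)
    a_fwd <- min(1, exp(-dE / kT))
    a_bwd <- min(1, exp(dE / kT))
    expect_equal(a_fwd / a_bwd, exp(-dE / kT), tolerance = 1e-12)
  }
})

test_that("a stiff bias pins the sampled extension near its centre", {
  sys <- lid_system()
  b <- list(center = c(30, 0), k = c(50, 50))
  ens <- sample_ensemble(sys, 20000, seed = 6, bias = b)
  expect_lt(abs(mean(ens$provenance$cv$extension_A) - 30), 1)
  # stiff-spring width check: sd ~ sqrt(kT/k) = 0.109 A
  expect_lt(sd(ens$provenance$cv$extension_A), 0.3)
})

test_that("window generation flags poor overlap and zero bias is unbiased", {
  sys <- lid_system()
  # unreachable centre: extension beyond the fully extended chain
  expect_warning(
    w_bad <- generate_bias_windows(sys, data.frame(extension_A = 120,
                                                   dihedral_deg = 0),
                                   c(5, 5), n_sweeps = 3000, seed = 2),
    "poor overlap"
  )
  expect_false(w_bad[[1]]$overlap_ok)
  # two identical windows with different seeds agree within joint error
  ctr <- data.frame(extension_A = 30, dihedral_deg = 90)
  w1 <- generate_bias_windows(sys, ctr, c(1, 5), n_sweeps = 30000, seed = 4)
  w2 <- generate_bias_windows(sys, ctr, c(1, 5), n_sweeps = 30000, seed = 14)
  m1 <- mean(w1[[1]]$samples$extension_A)
  m2 <- mean(w2[[1]]$samples$extension_A)
  se <- function(w) {
    x <- w[[1]]$samples$extension_A
    blk <- lidfold:::block_index(length(x), 8)
    sd(vapply(1:8, function(b) mean(x[blk == b]), 1.0)) / sqrt(8)
  }
  expect_lt(abs(m1 - m2), 4 * sqrt(se(w1)^2 + se(w2)^2))
})

test_that("contact coupling raises helicity next to the contact residue", {
  wt <- lid_system(ligand_present = TRUE)
  mut <- lid_system(ligand_present = TRUE, contact_epsilon = 0)
  e_wt <- sample_ensemble(wt, 80000, seed = 11, stride = 40)
  e_mut <- sample_ensemble(mut, 80000, seed = 12, stride = 40)
  adj <- (wt$contact_residue_index - 1):(wt$contact_residue_index + 1)
  occ_wt <- rowMeans(in_helix_basin(e_wt$torsions[, adj], wt))
  occ_mut <- rowMeans(in_helix_basin(e_mut$torsions[, adj], mut))
  tt <- t.test(occ_wt, occ_mut, alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("ensembles round-trip through multi-model PDB", {
  sys <- lid_system(ligand_present = TRUE)
  ens <- sample_ensemble(sys, 2000, seed = 7, stride = 100)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_ensemble_pdb(path)
  expect_equal(n_frames(back), n_frames(ens))
  expect_lt(max(abs(wrap_deg(back$torsions - ens$torsions))), 0.01)
  expect_equal(back$weights, ens$weights, tolerance = 1e-3)
  expect_identical(back$particles$role, ens$particles$role)
})

test_that("torsion and CV tables round-trip through CSV", {
  sys <- lid_system()
  ens <- sample_ensemble(sys, 1000, seed = 8, stride = 100)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_torsion_csv(ens, p1)
  tt <- read_torsion_csv(p1)
  expect_equal(nrow(tt), n_frames(ens) * ncol(ens$torsions))
  expect_equal(tt$theta_deg[1:20],
               torsion_table(ens)$theta_deg[1:20])
})
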