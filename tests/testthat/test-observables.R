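# Secondary structure, helix propensity, RMSF and SASA.

test_that("ideal alpha-helix gets H at interior residues (hbond mode)", {
  bb <- build_peptide(-57, -47, 12)
  lab <- assign_secondary_structure(bb)$labels[1, ]
  expect_true(all(lab[3:10] == "H"))
  expect_false(any(lab == "E"))
})

test_that("isolated extended strand gets neither H nor E", {
  bb <- build_peptide(-139, 135, 12)
  lab <- assign_secondary_structure(bb)$labels[1, ]
  expect_true(all(lab == "C"))
})

test_that("antiparallel two-strand sheet gets E at paired residues", {
  # geometric construction: a twist-free strand (phi/psi chosen so the
  # peptide units repeat with exact 2-fold screw symmetry) paired with its
  # own copy rotated 180 deg about the in-plane axis perpendicular to the
  # strand direction, offset by one H-bond distance
  s1 <- build_peptide(-141.89, 139.68, 8)
  m1 <- as.matrix(s1[, c("x", "y", "z")])
  cen <- colMeans(m1)
  ca <- as.matrix(s1[s1$atom == "CA", c("x", "y", "z")])
  u <- colMeans(diff(ca))
  u <- u / sqrt(sum(u^2))
  g <- function(r, a) {
    w <- s1[s1$residue == r & s1$atom == a, ]
    c(w$x, w$y, w$z)
  }
  o4 <- g(4, "O") - g(4, "C")
  o4 <- o4 - sum(o4 * u) * u
  v <- o4 / sqrt(sum(o4^2))
  R <- 2 * outer(v, v) - diag(3) # 180 deg rotation about v
  m2 <- sweep(sweep(m1, 2, cen) %*% t(R), 2,
              cen - 1.2 * u - 3.5 * v, "+")
  bb <- rbind(
    s1,
    transform(s1, residue = s1$residue + 8L,
              x = m2[, 1], y = m2[, 2], z = m2[, 3])
  )
  lab <- assign_secondary_structure(tibble::as_tibble(bb))$labels[1, ]
  expect_gte(sum(lab == "E"), 8)
  expect_false(any(lab == "H"))
  # paired interior residues of both strands are strand-labelled
  expect_true(all(lab[c(3:6, 11:14)] == "E"))
})

test_that("torsion-window mode marks helical runs and propensity tallies", {
  sys <- lid_system()
  nt <- n_torsions(sys)
  tor <- rbind(
    rep(sys$theta_c, nt),                      # coil frame
    c(rep(sys$theta_h, 6), rep(sys$theta_c, nt - 6)), # helical run 1..6
    rep(sys$theta_h, nt)                       # fully helical frame
  )
  ens <- ensemble_from_torsions(tor, sys)
  prof <- assign_secondary_structure(ens, "torsion_window", window = 30,
                                     min_run = 4)
  expect_true(all(prof$labels[1, ] == "C"))
  expect_true(all(prof$labels[2, 2:8] == "H"))
  expect_true(all(prof$labels[2, 10:23] == "C"))
  expect_true(all(prof$labels[3, 2:22] == "H"))
  # propensity = weighted H fraction; sigma_e = 0 for constant labels
  p <- helix_propensity(prof, n_blocks = 3)
  expect_equal(p$propensity[5], 2 / 3)
  expect_equal(p$propensity[1], 0)
  all_h <- ensemble_from_torsions(rbind(tor[3, ], tor[3, ], tor[3, ]), sys)
  ph <- helix_propensity(
    assign_secondary_structure(all_h, "torsion_window"), n_blocks = 3
  )
  expect_equal(ph$propensity[10], 1)
  expect_equal(ph$sigma_e[10], 0)
  # alternating H/C with equal weights -> 0.5
  alt <- ensemble_from_torsions(tor[c(1, 3, 1, 3), ], sys)
  pa <- helix_propensity(
    assign_secondary_structure(alt, "torsion_window"), n_blocks = 2
  )
  expect_equal(pa$propensity[10], 0.5)
  expect_error(helix_propensity(prof, residue_range = 99),
               class = "lidfold_invalid_config")
})

test_that("rmsf is zero for identical or rigidly moved frames", {
  sys <- lid_system()
  set.seed(2)
  tor <- runif(n_torsions(sys), -180, 180)
  xyz <- build_chain(tor, sys)
  np <- nrow(xyz)
  ident <- array(rep(xyz, 4), c(np, 3, 4))
  parts <- tibble::tibble(
    index = 1:np, role = c(rep("CA", sys$n_residues), "ANC", "ANC"),
    residue = c(sys$residue_start + 1:sys$n_residues - 1L, NA, NA)
  )
  e1 <- conformer_ensemble(ident, parts)
  expect_lt(max(rmsf(e1)$rmsf_A), 1e-10)
  moved <- array(NA_real_, c(np, 3, 5))
  for (f in 1:5) moved[, , f] <- apply_rigid_motion(xyz, seed = f)
  e2 <- conformer_ensemble(moved, parts)
  expect_lt(max(rmsf(e2)$rmsf_A), 1e-8)
})

test_that("a particle oscillating +-1 A has rmsf exactly 1", {
  # superposition frame fixed by many static particles
  base <- matrix(rnorm(30 * 3, sd = 5), 30, 3)
  coords <- array(rep(base, 2), c(30, 3, 2))
  coords[30, 1, 1] <- base[30, 1] + 1
  coords[30, 1, 2] <- base[30, 1] - 1
  parts <- tibble::tibble(index = 1:30, role = rep("CA", 30), residue = 1:30)
  ens <- conformer_ensemble(coords, parts)
  out <- rmsf(ens, superpose_selection = 1:29)
  expect_equal(out$rmsf_A[30], 1, tolerance = 1e-6)
  expect_lt(max(out$rmsf_A[1:29]), 1e-6)
})

test_that("rmsf input validation", {
  parts <- tibble::tibble(index = 1:3, role = rep("CA", 3), residue = 1:3)
  one <- conformer_ensemble(array(rnorm(9), c(3, 3, 1)), parts)
  expect_error(rmsf(one), class = "lidfold_invalid_config")
  coincident <- array(0, c(3, 3, 2))
  e <- conformer_ensemble(coincident, parts)
  expect_error(rmsf(e, superpose_selection = 1:3),
               class = "lidfold_degenerate_selection")
})

test_that("single-sphere SASA is the analytic expanded-sphere area", {
  s <- sasa(matrix(0, 1, 3), radii = 1.7, probe_radius = 1.4,
            n_sphere_points = 960)
  expect_equal(s, 4 * pi * 3.1^2, tolerance = 1e-6)
})

test_that("two overlapping spheres match the spherical-cap formula", {
  r <- 3.1
  d <- 3
  fr <- rbind(c(0, 0, 0), c(d, 0, 0))
  s <- sasa(fr, radii = c(1.7, 1.7), n_sphere_points = 3840)
  exact <- 4 * pi * r^2 - 2 * pi * r * (r - d / 2)
  expect_equal(s[1], exact, tolerance = 0.01 * exact)
  expect_equal(s[2], exact, tolerance = 0.01 * exact)
})

test_that("a caged particle has (near) zero SASA", {
  centre <- matrix(0, 1, 3)
  cage <- as.matrix(expand.grid(x = c(-2, 2), y = c(-2, 2), z = c(-2, 2)))
  cage <- rbind(cage, 3.2 * diag(3), -3.2 * diag(3))
  fr <- rbind(centre, cage)
  s <- sasa(fr, radii = c(1.7, rep(2.2, nrow(cage))), n_sphere_points = 960)
  expect_lt(s[1], 1)
})

test_that("SASA converges in the number of sphere points", {
  sys <- lid_system()
  fr <- build_chain(rep(180, n_torsions(sys)), sys)
  radii <- rep(2.2, nrow(fr))
  s1 <- sasa(fr, radii, n_sphere_points = 960)
  s2 <- sasa(fr, radii, n_sphere_points = 3840)
  expect_lt(max(abs(s1 - s2)), 0.5)
})

test_that("sasa validates inputs", {
  expect_error(sasa(matrix(0, 1, 3), radii = numeric(0)),
               class = "lidfold_missing_radius")
  expect_error(sasa(matrix(0, 1, 3), radii = 1.7, n_sphere_points = 32),
               class = "lidfold_invalid_config")
})

test_that("hydrophobic SASA change: identity, direction, arithmetic", {
  sys <- lid_system()
  tor_open <- rep(180, n_torsions(sys))
  tor_closed <- rep(sys$theta_h, n_torsions(sys))
  e_open <- ensemble_from_torsions(rbind(tor_open, tor_open), sys)
  e_closed <- ensemble_from_torsions(rbind(tor_closed, tor_closed), sys)
  hydro <- c(10, 12, 14)
  same <- hydrophobic_sasa_change(e_open, e_open, hydro, n_boot = 10)
  expect_equal(same$percent_decrease, 0)
  # burial by construction: helical compaction buries the patch
  dec <- hydrophobic_sasa_change(e_open, e_closed, hydro, n_boot = 10)
  expect_gt(dec$percent_decrease, 0)
  # two-frame toy agrees with direct arithmetic from sasa()
  radii <- lidfold:::default_radii(e_open$particles)
  s_free <- sum(sasa(e_open$coords[, , 1], radii,
                     n_sphere_points = 240)[hydro])
  s_bound <- sum(sasa(e_closed$coords[, , 1], radii,
                      n_sphere_points = 240)[hydro])
  expect_equal(dec$percent_decrease, 100 * (s_free - s_bound) / s_free,
               tolerance = 1e-6)
})
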