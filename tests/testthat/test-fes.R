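# Free-energy surface estimators against analytic landscapes.

flat_potential <- function(x, y) 0 * x + 0 * y

test_that("unbiased uniform window gives a flat WHAM surface", {
  s <- sample_cv_density(flat_potential, 20000, seed = 1,
                         ext_range = c(5, 25))
  w <- bias_window(s, c(15, 0), c(0, 0), 300)
  fes <- wham2d(list(w), grid_size = c(8, 8))
  vals <- fes$F[is.finite(fes$F)]
  se <- fes$se[is.finite(fes$F)]
  # every sampled bin flat within its own histogram noise
  expect_true(all(abs(vals - mean(vals)) < 3 * se + 0.1))
  expect_equal(min(vals), 0)
})

test_that("a harmonic bias on a flat landscape divides out exactly", {
  s <- sample_cv_density(flat_potential, 20000, seed = 2,
                         ext_range = c(5, 25),
                         center = c(15, 0), force_constants = c(0.3, 3))
  w <- bias_window(s, c(15, 0), c(0.3, 3), 300)
  fes <- wham2d(list(w), grid_size = c(12, 12))
  # judge cancellation on bins with enough counts for Gaussian-ish noise
  ok <- is.finite(fes$F) & is.finite(fes$se) & fes$se < 0.15
  vals <- fes$F[ok]
  expect_gt(sum(ok), 30)
  expect_true(all(abs(vals - mean(vals)) < 3 * fes$se[ok] + 0.1))
})

test_that("WHAM recovers an analytic double well from 5x5 windows", {
  U <- toy_double_well()
  wins <- toy_windows(U, n = 1500, seed = 42)
  fes <- wham2d(wins, grid_size = c(40, 40))
  expect_lt(fes_rmse(fes, U), 0.3)
})

test_that("MBAR weights: trivial limits and agreement with WHAM", {
  # single unbiased window -> uniform weights
  s <- sample_cv_density(flat_potential, 500, seed = 3, ext_range = c(5, 25))
  w0 <- bias_window(s, c(15, 0), c(0, 0), 300)
  mb0 <- mbar_weights(list(w0))
  expect_equal(mb0$weights, rep(1 / 500, 500), tolerance = 1e-12)
  # two identical windows -> same weight as the single-window case per sample
  mb2 <- mbar_weights(list(w0, w0))
  expect_equal(mb2$weights, rep(1 / 1000, 1000), tolerance = 1e-12)
  # dense windows on the double well: binned weights match WHAM
  U <- toy_double_well()
  wins <- toy_windows(U, n = 800, seed = 7)
  fw <- wham2d(wins, grid_size = c(30, 30))
  fm <- mbar_fes(mbar_weights(wins), grid_size = c(30, 30))
  expect_lt(fes_diff(fw, fm), 0.2)
})

test_that("spline estimator: flat null, quadratic well, double-well basins", {
  # flat landscape -> fitted surface within 0.2 of 0
  s <- sample_cv_density(flat_potential, 5000, seed = 5, ext_range = c(5, 25))
  w <- bias_window(s, c(15, 0), c(0, 0), 300)
  f0 <- spline_fes(list(w), knot_counts = c(6, 6), regularization = 2,
                   grid_size = c(25, 25))
  vals0 <- f0$F[f0$sampled]
  expect_lt(max(abs(vals0 - mean(vals0))), 0.2)

  # quadratic well: compare within the well region
  quad <- function(x, y) 0.05 * (x - 15)^2 +
    0.4 * (wrap_deg(y) * pi / 180)^2
  sq <- sample_cv_density(quad, 8000, seed = 6, ext_range = c(5, 25))
  wq <- bias_window(sq, c(15, 0), c(0, 0), 300)
  fq <- spline_fes(list(wq), knot_counts = c(8, 8), regularization = 0.5,
                   grid_size = c(30, 30))
  tb <- generics::tidy(fq)
  tb <- tb[tb$sampled, ]
  tru <- quad(tb$extension_A, tb$dihedral_deg)
  keep <- tru < 2 # well region where sampling supports the fit
  d <- tb$F_kcalmol[keep] - tru[keep]
  expect_lt(max(abs(d - mean(d))), 0.2)

  # double well: basin free-energy offset recovered within 0.3
  U <- toy_double_well(dg = 1.5)
  wins <- toy_windows(U, n = 1500, seed = 8)
  fs <- spline_fes(wins, knot_counts = c(10, 10), regularization = 0.5,
                   grid_size = c(40, 40))
  basins <- basin_free_energies(fs, list(
    A = list(extension_A = c(5, 15), dihedral_deg = c(-150, 30)),
    B = list(extension_A = c(15, 25), dihedral_deg = c(-30, 150))
  ))
  # quadrature oracle for the basin offset
  kT <- kT_kcal(300)
  gx <- seq(4, 26, length.out = 300)
  gy <- seq(-180, 180, length.out = 301)[-1]
  ug <- outer(gx, gy, U)
  pz <- exp(-(ug - min(ug)) / kT)
  inA <- outer(gx >= 5 & gx <= 15, gy >= -150 & gy <= 30, "&")
  inB <- outer(gx > 15 & gx <= 25, gy > -30 & gy <= 150, "&")
  dg_true <- -kT * (log(sum(pz[inB])) - log(sum(pz[inA])))
  dg_est <- basins$delta_g_kcalmol[basins$region == "B"] -
    basins$delta_g_kcalmol[basins$region == "A"]
  expect_lt(abs(dg_est - dg_true), 0.3)
})

test_that("basin free energies: whole-surface region is 0, symmetry holds", {
  U <- toy_double_well(dg = 0) # symmetric wells
  wins <- toy_windows(U, n = 1500, seed = 9)
  fes <- wham2d(wins, grid_size = c(30, 30))
  all_region <- list(all = list(extension_A = c(-Inf, Inf),
                                dihedral_deg = c(-180, 180)))
  expect_equal(unname(basin_free_energies(fes, all_region)$delta_g_kcalmol),
               0)
  two <- basin_free_energies(fes, list(
    A = list(extension_A = c(5, 15), dihedral_deg = c(-150, 30)),
    B = list(extension_A = c(15, 25), dihedral_deg = c(-30, 150))
  ))
  expect_lt(abs(diff(two$delta_g_kcalmol)), 0.15)
  expect_error(
    basin_free_energies(fes, list(x = list(extension_A = c(100, 110),
                                           dihedral_deg = c(0, 10)))),
    class = "lidfold_empty_region"
  )
})

test_that("adding a constant to every bias leaves the surface unchanged", {
  U <- toy_double_well()
  wins <- toy_windows(U, n = 800, seed = 10)
  shifted <- lapply(wins, function(w) {
    bias_window(w$samples, w$center, w$force_constants, w$temperature,
                offset = 2.7)
  })
  f1 <- wham2d(wins, grid_size = c(25, 25))
  f2 <- wham2d(shifted, grid_size = c(25, 25))
  expect_equal(f1$F, f2$F, tolerance = 1e-5)
  m1 <- mbar_weights(wins)
  m2 <- mbar_weights(shifted)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-8)
  s1 <- spline_fes(wins, knot_counts = c(6, 6), grid_size = c(20, 20))
  s2 <- spline_fes(shifted, knot_counts = c(6, 6), grid_size = c(20, 20))
  expect_lt(fes_diff(s1, s2), 0.02)
})

test_that("reweighting replaces weights and shifts observable averages", {
  sys <- lid_system()
  tor <- rbind(rep(sys$theta_h, 20), rep(sys$theta_c, 20))
  ens <- ensemble_from_torsions(tor, sys)
  cv <- cv_definition(sys)
  exts <- cv_timeseries(ens, cv)$extension_A
  # uniform -> unchanged mean; one-hot -> that frame; half/half -> midpoint
  e_uni <- reweighted_ensemble(ens, c(1, 1))
  expect_equal(sum(exts * e_uni$weights), mean(exts))
  e_hot <- reweighted_ensemble(ens, c(1, 0))
  expect_equal(sum(exts * e_hot$weights), exts[1])
  e_half <- reweighted_ensemble(ens, c(0.5, 0.5))
  expect_equal(sum(exts * e_half$weights), mean(exts))
  expect_error(reweighted_ensemble(ens, c(-1, 2)),
               class = "lidfold_bad_weights")
  expect_error(reweighted_ensemble(ens, c(1, 1, 1)),
               class = "lidfold_bad_weights")
})

test_that("WHAM surface uncertainty shrinks with total samples", {
  U <- toy_double_well()
  se_med <- vapply(c(400, 1600), function(n) {
    wins <- toy_windows(U, n = n, seed = 11)
    fb <- fes_bootstrap(wins, n_boot = 8, n_blocks = 8, seed = 1,
                        grid_size = c(20, 20))
    median(fb$se[is.finite(fb$se) & fb$se > 0])
  }, 1.0)
  # 4x samples ~ 2x smaller; allow slack
  expect_lt(se_med[2], se_med[1] / 1.3)
})
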