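# ITC forward models, fitting, and the thermodynamic signature.

std_protocol <- function() itc_titration(c(0.4, rep(2, 18)))

test_that("titration container validates its invariants", {
  expect_error(itc_titration(rep(2, 3)), class = "lidfold_invalid_itc")
  expect_error(itc_titration(rep(2, 19), cell_conc_M = 0),
               class = "lidfold_invalid_itc")
  expect_error(itc_titration(rep(500, 19)), class = "lidfold_invalid_itc")
  expect_error(itc_titration(rep(2, 19), heats_ucal = c(1, NA)),
               class = "lidfold_invalid_itc")
})

test_that("one-site heats: zero enthalpy, no-binding limit, tight binding", {
  ti <- std_protocol()
  expect_equal(one_site_heats(list(n = 1, kd_M = 1e-8, dh_kcal = 0), ti),
               rep(0, 19))
  # K_D -> Inf: heats vanish
  q_weak <- one_site_heats(list(n = 1, kd_M = 1e3, dh_kcal = -12), ti)
  expect_lt(max(abs(q_weak)), 1e-4)
  # tight-binding limit: early heats = dH * moles injected
  q_tight <- one_site_heats(list(n = 1, kd_M = 1e-13, dh_kcal = -12), ti)
  mol2 <- 2e-6 * 150e-6 # 2 uL of 150 uM, in mol
  expect_equal(q_tight[2], -12 * mol2 * 1e9, tolerance = 1e-3 * abs(q_tight[2]))
})

test_that("total heat equals dH times total complex formed (c = 100)", {
  # independent mass-balance bookkeeping of complex formed, including the
  # complex displaced from the cell by later injections
  n <- 1
  kd <- 1e-7 # c = n*[cell]/Kd = 100
  dh <- -12
  ti <- itc_titration(c(0.4, rep(2, 25)))
  q <- one_site_heats(list(n = n, kd_M = kd, dh_kcal = dh), ti)
  v0 <- ti$cell_volume_mL * 1e-3
  m <- ti$cell_conc_M
  x <- 0
  pl_prev <- 0
  formed <- 0
  for (j in seq_along(ti$injection_volumes_uL)) {
    dv <- ti$injection_volumes_uL[j] * 1e-6
    fd <- 1 - dv / v0
    m <- m * fd
    x <- x * fd + ti$syringe_conc_M * dv / v0
    s <- n * m + x + kd
    pl <- (s - sqrt(s^2 - 4 * n * m * x)) / 2
    formed <- formed + (pl - pl_prev * fd) * v0
    pl_prev <- pl
  }
  expect_equal(sum(q), dh * formed * 1e9, tolerance = 1e-9 * abs(sum(q)))
  # near-total conversion; the shortfall is protein displaced from the cell
  # before it bound plus the unbound remainder at K_D = 100 nM
  expect_gt(formed / (ti$cell_conc_M * v0), 0.95)
  expect_equal(sum(q), dh * ti$cell_conc_M * v0 * 1e9, tolerance =
                 0.05 * abs(sum(q)))
})

test_that("noiseless one-site isotherm is recovered to 4 significant figures", {
  truth <- list(n = 0.95, kd_M = 5e-8, dh_kcal = -11.3)
  ti <- simulate_itc_isotherm(truth, noise_frac = 0, seed = 1)
  fit <- fit_one_site(ti)
  expect_equal(fit$n, truth$n, tolerance = 1e-4)
  expect_equal(fit$kd_M, truth$kd_M, tolerance = 1e-4)
  expect_equal(fit$dh_kcal, truth$dh_kcal, tolerance = 1e-4)
})

test_that("recovery bias shrinks as noise decreases", {
  truth <- list(n = 1, kd_M = 5e-8, dh_kcal = -12)
  med_err <- vapply(c(0.02, 0.005, 0.001), function(nf) {
    errs <- vapply(1:12, function(s) {
      ti <- simulate_itc_isotherm(truth, noise_frac = nf, seed = 100 + s)
      f <- fit_one_site(ti)
      abs(f$kd_M - truth$kd_M) / truth$kd_M
    }, 1.0)
    median(errs)
  }, 1.0)
  expect_true(all(diff(med_err) < 0))
})

test_that("flat (pure dilution) heats are flagged unidentifiable", {
  ti <- std_protocol()
  ti$heats_ucal <- rep(0.3, 19)
  fit <- fit_one_site(ti)
  expect_false(fit$identifiable)
  expect_true(is.na(fit$kd_M))
})

test_that("competitive model reduces exactly to one-site at zero competitor", {
  p <- list(n = 1, kd_M = 1e-9, dh_kcal = -14)
  ti <- std_protocol()
  expect_equal(competitive_heats(p, ti), one_site_heats(p, ti),
               tolerance = 1e-12)
  ti2 <- itc_titration(c(0.4, rep(2, 18)), weak_conc_M = 1e-12,
                       weak_kd_M = 1e-6, weak_dh_kcal = -5)
  # continuity at zero weak-ligand concentration (1e-9 kcal heat units
  # corresponds to 1 microcal = 1e-9 kcal x 1e9)
  expect_lt(max(abs(competitive_heats(p, ti2) - one_site_heats(p, ti))),
            1e-3)
})

test_that("apparent K_D follows the competitor correction", {
  # one-site fit of noiseless competitive data gives
  # K_app ~ K_strong * (1 + [weak]/K_weak)
  kd_s <- 2e-9
  conc_b <- 50e-6
  kd_b <- 1e-6
  ti <- itc_titration(c(0.4, rep(2, 18)), weak_conc_M = conc_b,
                      weak_kd_M = kd_b, weak_dh_kcal = 0)
  q <- competitive_heats(list(n = 1, kd_M = kd_s, dh_kcal = -12), ti)
  ti_fit <- std_protocol()
  ti_fit$heats_ucal <- q
  app <- suppressWarnings(fit_one_site(ti_fit))
  kd_app_expected <- kd_s * (1 + conc_b / kd_b)
  expect_equal(app$kd_M, kd_app_expected, tolerance = 0.15)
})

test_that("competitive fit recovers a 0.1 nM K_D within factor 2", {
  truth <- list(n = 1, kd_M = 1e-10, dh_kcal = -14)
  ti <- itc_titration(c(0.4, rep(2, 18)), weak_conc_M = 50e-6,
                      weak_kd_M = 1e-6, weak_dh_kcal = -5)
  kds <- vapply(1:8, function(s) {
    sim <- simulate_itc_isotherm(truth, ti, noise_frac = 0.005,
                                 seed = 200 + s)
    suppressWarnings(fit_competitive(sim))$kd_M
  }, 1.0)
  expect_lt(median(kds) / truth$kd_M, 2)
  expect_gt(median(kds) / truth$kd_M, 0.5)
})

test_that("thermodynamic signature identity is exact", {
  fit <- list(kd_M = 1e-9, dh_kcal = -10, temperature = 298.15)
  sig <- thermodynamic_signature(fit)
  dg <- sig$kcal_per_mol[sig$quantity == "dG"]
  dh <- sig$kcal_per_mol[sig$quantity == "dH"]
  tds <- sig$kcal_per_mol[sig$quantity == "-TdS"]
  expect_identical(dg, dh + tds)
  expect_equal(dg, 1.987204e-3 * 298.15 * log(1e-9), tolerance = 1e-12)
  # dG = RT ln(1e-9) at 298.15 K is -12.28 kcal/mol
  expect_equal(round(dg, 2), -12.28)
  # K_D = 1 M -> dG = 0; dH = dG -> -TdS = 0
  sig0 <- thermodynamic_signature(list(kd_M = 1, dh_kcal = -5,
                                       temperature = 298.15))
  expect_equal(sig0$kcal_per_mol[sig0$quantity == "dG"], 0)
  sig1 <- thermodynamic_signature(list(kd_M = 1e-9,
                                       dh_kcal = unname(dg),
                                       temperature = 298.15))
  expect_equal(sig1$kcal_per_mol[sig1$quantity == "-TdS"], 0)
})

test_that("fits report the Wiseman window and broom methods are tidy", {
  truth <- list(n = 1, kd_M = 1e-11, dh_kcal = -12) # c = 1e6, outside window
  ti <- simulate_itc_isotherm(truth, noise_frac = 0.001, seed = 5)
  expect_warning(fit <- fit_one_site(ti), "Wiseman")
  expect_true(any(grepl("outside", fit$flags)))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("n", "kd_M", "dh_kcal", "dg_kcal",
                             "minus_tds_kcal"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1)
  # heats CSV round trip
  p <- withr::local_tempfile(fileext = ".csv")
  write_itc_csv(ti, p)
  back <- read_itc_csv(p)
  expect_equal(back$heats_ucal, ti$heats_ucal, tolerance = 1e-12)
})
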