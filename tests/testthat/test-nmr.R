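# Chemical-shift perturbation, secondary shifts, hetNOE differences, trend
# classification, and the synthetic shift-table generator.

shift_tbl <- function(residues, h, n, state = "free") {
  dplyr::bind_rows(
    tibble::tibble(residue = residues, restype = "ALA", atom = "H",
                   shift_ppm = h, state = state),
    tibble::tibble(residue = residues, restype = "ALA", atom = "N",
                   shift_ppm = n, state = state)
  )
}

test_that("combined CSP follows the weighted quadrature formula", {
  f <- shift_tbl(1:3, c(8.1, 8.2, 8.3), c(118, 119, 120))
  b <- shift_tbl(1:3, c(8.1, 8.23, 8.3), c(118, 119.5, 121), "bound")
  out <- combined_csp(f, b, alpha = 0.14)
  expect_equal(out$csp_ppm[1], 0)
  expect_equal(out$csp_ppm[2], sqrt(0.03^2 + (0.14 * 0.5)^2),
               tolerance = 1e-12)
  # 0.0762 ppm for the canonical example values
  expect_equal(round(out$csp_ppm[2], 4), 0.0762)
  # dN = 0 reduces to |dH|
  b2 <- shift_tbl(1:3, c(8.15, 8.2, 8.3), c(118, 119, 120), "bound")
  expect_equal(combined_csp(f, b2)$csp_ppm[1], 0.05, tolerance = 1e-12)
})

test_that("CSP reports missing residues as absent, not zero", {
  f <- shift_tbl(1:3, c(8.1, 8.2, 8.3), c(118, 119, 120))
  b <- shift_tbl(2:4, c(8.2, 8.3, 8.4), c(119, 120, 121), "bound")
  out <- combined_csp(f, b)
  expect_setequal(out$residue, 2:3)
  dup <- dplyr::bind_rows(f, f[1:2, ])
  expect_error(combined_csp(dup, b), class = "lidfold_duplicate_records")
})

test_that("operations are invariant to input row order", {
  f <- shift_tbl(1:5, 8 + (1:5) / 10, 118 + (1:5))
  b <- shift_tbl(1:5, 8.05 + (1:5) / 10, 118.5 + (1:5), "bound")
  out1 <- combined_csp(f, b)
  out2 <- combined_csp(f[sample(nrow(f)), ], b[sample(nrow(b)), ])
  expect_equal(out1, out2)
})

test_that("secondary shifts subtract the random-coil reference by type", {
  ref <- random_coil_reference()
  ala_ca <- ref$shift_ppm[ref$restype == "ALA" & ref$atom == "CA"]
  tb <- tibble::tibble(residue = 1:3, restype = "ALA", atom = "CA",
                       shift_ppm = ala_ca + c(0, 2, -1.4), state = "free")
  out <- secondary_shifts(tb, "CA")
  expect_equal(out$secondary_shift_ppm, c(0, 2, -1.4), tolerance = 1e-12)
  # uniform offset propagates
  tb2 <- tb
  tb2$shift_ppm <- tb2$shift_ppm + 2
  expect_equal(secondary_shifts(tb2, "CA")$secondary_shift_ppm,
               c(2, 4, 0.6), tolerance = 1e-12)
  tb3 <- tb
  tb3$restype <- "XXX"
  expect_error(secondary_shifts(tb3, "CA"),
               class = "lidfold_missing_reference")
})

test_that("hetNOE difference is a literal subtraction with mobility flag", {
  b <- tibble::tibble(residue = 1:3, hetnoe = c(0.8, 0.5, 0.3))
  f <- tibble::tibble(residue = 1:3, hetnoe = c(0.3, 0.5, 0.4))
  out <- delta_hetnoe(b, f)
  expect_equal(out$delta_hetnoe, c(0.5, 0, -0.1))
  expect_equal(out$decreased_mobility, c(TRUE, FALSE, FALSE))
  expect_error(delta_hetnoe(b, f[1:2, ]), class = "lidfold_missing_state")
})

test_that("trend classifier reproduces the strand-then-helix pattern", {
  # profile shaped like the measured secondary-shift pattern: negative
  # around residues 12-16, positive around 20-23
  prof <- tibble::tibble(
    residue = 10:25,
    secondary_shift_ppm = c(0.05, -0.1, -0.3, -0.25, -0.4, -0.2, -0.35,
                            0.1, -0.05, 0.1, 0.45, 0.5, 0.3, 0.4, 0.1,
                            -0.05)
  )
  s1 <- trend_classifier(prof, 12:16)
  expect_equal(s1$trend, "strand-ward")
  s2 <- trend_classifier(prof, 20:23)
  expect_equal(s2$trend, "helix-ward")
  # all positive -> helix-ward; symmetric -> none
  allpos <- tibble::tibble(residue = 1:6, secondary_shift_ppm = rep(0.2, 6))
  expect_equal(trend_classifier(allpos, 1:6)$trend, "helix-ward")
  sym <- tibble::tibble(residue = 1:6,
                        secondary_shift_ppm = c(-1, 1, -1, 1, -1, 1))
  expect_equal(trend_classifier(sym, 1:6)$trend, "none")
  expect_error(trend_classifier(sym, 1:2), class = "lidfold_invalid_config")
})

test_that("shift simulation: identity, helix signature, linear mixing", {
  sys <- lid_system()
  ens <- sample_ensemble(sys, 10000, seed = 2, stride = 20)
  # identical ensembles, zero noise -> zero CSP and zero delta-hetNOE
  tabs <- simulate_shift_tables(ens, ens, noise_sd = 0, seed = 1)
  f <- tabs$shifts[tabs$shifts$state == "free", ]
  b <- tabs$shifts[tabs$shifts$state == "bound", ]
  expect_equal(max(combined_csp(f, b)$csp_ppm), 0)
  relax <- tabs$relaxation
  dn <- delta_hetnoe(relax[relax$state == "bound", ],
                     relax[relax$state == "free", ])
  expect_equal(max(abs(dn$delta_hetnoe)), 0)
  # fully helical bound ensemble -> positive secondary 13Ca everywhere
  hel <- ensemble_from_torsions(
    matrix(rep(sys$theta_h, 2 * n_torsions(sys)), 2, byrow = TRUE), sys
  )
  tabs2 <- simulate_shift_tables(ens, hel, noise_sd = 0, seed = 1)
  b2 <- tabs2$shifts[tabs2$shifts$state == "bound", ]
  sec <- secondary_shifts(b2, "CA")
  expect_true(all(sec$secondary_shift_ppm > 0))
  # linear mixing arithmetic: 0.5/0.5 at amplitudes +2.6/-1.4 -> +0.6 ppm
  expect_equal(0.5 * 2.6 + 0.5 * (-1.4), 0.6)
})

test_that("shift tables round-trip through CSV and NMR-STAR import works", {
  sys <- lid_system()
  ens <- sample_ensemble(sys, 4000, seed = 4, stride = 40)
  tabs <- simulate_shift_tables(ens, ens, noise_sd = 0.01, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_shift_csv(tabs$shifts, p)
  back <- read_shift_csv(p)
  expect_equal(back$shift_ppm, tabs$shifts$shift_ppm, tolerance = 1e-9)
  # minimal NMR-STAR assigned-chemical-shift loop
  star <- withr::local_tempfile(fileext = ".str")
  writeLines(c(
    "data_synthetic", "", "save_assigned_chem_shift_list_1", "loop_",
    "   _Atom_chem_shift.Seq_ID", "   _Atom_chem_shift.Comp_ID",
    "   _Atom_chem_shift.Atom_ID", "   _Atom_chem_shift.Val",
    "   6 ALA H 8.31", "   6 ALA N 118.2", "   6 ALA CA 52.7",
    "   6 ALA C 177.5", "   7 ALA HB 1.2", "stop_", "save_"
  ), star)
  got <- read_nmrstar_shifts(star, state = "free")
  expect_equal(nrow(got), 4) # HB filtered out
  expect_setequal(got$atom, c("H", "N", "CA", "CO"))
  expect_equal(got$shift_ppm[got$atom == "CO"], 177.5)
})
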