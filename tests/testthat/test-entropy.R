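# k-NN entropy estimators and conformational / roto-translational
# entropy differences.

test_that("knn entropy matches analytic values for circular distributions", {
  set.seed(101)
  sigma <- 20 * pi / 180
  x <- rnorm(5000, 0, sigma) # narrow: wrapping negligible
  h_gauss <- knn_entropy(matrix(x, ncol = 1))
  expect_lt(abs(h_gauss - 0.5 * log(2 * pi * exp(1) * sigma^2)),
            0.05 * abs(0.5 * log(2 * pi * exp(1) * sigma^2)))
  u <- runif(5000, -pi, pi)
  h_unif <- knn_entropy(matrix(u, ncol = 1))
  expect_lt(abs(h_unif - log(2 * pi)), 0.03 * log(2 * pi))
})

test_that("degenerate samples raise an error", {
  x <- matrix(rep(0.3, 50), ncol = 1)
  expect_error(knn_entropy(x), class = "lidfold_degenerate_density")
  expect_error(knn_entropy(matrix(rnorm(3), ncol = 1), k = 4),
               class = "lidfold_invalid_config")
})

test_that("estimator bias decreases with sample size", {
  sigma <- 0.5
  h_true <- 0.5 * log(2 * pi * exp(1) * sigma^2)
  err <- vapply(c(250, 1000, 3000), function(n) {
    e <- vapply(1:10, function(s) {
      set.seed(1000 + s)
      abs(knn_entropy(matrix(rnorm(n, 0, sigma), ncol = 1)) - h_true)
    }, 1.0)
    median(e)
  }, 1.0)
  expect_true(all(diff(err) < 0))
})

test_that("identical ensembles give zero entropy difference", {
  sys <- lid_system()
  ens <- sample_ensemble(sys, 20000, seed = 3, stride = 20)
  rep_ <- conformational_entropy_difference(ens, ens, n_boot = 16, seed = 2)
  expect_equal(rep_$minus_t_delta_s, 0)
  expect_true(rep_$ci[1] <= 0 && rep_$ci[2] >= 0)
})

test_that("halving one torsion's variance gives (kT/2) ln 2 for that term", {
  set.seed(7)
  n <- 4000
  sys <- lid_system(n_residues = 8, contact_residue_index = 4)
  free_t <- matrix(rnorm(n * 5, 0, 25), n, 5)
  bound_t <- free_t
  bound_t[, 3] <- rnorm(n, 0, 25 / sqrt(2)) # variance halved
  free <- ensemble_from_torsions(wrap_deg(free_t), sys)
  bound <- ensemble_from_torsions(wrap_deg(bound_t), sys)
  rep_ <- conformational_entropy_difference(free, bound, n_boot = 0)
  kT <- kT_kcal(300)
  expected <- kT / 2 * log(2)
  got <- rep_$per_torsion$minus_t_ds
  expect_equal(got[3], expected, tolerance = 0.15)
  expect_lt(max(abs(got[-3])), 0.03)
  expect_equal(rep_$minus_t_delta_s, sum(got))
})

test_that("joint order captures pairwise correlation exactly", {
  # bivariate Gaussian: H_joint = H1 + H2 + 0.5 log(1 - rho^2)
  set.seed(12)
  n <- 4000
  rho <- 0.8
  sigma <- 20 # degrees: narrow enough that wrapping is negligible
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  sys <- lid_system(n_residues = 8, contact_residue_index = 4)
  tor <- cbind(sigma * z1, sigma * z2,
               matrix(rnorm(n * 3, 0, sigma), n, 3))
  ens <- ensemble_from_torsions(wrap_deg(tor), sys)
  rep_j <- conformational_entropy_difference(ens, ens, order = "joint",
                                             n_boot = 0,
                                             torsion_subset = 1:2)
  # difference of identical ensembles is zero regardless of order...
  expect_equal(rep_j$minus_t_delta_s, 0)
  # ...so check the joint estimator itself against the closed form
  h_joint <- knn_entropy(wrap_deg(tor[, 1:2]) * pi / 180)
  h1 <- 0.5 * log(2 * pi * exp(1) * (sigma * pi / 180)^2)
  h_true <- 2 * h1 + 0.5 * log(1 - rho^2)
  expect_lt(abs(h_joint - h_true), 0.05 * abs(h_true))
})

test_that("independent torsions have near-zero MI correction", {
  set.seed(8)
  n <- 3000
  sys <- lid_system(n_residues = 8, contact_residue_index = 4)
  tor <- matrix(rnorm(n * 5, 0, 30), n, 5)
  ens <- ensemble_from_torsions(wrap_deg(tor), sys)
  rep_ <- conformational_entropy_difference(ens, ens, order = "first+MI",
                                            n_boot = 0)
  # MI estimates on independent data: small positive bias only
  expect_lt(max(c(rep_$mi_free, rep_$mi_bound)), 0.05)
})

test_that("entropy difference errors on weight degeneracy and mismatch", {
  sys <- lid_system(n_residues = 8, contact_residue_index = 4)
  tor <- matrix(rnorm(500 * 5, 0, 30), 500, 5)
  ens <- ensemble_from_torsions(wrap_deg(tor), sys)
  w <- c(rep(1e-12, 499), 1)
  degen <- reweighted_ensemble(ens, w)
  expect_error(conformational_entropy_difference(degen, ens),
               class = "lidfold_degenerate_weights")
  sys2 <- lid_system(n_residues = 10, contact_residue_index = 4)
  ens2 <- ensemble_from_torsions(matrix(rnorm(500 * 7, 0, 30), 500, 7), sys2)
  expect_error(conformational_entropy_difference(ens, ens2),
               class = "lidfold_topology_mismatch")
})

make_pose_ensemble <- function(pos, q) {
  n <- nrow(pos)
  parts <- tibble::tibble(index = 1:3, role = rep("CA", 3), residue = 1:3)
  conformer_ensemble(array(rep(diag(3), n), c(3, 3, n)), parts,
                     lig_pose = cbind(pos, q))
}

rand_quat <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q / sqrt(rowSums(q^2))
}

test_that("ligand entropy reference case: uniform in standard volume", {
  set.seed(9)
  n <- 4000
  side <- 1661^(1 / 3)
  pos <- matrix(runif(3 * n, 0, side), ncol = 3)
  ens <- make_pose_ensemble(pos, rand_quat(n))
  out <- ligand_rototranslational_entropy(ens)
  # additive allowances cover the known k-NN boundary bias of a uniform box
  expect_lt(abs(out$minus_t_ds_trans), 3 * out$se_trans + 0.05)
  expect_lt(abs(out$minus_t_ds_rot), 3 * out$se_rot + 0.05)
})

test_that("Gaussian pose cloud matches the closed-form translational loss", {
  set.seed(10)
  n <- 4000
  pos <- matrix(rnorm(3 * n, 0, 0.5), ncol = 3)
  ens <- make_pose_ensemble(pos, rand_quat(n))
  out <- ligand_rototranslational_entropy(ens)
  analytic <- -kT_kcal(300) * log((2 * pi * exp(1))^(3 / 2) * 0.5^3 / 1661)
  expect_lt(abs(out$minus_t_ds_trans - analytic), 0.1 * analytic)
  # tighter binding -> strictly larger loss
  pos2 <- matrix(rnorm(3 * n, 0, 0.25), ncol = 3)
  out2 <- ligand_rototranslational_entropy(make_pose_ensemble(pos2,
                                                              rand_quat(n)))
  expect_gt(out2$minus_t_ds_trans, out$minus_t_ds_trans)
})

test_that("ligand entropy input validation", {
  sys <- lid_system(n_residues = 8, contact_residue_index = 4)
  ens <- ensemble_from_torsions(matrix(rnorm(200 * 5, 0, 30), 200, 5), sys)
  expect_error(ligand_rototranslational_entropy(ens),
               class = "lidfold_no_ligand")
  set.seed(11)
  small <- make_pose_ensemble(matrix(rnorm(150, 0, 1), ncol = 3),
                              rand_quat(50))
  w <- c(1, rep(1e-14, 49))
  expect_error(
    ligand_rototranslational_entropy(reweighted_ensemble(small, w)),
    class = "lidfold_degenerate_weights"
  )
})
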