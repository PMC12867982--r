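# Coarse-grained two-basin lid-peptide model.
#
# The lid is a CA trace with fixed pseudo-bond length and pseudo-bond angle;
# each sliding 4-particle pseudo-dihedral feels a two-basin potential (helical
# and coil minima), nearest-neighbour torsions are coupled cooperatively, and
# an optional rigid three-particle ligand rewards contact between its contact
# site and one designated lid residue -- the synthetic analogue of the
# I19/chlorophenyl non-polar contact that drives folding-upon-binding.

#' Build a coarse-grained lid-peptide system
#'
#' Defines the energy function
#' \deqn{U(\theta, \mathrm{pose}) = \sum_i V_{tor}(\theta_i)
#'   - J \sum_i \cos(\theta_i - \theta_{i+1}) - \epsilon\, S(d_{contact})
#'   + U_{box}(\mathrm{pose})}
#' where \eqn{V_{tor}} is minus \eqn{k_BT} times the log of a two-Gaussian
#' mixture in the wrapped torsion angle (helical minimum `theta_h`, coil
#' minimum `theta_c`, basin offset `delta_u_hc` penalising the helical basin),
#' \eqn{S} is a logistic switching function on the distance between the
#' contact residue and the ligand contact site, and \eqn{U_{box}} confines the
#' ligand centroid to a flat-bottom binding box. With `ligand_present = FALSE`
#' the last two terms vanish.
#'
#' The chain is anchored at its C-terminal stub (the attachment to the
#' structured core), so the laboratory frame is the core frame. The ligand
#' binding box is centred on the position the contact residue occupies in the
#' all-helical conformation, which couples helix formation at the base of the
#' lid to formation of the residue-ligand contact.
#'
#' @param n_residues number of CA particles (default 23, a lid of residues
#'   6-28 numbered by `residue_start`).
#' @param bond_length pseudo-bond length in Angstrom.
#' @param pseudo_angle fixed pseudo-bond angle in degrees.
#' @param theta_h,sigma_h helical torsion minimum and Gaussian width (degrees).
#' @param theta_c,sigma_c coil torsion minimum and width (degrees).
#' @param delta_u_hc free-energy offset of the helical basin relative to the
#'   coil basin, kcal/mol (positive disfavours helix, so the apo lid is
#'   disordered).
#' @param coupling_j nearest-neighbour torsion coupling strength, kcal/mol.
#' @param contact_residue_index 1-based particle index of the contact residue
#'   (the "I19 analog").
#' @param contact_epsilon well depth of the residue-ligand contact, kcal/mol.
#'   Setting this to 0 is the "I19G analog" mutation.
#' @param contact_range switching distance of the contact, Angstrom. Reducing
#'   it is the "T16G analog" mutation.
#' @param switch_width logistic switching width, Angstrom.
#' @param box_halfwidth,box_k flat-bottom binding-box half width (Angstrom)
#'   and wall stiffness (kcal/mol/A^2).
#' @param ligand_site_offset distance from ligand centroid to its contact site
#'   and orientation marker, Angstrom.
#' @param ligand_present logical; include the rigid three-particle ligand?
#' @param temperature Kelvin.
#' @param residue_start residue number of the first particle (for labelling
#'   per-residue observables; default 6).
#' @return an object of class `lid_system`.
#' @export
lid_system <- function(n_residues = 23, bond_length = 3.8, pseudo_angle = 91,
                       theta_h = 50, sigma_h = 15, theta_c = 180,
                       sigma_c = 35, delta_u_hc = 0.4, coupling_j = 0.3,
                       contact_residue_index = 14, contact_epsilon = 9,
                       contact_range = 2.5, switch_width = 1,
                       box_halfwidth = 1.5, box_k = 10,
                       ligand_site_offset = 1.5, ligand_present = FALSE,
                       temperature = 300, residue_start = 6) {
  if (n_residues < 5) {
    stop_lidfold("n_residues must be >= 5 (no helix definable below that)",
                 "lidfold_invalid_system")
  }
  if (bond_length <= 0) {
    stop_lidfold("bond_length must be positive", "lidfold_invalid_system")
  }
  if (sigma_h <= 0 || sigma_c <= 0) {
    stop_lidfold("basin widths must be positive", "lidfold_invalid_system")
  }
  if (contact_epsilon < 0) {
    stop_lidfold("contact_epsilon must be >= 0", "lidfold_invalid_system")
  }
  if (contact_residue_index < 1 || contact_residue_index > n_residues) {
    stop_lidfold("contact_residue_index out of range",
                 "lidfold_invalid_system")
  }
  if (temperature <= 0) {
    stop_lidfold("temperature must be positive", "lidfold_invalid_system")
  }
  sys <- structure(
    list(
      n_residues = as.integer(n_residues), bond_length = bond_length,
      pseudo_angle = pseudo_angle, theta_h = theta_h, sigma_h = sigma_h,
      theta_c = theta_c, sigma_c = sigma_c, delta_u_hc = delta_u_hc,
      coupling_j = coupling_j,
      contact_residue_index = as.integer(contact_residue_index),
      contact_epsilon = contact_epsilon, contact_range = contact_range,
      switch_width = switch_width, box_halfwidth = box_halfwidth,
      box_k = box_k, ligand_site_offset = ligand_site_offset,
      ligand_present = isTRUE(ligand_present), temperature = temperature,
      residue_start = as.integer(residue_start),
      anchor = c(0, 0, 0)
    ),
    class = "lid_system"
  )
  # binding-box centre: contact-residue position in the all-helical chain
  helical <- build_chain(rep(theta_h, n_residues - 3), sys)
  sys$anchor <- as.numeric(helical[contact_residue_index, ])
  sys
}

#' @export
print.lid_system <- function(x, ...) {
  cat("<lid_system> ", x$n_residues, " residues (",
      x$residue_start, "-", x$residue_start + x$n_residues - 1, "), ",
      if (x$ligand_present) "holo" else "apo", "\n", sep = "")
  cat("  torsion basins: helix ", x$theta_h, "deg (sd ", x$sigma_h,
      "), coil ", x$theta_c, "deg (sd ", x$sigma_c, "), offset ",
      x$delta_u_hc, " kcal/mol\n", sep = "")
  cat("  coupling J = ", x$coupling_j, " kcal/mol; contact eps = ",
      x$contact_epsilon, " kcal/mol at residue index ",
      x$contact_residue_index, "\n", sep = "")
  invisible(x)
}

# number of pseudo-dihedrals
n_torsions <- function(system) system$n_residues - 3L

#' Rebuild chain coordinates from torsions
#'
#' Serial chain extension with fixed bond length and pseudo-bond angle from
#' the fixed C-terminal stub. Rows 1..n_residues are CA particles (row 1 is
#' the lid tip); the final two rows are the rigid core-anchor pseudo-particles.
#'
#' @param torsions numeric vector of `n_residues - 3` pseudo-dihedrals (deg).
#' @param system a [lid_system()].
#' @return a numeric matrix with `n_residues + 2` rows and columns x, y, z.
#' @export
build_chain <- function(torsions, system) {
  stopifnot(length(torsions) == n_torsions(system))
  xyz <- build_chain_cpp(as.numeric(torsions), system$n_residues,
                         system$bond_length, system$pseudo_angle)
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Total potential energy of a conformation
#'
#' @param system a [lid_system()].
#' @param torsions pseudo-dihedral vector in degrees.
#' @param ligand_pose length-7 numeric `(x, y, z, qw, qx, qy, qz)` giving the
#'   ligand centroid and orientation quaternion; required when
#'   `system$ligand_present`.
#' @return energy in kcal/mol (finite for all torsion values).
#' @export
lid_energy <- function(system, torsions, ligand_pose = NULL) {
  stopifnot(inherits(system, "lid_system"),
            length(torsions) == n_torsions(system))
  chain_energy_cpp(unclass(system), as.numeric(torsions),
                   if (is.null(ligand_pose)) NULL else as.numeric(ligand_pose))
}

#' Single-torsion potential
#'
#' The two-basin torsion potential evaluated at angles `theta` (degrees).
#'
#' @inheritParams lid_energy
#' @param theta angles in degrees.
#' @return energies in kcal/mol.
#' @export
torsion_potential <- function(system, theta) {
  torsion_potential_cpp(unclass(system), as.numeric(theta))
}

#' Helical-basin boundary (Voronoi midpoints between the two minima)
#'
#' @inheritParams lid_energy
#' @return numeric length-2: the wrapped interval (lo, hi) around `theta_h`
#'   closer to the helical minimum than to the coil minimum.
#' @export
helix_basin <- function(system) {
  th <- system$theta_h
  tc <- system$theta_c
  # midpoints between the two minima along both arcs of the circle
  m1 <- th + wrap_deg(tc - th) / 2
  b <- sort(wrap_deg(c(m1, m1 + 180)))
  if (wrap_deg(th) > b[1] && wrap_deg(th) <= b[2]) {
    c(lo = b[1], hi = b[2])
  } else {
    c(lo = b[2], hi = b[1] + 360)
  }
}

# is angle (deg) inside the helical basin of the system?
in_helix_basin <- function(theta, system) {
  b <- helix_basin(system)
  y <- wrap_deg(theta)
  y2 <- ifelse(y < b["lo"], y + 360, y)
  y2 >= b["lo"] & y2 <= b["hi"]
}

#' Single-torsion Boltzmann marginal by quadrature
#'
#' For an uncoupled system (`coupling_j = 0`, no ligand) the per-torsion
#' Boltzmann marginal factorises; this evaluates it on a grid by numerical
#' quadrature, and integrates the helical-basin occupancy. Used as the
#' analytic oracle for the Metropolis sampler.
#'
#' @inheritParams lid_energy
#' @param n_grid quadrature grid size over (-180, 180].
#' @return a list with `grid` (degrees), `density` (per degree, sums to 1 when
#'   multiplied by the grid step) and `helix_occupancy`.
#' @export
torsion_marginal <- function(system, n_grid = 7200) {
  kT <- kT_kcal(system$temperature)
  grid <- seq(-180, 180, length.out = n_grid + 1)[-1]
  v <- torsion_potential(system, grid)
  w <- exp(-(v - min(v)) / kT)
  step <- 360 / n_grid
  dens <- w / (sum(w) * step)
  occ <- sum(dens[in_helix_basin(grid, system)]) * step
  list(grid = grid, density = dens, helix_occupancy = occ)
}
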