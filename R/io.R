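# File interchange: multi-model PDB for ensembles (occupancy column carries
# the frame weight), CSV for torsion/CV/ITC/shift/FES tables, JSON for run
# configurations. PDB reading goes through bio3d; writing uses a small
# fixed-width formatter because no installed package writes multi-model
# coordinate ensembles.

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; chain CA particles are ATOM records
#' (residue type UNK), core anchors and ligand particles are HETATM records
#' (residues ANC and LIG). The occupancy column carries the frame weight.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  parts <- ensemble$particles
  nf <- n_frames(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK  synthetic lid-peptide ensemble (lidfold)", con)
  # coordinates are 1e-3 A in PDB format; carry torsions at full precision
  if (!is.null(ensemble$torsions)) {
    for (f in seq_len(nf)) {
      writeLines(sprintf("REMARK 299 TORSIONS %d %s", f,
                         paste(sprintf("%.6f", ensemble$torsions[f, ]),
                               collapse = " ")), con)
    }
  }
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    occ <- min(ensemble$weights[f], 9.9999)
    for (p in seq_len(nrow(parts))) {
      role <- parts$role[p]
      rec <- if (role == "CA") "ATOM  " else "HETATM"
      resn <- switch(role, CA = "UNK", ANC = "ANC", LIG = "LIG")
      atn <- switch(role, CA = " CA ", ANC = " X  ",
                    LIG = c(" L1 ", " L2 ", " L3 ")[
                      p - min(which(parts$role == "LIG")) + 1])
      resid <- if (role == "CA") parts$residue[p] else parts$index[p]
      writeLines(sprintf(
        "%s%5d %s %s A%4d    %8.3f%8.3f%8.3f%6.4f%6.2f",
        rec, p, atn, resn, resid,
        ensemble$coords[p, 1, f], ensemble$coords[p, 2, f],
        ensemble$coords[p, 3, f], occ, 0
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into an ensemble
#'
#' Uses `bio3d::read.pdb(..., multi = TRUE)`. CA atoms become chain
#' particles; HETATM residues ANC and LIG are restored to their roles. Frame
#' weights are taken from the occupancy column and renormalised.
#' Pseudo-dihedrals are recomputed from the CA coordinates.
#'
#' @param path a PDB file.
#' @return a [conformer_ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop_lidfold("bio3d is required to read PDB files", "lidfold_missing_pkg")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  np <- nrow(at)
  nf <- nrow(pdb$xyz)
  coords <- array(NA_real_, c(np, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  }
  role <- ifelse(at$resid == "ANC", "ANC",
                 ifelse(at$resid == "LIG", "LIG", "CA"))
  particles <- tibble(
    index = seq_len(np), role = role,
    residue = ifelse(role == "CA", at$resno, NA_integer_)
  )
  w <- rep(NA_real_, nf)
  # occupancy of the first atom per model carries the frame weight
  w[] <- vapply(seq_len(nf), function(f) at$o[1], 1.0)
  # bio3d keeps only the first model's occupancy; recover per-model weights
  # directly from the file text when present
  occ_lines <- grep("^(ATOM  |HETATM)", readLines(path), value = TRUE)
  if (length(occ_lines) == np * nf) {
    occ <- as.numeric(substr(occ_lines, 55, 60))
    w <- occ[seq(1, np * nf, by = np)]
  }
  if (anyNA(w) || sum(w) <= 0) w <- rep(1, nf)
  ca <- which(role == "CA")
  n_res <- length(ca)
  torsions <- NULL
  rem <- grep("^REMARK 299 TORSIONS", readLines(path), value = TRUE)
  if (length(rem) == nf) {
    torsions <- do.call(rbind, lapply(rem, function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]][-(1:4)])
    }))
  } else if (n_res >= 4) {
    torsions <- matrix(NA_real_, nf, n_res - 3)
    for (f in seq_len(nf)) {
      for (i in seq_len(n_res - 3)) {
        torsions[f, i] <- dihedral_cpp(
          coords[ca[i], , f], coords[ca[i + 1], , f],
          coords[ca[i + 2], , f], coords[ca[i + 3], , f]
        )
      }
    }
  }
  conformer_ensemble(coords, particles, weights = w, torsions = torsions,
                     provenance = list(source = path))
}

#' Write / read a torsion table CSV
#'
#' Columns `frame`, `residue`, `theta_deg` (the CSV dialect shared by the
#' pipeline outputs).
#'
#' @param ensemble a [conformer_ensemble()] with torsions.
#' @param path file path.
#' @return `path` (write) or a tibble (read).
#' @export
write_torsion_csv <- function(ensemble, path) {
  readr::write_csv(torsion_table(ensemble)[, c("frame", "residue",
                                               "theta_deg")], path)
  invisible(path)
}

#' @rdname write_torsion_csv
#' @export
read_torsion_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a CV series CSV (`frame`, `extension_A`, `dihedral_deg`)
#'
#' @param cv_table a tibble as from [cv_timeseries()].
#' @param path file path.
#' @export
write_cv_csv <- function(cv_table, path) {
  readr::write_csv(cv_table, path)
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
read_cv_csv <- function(path) readr::read_csv(path, show_col_types = FALSE)

#' Write / read ITC heats CSV (`injection`, `volume_uL`, `heat_ucal`)
#'
#' @param titration an [itc_titration()] with heats.
#' @param path file path.
#' @export
write_itc_csv <- function(titration, path) {
  readr::write_csv(
    tibble(injection = seq_along(titration$injection_volumes_uL),
           volume_uL = titration$injection_volumes_uL,
           heat_ucal = titration$heats_ucal),
    path
  )
  invisible(path)
}

#' @rdname write_itc_csv
#' @param cell_conc_M,syringe_conc_M,cell_volume_mL,temperature protocol
#'   fields not stored in the CSV.
#' @export
read_itc_csv <- function(path, cell_conc_M = 10e-6, syringe_conc_M = 150e-6,
                         cell_volume_mL = 0.2, temperature = 298.15) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  itc_titration(d$volume_uL, d$heat_ucal, cell_conc_M, syringe_conc_M,
                cell_volume_mL, temperature)
}

#' Write a free-energy surface as CSV
#'
#' Columns `cv1` (extension, A), `cv2` (dihedral, deg), `F_kcalmol`,
#' `uncertainty`, `sampled_flag`.
#'
#' @param fes a [free_energy_surface()].
#' @param path file path.
#' @export
write_fes_csv <- function(fes, path) {
  tb <- tidy(fes)
  readr::write_csv(
    tibble(cv1 = tb$extension_A, cv2 = tb$dihedral_deg,
           F_kcalmol = tb$F_kcalmol, uncertainty = tb$se,
           sampled_flag = tb$sampled),
    path
  )
  invisible(path)
}

#' Write / read shift tables CSV
#' (`residue`, `restype`, `atom`, `shift_ppm`, `state`)
#'
#' @param shifts a shift tibble.
#' @param path file path.
#' @export
write_shift_csv <- function(shifts, path) {
  readr::write_csv(shifts, path)
  invisible(path)
}

#' @rdname write_shift_csv
#' @export
read_shift_csv <- function(path) readr::read_csv(path, show_col_types = FALSE)
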