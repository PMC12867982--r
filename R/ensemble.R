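# ConformerEnsemble: frames of labelled particle coordinates with per-frame
# statistical weights -- the universal currency of the pipeline.

#' Construct a conformer ensemble
#'
#' Usually produced by [sample_ensemble()]; the constructor is exported so
#' ensembles can also be assembled from user-supplied coordinates (e.g. a
#' multi-model PDB read with [read_ensemble_pdb()]).
#'
#' @param coords numeric array `(n_particles, 3, n_frames)` in Angstrom.
#' @param particles a tibble describing the shared topology, with columns
#'   `index`, `role` (one of `"CA"`, `"ANC"`, `"LIG"`) and `residue`
#'   (residue number for CA particles, `NA` otherwise).
#' @param weights per-frame non-negative weights; normalised to sum to 1.
#' @param torsions optional `(n_frames, n_torsions)` matrix of pseudo-dihedrals
#'   in degrees, wrapped into (-180, 180].
#' @param lig_pose optional `(n_frames, 7)` matrix of ligand poses
#'   `(x, y, z, qw, qx, qy, qz)`.
#' @param system the generating [lid_system()], if any.
#' @param provenance a list recording seed and sampling parameters.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(coords, particles, weights = NULL,
                               torsions = NULL, lig_pose = NULL,
                               system = NULL, provenance = list()) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_frames <- dim(coords)[3]
  if (nrow(particles) != dim(coords)[1]) {
    stop_lidfold("particle table does not match coordinate array",
                 "lidfold_topology_mismatch")
  }
  if (is.null(weights)) weights <- rep(1, n_frames)
  if (length(weights) != n_frames || any(weights < 0) || sum(weights) <= 0) {
    stop_lidfold("weights must be non-negative, one per frame, with positive sum",
                 "lidfold_bad_weights")
  }
  if (!is.null(torsions)) {
    stopifnot(nrow(torsions) == n_frames)
    torsions <- wrap_deg(torsions)
  }
  structure(
    list(coords = coords, particles = as_tibble(particles),
         weights = weights / sum(weights), torsions = torsions,
         lig_pose = lig_pose, system = system, provenance = provenance),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", n_frames(x), " frames, ",
      nrow(x$particles), " particles (",
      sum(x$particles$role == "CA"), " CA, ",
      sum(x$particles$role == "LIG"), " ligand)\n", sep = "")
  if (!is.null(x$provenance$seed)) {
    cat("  seed ", x$provenance$seed, ", ",
        x$provenance$n_sweeps %||% NA, " sweeps\n", sep = "")
  }
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [conformer_ensemble()].
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Coordinates of one frame
#' @param ensemble a [conformer_ensemble()].
#' @param i frame index.
#' @return matrix `(n_particles, 3)`.
#' @export
frame_coords <- function(ensemble, i) {
  out <- ensemble$coords[, , i, drop = TRUE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Tidy view of an ensemble
#'
#' One row per (frame, particle) with coordinates and frame weight.
#'
#' @param x a [conformer_ensemble()].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.conformer_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  np <- nrow(x$particles)
  tibble(
    frame = rep(seq_len(nf), each = np),
    index = rep(x$particles$index, nf),
    role = rep(x$particles$role, nf),
    residue = rep(x$particles$residue, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ]),
    weight = rep(x$weights, each = np)
  )
}

#' Per-frame torsion table
#'
#' @param ensemble a [conformer_ensemble()] carrying torsions.
#' @return a tibble with columns `frame`, `torsion` (index), `residue` (the
#'   first residue of the 4-particle window) and `theta_deg`.
#' @export
torsion_table <- function(ensemble) {
  if (is.null(ensemble$torsions)) {
    stop_lidfold("ensemble carries no torsions", "lidfold_no_torsions")
  }
  tt <- ensemble$torsions
  nf <- nrow(tt)
  nt <- ncol(tt)
  res0 <- ensemble$system$residue_start %||% 1L
  tibble(
    frame = rep(seq_len(nf), times = nt),
    torsion = rep(seq_len(nt), each = nf),
    residue = rep(res0 + seq_len(nt) - 1L, each = nf),
    theta_deg = as.vector(tt)
  )
}

#' Replace frame weights (reweighted ensemble)
#'
#' Downstream observables computed from the returned ensemble become weighted
#' averages under the new weights (e.g. MBAR weights from umbrella windows).
#'
#' @param ensemble a [conformer_ensemble()].
#' @param weights non-negative weights, one per frame.
#' @return the reweighted `conformer_ensemble`.
#' @export
reweighted_ensemble <- function(ensemble, weights) {
  if (length(weights) != n_frames(ensemble)) {
    stop_lidfold("weight count must equal frame count", "lidfold_bad_weights")
  }
  if (any(weights < 0)) {
    stop_lidfold("weights must be non-negative", "lidfold_bad_weights")
  }
  ensemble$weights <- weights / sum(weights)
  ensemble
}

# weighted mean helper used by observables
wmean <- function(x, w) sum(x * w) / sum(w)

#' Concatenate ensembles sharing a topology
#'
#' @param ensembles list of [conformer_ensemble()] objects with identical
#'   particle tables.
#' @param weights optional per-frame weights for the pooled ensemble.
#' @return a pooled `conformer_ensemble`.
#' @export
bind_ensembles <- function(ensembles, weights = NULL) {
  stopifnot(length(ensembles) >= 1)
  p0 <- ensembles[[1]]$particles
  for (e in ensembles) {
    if (!identical(dim(e$particles), dim(p0)) ||
        !all(e$particles$role == p0$role)) {
      stop_lidfold("ensembles do not share a topology",
                   "lidfold_topology_mismatch")
    }
  }
  coords <- array(
    unlist(lapply(ensembles, function(e) e$coords), use.names = FALSE),
    dim = c(nrow(p0), 3, sum(vapply(ensembles, n_frames, 1L)))
  )
  tors <- if (!is.null(ensembles[[1]]$torsions)) {
    do.call(rbind, lapply(ensembles, function(e) e$torsions))
  }
  lp <- if (!is.null(ensembles[[1]]$lig_pose)) {
    do.call(rbind, lapply(ensembles, function(e) e$lig_pose))
  }
  conformer_ensemble(coords, p0, weights = weights, torsions = tors,
                     lig_pose = lp, system = ensembles[[1]]$system,
                     provenance = list(pooled_from = length(ensembles)))
}
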