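# The two reaction coordinates: lid extension and lid-core dihedral.

#' Define the two collective variables
#'
#' Lid extension is the distance between the centroids of a lid-tip and a
#' lid-base particle group; the lid-core dihedral is the signed dihedral of
#' four group centroids (tip, base, and two core anchor groups). Defaults are
#' derived from the synthetic system topology (tip = first five CA, base =
#' last five CA, core anchors = the two rigid anchor pseudo-particles) and are
#' deliberately configurable: for user-supplied ensembles the group choice is
#' a modelling decision.
#'
#' @param system optional [lid_system()] used to build default selections.
#' @param tip,base integer particle selections for the extension CV.
#' @param dihedral_groups list of four integer particle selections whose
#'   centroids define the pseudo-dihedral, ordered tip-block, base-block,
#'   core anchor 1, core anchor 2.
#' @return an object of class `cv_definition`.
#' @export
cv_definition <- function(system = NULL, tip = NULL, base = NULL,
                          dihedral_groups = NULL) {
  if (!is.null(system)) {
    n <- system$n_residues
    tip <- tip %||% 1:5
    base <- base %||% ((n - 4):n)
    dihedral_groups <- dihedral_groups %||%
      list(tip, base, n + 1L, n + 2L)
  }
  if (is.null(tip) || is.null(base) || is.null(dihedral_groups)) {
    stop_lidfold("provide a system or explicit selections",
                 "lidfold_invalid_cv")
  }
  if (length(tip) == 0 || length(base) == 0 ||
      any(lengths(dihedral_groups) == 0)) {
    stop_lidfold("selections must be non-empty", "lidfold_invalid_cv")
  }
  if (length(intersect(tip, base)) > 0) {
    stop_lidfold("extension groups must be disjoint", "lidfold_invalid_cv")
  }
  if (length(dihedral_groups) != 4) {
    stop_lidfold("dihedral needs four ordered groups", "lidfold_invalid_cv")
  }
  for (i in 1:3) {
    for (j in (i + 1):4) {
      if (length(intersect(dihedral_groups[[i]], dihedral_groups[[j]])) > 0) {
        stop_lidfold("dihedral groups must be disjoint", "lidfold_invalid_cv")
      }
    }
  }
  structure(
    list(extension_groups = list(tip = as.integer(tip),
                                 base = as.integer(base)),
         dihedral_groups = lapply(dihedral_groups, as.integer)),
    class = "cv_definition"
  )
}

resolve_centroid <- function(frame, sel) {
  if (any(sel < 1) || any(sel > nrow(frame))) {
    stop_lidfold("selection does not resolve against the topology",
                 "lidfold_invalid_cv")
  }
  colMeans(frame[sel, , drop = FALSE])
}

#' Lid extension of one frame
#'
#' Euclidean distance (Angstrom) between the tip-group and base-group
#' centroids; non-negative and invariant under rigid motion.
#'
#' @param frame coordinate matrix `(n_particles, 3)`.
#' @param cv a [cv_definition()].
#' @export
lid_extension <- function(frame, cv) {
  a <- resolve_centroid(frame, cv$extension_groups$tip)
  b <- resolve_centroid(frame, cv$extension_groups$base)
  sqrt(sum((a - b)^2))
}

#' Lid-core dihedral of one frame
#'
#' Signed dihedral angle (degrees, in (-180, 180]) of the four group
#' centroids by the standard atan2 construction. Invariant under rigid
#' motion; changes sign under mirror reflection.
#'
#' @inheritParams lid_extension
#' @export
lid_core_dihedral <- function(frame, cv) {
  p <- lapply(cv$dihedral_groups, function(s) resolve_centroid(frame, s))
  b1 <- p[[2]] - p[[1]]
  b2 <- p[[3]] - p[[2]]
  b3 <- p[[4]] - p[[3]]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop_lidfold("collinear centroids: dihedral undefined",
                 "lidfold_undefined_dihedral")
  }
  u2 <- b2 / sqrt(sum(b2^2))
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2],
          n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(cr * u2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Collective-variable time series of an ensemble
#'
#' @param ensemble a [conformer_ensemble()].
#' @param cv a [cv_definition()].
#' @return a tibble `(frame, extension_A, dihedral_deg)`, one row per frame in
#'   frame order.
#' @export
cv_timeseries <- function(ensemble, cv) {
  nf <- n_frames(ensemble)
  ext <- numeric(nf)
  dih <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- frame_coords(ensemble, i)
    ext[i] <- lid_extension(fr, cv)
    dih[i] <- lid_core_dihedral(fr, cv)
  }
  tibble(frame = seq_len(nf), extension_A = ext, dihedral_deg = dih)
}
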