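# Secondary-structure assignment (hydrogen-bond based in the Kabsch-Sander
# style, or torsion-window based for CA-only models) and helix propensity
# with block-averaged standard errors.

# Kabsch-Sander electrostatic H-bond energy between donor residue d (N, H)
# and acceptor residue a (C, O): E = q1*q2*(1/rON + 1/rCH - 1/rOH - 1/rCN)*f,
# kcal/mol, bond when E < -0.5.
ks_energy <- function(N, H, C, O) {
  f <- 332
  q1q2 <- 0.42 * 0.20
  rON <- sqrt(sum((O - N)^2))
  rCH <- sqrt(sum((C - H)^2))
  rOH <- sqrt(sum((O - H)^2))
  rCN <- sqrt(sum((C - N)^2))
  if (min(rON, rCH, rOH, rCN) < 0.5) return(-Inf) # clash guard
  q1q2 * f * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

# backbone tibble (residue, atom, x, y, z) -> logical H-bond matrix
# hb[a, d]: CO of residue a accepts from NH of residue d
ks_hbond_matrix <- function(bb, cutoff = -0.5) {
  res <- sort(unique(bb$residue))
  n <- length(res)
  coord <- function(r, a) {
    row <- bb[bb$residue == r & bb$atom == a, ]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  Ns <- lapply(res, coord, a = "N")
  Hs <- lapply(res, coord, a = "H")
  Cs <- lapply(res, coord, a = "C")
  Os <- lapply(res, coord, a = "O")
  CAs <- lapply(res, coord, a = "CA")
  hb <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    if (is.null(Cs[[a]]) || is.null(Os[[a]])) next
    for (d in seq_len(n)) {
      if (abs(a - d) < 2) next # no bonds to self or sequence neighbours
      if (is.null(Ns[[d]]) || is.null(Hs[[d]])) next
      # cheap CA distance prefilter
      if (!is.null(CAs[[a]]) && !is.null(CAs[[d]]) &&
          sum((CAs[[a]] - CAs[[d]])^2) > 81) next
      e <- ks_energy(Ns[[d]], Hs[[d]], Cs[[a]], Os[[a]])
      hb[a, d] <- e < cutoff
    }
  }
  hb
}

# per-residue labels from the H-bond matrix: H for runs of i->i+4 turns,
# E for beta-bridge ladders (parallel or antiparallel), C otherwise
ks_labels <- function(hb) {
  n <- nrow(hb)
  lab <- rep("C", n)
  turn4 <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i + 4 <= n && hb[i, i + 4]) turn4[i] <- TRUE
  }
  # two consecutive 4-turns at i-1, i define helix for residues i..i+3
  for (i in 2:max(2, n)) {
    if (i <= n && turn4[i] && turn4[i - 1]) {
      lab[i:min(n, i + 3)] <- "H"
    }
  }
  # elementary bridges
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (i - 1 >= 1 && i + 1 <= n &&
                hb[i - 1, j] && hb[j, i + 1]) ||
        (j - 1 >= 1 && j + 1 <= n && hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) ||
        (i - 1 >= 1 && i + 1 <= n && j - 1 >= 1 && j + 1 <= n &&
           hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) bridge[i] <- TRUE
    }
  }
  # ladders: bridge residues adjacent to another bridge residue
  for (i in seq_len(n)) {
    if (bridge[i] &&
        ((i > 1 && bridge[i - 1]) || (i < n && bridge[i + 1]))) {
      if (lab[i] != "H") lab[i] <- "E"
    }
  }
  lab
}

#' Assign per-residue secondary structure to every frame
#'
#' `mode = "hbond"` implements a Kabsch-Sander-style assignment: the
#' electrostatic H-bond energy
#' \eqn{E = q_1 q_2 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN}) \cdot 332}
#' with the standard -0.5 kcal/mol cutoff; H where two consecutive
#' i to i+4 turns occur, E where beta-bridge ladders occur. It requires
#' backbone N/CA/C/O atoms; amide H atoms are built geometrically when
#' absent, and for CA-only ensembles the backbone is first reconstructed
#' with [backbone_from_ca()].
#'
#' `mode = "torsion_window"` labels residue stretches H when at least
#' `min_run` consecutive pseudo-dihedrals fall within `window` degrees of the
#' helical minimum (it cannot detect strand).
#'
#' @param ensemble a [conformer_ensemble()], or a backbone tibble
#'   `(residue, atom, x, y, z)` for a single conformation.
#' @param mode `"hbond"` or `"torsion_window"`.
#' @param window half-width (deg) of the helical torsion window.
#' @param min_run minimum consecutive helical torsions for an H call.
#' @return an object of class `ss_profile`: a list with `labels` (character
#'   matrix frames x residues), `residues`, `weights`.
#' @export
assign_secondary_structure <- function(ensemble, mode = c("hbond",
                                                          "torsion_window"),
                                       window = 45, min_run = 3) {
  mode <- match.arg(mode)
  if (is.data.frame(ensemble)) {
    # single backbone conformation
    bb <- add_amide_h(ensemble)
    lab <- ks_labels(ks_hbond_matrix(bb))
    return(structure(
      list(labels = matrix(lab, nrow = 1),
           residues = sort(unique(ensemble$residue)), weights = 1),
      class = "ss_profile"
    ))
  }
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  ca_rows <- which(ensemble$particles$role == "CA")
  residues <- ensemble$particles$residue[ca_rows]
  nf <- n_frames(ensemble)

  if (mode == "torsion_window") {
    if (is.null(ensemble$torsions)) {
      stop_lidfold("torsion_window mode requires torsions",
                   "lidfold_no_torsions")
    }
    sys <- ensemble$system
    th <- if (!is.null(sys)) sys$theta_h else 50
    nt <- ncol(ensemble$torsions)
    n_res <- length(residues)
    labs <- matrix("C", nf, n_res)
    hel <- ang_diff(ensemble$torsions, th) <= window
    for (f in seq_len(nf)) {
      r <- rle(hel[f, ])
      pos <- cumsum(c(1, r$lengths))
      for (k in seq_along(r$values)) {
        if (r$values[k] && r$lengths[k] >= min_run) {
          a <- pos[k]
          b <- pos[k + 1] - 1
          # torsion i spans particles i..i+3; mark the covered interior
          labs[f, (a + 1):min(n_res, b + 2)] <- "H"
        }
      }
    }
  } else {
    has_bb <- all(c("N", "C", "O") %in% ensemble$particles$role)
    labs <- matrix("C", nf, length(residues))
    for (f in seq_len(nf)) {
      if (has_bb) {
        keep <- ensemble$particles$role %in% c("N", "CA", "C", "O", "H")
        bb <- tibble(
          residue = ensemble$particles$residue[keep],
          atom = ensemble$particles$role[keep],
          x = ensemble$coords[keep, 1, f],
          y = ensemble$coords[keep, 2, f],
          z = ensemble$coords[keep, 3, f]
        )
      } else {
        bb <- backbone_from_ca(ensemble$coords[ca_rows, , f])
        bb$residue <- residues[bb$residue]
      }
      labs[f, ] <- ks_labels(ks_hbond_matrix(add_amide_h(bb)))
    }
  }
  structure(
    list(labels = labs, residues = residues, weights = ensemble$weights),
    class = "ss_profile"
  )
}

#' @export
print.ss_profile <- function(x, ...) {
  cat("<ss_profile> ", nrow(x$labels), " frames x ", length(x$residues),
      " residues; mean H fraction ",
      round(mean(x$labels == "H"), 3), "\n", sep = "")
  invisible(x)
}

#' Per-residue helix propensity with block-averaged standard error
#'
#' Weighted fraction of frames labelled H per residue; the standard error is
#' that of the means of `n_blocks` contiguous frame blocks, which accounts
#' for autocorrelation in sampled trajectories.
#'
#' @param profile an `ss_profile` from [assign_secondary_structure()].
#' @param residue_range optional integer residues to report (default all).
#' @param n_blocks contiguous blocks (>= 2) for the error estimate.
#' @return a tibble `(residue, propensity, sigma_e)`.
#' @export
helix_propensity <- function(profile, residue_range = NULL, n_blocks = 5) {
  if (n_blocks < 2) {
    stop_lidfold("n_blocks must be >= 2", "lidfold_invalid_config")
  }
  residues <- profile$residues
  keep <- if (is.null(residue_range)) {
    seq_along(residues)
  } else {
    match(residue_range, residues)
  }
  if (anyNA(keep)) {
    stop_lidfold("residue_range outside the topology",
                 "lidfold_invalid_config")
  }
  H <- profile$labels[, keep, drop = FALSE] == "H"
  w <- profile$weights
  prop <- colSums(H * w) / sum(w)
  blk <- block_index(nrow(H), n_blocks)
  bm <- vapply(seq_len(n_blocks), function(b) {
    rows <- blk == b
    colSums(H[rows, , drop = FALSE] * w[rows]) / sum(w[rows])
  }, numeric(length(keep)))
  bm <- matrix(bm, nrow = length(keep))
  sig <- apply(bm, 1, sd) / sqrt(n_blocks)
  tibble(residue = residues[keep], propensity = prop, sigma_e = sig)
}
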