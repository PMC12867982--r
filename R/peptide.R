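# Backbone geometry: ideal-geometry peptide builder (NeRF) and approximate
# backbone reconstruction from a CA trace. Needed by the hydrogen-bond-based
# secondary-structure assigner, which wants N/CA/C/O (+ amide H) atoms.

# ideal backbone internal coordinates (Engh-Huber-like)
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_n_h = 1.02,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_ca_c_o = 120.5,
  a_h_n_c = 119.5
)

# NeRF: place D with |D-A| = r, angle(D,A,B) = theta, dihedral(D,A,B,C) = phi
nerf_r <- function(A, B, C, r, theta_deg, phi_deg) {
  theta <- theta_deg * pi / 180
  phi <- phi_deg * pi / 180
  ab <- B - C
  bc <- A - B
  bcu <- bc / sqrt(sum(bc^2))
  n <- c(ab[2] * bcu[3] - ab[3] * bcu[2],
         ab[3] * bcu[1] - ab[1] * bcu[3],
         ab[1] * bcu[2] - ab[2] * bcu[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bcu[3] - n[3] * bcu[2],
         n[3] * bcu[1] - n[1] * bcu[3],
         n[1] * bcu[2] - n[2] * bcu[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  A + bcu * d[1] + m * d[2] + n * d[3]
}

#' Build an ideal-geometry peptide backbone from phi/psi angles
#'
#' Serial NeRF construction with ideal bond lengths and angles, trans peptide
#' bonds, carbonyl O in the peptide plane anti to the next amide N, and amide
#' H in the peptide plane anti to the preceding carbonyl O.
#'
#' @param phi,psi backbone dihedrals in degrees; scalars are recycled to
#'   `n_res`.
#' @param n_res number of residues.
#' @return a tibble `(residue, atom, x, y, z)` with atoms N, H, CA, C, O
#'   (no H on residue 1).
#' @export
build_peptide <- function(phi, psi, n_res = max(length(phi), length(psi))) {
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  g <- .bb
  atoms <- list()
  # residue 1 seed
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  a <- g$a_n_ca_c * pi / 180
  C <- CA + g$b_ca_c * c(-cos(a), sin(a), 0)
  atoms[[1]] <- list(N = N, CA = CA, C = C, H = NULL, O = NULL)
  for (i in seq_len(n_res)) {
    res <- atoms[[i]]
    if (i < n_res) {
      Nn <- nerf_r(res$C, res$CA, res$N, g$b_c_n, g$a_ca_c_n, psi[i])
      CAn <- nerf_r(Nn, res$C, res$CA, g$b_n_ca, g$a_c_n_ca, 180)
      Cn <- nerf_r(CAn, Nn, res$C, g$b_ca_c, g$a_n_ca_c, phi[i + 1])
      atoms[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn, H = NULL, O = NULL)
    }
    # carbonyl O anti to next N (psi + 180), using this residue's psi
    atoms[[i]]$O <- nerf_r(res$C, res$CA, res$N, g$b_c_o, g$a_ca_c_o,
                           psi[i] + 180)
    if (i > 1) {
      prev <- atoms[[i - 1]]
      atoms[[i]]$H <- nerf_r(res$N, prev$C, prev$O, g$b_n_h, g$a_h_n_c, 180)
    }
  }
  rows <- purrr::imap(atoms, function(a, i) {
    nm <- c("N", "H", "CA", "C", "O")
    keep <- !vapply(a[nm], is.null, TRUE)
    tibble(residue = as.integer(i), atom = nm[keep],
           xyz = a[nm[keep]])
  })
  out <- dplyr::bind_rows(rows)
  m <- do.call(rbind, out$xyz)
  tibble(residue = out$residue, atom = out$atom,
         x = m[, 1], y = m[, 2], z = m[, 3])
}

# --- CA-trace backbone reconstruction -------------------------------------
#
# For each CA(i)-CA(i+1) virtual bond the peptide-unit atoms C(i), O(i),
# N(i+1), H(i+1) are placed in a local cylindrical frame about the virtual
# bond. Their (axial, radial, azimuth) parameters are measured once from
# ideal-geometry reference builds (alpha-helix and extended strand) and
# interpolated by the local CA pseudo-dihedral, so the reconstruction is
# exact at the two anchors and smooth in between.

peptide_unit_params <- function(phi, psi) {
  bb <- build_peptide(rep(phi, 6), rep(psi, 6))
  get <- function(res, atom) {
    r <- bb[bb$residue == res & bb$atom == atom, ]
    c(r$x, r$y, r$z)
  }
  i <- 3 # interior unit between residues 3 and 4
  ca1 <- get(i, "CA"); ca2 <- get(i + 1, "CA"); ca0 <- get(i - 1, "CA")
  u <- (ca2 - ca1); L <- sqrt(sum(u^2)); u <- u / L
  # reference azimuth from the previous CA
  vref <- ca0 - ca1
  vref <- vref - sum(vref * u) * u
  vref <- vref / sqrt(sum(vref^2))
  wref <- c(u[2] * vref[3] - u[3] * vref[2],
            u[3] * vref[1] - u[1] * vref[3],
            u[1] * vref[2] - u[2] * vref[1])
  param <- function(p) {
    d <- p - ca1
    t <- sum(d * u)
    perp <- d - t * u
    rad <- sqrt(sum(perp^2))
    az <- atan2(sum(perp * wref), sum(perp * vref))
    c(t = t / L, rad = rad, az = az)
  }
  list(
    L = L,
    C = param(get(i, "C")), O = param(get(i, "O")),
    N = param(get(i + 1, "N")), H = param(get(i + 1, "H")),
    tau = dihedral_cpp(ca0, ca1, ca2, get(i + 2, "CA"))
  )
}

.pep_anchor_cache <- new.env(parent = emptyenv())

pep_anchors <- function() {
  if (is.null(.pep_anchor_cache$helix)) {
    .pep_anchor_cache$helix <- peptide_unit_params(-57, -47)
    .pep_anchor_cache$strand <- peptide_unit_params(-139, 135)
  }
  list(helix = .pep_anchor_cache$helix, strand = .pep_anchor_cache$strand)
}

#' Reconstruct backbone N/C/O/H atoms from a CA trace
#'
#' Places the peptide-unit atoms of each CA-CA virtual bond using ideal-
#' geometry parameters interpolated between helix and strand anchor
#' conformations according to the local CA pseudo-dihedral. The
#' reconstruction is approximate away from the anchors; it exists to let the
#' hydrogen-bond secondary-structure assigner run on CA-only ensembles.
#'
#' @param ca numeric matrix `(n_res, 3)` of CA coordinates.
#' @return a tibble `(residue, atom, x, y, z)` with CA rows plus
#'   reconstructed C, O, N, H where defined.
#' @export
backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  stopifnot(n >= 4)
  anch <- pep_anchors()
  tau_h <- anch$helix$tau
  tau_s <- anch$strand$tau
  rows <- list(tibble(residue = seq_len(n), atom = "CA",
                      x = ca[, 1], y = ca[, 2], z = ca[, 3]))
  # pseudo-dihedrals tau[i] over CA(i-1..i+2), defined for i = 2..n-2
  tau <- rep(NA_real_, n)
  for (i in 2:(n - 2)) {
    tau[i] <- dihedral_cpp(ca[i - 1, ], ca[i, ], ca[i + 1, ], ca[i + 2, ])
  }
  interp_angle <- function(a, b, w) {
    # shortest-arc interpolation between two azimuths (radians)
    d <- atan2(sin(b - a), cos(b - a))
    a + (1 - w) * d # w = helix weight: w=1 -> a (helix), w=0 -> b
  }
  for (i in seq_len(n - 1)) {
    # local conformation for the unit (i, i+1)
    t_loc <- tau[i]
    if (is.na(t_loc)) t_loc <- tau[max(2, min(i, n - 2))]
    if (is.na(t_loc)) t_loc <- 180
    dh <- ang_diff(t_loc, tau_h)
    ds <- ang_diff(t_loc, tau_s)
    w <- ds^2 / (dh^2 + ds^2 + 1e-12) # 1 near helix anchor, 0 near strand
    u <- ca[i + 1, ] - ca[i, ]
    L <- sqrt(sum(u^2))
    u <- u / L
    prev <- if (i > 1) ca[i - 1, ] else ca[i + 2, ]
    vref <- prev - ca[i, ]
    vref <- vref - sum(vref * u) * u
    nv <- sqrt(sum(vref^2))
    if (nv < 1e-8) next
    vref <- vref / nv
    wref <- c(u[2] * vref[3] - u[3] * vref[2],
              u[3] * vref[1] - u[1] * vref[3],
              u[1] * vref[2] - u[2] * vref[1])
    place <- function(ph, ps) {
      az <- interp_angle(ph[["az"]], ps[["az"]], w)
      tt <- w * ph[["t"]] + (1 - w) * ps[["t"]]
      rad <- w * ph[["rad"]] + (1 - w) * ps[["rad"]]
      ca[i, ] + tt * L * u + rad * (cos(az) * vref + sin(az) * wref)
    }
    Cp <- place(anch$helix$C, anch$strand$C)
    Op <- place(anch$helix$O, anch$strand$O)
    Np <- place(anch$helix$N, anch$strand$N)
    Hp <- place(anch$helix$H, anch$strand$H)
    rows[[length(rows) + 1]] <- tibble(
      residue = c(i, i, i + 1L, i + 1L),
      atom = c("C", "O", "N", "H"),
      x = c(Cp[1], Op[1], Np[1], Hp[1]),
      y = c(Cp[2], Op[2], Np[2], Hp[2]),
      z = c(Cp[3], Op[3], Np[3], Hp[3])
    )
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$residue, .data$atom)
}

# geometric amide-H placement from N, CA and previous C when H is absent
add_amide_h <- function(bb) {
  have_h <- unique(bb$residue[bb$atom == "H"])
  res_ids <- sort(unique(bb$residue))
  out <- list(bb)
  getx <- function(res, atom) {
    r <- bb[bb$residue == res & bb$atom == atom, ]
    if (nrow(r) == 0) return(NULL)
    c(r$x[1], r$y[1], r$z[1])
  }
  for (r in res_ids[-1]) {
    if (r %in% have_h) next
    N <- getx(r, "N"); CA <- getx(r, "CA"); Cp <- getx(r - 1, "C")
    Op <- getx(r - 1, "O")
    if (is.null(N) || is.null(Cp)) next
    H <- if (!is.null(Op)) {
      nerf_r(N, Cp, Op, .bb$b_n_h, .bb$a_h_n_c, 180)
    } else if (!is.null(CA)) {
      # bisector fallback in the C(prev)-N-CA plane
      v1 <- Cp - N; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- CA - N; v2 <- v2 / sqrt(sum(v2^2))
      b <- -(v1 + v2); b <- b / sqrt(sum(b^2))
      N + .bb$b_n_h * b
    } else {
      next
    }
    out[[length(out) + 1]] <- tibble(residue = r, atom = "H",
                                     x = H[1], y = H[2], z = H[3])
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$residue, .data$atom)
}
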