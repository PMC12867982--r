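# Free-energy surface reconstruction from harmonic-bias windows: WHAM on a
# histogram grid, binless multistate reweighting (MBAR), and a variational
# tensor-product-spline estimator. The dihedral axis is treated as periodic
# throughout (histogram bins, bias energies, spline basis).

#' Gridded 2D free-energy surface container
#'
#' @param edges1,edges2 bin edges along extension (A) and dihedral (deg).
#' @param F matrix `(n1, n2)` of free energies, kcal/mol, `NA` in unsampled
#'   bins; shifted so the minimum over sampled bins is 0.
#' @param sampled logical matrix of sampled bins.
#' @param se optional matrix of per-bin uncertainties.
#' @param temperature Kelvin.
#' @param method estimator name.
#' @return object of class `free_energy_surface`.
#' @export
free_energy_surface <- function(edges1, edges2, F, sampled, se = NULL,
                                temperature = 300, method = "wham") {
  stopifnot(nrow(F) == length(edges1) - 1, ncol(F) == length(edges2) - 1)
  F[!sampled] <- NA_real_
  F <- F - min(F[sampled], na.rm = TRUE)
  structure(
    list(edges1 = edges1, edges2 = edges2,
         mid1 = (edges1[-1] + edges1[-length(edges1)]) / 2,
         mid2 = (edges2[-1] + edges2[-length(edges2)]) / 2,
         F = F, sampled = sampled, se = se,
         temperature = temperature, method = method),
    class = "free_energy_surface"
  )
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat("<free_energy_surface> ", length(x$mid1), "x", length(x$mid2),
      " grid (", x$method, "), ", sum(x$sampled), " sampled bins, max ",
      round(max(x$F, na.rm = TRUE), 2), " kcal/mol\n", sep = "")
  invisible(x)
}

#' @param x a `free_energy_surface`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.free_energy_surface <- function(x, ...) {
  tibble(
    extension_A = rep(x$mid1, times = length(x$mid2)),
    dihedral_deg = rep(x$mid2, each = length(x$mid1)),
    F_kcalmol = as.vector(x$F),
    se = if (is.null(x$se)) NA_real_ else as.vector(x$se),
    sampled = as.vector(x$sampled)
  )
}

# shared grid construction over the pooled sampled range
fes_grid <- function(windows, grid_size) {
  ext <- unlist(lapply(windows, function(w) w$samples$extension_A))
  rng <- range(ext)
  pad <- diff(rng) * 1e-6 + 1e-9
  list(
    edges1 = seq(rng[1] - pad, rng[2] + pad, length.out = grid_size[1] + 1),
    edges2 = seq(-180, 180, length.out = grid_size[2] + 1)
  )
}

bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' WHAM on a 2D histogram grid
#'
#' Weighted-histogram analysis of harmonic-bias windows over (lid extension,
#' lid-core dihedral). Bias energies at bin centres use the minimum-image
#' angular difference on the dihedral axis. Iteration stops when the maximum
#' change in window free energies falls below `tol`; the surface is shifted so
#' the minimum over sampled bins is zero.
#'
#' @param windows list of [bias_window()] objects at one temperature.
#' @param grid_size `c(n_ext, n_dih)` histogram bins (default 50 x 50).
#' @param tol convergence tolerance on window free energies, kcal/mol.
#' @param max_iter maximum self-consistency iterations.
#' @return a [free_energy_surface()].
#' @export
wham2d <- function(windows, grid_size = c(50, 50), tol = 1e-7,
                   max_iter = 1e5) {
  stopifnot(length(windows) >= 1)
  kT <- kT_kcal(windows[[1]]$temperature)
  g <- fes_grid(windows, grid_size)
  n1 <- grid_size[1]; n2 <- grid_size[2]
  mid1 <- (g$edges1[-1] + g$edges1[-(n1 + 1)]) / 2
  mid2 <- (g$edges2[-1] + g$edges2[-(n2 + 1)]) / 2

  K <- length(windows)
  counts <- matrix(0, n1 * n2, K)
  for (k in seq_len(K)) {
    s <- windows[[k]]$samples
    i1 <- bin_index(s$extension_A, g$edges1)
    i2 <- bin_index(wrap_deg(s$dihedral_deg), g$edges2)
    ok <- !is.na(i1) & !is.na(i2)
    tab <- table(factor(i1[ok] + (i2[ok] - 1) * n1, levels = seq_len(n1 * n2)))
    counts[, k] <- as.numeric(tab)
  }
  N_b <- rowSums(counts)                 # total counts per bin
  N_k <- colSums(counts)                 # samples per window
  # bias energy of each window at each bin centre
  B <- vapply(windows, function(w) {
    bias_energy(w,
                rep(mid1, times = n2),
                rep(mid2, each = n1))
  }, numeric(n1 * n2))
  C <- exp(-B / kT)

  f <- rep(0, K)                          # window free energies, kcal/mol
  sampled_bins <- N_b > 0
  for (it in seq_len(max_iter)) {
    denom <- as.vector(C %*% (N_k * exp(f / kT)))
    p <- ifelse(sampled_bins & denom > 0, N_b / denom, 0)
    zk <- colSums(p * C)
    f_new <- -kT * log(zk)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop_lidfold(
      sprintf("WHAM did not converge in %d iterations (residual %.3g)",
              as.integer(max_iter), delta),
      "lidfold_wham_nonconvergence"
    )
  }
  Fb <- matrix(NA_real_, n1, n2)
  Fb[sampled_bins] <- -kT * log(p[sampled_bins])
  # Poisson (counting) uncertainty per bin in kcal/mol
  se <- matrix(NA_real_, n1, n2)
  se[sampled_bins] <- kT / sqrt(N_b[sampled_bins])
  free_energy_surface(g$edges1, g$edges2, Fb,
                      matrix(sampled_bins, n1, n2), se = se,
                      temperature = windows[[1]]$temperature,
                      method = "wham")
}

#' Binless multistate reweighting (MBAR) over pooled window samples
#'
#' Solves the standard multistate self-consistency for the window free
#' energies over all pooled samples and returns non-negative, normalised
#' per-sample weights in the unbiased state. Deterministic given input order.
#'
#' @param windows list of [bias_window()] objects.
#' @param tol convergence tolerance on window free energies (kcal/mol).
#' @param max_iter maximum iterations.
#' @return a list with `weights` (per pooled sample, summing to 1, in window
#'   order), `window_f` (window free energies, kcal/mol, first window = 0),
#'   `samples` (the pooled CV tibble) and `n_iter`.
#' @export
mbar_weights <- function(windows, tol = 1e-8, max_iter = 1e4) {
  stopifnot(length(windows) >= 1)
  kT <- kT_kcal(windows[[1]]$temperature)
  pooled <- dplyr::bind_rows(lapply(windows, function(w) w$samples))
  N <- nrow(pooled)
  K <- length(windows)
  N_k <- vapply(windows, function(w) nrow(w$samples), 1L)
  # u[n, k]: reduced bias energy of sample n evaluated in window k
  u <- vapply(windows, function(w) {
    bias_energy(w, pooled$extension_A, pooled$dihedral_deg) / kT
  }, numeric(N))

  # minimise the convex MBAR objective in the reduced free energies
  # (gradient = average weights minus sample fractions), then verify the
  # self-consistency equations to the requested tolerance
  Nn <- sum(N_k)
  obj <- function(f) {
    A <- sweep(-u, 2L, f + log(N_k), "+")
    sum(row_logsumexp(A)) / Nn - sum(N_k * f) / Nn
  }
  gobj <- function(f) {
    A <- sweep(-u, 2L, f + log(N_k), "+")
    logden <- row_logsumexp(A)
    w <- exp(sweep(A, 1L, logden, "-"))
    colSums(w) / Nn - N_k / Nn
  }
  fit <- optim(rep(0, K), obj, gobj, method = "L-BFGS-B",
               control = list(maxit = as.integer(max_iter), factr = 10))
  f <- fit$par - fit$par[1]
  sc_update <- function(f) {
    A <- sweep(-u, 2L, f + log(N_k), "+")
    logden <- row_logsumexp(A)
    f_new <- vapply(seq_len(K), function(k) {
      -logsumexp(-u[, k] - logden)
    }, 1.0)
    f_new - f_new[1]
  }
  it <- 0L
  repeat {
    it <- it + 1L
    f_new <- sc_update(f)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol * max(1, max(abs(f))) || it >= 50L) break
  }
  if (delta >= tol * max(1, max(abs(f)))) {
    stop_lidfold("MBAR iteration did not converge; windows may not overlap",
                 "lidfold_mbar_nonconvergence")
  }
  A <- sweep(-u, 2L, f + log(N_k), "+")
  logw <- -row_logsumexp(A)
  if (!all(is.finite(logw))) {
    stop_lidfold("ill-conditioned MBAR weights (non-overlapping windows?)",
                 "lidfold_mbar_illconditioned")
  }
  w <- exp(logw - logsumexp(logw))
  list(weights = w, window_f = f * kT, samples = pooled, n_iter = it)
}

#' Histogram MBAR weights onto a free-energy surface
#'
#' @param mbar result of [mbar_weights()].
#' @param grid_size,temperature as in [wham2d()].
#' @return a [free_energy_surface()] with method `"mbar"`.
#' @export
mbar_fes <- function(mbar, grid_size = c(50, 50), temperature = 300) {
  kT <- kT_kcal(temperature)
  s <- mbar$samples
  rng <- range(s$extension_A)
  pad <- diff(rng) * 1e-6 + 1e-9
  edges1 <- seq(rng[1] - pad, rng[2] + pad, length.out = grid_size[1] + 1)
  edges2 <- seq(-180, 180, length.out = grid_size[2] + 1)
  i1 <- bin_index(s$extension_A, edges1)
  i2 <- bin_index(wrap_deg(s$dihedral_deg), edges2)
  idx <- i1 + (i2 - 1) * grid_size[1]
  p <- vapply(split(mbar$weights, factor(idx, levels = seq_len(prod(grid_size)))),
              sum, 1.0)
  sampled <- p > 0
  Fb <- matrix(NA_real_, grid_size[1], grid_size[2])
  Fb[sampled] <- -kT * log(p[sampled])
  free_energy_surface(edges1, edges2, Fb,
                      matrix(sampled, grid_size[1], grid_size[2]),
                      temperature = temperature, method = "mbar")
}

# ---------------------------------------------------------------- spline FES

# cubic B-spline design matrix, optionally periodic, for x in [lo, hi]
bspline_basis <- function(x, lo, hi, n_basis, periodic = FALSE) {
  degree <- 3L
  if (!periodic) {
    knots <- seq(lo, hi, length.out = n_basis - degree + 1)
    all_knots <- c(rep(knots[1], degree), knots,
                   rep(knots[length(knots)], degree))
    B <- splines::splineDesign(all_knots, x, ord = degree + 1,
                               outer.ok = TRUE)
  } else {
    # periodic basis by wrapping columns of an extended open basis
    period <- hi - lo
    step <- period / n_basis
    knots <- lo + step * seq(-degree, n_basis + degree)
    Bx <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
    B <- matrix(0, length(x), n_basis)
    for (j in seq_len(ncol(Bx))) {
      col <- ((j - 1) %% n_basis) + 1
      B[, col] <- B[, col] + Bx[, j]
    }
  }
  B
}

# second-difference roughness penalty, periodic wrap optional
diff2_penalty <- function(n, periodic = FALSE) {
  if (periodic) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      D[i, i] <- -2
      D[i, (i %% n) + 1] <- 1
      D[i, ((i - 2) %% n) + 1] <- 1
    }
  } else {
    D <- diff(diag(n), differences = 2)
  }
  crossprod(D)
}

#' Variational spline estimate of the 2D free-energy surface
#'
#' Maximises the likelihood of observing each window's CV samples under a
#' tensor-product cubic B-spline surface (periodic basis along the dihedral
#' axis) plus the known harmonic biases, with a second-difference smoothness
#' penalty. The negative log-likelihood per window is
#' \eqn{\sum_j [F(x_j) + B_w(x_j)]/k_BT + n_w \log Z_w} with
#' \eqn{Z_w = \int e^{-(F+B_w)/k_BT}}, evaluated by grid quadrature.
#'
#' @param windows list of [bias_window()] objects.
#' @param knot_counts `c(n_ext, n_dih)` basis functions per axis (>= 4).
#' @param regularization smoothness penalty weight.
#' @param grid_size evaluation grid for the returned surface and for the
#'   quadrature of the window normalisers.
#' @param maxit optimiser iteration cap.
#' @return a [free_energy_surface()] with method `"spline"`; attribute
#'   `coefficients` carries the fitted spline coefficients.
#' @export
spline_fes <- function(windows, knot_counts = c(8, 8), regularization = 1,
                       grid_size = c(50, 50), maxit = 400) {
  if (any(knot_counts < 4)) {
    stop_lidfold("knot_counts must be >= 4 per axis", "lidfold_invalid_config")
  }
  kT <- kT_kcal(windows[[1]]$temperature)
  g <- fes_grid(windows, grid_size)
  lo1 <- g$edges1[1]; hi1 <- g$edges1[length(g$edges1)]
  n1 <- grid_size[1]; n2 <- grid_size[2]
  mid1 <- (g$edges1[-1] + g$edges1[-(n1 + 1)]) / 2
  mid2 <- (g$edges2[-1] + g$edges2[-(n2 + 1)]) / 2
  K <- length(windows)
  m1 <- knot_counts[1]; m2 <- knot_counts[2]

  basis_2d <- function(ext, dih) {
    B1 <- bspline_basis(ext, lo1, hi1, m1, periodic = FALSE)
    B2 <- bspline_basis(wrap_deg(dih), -180, 180, m2, periodic = TRUE)
    # row-wise Kronecker (tensor product)
    out <- matrix(0, length(ext), m1 * m2)
    for (j in seq_len(m2)) {
      out[, ((j - 1) * m1 + 1):(j * m1)] <- B1 * B2[, j]
    }
    out
  }

  # design-sum per window and pooled, and quadrature basis on the grid
  Phi_sum <- matrix(0, K, m1 * m2)
  N_k <- numeric(K)
  for (k in seq_len(K)) {
    s <- windows[[k]]$samples
    Phi_sum[k, ] <- colSums(basis_2d(s$extension_A, s$dihedral_deg))
    N_k[k] <- nrow(s)
  }
  Phi_grid <- basis_2d(rep(mid1, times = n2), rep(mid2, each = n1))
  B_grid <- vapply(windows, function(w) {
    bias_energy(w, rep(mid1, times = n2), rep(mid2, each = n1))
  }, numeric(n1 * n2))

  P1 <- diff2_penalty(m1, periodic = FALSE)
  P2 <- diff2_penalty(m2, periodic = TRUE)
  Pen <- kronecker(P2, diag(m1)) + kronecker(diag(m2), P1)

  nll <- function(coef) {
    Fg <- as.vector(Phi_grid %*% coef)
    val <- sum(Phi_sum %*% coef) / kT
    for (k in seq_len(K)) {
      val <- val + N_k[k] * logsumexp(-(Fg + B_grid[, k]) / kT)
    }
    val + regularization * as.numeric(crossprod(coef, Pen %*% coef))
  }
  grad <- function(coef) {
    Fg <- as.vector(Phi_grid %*% coef)
    gr <- colSums(Phi_sum) / kT
    for (k in seq_len(K)) {
      lw <- -(Fg + B_grid[, k]) / kT
      w <- exp(lw - logsumexp(lw))
      gr <- gr - N_k[k] * as.vector(crossprod(Phi_grid, w)) / kT
    }
    gr + 2 * regularization * as.vector(Pen %*% coef)
  }
  fit <- optim(rep(0, m1 * m2), nll, grad, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  if (fit$convergence != 0 && fit$convergence != 1) {
    stop_lidfold(
      sprintf("spline FES optimiser failed (code %d, |grad| %.3g)",
              fit$convergence, sqrt(sum(grad(fit$par)^2))),
      "lidfold_spline_failure"
    )
  }
  Fg <- matrix(Phi_grid %*% fit$par, n1, n2)
  # sampled mask from the pooled histogram
  pooled <- dplyr::bind_rows(lapply(windows, function(w) w$samples))
  i1 <- bin_index(pooled$extension_A, g$edges1)
  i2 <- bin_index(wrap_deg(pooled$dihedral_deg), g$edges2)
  sampled <- matrix(FALSE, n1, n2)
  sampled[cbind(i1, i2)] <- TRUE
  out <- free_energy_surface(g$edges1, g$edges2, Fg, sampled,
                             temperature = windows[[1]]$temperature,
                             method = "spline")
  attr(out, "coefficients") <- fit$par
  out
}

#' Relative free energies of named surface regions
#'
#' \deqn{\Delta G_{region} = -k_BT \log \sum_{bins \in region} e^{-F_b/k_BT}}
#' reported relative to the lowest region.
#'
#' @param fes a [free_energy_surface()].
#' @param regions named list of rectangles
#'   `list(name = list(extension_A = c(lo, hi), dihedral_deg = c(lo, hi)))`;
#'   dihedral rectangles may wrap (lo > hi means the region crosses 180).
#' @return a tibble `(region, delta_g_kcalmol, n_bins)`.
#' @export
basin_free_energies <- function(fes, regions) {
  kT <- kT_kcal(fes$temperature)
  gvals <- purrr::map_dbl(regions, function(r) {
    in1 <- fes$mid1 >= r$extension_A[1] & fes$mid1 <= r$extension_A[2]
    d <- r$dihedral_deg
    in2 <- if (d[1] <= d[2]) {
      fes$mid2 >= d[1] & fes$mid2 <= d[2]
    } else {
      fes$mid2 >= d[1] | fes$mid2 <= d[2]
    }
    sub <- fes$F[in1, in2, drop = FALSE]
    sub <- sub[is.finite(sub)]
    if (length(sub) == 0) {
      stop_lidfold("region contains no sampled bins", "lidfold_empty_region")
    }
    -kT * logsumexp(-sub / kT)
  })
  tibble(
    region = names(regions),
    delta_g_kcalmol = gvals - min(gvals),
    n_bins = purrr::map_int(regions, function(r) {
      in1 <- fes$mid1 >= r$extension_A[1] & fes$mid1 <= r$extension_A[2]
      d <- r$dihedral_deg
      in2 <- if (d[1] <= d[2]) {
        fes$mid2 >= d[1] & fes$mid2 <= d[2]
      } else {
        fes$mid2 >= d[1] | fes$mid2 <= d[2]
      }
      sum(is.finite(fes$F[in1, in2]))
    })
  )
}

#' Block-bootstrap uncertainty of a WHAM surface
#'
#' Resamples contiguous blocks of each window's CV series, recomputes the
#' surface, and reports the per-bin standard deviation across replicates.
#'
#' @param windows list of [bias_window()] objects.
#' @param n_boot bootstrap replicates.
#' @param n_blocks contiguous blocks per window.
#' @param seed RNG seed.
#' @param ... passed to [wham2d()].
#' @return a [free_energy_surface()] whose `se` field holds the bootstrap
#'   standard deviation.
#' @export
fes_bootstrap <- function(windows, n_boot = 20, n_blocks = 10, seed = 1, ...) {
  base_fes <- wham2d(windows, ...)
  set.seed(derive_seed(seed, 0L))
  reps <- array(NA_real_, c(nrow(base_fes$F), ncol(base_fes$F), n_boot))
  for (b in seq_len(n_boot)) {
    wb <- lapply(windows, function(w) {
      n <- nrow(w$samples)
      blk <- block_index(n, n_blocks)
      pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
      rows <- unlist(lapply(pick, function(p) which(blk == p)))
      bias_window(w$samples[rows, ], w$center, w$force_constants,
                  w$temperature)
    })
    fb <- tryCatch(wham2d(wb, ...), error = function(e) NULL)
    if (!is.null(fb)) reps[, , b] <- fb$F
  }
  base_fes$se <- apply(reps, c(1, 2), sd, na.rm = TRUE)
  base_fes
}
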