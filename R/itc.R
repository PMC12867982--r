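# Isothermal titration calorimetry: one-site and competitive-displacement
# binding models, synthetic isotherm generation, nonlinear fitting, and the
# thermodynamic signature decomposition dG = dH - T dS.

#' ITC titration container
#'
#' @param injection_volumes_uL per-injection volumes (microlitre), >= 5
#'   injections.
#' @param heats_ucal integrated heat per injection (microcalorie); may be
#'   `NULL` for a protocol-only object used with the forward models.
#' @param cell_conc_M protein concentration in the cell (molar).
#' @param syringe_conc_M ligand concentration in the syringe (molar).
#' @param cell_volume_mL calorimeter cell volume (default 0.2, an
#'   Auto-iTC200-style cell).
#' @param temperature Kelvin.
#' @param weak_conc_M,weak_kd_M,weak_dh_kcal for competitive (displacement)
#'   titrations: concentration of the pre-loaded weak ligand in the cell and
#'   its fixed dissociation constant / enthalpy.
#' @return object of class `itc_titration`.
#' @export
itc_titration <- function(injection_volumes_uL, heats_ucal = NULL,
                          cell_conc_M = 10e-6, syringe_conc_M = 150e-6,
                          cell_volume_mL = 0.2, temperature = 298.15,
                          weak_conc_M = 0, weak_kd_M = NA_real_,
                          weak_dh_kcal = NA_real_) {
  if (length(injection_volumes_uL) < 5) {
    stop_lidfold("at least 5 injections are required", "lidfold_invalid_itc")
  }
  if (cell_conc_M <= 0 || syringe_conc_M <= 0 || cell_volume_mL <= 0) {
    stop_lidfold("concentrations and volumes must be positive",
                 "lidfold_invalid_itc")
  }
  if (sum(injection_volumes_uL) > 1000 * cell_volume_mL) {
    stop_lidfold("injection schedule exceeds syringe/cell volume",
                 "lidfold_invalid_itc")
  }
  if (!is.null(heats_ucal) &&
      (length(heats_ucal) != length(injection_volumes_uL) ||
         any(!is.finite(heats_ucal)))) {
    stop_lidfold("heats must be finite, one per injection",
                 "lidfold_invalid_itc")
  }
  structure(
    list(injection_volumes_uL = injection_volumes_uL,
         heats_ucal = heats_ucal, cell_conc_M = cell_conc_M,
         syringe_conc_M = syringe_conc_M, cell_volume_mL = cell_volume_mL,
         temperature = temperature, weak_conc_M = weak_conc_M,
         weak_kd_M = weak_kd_M, weak_dh_kcal = weak_dh_kcal),
    class = "itc_titration"
  )
}

#' @export
print.itc_titration <- function(x, ...) {
  cat("<itc_titration> ", length(x$injection_volumes_uL), " injections, ",
      x$cell_conc_M * 1e6, " uM cell / ", x$syringe_conc_M * 1e6,
      " uM syringe", if (x$weak_conc_M > 0) " (competitive)", "\n", sep = "")
  invisible(x)
}

#' @param x an `itc_titration`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.itc_titration <- function(x, ...) {
  inj <- seq_along(x$injection_volumes_uL)
  mol_ratio <- cumsum(x$injection_volumes_uL * 1e-6 * x$syringe_conc_M) /
    (x$cell_volume_mL * 1e-3 * x$cell_conc_M)
  tibble(
    injection = inj, volume_uL = x$injection_volumes_uL,
    molar_ratio = mol_ratio,
    heat_ucal = if (is.null(x$heats_ucal)) NA_real_ else x$heats_ucal,
    heat_kcal_per_mol = if (is.null(x$heats_ucal)) NA_real_ else
      x$heats_ucal * 1e-9 /
        (x$injection_volumes_uL * 1e-6 * x$syringe_conc_M * 1e-3)
  )
}

# stepwise perfusion bookkeeping: each injection of dV displaces cell
# contents (factor 1 - dV/V0) before adding ligand
itc_concentrations <- function(titration) {
  v0 <- titration$cell_volume_mL * 1e-3
  dv <- titration$injection_volumes_uL * 1e-6
  nI <- length(dv)
  Mt <- numeric(nI); Xt <- numeric(nI); Bt <- numeric(nI); fd <- 1 - dv / v0
  m <- titration$cell_conc_M
  x <- 0
  b <- titration$weak_conc_M
  for (j in seq_len(nI)) {
    m <- m * fd[j]
    b <- b * fd[j]
    x <- x * fd[j] + titration$syringe_conc_M * dv[j] / v0
    Mt[j] <- m; Xt[j] <- x; Bt[j] <- b
  }
  list(Mt = Mt, Xt = Xt, Bt = Bt, fd = fd, v0 = v0)
}

# exact one-site bound complex from the quadratic mass balance
one_site_complex <- function(n, kd, Mt, Xt) {
  s <- n * Mt + Xt + kd
  (s - sqrt(pmax(s^2 - 4 * n * Mt * Xt, 0))) / 2
}

#' Predicted per-injection heats for the one-site model
#'
#' Solves the quadratic mass balance for the bound complex at each injection
#' (with standard displaced-volume dilution bookkeeping) and differences the
#' complex amounts: \eqn{q_j = \Delta H\, V_0\, ([PL]_j - [PL]_{j-1} f_j)}
#' where \eqn{f_j} is the displacement factor.
#'
#' @param params list or named vector with `n` (stoichiometry), `kd_M`, and
#'   `dh_kcal` (enthalpy per mole of ligand).
#' @param titration an [itc_titration()] (heats not required).
#' @return numeric vector of heats in microcalories.
#' @export
one_site_heats <- function(params, titration) {
  p <- as.list(params)
  conc <- itc_concentrations(titration)
  pl <- one_site_complex(p$n, p$kd_M, conc$Mt, conc$Xt)
  dpl <- pl - c(0, head(pl, -1)) * conc$fd
  p$dh_kcal * conc$v0 * dpl * 1e9
}

#' Predicted heats for the competitive (displacement) model
#'
#' The syringe ligand (strong, parameters being fitted) competes with a
#' pre-loaded weak ligand of known, fixed `(K_D, dH)`. Free protein is found
#' per injection by bracketed root finding on the ternary mass balance
#' \eqn{P + A_t P/(K_A + P) + B_t P/(K_B + P) = P_t}; heats include the
#' displacement enthalpy of the weak ligand. With zero weak-ligand
#' concentration this reduces exactly to [one_site_heats()].
#'
#' @inheritParams one_site_heats
#' @return heats in microcalories.
#' @export
competitive_heats <- function(params, titration) {
  p <- as.list(params)
  if (titration$weak_conc_M <= 0) {
    return(one_site_heats(params, titration))
  }
  if (!is.finite(titration$weak_kd_M) || !is.finite(titration$weak_dh_kcal)) {
    stop_lidfold("competitive mode needs fixed weak-ligand (K_D, dH)",
                 "lidfold_invalid_itc")
  }
  conc <- itc_concentrations(titration)
  ka <- p$kd_M
  kb <- titration$weak_kd_M
  nI <- length(conc$Mt)
  pa <- numeric(nI)
  pb <- numeric(nI)
  for (j in seq_len(nI)) {
    pt <- p$n * conc$Mt[j]
    at <- conc$Xt[j]
    bt <- conc$Bt[j]
    fn <- function(pf) pf + at * pf / (ka + pf) + bt * pf / (kb + pf) - pt
    root <- tryCatch(
      uniroot(fn, c(0, pt), tol = pt * 1e-12)$root,
      error = function(e) {
        stop_lidfold("root bracketing failed in competitive mass balance",
                     "lidfold_root_failure")
      }
    )
    pa[j] <- at * root / (ka + root)
    pb[j] <- bt * root / (kb + root)
  }
  dpa <- pa - c(0, head(pa, -1)) * conc$fd
  dpb <- pb - c(0, head(pb, -1)) * conc$fd
  (p$dh_kcal * dpa + titration$weak_dh_kcal * dpb) * conc$v0 * 1e9
}

#' Simulate a synthetic ITC isotherm with known ground truth
#'
#' Per-injection heats from the exact one-site (or competitive) mass-balance
#' solution with cumulative-dilution bookkeeping plus Gaussian noise. The
#' generating parameters are stored for recovery tests.
#'
#' @param true_params list with `n`, `kd_M`, `dh_kcal`.
#' @param titration an [itc_titration()] defining the protocol (the defaults
#'   of [itc_titration()] follow the study protocol: 10 uM protein in the
#'   cell, 150 uM ligand in the syringe).
#' @param noise_frac Gaussian noise s.d. as a fraction of the maximum
#'   absolute heat (used when `noise_ucal` is `NULL`).
#' @param noise_ucal absolute Gaussian noise s.d. in microcalories.
#' @param seed integer seed.
#' @return the titration with `heats_ucal` filled in and the truth in
#'   attribute `"truth"`.
#' @export
simulate_itc_isotherm <- function(true_params, titration = itc_titration(
                                    c(0.4, rep(2, 18))),
                                  noise_frac = 0.005, noise_ucal = NULL,
                                  seed = 1) {
  stopifnot(true_params$kd_M > 0)
  model <- if (titration$weak_conc_M > 0) competitive_heats else one_site_heats
  q <- model(true_params, titration)
  set.seed(derive_seed(seed, 0L))
  sdq <- noise_ucal %||% (noise_frac * max(abs(q)))
  titration$heats_ucal <- q + rnorm(length(q), 0, sdq)
  attr(titration, "truth") <- true_params
  titration
}

# shared fitting engine over (n, log10 Kd, dH); c_factor rescales the
# Wiseman-window check to the apparent Kd in competitive mode
fit_itc <- function(titration, model, init, exclude_first, fixed_n = NULL,
                    c_factor = 1) {
  q <- titration$heats_ucal
  if (is.null(q)) {
    stop_lidfold("titration carries no heats", "lidfold_invalid_itc")
  }
  use <- seq_along(q)
  if (exclude_first) use <- use[-1]
  if (length(use) < 5) {
    stop_lidfold("fewer than 5 informative injections", "lidfold_invalid_itc")
  }
  # degenerate (flat / pure dilution) detection on molar heats
  qm <- q[use] * 1e-9 /
    (titration$injection_volumes_uL[use] * 1e-6 * titration$syringe_conc_M *
       1e-3)
  if (sd(qm) < 1e-9 + 1e-3 * abs(median(qm))) {
    return(structure(
      list(n = NA_real_, kd_M = NA_real_, dh_kcal = NA_real_,
           dg_kcal = NA_real_, minus_tds_kcal = NA_real_,
           se = c(n = NA, log10_kd = NA, dh = NA), residual = NA_real_,
           c_value = NA_real_, temperature = titration$temperature,
           identifiable = FALSE, flags = "unidentifiable: flat heats",
           titration = titration, model = "one_site"),
      class = "binding_fit"
    ))
  }
  # default inits: dH from early heats, Kd a tenth of the cell concentration
  mol_inj <- titration$injection_volumes_uL[use] * 1e-6 *
    titration$syringe_conc_M * 1e-3
  init <- init %||% list(
    n = 1,
    kd_M = titration$cell_conc_M / 10,
    dh_kcal = q[use][1] * 1e-9 / mol_inj[1]
  )
  obj <- function(par) {
    prm <- list(n = if (is.null(fixed_n)) exp(par[1]) else fixed_n,
                kd_M = 10^par[2], dh_kcal = par[3])
    model(prm, titration)[use] - q[use]
  }
  start <- c(log(init$n), log10(init$kd_M), init$dh_kcal)
  fit <- minpack.lm::nls.lm(
    par = start, fn = obj,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12)
  )
  if (fit$info %in% c(0, 9)) {
    stop_lidfold(paste0("ITC fit did not converge: ", fit$message),
                 "lidfold_fit_nonconvergence")
  }
  par <- fit$par
  n_hat <- if (is.null(fixed_n)) exp(par[1]) else fixed_n
  kd <- 10^par[2]
  dh <- par[3]
  RT <- .kB * titration$temperature
  dg <- RT * log(kd)
  cval <- n_hat * titration$cell_conc_M / (kd * c_factor)
  flags <- character()
  if (cval < 1 || cval > 1000) {
    flags <- c(flags, sprintf("Wiseman c = %.3g outside [1, 1000]", cval))
    warn(flags[length(flags)])
  }
  vc <- tryCatch(diag(solve(crossprod(fit$fjac)) *
                        sum(fit$fvec^2) / (length(use) - 3)),
                 error = function(e) rep(NA_real_, 3))
  structure(
    list(n = n_hat, kd_M = kd, dh_kcal = dh, dg_kcal = dg,
         minus_tds_kcal = dg - dh,
         se = setNames(sqrt(abs(vc)), c("log_n", "log10_kd", "dh")),
         residual = sqrt(mean(fit$fvec^2)), c_value = cval,
         temperature = titration$temperature, identifiable = TRUE,
         flags = flags, titration = titration,
         model = if (identical(model, competitive_heats)) {
           "competitive"
         } else {
           "one_site"
         }),
    class = "binding_fit"
  )
}

#' Fit the one-site binding model to an ITC titration
#'
#' Least-squares fit of `(n, K_D, dH)` with the analytic one-site model;
#' deterministic given the initial values. The first injection is excluded by
#' default (instrument-artifact convention). Reports the Wiseman parameter
#' `c = n [cell] / K_D` and warns when it falls outside `[1, 1000]`; flat
#' (pure-dilution) heat series are flagged unidentifiable instead of fitted.
#'
#' @param titration an [itc_titration()] with heats.
#' @param init optional list `n`, `kd_M`, `dh_kcal` of starting values.
#' @param exclude_first drop the first injection from the fit?
#' @return a `binding_fit` with `n`, `kd_M`, `dh_kcal`,
#'   `dg_kcal = RT ln K_D`, `minus_tds_kcal = dG - dH` (the identity holds
#'   exactly), standard errors, residual, `c_value`.
#' @export
fit_one_site <- function(titration, init = NULL, exclude_first = TRUE) {
  fit_itc(titration, one_site_heats, init, exclude_first)
}

#' Fit the competitive-displacement model for a tight binder
#'
#' The weak competitor's `(K_D, dH)` are fixed (carried by the titration);
#' the strong ligand's `(n, K_D, dH)` are fitted through the ternary
#' equilibrium. Warns when the competitor is too weak to compress the
#' apparent isotherm into the measurable c-window.
#'
#' @inheritParams fit_one_site
#' @return a `binding_fit` for the strong ligand.
#' @export
fit_competitive <- function(titration, init = NULL, exclude_first = TRUE) {
  if (titration$weak_conc_M <= 0) {
    return(fit_one_site(titration, init, exclude_first))
  }
  app_factor <- 1 + titration$weak_conc_M / titration$weak_kd_M
  init <- init %||% list(
    n = 1,
    kd_M = titration$cell_conc_M / 10 / app_factor,
    dh_kcal = -10
  )
  out <- fit_itc(titration, competitive_heats, init, exclude_first,
                 c_factor = app_factor)
  if (is.finite(out$c_value) && out$c_value > 1000) {
    out$flags <- c(out$flags, "competitor too weak: apparent c above window")
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$identifiable) {
    cat("<binding_fit> unidentifiable (flat heats)\n")
    return(invisible(x))
  }
  cat("<binding_fit> ", x$model, ": n = ", signif(x$n, 3), ", K_D = ",
      signif(x$kd_M * 1e9, 3), " nM, dH = ", signif(x$dh_kcal, 4),
      " kcal/mol, dG = ", signif(x$dg_kcal, 4), ", -TdS = ",
      signif(x$minus_tds_kcal, 4), "\n", sep = "")
  invisible(x)
}

#' @param x a `binding_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.binding_fit <- function(x, ...) {
  tibble(
    term = c("n", "kd_M", "dh_kcal", "dg_kcal", "minus_tds_kcal"),
    estimate = c(x$n, x$kd_M, x$dh_kcal, x$dg_kcal, x$minus_tds_kcal)
  )
}

#' @param x a `binding_fit`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.binding_fit <- function(x, ...) {
  tibble(
    kd_M = x$kd_M, dh_kcal = x$dh_kcal, dg_kcal = x$dg_kcal,
    minus_tds_kcal = x$minus_tds_kcal, n = x$n, c_value = x$c_value,
    residual_ucal = x$residual, identifiable = x$identifiable,
    model = x$model
  )
}

#' Thermodynamic signature of a binding fit
#'
#' \eqn{\Delta G = RT \ln K_D} (R = 1.987e-3 kcal/mol/K) and
#' \eqn{-T\Delta S = \Delta G - \Delta H}; the decomposition
#' \eqn{\Delta G = \Delta H - T\Delta S} holds exactly.
#'
#' @param fit a `binding_fit`, or a list with `kd_M` and `dh_kcal`.
#' @param temperature Kelvin (defaults to the fit's).
#' @return a tibble `(quantity, kcal_per_mol)` with dG, dH and -TdS.
#' @export
thermodynamic_signature <- function(fit, temperature = NULL) {
  temperature <- temperature %||% fit$temperature %||% 298.15
  dg <- .kB * temperature * log(fit$kd_M)
  tibble(
    quantity = c("dG", "dH", "-TdS"),
    kcal_per_mol = c(dg, fit$dh_kcal, dg - fit$dh_kcal)
  )
}
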