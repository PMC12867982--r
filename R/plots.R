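# ggplot2 views of the main result types.

#' @param object a [free_energy_surface()].
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.free_energy_surface <- function(object, ...) {
  tb <- tidy(object) |> dplyr::filter(.data$sampled)
  ggplot2::ggplot(tb, ggplot2::aes(.data$extension_A, .data$dihedral_deg,
                                   fill = .data$F_kcalmol)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)", option = "C") +
    ggplot2::labs(x = "lid extension (Å)",
                  y = "lid-core dihedral (°)") +
    ggplot2::theme_minimal()
}

#' @param object an [itc_titration()] with heats.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.itc_titration <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$molar_ratio,
                                   .data$heat_kcal_per_mol)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "molar ratio", y = "kcal/mol of injectant") +
    ggplot2::theme_minimal()
}

#' @param object a `binding_fit`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.binding_fit <- function(object, ...) {
  titr <- object$titration
  tb <- tidy(titr)
  model <- if (object$model == "competitive") competitive_heats else
    one_site_heats
  pred <- model(list(n = object$n, kd_M = object$kd_M,
                     dh_kcal = object$dh_kcal), titr)
  tb$pred <- pred * 1e-9 /
    (titr$injection_volumes_uL * 1e-6 * titr$syringe_conc_M * 1e-3)
  ggplot2::ggplot(tb, ggplot2::aes(.data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat_kcal_per_mol)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred), colour = "steelblue") +
    ggplot2::labs(x = "molar ratio", y = "kcal/mol of injectant") +
    ggplot2::theme_minimal()
}

#' Bar plot of per-residue helix propensity with error bars
#'
#' @param propensity a tibble from [helix_propensity()], optionally with a
#'   `condition` column to facet by.
#' @return a ggplot object.
#' @export
plot_helix_propensity <- function(propensity) {
  p <- ggplot2::ggplot(propensity,
                       ggplot2::aes(factor(.data$residue),
                                    .data$propensity)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$propensity - .data$sigma_e,
                   ymax = .data$propensity + .data$sigma_e),
      width = 0.3
    ) +
    ggplot2::labs(x = "residue", y = "helix propensity") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(propensity)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}

#' Line plot of per-residue RMSF
#'
#' @param rmsf_table a tibble from [rmsf()] (CA rows are plotted), optionally
#'   with a `condition` column.
#' @return a ggplot object.
#' @export
plot_rmsf <- function(rmsf_table) {
  tb <- dplyr::filter(rmsf_table, .data$role == "CA")
  p <- ggplot2::ggplot(tb, ggplot2::aes(.data$residue, .data$rmsf_A)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "residue", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
  if ("condition" %in% names(tb)) {
    p <- p + ggplot2::aes(colour = .data$condition)
  }
  p
}

#' Per-residue profile plot for CSP / secondary-shift / hetNOE tables
#'
#' @param profile a tibble with a `residue` column and one value column.
#' @param value name of the value column.
#' @return a ggplot object.
#' @export
plot_residue_profile <- function(profile, value) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$residue,
                                        .data[[value]])) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "residue", y = value) +
    ggplot2::theme_minimal()
}
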