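# End-to-end orchestration: one configuration drives the four study
# conditions {apo, holo} x {WT-analog, contact-deleted analog}, producing
# free-energy surfaces, per-residue observables, SASA and entropy reports,
# synthetic NMR tables, and a summary comparing conditions. Deterministic
# given the configuration (every stochastic stage derives its stream from the
# master seed).

#' Build a pipeline run configuration
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_sweeps Monte-Carlo sweeps per condition.
#' @param stride frame-recording stride.
#' @param system_args list of [lid_system()] overrides shared by all
#'   conditions (`ligand_present` and `contact_epsilon` are set per
#'   condition).
#' @param mutant_epsilon contact well depth of the mutant analog (0 deletes
#'   the contact, the "I19G analog").
#' @param do_fes run umbrella sampling + estimators per condition?
#' @param fes_windows number of window centres per CV axis.
#' @param fes_sweeps sweeps per umbrella window.
#' @param fes_force_constants `c(k_ext, k_dih)` for the windows; `NULL`
#'   (default) matches each constant to the window spacing so neighbouring
#'   windows overlap (`k = k_BT / (spacing/2)^2`).
#' @param estimator `"wham"`, `"mbar"` or `"spline"`.
#' @param base_residues residues reported as the helix-forming base of the
#'   lid.
#' @param entropy_order `"joint"` (default; full-dimensional k-NN over the
#'   lid-base sub-chain, which captures the collective ordering), `"first"`
#'   or `"first+MI"`.
#' @param entropy_subset torsion indices for the entropy comparison; `NULL`
#'   selects the sub-chain from two torsions below the contact residue to
#'   the chain base.
#' @param n_boot bootstrap replicates for uncertainty estimates.
#' @param out_dir optional output directory for CSV/JSON/plot files.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_sweeps = 150000, stride = 50,
                       system_args = list(), mutant_epsilon = 0,
                       do_fes = TRUE, fes_windows = c(4, 4),
                       fes_sweeps = 20000, fes_force_constants = NULL,
                       estimator = c("wham", "mbar", "spline"),
                       base_residues = 21:25,
                       entropy_order = c("joint", "first", "first+MI"),
                       entropy_subset = NULL,
                       n_boot = 32, out_dir = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_sweeps = as.integer(n_sweeps),
    stride = as.integer(stride), system_args = system_args,
    mutant_epsilon = mutant_epsilon, do_fes = isTRUE(do_fes),
    fes_windows = as.integer(fes_windows),
    fes_sweeps = as.integer(fes_sweeps),
    fes_force_constants = fes_force_constants,
    estimator = match.arg(estimator),
    base_residues = as.integer(base_residues),
    entropy_order = match.arg(entropy_order),
    entropy_subset = if (!is.null(entropy_subset)) as.integer(entropy_subset),
    n_boot = as.integer(n_boot), out_dir = out_dir
  )
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_sweeps < 1) {
    stop_lidfold("n_sweeps must be >= 1", "lidfold_invalid_config")
  }
  if (cfg$stride < 1 || cfg$stride > cfg$n_sweeps) {
    stop_lidfold("stride must be in [1, n_sweeps]", "lidfold_invalid_config")
  }
  if (cfg$mutant_epsilon < 0) {
    stop_lidfold("mutant_epsilon must be >= 0", "lidfold_invalid_config")
  }
  if (cfg$do_fes && (any(cfg$fes_windows < 2) || cfg$fes_sweeps < 1 ||
                       (!is.null(cfg$fes_force_constants) &&
                          any(cfg$fes_force_constants <= 0)))) {
    stop_lidfold("invalid umbrella-sampling settings",
                 "lidfold_invalid_config")
  }
  invisible(cfg)
}

#' Serialise / restore a run configuration (JSON round trip)
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$system_args <- as.list(raw$system_args)
  do.call(run_config, raw[setdiff(names(raw), character(0))])
}

#' Stable hash of a run configuration
#'
#' Hashes the canonical JSON serialisation of the scientific fields, so the
#' hash is stable across JSON round trips and independent of where outputs
#' are written (`out_dir` is excluded).
#'
#' @param config a [run_config()].
#' @return a character hash.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  rlang::hash(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                            digits = NA, null = "null")))
}

condition_system <- function(cfg, holo, mutant) {
  args <- cfg$system_args
  args$ligand_present <- holo
  if (mutant) args$contact_epsilon <- cfg$mutant_epsilon
  do.call(lid_system, args)
}

fes_centers <- function(cfg, system) {
  # window centres spanning the reachable extension range (between the
  # compact helical and fully extended conformations) and the full circle
  cv <- cv_definition(system)
  ext_max <- lid_extension(build_chain(rep(180, n_torsions(system)), system),
                           cv)
  ext <- seq(0.2 * ext_max, 0.95 * ext_max,
             length.out = cfg$fes_windows[1])
  dih <- seq(-180, 180, length.out = cfg$fes_windows[2] + 1)[-1] -
    180 / cfg$fes_windows[2]
  tidyr::expand_grid(extension_A = ext, dihedral_deg = wrap_deg(dih))
}

run_condition <- function(cfg, name, holo, mutant, stream) {
  sys <- condition_system(cfg, holo, mutant)
  ens <- sample_ensemble(sys, cfg$n_sweeps, seed = derive_seed(cfg$seed,
                                                               stream),
                         stride = cfg$stride)
  ssp <- assign_secondary_structure(ens, "torsion_window")
  prop <- helix_propensity(ssp)
  flex <- rmsf(ens)
  fes <- NULL
  if (cfg$do_fes) {
    ctrs <- fes_centers(cfg, sys)
    fc <- cfg$fes_force_constants %||% {
      kT <- kT_kcal(sys$temperature)
      sp_ext <- diff(sort(unique(ctrs$extension_A)))[1]
      sp_dih <- (360 / cfg$fes_windows[2]) * pi / 180
      c(kT / (sp_ext / 2)^2, kT / (sp_dih / 2)^2)
    }
    wins <- generate_bias_windows(
      sys, ctrs, fc,
      n_sweeps = cfg$fes_sweeps, seed = derive_seed(cfg$seed, stream + 100)
    )
    fes <- switch(cfg$estimator,
      wham = wham2d(wins),
      mbar = mbar_fes(mbar_weights(wins), temperature = sys$temperature),
      spline = spline_fes(wins)
    )
  }
  list(name = name, system = sys, ensemble = ens, ss = ssp,
       propensity = prop, rmsf = flex, fes = fes)
}

#' Run the full analysis pipeline
#'
#' Samples the four conditions, computes per-residue helix propensity and
#' RMSF, free-energy surfaces (optional), hydrophobic SASA changes and
#' conformational / ligand roto-translational entropy differences upon
#' binding for both analogs, synthetic shift tables, and a summary of
#' condition orderings. When `config$out_dir` is set, tables are written as
#' CSV, the summary as JSON, surfaces as CSV + PDF plots; every file name is
#' prefixed by the condition and the summary carries the config hash.
#'
#' @param config a [run_config()].
#' @return a `pipeline_result` list with `conditions` (per-condition
#'   bundles), `sasa`, `entropy`, `ligand_entropy`, `nmr`, `summary`,
#'   `config`, `hash`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  conds <- list(
    wt_apo = run_condition(config, "wt_apo", FALSE, FALSE, 1L),
    wt_holo = run_condition(config, "wt_holo", TRUE, FALSE, 2L),
    mut_apo = run_condition(config, "mut_apo", FALSE, TRUE, 3L),
    mut_holo = run_condition(config, "mut_holo", TRUE, TRUE, 4L)
  )
  sys0 <- conds$wt_apo$system
  # hydrophobic class: contact residue, its sequence neighbours (the T16/I19
  # analog patch) and the ligand particles
  hydro <- c(sys0$contact_residue_index - 2, sys0$contact_residue_index,
             sys0$contact_residue_index + 2)
  hydro_holo <- c(hydro, which(conds$wt_holo$ensemble$particles$role ==
                                 "LIG"))
  sasa_tbl <- dplyr::bind_rows(
    hydrophobic_sasa_change(conds$wt_apo$ensemble, conds$wt_holo$ensemble,
                            hydro, seed = derive_seed(config$seed, 11),
                            n_boot = config$n_boot) |>
      dplyr::mutate(analog = "wt", part = "protein"),
    hydrophobic_sasa_change(conds$mut_apo$ensemble, conds$mut_holo$ensemble,
                            hydro, seed = derive_seed(config$seed, 12),
                            n_boot = config$n_boot) |>
      dplyr::mutate(analog = "mutant", part = "protein")
  )
  ent_sub <- config$entropy_subset %||%
    ((sys0$contact_residue_index - 2):(sys0$n_residues - 3))
  entropy <- list(
    wt = conformational_entropy_difference(
      conds$wt_apo$ensemble, conds$wt_holo$ensemble,
      temperature = sys0$temperature, order = config$entropy_order,
      n_boot = config$n_boot, seed = derive_seed(config$seed, 21),
      torsion_subset = ent_sub
    ),
    mutant = conformational_entropy_difference(
      conds$mut_apo$ensemble, conds$mut_holo$ensemble,
      temperature = sys0$temperature, order = config$entropy_order,
      n_boot = config$n_boot, seed = derive_seed(config$seed, 22),
      torsion_subset = ent_sub
    )
  )
  lig_entropy <- dplyr::bind_rows(
    ligand_rototranslational_entropy(conds$wt_holo$ensemble,
                                     temperature = sys0$temperature) |>
      dplyr::mutate(analog = "wt"),
    ligand_rototranslational_entropy(conds$mut_holo$ensemble,
                                     temperature = sys0$temperature) |>
      dplyr::mutate(analog = "mutant")
  )
  nmr <- list(
    wt = simulate_shift_tables(conds$wt_apo$ensemble,
                               conds$wt_holo$ensemble,
                               seed = derive_seed(config$seed, 31)),
    mutant = simulate_shift_tables(conds$mut_apo$ensemble,
                                   conds$mut_holo$ensemble,
                                   seed = derive_seed(config$seed, 32))
  )

  base <- config$base_residues
  base_prop <- function(cond) {
    p <- conds[[cond]]$propensity
    p[p$residue %in% base, ]
  }
  mean_se <- function(p) {
    c(mean = mean(p$propensity), se = sqrt(sum(p$sigma_e^2)) / nrow(p))
  }
  bp <- lapply(c("wt_apo", "wt_holo", "mut_apo", "mut_holo"), function(cn) {
    m <- mean_se(base_prop(cn))
    tibble(condition = cn, base_helix_propensity = m["mean"],
           se = m["se"])
  })
  contact_res <- sys0$contact_residue_index
  near <- (contact_res - 2):(contact_res + 2)
  rmsf_near <- vapply(conds, function(cd) {
    mean(cd$rmsf$rmsf_A[cd$rmsf$index %in% near])
  }, 1.0)
  summary <- list(
    config_hash = config_hash(config),
    base_helix_propensity = dplyr::bind_rows(bp),
    rmsf_near_contact = tibble(condition = names(rmsf_near),
                               rmsf_A = unname(rmsf_near)),
    minus_t_ds_conf = tibble(
      analog = c("wt", "mutant"),
      kcal_per_mol = c(entropy$wt$minus_t_delta_s,
                       entropy$mutant$minus_t_delta_s),
      ci_lo = c(entropy$wt$ci[1], entropy$mutant$ci[1]),
      ci_hi = c(entropy$wt$ci[2], entropy$mutant$ci[2])
    ),
    sasa_percent_decrease = sasa_tbl,
    ligand_minus_t_ds = lig_entropy,
    orderings = list(
      helix_wt_holo_gt_mut_holo =
        bp[[2]]$base_helix_propensity > bp[[4]]$base_helix_propensity,
      entropy_loss_wt_gt_mut =
        entropy$wt$minus_t_delta_s > entropy$mutant$minus_t_delta_s,
      rmsf_wt_holo_lt_mut_holo =
        rmsf_near[["wt_holo"]] < rmsf_near[["mut_holo"]]
    )
  )
  out <- structure(
    list(conditions = conds, sasa = sasa_tbl, entropy = entropy,
         ligand_entropy = lig_entropy, nmr = nmr, summary = summary,
         config = config, hash = summary$config_hash),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cd in result$conditions) {
    pre <- file.path(out_dir, cd$name)
    readr::write_csv(cd$propensity, paste0(pre, "_helix_propensity.csv"))
    readr::write_csv(cd$rmsf, paste0(pre, "_rmsf.csv"))
    write_torsion_csv(cd$ensemble, paste0(pre, "_torsions.csv"))
    if (!is.null(cd$fes)) {
      write_fes_csv(cd$fes, paste0(pre, "_fes.csv"))
      grDevices::pdf(paste0(pre, "_fes.pdf"), width = 6, height = 5)
      print(autoplot(cd$fes) + ggplot2::ggtitle(cd$name))
      grDevices::dev.off()
    }
  }
  for (an in names(result$nmr)) {
    write_shift_csv(result$nmr[[an]]$shifts,
                    file.path(out_dir, paste0(an, "_shifts.csv")))
  }
  summ <- result$summary
  summ$base_helix_propensity <- as.data.frame(summ$base_helix_propensity)
  summ$rmsf_near_contact <- as.data.frame(summ$rmsf_near_contact)
  summ$minus_t_ds_conf <- as.data.frame(summ$minus_t_ds_conf)
  summ$sasa_percent_decrease <- as.data.frame(summ$sasa_percent_decrease)
  summ$ligand_minus_t_ds <- as.data.frame(summ$ligand_minus_t_ds)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "columns")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> hash ", x$hash, "\n", sep = "")
  print(x$summary$base_helix_propensity)
  invisible(x)
}

#' Compare pipeline conditions
#'
#' Pairwise differences of the headline observables between two (or more)
#' pipeline bundles or conditions within one bundle, with bootstrap/block
#' standard errors carried through.
#'
#' @param result a `pipeline_result`.
#' @return a tibble of differences `(comparison, quantity, difference, se)`.
#' @export
compare_conditions <- function(result) {
  s <- result$summary
  bp <- s$base_helix_propensity
  g <- function(cond, col) bp[bp$condition == cond, ][[col]]
  rn <- s$rmsf_near_contact
  r <- function(cond) rn$rmsf_A[rn$condition == cond]
  e <- s$minus_t_ds_conf
  tibble(
    comparison = c("wt_holo - mut_holo", "wt_apo - mut_apo",
                   "wt_holo - mut_holo", "wt - mutant"),
    quantity = c("base helix propensity", "base helix propensity",
                 "rmsf near contact (A)", "-T dS_conf (kcal/mol)"),
    difference = c(
      g("wt_holo", "base_helix_propensity") -
        g("mut_holo", "base_helix_propensity"),
      g("wt_apo", "base_helix_propensity") -
        g("mut_apo", "base_helix_propensity"),
      r("wt_holo") - r("mut_holo"),
      e$kcal_per_mol[e$analog == "wt"] - e$kcal_per_mol[e$analog == "mutant"]
    ),
    se = c(
      sqrt(g("wt_holo", "se")^2 + g("mut_holo", "se")^2),
      sqrt(g("wt_apo", "se")^2 + g("mut_apo", "se")^2),
      NA_real_,
      sqrt(result$entropy$wt$boot_sd^2 + result$entropy$mutant$boot_sd^2)
    )
  )
}
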