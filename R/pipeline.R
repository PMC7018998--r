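#' Default end-to-end run configuration
#'
#' Returns the full parameter block consumed by [run_pipeline()], seeded at
#' the unstimulated CHO-ErbB2-ErbB3 operating point. Any subset can be
#' overridden via YAML (see [run_pipeline()]) or by modifying the list.
#'
#' @param master_seed master RNG seed; per-stage seeds are derived as
#'   `master_seed * 13 + stage_offset` (offsets: simulate_homo 1,
#'   simulate_hetero 2, corrections 3, global 4, frap 5, binding 6), kept
#'   below 2^31.
#' @return nested configuration list.
#' @export
default_run_config <- function(master_seed = 1) {
  list(
    master_seed = master_seed,
    condition = "untreated",
    n_cells = 20,
    sim = list(field_width_um = 40, field_height_um = 10,
               aperture_width_um = 10, recovery_time_s = 7.5,
               channel_gap_s = 0.02, localization_sigma_um = 0.02,
               frame_interval_s = 0.01, n_tracking_frames = 0),
    population = list(density_erbb3_per_um2 = 10,
                      density_erbb2_per_um2 = 10,
                      f_homodimer = 0.2, f_heterodimer = 0.3,
                      D = list(monomer = 0.095, homodimer = 0.031,
                               heterodimer = 0.017, erbb2_monomer = 0.044)),
    labeling = list(fab_conc_green_nM = 200, fab_conc_red_nM = 200,
                    Kd_green_nM = 5, Kd_red_nM = 5,
                    dol_green = 1.5, dol_red = 1.8),
    coloc = list(radius_um = 0.16, fp_method = "mirror_xy"),
    frap = list(f_m = 0.41, tau_s = 20, k_bleach = 0.005,
                n_postbleach = 120, t_lag_s = 2, noise_sd = 0.02,
                n_cells = 10),
    binding = list(Kd_nM = 5, Bmax = 1000,
                   concentrations_nM = c(0.5, 1, 2, 5, 10, 20, 50, 100),
                   noise_cv = 0.03),
    n_boot = 500)
}

stage_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 13 + offset) %% 2147483647)
}

#' Run the full synthetic TOCCSL analysis pipeline
#'
#' Orchestrates simulate (homodimer- and heterodimer-mode experiments) ->
#' co-localization -> labeling/recovery corrections -> global composition
#' fit, plus a FRAP cohort and a binding titration, from one configuration.
#' All randomness derives deterministically from `master_seed`, so a rerun
#' with the same config reproduces the report bit for bit.
#'
#' @param config a list as from [default_run_config()], or a path to a YAML
#'   file with the same structure (parsed with [yaml::read_yaml()]; missing
#'   entries take defaults).
#' @param out_dir optional output directory; when given, the report is
#'   written to `report.json` and localization tables to CSV.
#' @return run report (list, class `toccsl_report`): per-experiment dimer
#'   fractions, composition estimate, diffusion estimates, FRAP summary,
#'   binding fit, provenance (seed, config).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(default_run_config(), config)
  ms <- config$master_seed

  simc <- do.call(sim_config, config$sim)
  pop_args <- config$population
  pop_args$D <- unlist(pop_args$D)
  pop <- do.call(population_spec, pop_args)
  lab_homo <- do.call(labeling_spec, c(list(mode = "homo"), config$labeling))
  lab_het <- do.call(labeling_spec, c(list(mode = "hetero"), config$labeling))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ds_homo <- run_stage("simulate_homo",
    simulate_toccsl_dataset(simc, pop, lab_homo, n_cells = config$n_cells,
                            seed = stage_seed(ms, 1)))
  ds_het <- run_stage("simulate_hetero",
    simulate_toccsl_dataset(simc, pop, lab_het, n_cells = config$n_cells,
                            seed = stage_seed(ms, 2)))

  cc_homo <- run_stage("coloc",
    colocalize_dataset(ds_homo, config$coloc$radius_um,
                       config$coloc$fp_method))
  cc_het <- colocalize_dataset(ds_het, config$coloc$radius_um,
                               config$coloc$fp_method)

  rmod <- recovery_model(simc$aperture_width_um, simc$analysis_width_um,
                         simc$recovery_time_s, simc$bleach_duration_s)
  D <- pop$D
  homo_est <- run_stage("corrections_homo",
    estimate_homodimer_fraction(cc_homo, lab_homo, D[["monomer"]],
                                D[["homodimer"]], rmod,
                                simc$channel_gap_s,
                                simc$localization_sigma_um,
                                n_boot = config$n_boot,
                                seed = stage_seed(ms, 3)))
  het_est <- run_stage("corrections_hetero",
    estimate_heterodimer_fraction(cc_het, lab_het, D[["monomer"]],
                                  D[["heterodimer"]], rmod,
                                  simc$channel_gap_s,
                                  simc$localization_sigma_um,
                                  n_boot = config$n_boot,
                                  seed = stage_seed(ms, 3)))
  comp <- run_stage("global_fit",
    fit_global(cc_homo, cc_het, lab_homo, lab_het, D, rmod,
               simc$channel_gap_s, simc$localization_sigma_um,
               n_boot = min(100, config$n_boot),
               seed = stage_seed(ms, 4), condition = config$condition))

  fr <- config$frap
  set.seed(stage_seed(ms, 5))
  curves <- lapply(seq_len(fr$n_cells), function(i)
    simulate_frap_curve(fr$f_m, fr$tau_s, fr$k_bleach, fr$n_postbleach,
                        fr$t_lag_s, fr$noise_sd))
  fast <- simulate_frap_curve(1, 1e-6, fr$k_bleach, 200, 0.015, fr$noise_sd)
  kb <- fit_bleach_rate(fast$series)
  frap_sum <- run_stage("frap", pool_frap_fits(curves, kb$k_bleach))

  bd <- config$binding
  tit <- simulate_binding_titration(bd$Kd_nM, bd$Bmax, bd$concentrations_nM,
                                    bd$noise_cv, seed = stage_seed(ms, 6))
  kd_fit <- run_stage("binding", fit_specific_binding(tit))

  report <- list(
    condition = config$condition,
    seed = ms,
    config_hash = digest_config(config),
    truth = list(fractions = as.list(pop$fractions)),
    homodimer = list(fraction = homo_est$fraction, se = homo_est$se,
                     n_cells = homo_est$n_cells),
    heterodimer = list(fraction = het_est$fraction, se = het_est$se,
                       n_cells = het_est$n_cells),
    composition = list(mu = comp$mu, alpha = comp$alpha, beta = comp$beta,
                       se = as.list(comp$se)),
    frap = list(f_m_mean = frap_sum$f_m_mean, f_m_sd = frap_sum$f_m_sd,
                k_bleach = kb$k_bleach, n_cells = frap_sum$n_cells),
    binding = list(Kd = kd_fit$Kd, Bmax = kd_fit$Bmax),
    versions = list(toccslr = as.character(utils::packageVersion("toccslr")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  class(report) <- "toccsl_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_toccsl_csv(ds_homo, file.path(out_dir, "homo"),
                     ground_truth = TRUE)
    write_toccsl_csv(ds_het, file.path(out_dir, "hetero"),
                     ground_truth = TRUE)
  }
  report
}

digest_config <- function(config) {
  # order-stable hash of the config without external dependencies
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            4294967295)
}

#' @export
print.toccsl_report <- function(x, ...) {
  cat("TOCCSL pipeline report (", x$condition, ", seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  homodimer fraction:   %.3f +/- %.3f\n",
              x$homodimer$fraction, x$homodimer$se))
  cat(sprintf("  heterodimer fraction: %.3f +/- %.3f\n",
              x$heterodimer$fraction, x$heterodimer$se))
  cat(sprintf("  composition (mu, alpha, beta): %.3f, %.3f, %.3f\n",
              x$composition$mu, x$composition$alpha, x$composition$beta))
  cat(sprintf("  FRAP mobile fraction: %.3f +/- %.3f\n",
              x$frap$f_m_mean, x$frap$f_m_sd))
  cat(sprintf("  Fab Kd: %.2f nM\n", x$binding$Kd))
  invisible(x)
}
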