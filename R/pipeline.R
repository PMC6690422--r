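#' Configuration of the end-to-end analysis pipeline
#'
#' @param participants optional participant table; if `NULL`, either
#'   `participants_csv` is read or data are generated from `generator`.
#' @param participants_csv optional path to a participant CSV.
#' @param generator a [generator_config()] used when no data are supplied.
#' @param measures density measures to analyse (any of `"vpd_log"`,
#'   `"birads_integer"`, `"fibro_log"`, `"fat_log"`).
#' @param adjustments adjustment columns for the logistic models.
#' @param n_groups quantile groups for the grouped odds ratios.
#' @param thresholds percent thresholds of the low/high 10-year risk strata.
#' @param hist_bin_width histogram bin width, percent.
#' @param n_boot_kappa,n_boot_mc bootstrap replicate counts.
#' @param seed master seed for all bootstrap streams.
#' @param out_dir optional directory for the JSON report and TSV tables.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(participants = NULL,
                            participants_csv = NULL,
                            generator = generator_config(),
                            measures = c("vpd_log", "birads_integer"),
                            adjustments = standard_adjustments(),
                            n_groups = 5,
                            thresholds = c(2, 8),
                            hist_bin_width = 0.5,
                            n_boot_kappa = 2000,
                            n_boot_mc = 1000,
                            seed = 1,
                            out_dir = NULL) {
  cfg <- list(participants = participants, participants_csv = participants_csv,
              generator = generator, measures = measures,
              adjustments = adjustments, n_groups = n_groups,
              thresholds = thresholds, hist_bin_width = hist_bin_width,
              n_boot_kappa = n_boot_kappa, n_boot_mc = n_boot_mc,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full density-and-risk analysis
#'
#' Chains data acquisition (simulate or read), BI-RADS/volumetric agreement,
#' expected-density fitting and residualization, adjusted odds ratios with
#' likelihood-ratio tests and quantile-group ORs, matched concordance,
#' baseline-risk calibration, and combination of the density relative risk
#' with the 10-year absolute risk into clinical strata. Deterministic given
#' the seeds in the configuration.
#'
#' @param config a [pipeline_config()].
#' @return Report list with sections `meta`, `summary`, `agreement`,
#'   `density` (per measure: IQ-OR, LR test, mC, quantile ORs, combined risk
#'   strata and histograms) and `calibration`. When `out_dir` is set, also
#'   writes `report.json` plus TSV tables there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  tab <- stage("input", {
    if (!is.null(config$participants)) config$participants
    else if (!is.null(config$participants_csv)) read_participants(config$participants_csv)
    else generate_population(config$generator)
  })
  message(sprintf("pipeline: input stage complete (%d rows)", nrow(tab)))
  tab <- stage("prepare", prepare_analysis_data(tab))

  agreement <- stage("agreement", {
    vpd_grade <- assign_birads(tab$vpd, noise_sd = 0)
    ct <- table(factor(tab$birads, levels = 1:4),
                factor(vpd_grade, levels = 1:4))
    list(crosstab = unclass(as.matrix(ct)),
         kappa = weighted_kappa(as.matrix(ct), "linear",
                                n_boot = config$n_boot_kappa,
                                seed = config$seed))
  })

  controls <- tab[tab$status == "control", , drop = FALSE]
  adj_no_age <- setdiff(config$adjustments, "age_group")
  density <- list()
  for (measure in config$measures) {
    density[[measure]] <- stage(paste0("assess_", measure), {
      model <- fit_expected_density(controls, measure)
      rescol <- paste0(sub("_.*$", "", measure), "_residual")
      tab2 <- add_residual(tab, model, rescol)
      fit <- fit_adjusted_logistic(tab2, rescol, config$adjustments)
      fit0 <- fit_adjusted_logistic(tab2, NULL, config$adjustments)
      q <- residual_iqr(model)
      ior <- iq_or(fit, q[["q25"]], q[["q75"]], term = rescol)
      lrt <- lr_test(fit, fit0)
      qor <- quantile_group_ors(tab2, rescol, config$n_groups,
                                config$adjustments)
      tab2$.mc_score <- adjust_predictor(tab2, rescol, adj_no_age)
      mc <- matched_concordance(tab2, ".mc_score", "age_group",
                                n_boot = config$n_boot_mc, seed = config$seed)
      # combined absolute risk among screening-representative controls
      ctrl2 <- tab2[tab2$status == "control", , drop = FALSE]
      if ("region" %in% names(ctrl2) && any(ctrl2$region == "primary")) {
        ctrl2 <- ctrl2[ctrl2$region == "primary", , drop = FALSE]
      }
      beta <- unname(fit$coefficients[rescol])
      ctrl_res <- tab2[[rescol]][tab2$status == "control"]
      rr <- density_relative_risk(ctrl2[[rescol]], beta,
                                  control_residuals = ctrl_res)
      combined <- combine_risk(ctrl2$tc10, rr)
      list(
        expected_density_model = model,
        iq_or = ior, lr_test = lrt,
        quantile_ors = qor$groups,
        concordance = mc,
        strata_baseline = risk_strata_proportions(ctrl2$tc10,
                                                  config$thresholds),
        strata_combined = risk_strata_proportions(combined,
                                                  config$thresholds),
        hist_baseline = risk_histogram(ctrl2$tc10, config$hist_bin_width),
        hist_combined = risk_histogram(combined, config$hist_bin_width)
      )
    })
    message(sprintf("pipeline: %s assessed (IQ-OR %.2f)", measure,
                    density[[measure]]$iq_or$or))
  }

  calibration <- stage("calibration", calibration_coefficient(tab, "tc10"))
  report <- list(
    meta = list(
      package_version = as.character(utils::packageVersion("densrisk")),
      seed = config$seed,
      n_rows = nrow(tab),
      n_cases = sum(tab$case == 1),
      n_controls = sum(tab$case == 0),
      measures = config$measures,
      adjustments = config$adjustments
    ),
    summary = stage("summary", summarize_population(tab)),
    agreement = agreement,
    density = density,
    calibration = calibration
  )
  if (!is.null(config$out_dir)) {
    stage("write_report", write_report(report, config$out_dir))
  }
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report
  for (m in names(slim$density)) {
    slim$density[[m]]$expected_density_model <-
      unclass(slim$density[[m]]$expected_density_model)
    slim$density[[m]]$concordance <- unclass(slim$density[[m]]$concordance)
    slim$density[[m]]$iq_or <- unclass(slim$density[[m]]$iq_or)
  }
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (m in names(report$density)) {
    write.table(report$density[[m]]$quantile_ors,
                file.path(out_dir, paste0("quantile_ors_", m, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(as.data.frame(report$agreement$crosstab),
              file.path(out_dir, "agreement_crosstab.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
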