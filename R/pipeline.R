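#' Study configuration
#'
#' Assembles the configuration of the end-to-end in-silico study: stage
#' seeds, cohort sizes, selection, PK and trial settings, and analysis
#' thresholds. Defaults reproduce the study design (30,000 plausible
#' patients, 400 PK pseudo-patients, 500 basis deviations, 750 mg flat
#' Q2W dosing, 400-day horizon, PD-L1 threshold 0.25, target sensitivity
#' 0.8); [smoke_study_config()] scales the expensive stages down for
#' desk-scale runs.
#'
#' @param ... Named overrides of any top-level config entry.
#' @return A `vp_study_config` list.
#' @export
study_config <- function(...) {
  cfg <- list(
    seeds = list(
      data = 101, plausible = 102, select = 103, pk = 104,
      trial = 105, morris = 106
    ),
    n_observed = 800,
    n_plausible = 30000,
    n_pseudo = 400,
    ratio_config = ratio_config(),
    selection = list(N = 8, annealing = list(n_iter = 150, min_cohort = 50)),
    pk = list(
      k = 500, lambda = 0.1, n_starts = 4,
      times = seq(0, 112, by = 0.5), bounds = default_pk_bounds()
    ),
    regimen = dose_regimen(mode = "flat", amount = 750, interval = 14),
    horizon = 400,
    pdl1_threshold = 0.25,
    target_sensitivity = 0.8,
    bootstrap_B = 2000,
    morris = list(enabled = FALSE, n_requested = 1000, levels = 11, delta = 0.1)
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown config entries: ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    cfg <- utils::modifyList(cfg, dots)
  }
  needed <- c("data", "plausible", "select", "pk", "trial", "morris")
  if (!all(needed %in% names(cfg$seeds)) ||
    any(vapply(cfg$seeds[needed], is.null, logical(1)))) {
    stop("every stage seed must be set: ", paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  class(cfg) <- c("vp_study_config", "list")
  cfg
}

#' @rdname study_config
#' @export
smoke_study_config <- function(...) {
  study_config(
    n_observed = 500,
    n_plausible = 2000,
    n_pseudo = 40,
    pk = list(
      k = 60, lambda = 0.1, n_starts = 2,
      times = seq(0, 112, by = 1), bounds = default_pk_bounds()
    ),
    ...
  )
}

#' Read / write a study configuration as YAML
#'
#' Scalars and nested lists are serialized; the regimen and parameter
#' specs are reconstructed through their constructors on read.
#'
#' @param config A `vp_study_config`.
#' @param path File path.
#' @return `read_study_config` returns a `vp_study_config`.
#' @export
write_study_config <- function(config, path) {
  plain <- unclass(config)
  plain$regimen <- unclass(plain$regimen)
  plain$ratio_config$corr <- as.vector(plain$ratio_config$corr)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$regimen <- do.call(dose_regimen, raw$regimen)
  raw$ratio_config$corr <- matrix(unlist(raw$ratio_config$corr), 3, 3)
  raw$ratio_config$meanlog <- unlist(raw$ratio_config$meanlog)
  raw$ratio_config$sdlog <- unlist(raw$ratio_config$sdlog)
  do.call(study_config, raw)
}

.write_csv_with_provenance <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s; stage_seed: %s", config_hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.config_hash <- function(config) {
  ser <- serialize(unclass(config), NULL)
  # cheap stable hash (sum of byte values folded with position)
  sprintf("%08x", sum(as.integer(ser) * (seq_along(ser) %% 251)) %% .Machine$integer.max)
}

#' Run the whole in-silico study
#'
#' Executes the pipeline end to end: synthetic immune-ratio data,
#' plausible patient generation, probability-of-inclusion cohort
#' selection, pseudo-patient PK generation and compressed-latent fitting,
#' the Q2W dosing trial with RECIST classification and bootstrap CIs,
#' biomarker analytics, and (optionally) Morris screening. All stages are
#' seeded from the configuration; rerunning with an identical
#' configuration reproduces the report.
#'
#' @param config A [study_config()].
#' @param out_dir Optional output directory; when given, stage artifacts
#'   (CSV with a provenance header, JSON report, Markdown summary) are
#'   written there.
#' @param progress Print stage progress to stderr.
#' @return A `vp_study_report` list; see the methods vignette for the
#'   field-by-field description.
#' @export
run_study <- function(config = smoke_study_config(), out_dir = NULL,
                      progress = FALSE) {
  say <- function(...) if (progress) message("[vptrial] ", ...)
  hash <- .config_hash(config)

  say("stage 1/6: synthetic immune-ratio data")
  observed <- generate_immune_ratio_dataset(
    config$n_observed, config$ratio_config, seed = config$seeds$data
  )

  say("stage 2/6: plausible patients (n = ", config$n_plausible, ")")
  plausible <- generate_plausible_patients(
    config$n_plausible, seed = config$seeds$plausible
  )
  if (length(plausible$snapshots) < 2 * config$selection$N) {
    stop("stage plausible: too few plausible patients (",
      length(plausible$snapshots), ")",
      call. = FALSE
    )
  }

  say("stage 3/6: virtual cohort selection")
  sel <- select_virtual_cohort(
    observed, plausible$snapshots,
    N = config$selection$N,
    annealing = config$selection$annealing,
    seed = config$seeds$select
  )
  cohort <- sel$cohort
  if (!length(cohort)) stop("stage select: empty cohort", call. = FALSE)

  say("stage 4/6: PK pseudo-patients and compressed-latent fitting")
  pop <- generate_poppk_population(config$n_pseudo, seed = config$seeds$pk)
  curves <- vapply(
    seq_len(nrow(pop)),
    function(j) {
      simulate_2cpt(pop[j, ], config$regimen, config$pk$times)$conc
    },
    numeric(length(config$pk$times))
  )
  space <- fit_pk_population(
    curves, config$pk$times, config$regimen,
    lambda = config$pk$lambda, k = config$pk$k,
    bounds = config$pk$bounds, n_starts = config$pk$n_starts,
    seed = config$seeds$pk
  )
  pk_sets <- sample_pk_parameters(space, length(cohort),
    seed = config$seeds$pk + 1
  )

  say("stage 5/6: in-silico trial (", length(cohort), " patients)")
  trial <- run_trial(cohort, pk_sets,
    regimen = config$regimen,
    horizon = config$horizon
  )
  pdl1 <- vapply(cohort, `[[`, numeric(1), "pdl1_expression")
  high <- pdl1 > config$pdl1_threshold
  resp <- vapply(trial$records, `[[`, logical(1), "responder")
  ci <- list(
    overall = bootstrap_ci(resp, B = config$bootstrap_B, seed = config$seeds$trial),
    pdl1_high = if (any(high)) {
      bootstrap_ci(resp[high], B = config$bootstrap_B, seed = config$seeds$trial + 1)
    },
    pdl1_low = if (any(!high)) {
      bootstrap_ci(resp[!high], B = config$bootstrap_B, seed = config$seeds$trial + 2)
    }
  )

  say("stage 6/6: biomarker analytics")
  bm <- trial$biomarkers
  panel <- c(
    "CD8", "pdl1_expression", "CD8_Treg", "CD8_CD4", "MDSC", "tcc"
  )
  wilcoxon <- vapply(panel, function(v) {
    rank_sum_test(bm[[v]][resp], bm[[v]][!resp])
  }, numeric(1))
  rf <- if (sum(resp) >= 2 && sum(!resp) >= 2) {
    rf_importance(bm[, panel], resp, seed = config$seeds$trial + 3)
  }
  roc_panel <- list(
    CD8_Treg = bm$CD8_Treg,
    pdl1_expression = bm$pdl1_expression,
    CD8_2d = density_3d_to_2d(bm$CD8),
    tcc = bm$tcc,
    MDSC_neg = -bm$MDSC # low MDSC predicts response
  )
  roc <- lapply(roc_panel, function(s) {
    roc_at_sensitivity(s, resp, config$target_sensitivity)[
      c("threshold", "sensitivity", "specificity", "auroc")
    ]
  })
  quintiles <- lapply(
    stats::setNames(panel, panel),
    function(v) {
      if (length(resp) >= 5) quintile_response(bm[[v]], trial$records)
    }
  )
  tvdt_days <- vapply(cohort, function(s) {
    V2 <- diameter_to_volume(s$tumor_diameter)
    ## volume 8 weeks before the preset size is reached, from the
    ## patient's own growth history, approximated by its logistic rate
    g <- s$parameters$k_growth *
      (1 - s$state[["C_total"]] / s$parameters$C_max)
    tvdt(V2 * exp(-g * 56), V2, 56)
  }, numeric(1))

  morris_out <- NULL
  if (isTRUE(config$morris$enabled)) {
    say("Morris screening")
    specs <- default_parameter_specs()
    morris_out <- morris_screen(
      specs,
      n_requested = config$morris$n_requested,
      levels = config$morris$levels, delta = config$morris$delta,
      seed = config$seeds$morris,
      regimen = config$regimen, horizon = config$horizon
    )
  }

  report <- structure(
    list(
      config_hash = hash,
      n_plausible = config$n_plausible,
      n_plausible_ok = length(plausible$snapshots),
      cohort_size = length(cohort),
      beta_star = sel$beta_star,
      ks = stats::setNames(sel$ks, c("M1_M2", "CD8_Treg", "CD8_CD4")),
      summary = trial$summary,
      bootstrap = ci,
      wilcoxon_p = wilcoxon,
      rf_importance = if (!is.null(rf)) rf$importance,
      rf_oob_error = if (!is.null(rf)) rf$oob_error,
      roc = roc,
      quintiles = quintiles,
      tvdt = c(
        mean = mean(tvdt_days[tvdt_days > 0]),
        median = stats::median(tvdt_days[tvdt_days > 0])
      ),
      median_densities = apply(
        t(vapply(cohort, `[[`, numeric(5), "densities")), 2, stats::median
      ),
      pdl1 = pdl1,
      biomarkers = bm,
      records = trial$records,
      trajectories = trial$trajectories,
      exposure = trial$exposure,
      morris = morris_out,
      latent_space = space,
      selection = sel[c("beta_star", "ks", "probabilities", "indices")]
    ),
    class = "vp_study_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_csv_with_provenance(
      observed, file.path(out_dir, "observed_ratios.csv"), hash,
      config$seeds$data
    )
    .write_csv_with_provenance(
      bm, file.path(out_dir, "biomarkers.csv"), hash, config$seeds$trial
    )
    traj <- do.call(rbind, trial$trajectories)
    .write_csv_with_provenance(
      traj, file.path(out_dir, "trajectories.csv"), hash, config$seeds$trial
    )
    jsonlite::write_json(
      list(
        config_hash = hash,
        cohort_size = report$cohort_size,
        beta_star = report$beta_star,
        ks = as.list(report$ks),
        summary = report$summary,
        bootstrap = report$bootstrap,
        wilcoxon_p = as.list(report$wilcoxon_p),
        roc = report$roc,
        tvdt = as.list(report$tvdt),
        median_densities = as.list(report$median_densities)
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

#' Render a Markdown summary of a study report
#' @param report A `vp_study_report`.
#' @return Character vector of Markdown lines.
#' @export
render_report_md <- function(report) {
  s <- report$summary
  fmt_ci <- function(ci) {
    if (is.null(ci)) return("NA")
    sprintf("%.1f%% (%.1f, %.1f)", 100 * ci[["median"]], 100 * ci[["lower"]], 100 * ci[["upper"]])
  }
  c(
    "# In-silico PD-L1 inhibition study report",
    "",
    sprintf("- config hash: %s", report$config_hash),
    sprintf(
      "- plausible patients: %d of %d reached their preset tumor size",
      report$n_plausible_ok, report$n_plausible
    ),
    sprintf("- virtual cohort: %d patients (beta* = %.3g)", report$cohort_size, report$beta_star),
    sprintf(
      "- ratio-distribution match (KS D): M1/M2 %.3f, CD8/Treg %.3f, CD8/CD4 %.3f",
      report$ks[1], report$ks[2], report$ks[3]
    ),
    "",
    "## Response",
    sprintf("- ORR overall: %s", fmt_ci(report$bootstrap$overall)),
    sprintf("- ORR PD-L1 high: %s", fmt_ci(report$bootstrap$pdl1_high)),
    sprintf("- ORR PD-L1 low: %s", fmt_ci(report$bootstrap$pdl1_low)),
    sprintf(
      "- DCR overall: %.1f%%",
      100 * s$dcr[s$group == "overall"]
    ),
    "",
    "## Pre-treatment characteristics",
    sprintf(
      "- TVDT mean %.0f days, median %.0f days",
      report$tvdt[["mean"]], report$tvdt[["median"]]
    ),
    sprintf(
      "- median densities (cells/mL): CD8 %.3g, CD4 %.3g, Treg %.3g, TAM %.3g, MDSC %.3g",
      report$median_densities[["CD8"]], report$median_densities[["CD4"]],
      report$median_densities[["Treg"]], report$median_densities[["TAM"]],
      report$median_densities[["MDSC"]]
    ),
    "",
    "## Biomarkers",
    sprintf(
      "- Wilcoxon p (responders vs non): %s",
      paste(sprintf("%s=%.3g", names(report$wilcoxon_p), report$wilcoxon_p),
        collapse = ", "
      )
    ),
    sprintf(
      "- auROC: %s",
      paste(
        sprintf(
          "%s=%.2f", names(report$roc),
          vapply(report$roc, `[[`, numeric(1), "auroc")
        ),
        collapse = ", "
      )
    )
  )
}
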