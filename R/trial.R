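#' Scheduled tumor measurement times
#'
#' Scans at 6, 12 and 16 weeks after treatment start, then every 8 weeks,
#' up to the horizon.
#'
#' @param horizon Days of follow-up (>= 42).
#' @return Vector of scan days: 42, 84, 112, 168, 224, ...
#' @export
measurement_schedule <- function(horizon) {
  if (horizon < 42) stop("horizon must cover the first scan (42 days)", call. = FALSE)
  base <- c(42, 84, 112)
  later <- if (horizon >= 168) seq(168, horizon, by = 56) else numeric(0)
  sched <- c(base, later)
  sched[sched <= horizon]
}

#' Classify a tumor trajectory by RECIST v1.1
#'
#' Per scan: complete response (CR) when the diameter falls below the
#' detection floor; partial response (PR) at a >= 30% decrease from
#' baseline; progressive disease (PD) at a >= 20% increase from the nadir
#' that is also an absolute increase of >= 5 mm; stable disease (SD)
#' otherwise. Best overall response is the best category achieved at or
#' before the first PD; SD additionally requires a qualifying scan at
#' least `sd_min_days` days after treatment start (the week-6 first scan
#' satisfies this by construction). No confirmation scan is required.
#'
#' @param traj A `vp_trajectory` (or data frame with `time`, `diameter`
#'   and a `baseline` attribute or `baseline` argument).
#' @param baseline Baseline diameter (cm); defaults to the trajectory's
#'   `baseline` attribute.
#' @param detection_floor CR threshold (cm).
#' @param pd_abs Absolute nadir-increase requirement for PD (cm).
#' @param sd_min_days Minimum duration for stable disease (days).
#' @return A `vp_response` list: `patient_id`, `best_response` (one of
#'   `"CR"`, `"PR"`, `"SD"`, `"PD"`), `responder` (CR or PR),
#'   `best_change` (best fractional change from baseline, negative =
#'   shrinkage), `time_of_response`, `time_of_progression` (NA if none),
#'   and the per-scan classification.
#' @export
classify_recist <- function(traj, baseline = attr(traj, "baseline"),
                            detection_floor = 0.1, pd_abs = 0.5,
                            sd_min_days = 42) {
  if (is.null(baseline) || is.na(baseline) || baseline <= 0) {
    stop("positive baseline diameter required", call. = FALSE)
  }
  if (!nrow(traj)) stop("empty trajectory", call. = FALSE)
  d <- traj$diameter
  t <- traj$time
  nadir_prev <- cummin(c(baseline, utils::head(d, -1))) # nadir before each scan
  scan <- character(length(d))
  for (k in seq_along(d)) {
    if (d[k] < detection_floor) {
      scan[k] <- "CR"
    } else if (d[k] <= 0.7 * baseline) {
      scan[k] <- "PR"
    } else if (d[k] >= 1.2 * nadir_prev[k] && d[k] - nadir_prev[k] >= pd_abs) {
      scan[k] <- "PD"
    } else {
      scan[k] <- "SD"
    }
  }
  first_pd <- match("PD", scan)
  upto <- if (is.na(first_pd)) seq_along(scan) else seq_len(first_pd)
  rank <- c(CR = 4, PR = 3, SD = 2, PD = 1)
  considered <- scan[upto]
  ## SD requires a qualifying scan at >= sd_min_days
  sd_ok <- any(considered == "SD" & t[upto] >= sd_min_days)
  cand <- considered
  if (!sd_ok) cand[cand == "SD"] <- "PD"
  best <- names(rank)[rank == max(rank[cand])][1]
  responder <- best %in% c("CR", "PR")
  structure(
    list(
      patient_id = traj$patient_id[1],
      best_response = best,
      responder = responder,
      best_change = min(d[upto]) / baseline - 1,
      time_of_response = if (responder) t[upto][match(TRUE, considered %in% c("CR", "PR"))] else NA_real_,
      time_of_progression = if (is.na(first_pd)) NA_real_ else t[first_pd],
      scans = data.frame(time = t, diameter = d, response = scan)
    ),
    class = "vp_response"
  )
}

#' Objective response and disease control rates with PD-L1 subgroups
#'
#' @param records List of `vp_response` objects.
#' @param pdl1 Numeric vector of PD-L1 expression fractions, aligned with
#'   `records`.
#' @param pdl1_threshold High/low split threshold (default 0.25).
#' @return Data frame with one row per group (`overall`, `PD-L1 high`,
#'   `PD-L1 low`): `n`, `responders`, `orr`, `dcr`. Empty subgroups get
#'   `NA` rates with a warning.
#' @export
trial_summary <- function(records, pdl1, pdl1_threshold = 0.25) {
  if (length(records) != length(pdl1)) {
    stop("records and pdl1 must be keyed identically", call. = FALSE)
  }
  resp <- vapply(records, `[[`, logical(1), "responder")
  best <- vapply(records, `[[`, character(1), "best_response")
  rate <- function(idx) {
    n <- sum(idx)
    if (!n) {
      warning("empty subgroup: rates reported as NA")
      return(c(n = 0, responders = NA, orr = NA, dcr = NA))
    }
    c(
      n = n,
      responders = sum(resp[idx]),
      orr = mean(resp[idx]),
      dcr = mean(resp[idx] | best[idx] == "SD")
    )
  }
  groups <- list(
    overall = rep(TRUE, length(records)),
    `PD-L1 high` = pdl1 > pdl1_threshold,
    `PD-L1 low` = pdl1 <= pdl1_threshold
  )
  out <- as.data.frame(t(vapply(groups, rate, numeric(4))))
  out$group <- names(groups)
  out[, c("group", "n", "responders", "orr", "dcr")]
}

#' Percentile bootstrap of a response rate
#'
#' Resamples the binary outcome vector with replacement `B` times at the
#' given resample size and reports the 50th / 2.5th / 97.5th percentiles
#' of the resampled rates.
#'
#' @param outcomes Binary (logical or 0/1) outcome vector.
#' @param resample_size Resample size (defaults to `length(outcomes)`; in
#'   the study design it matches the clinical subgroup size).
#' @param B Number of bootstrap resamples (>= 100; default 2000).
#' @param seed Integer seed.
#' @return Named vector `median`, `lower`, `upper` (95% interval).
#' @export
bootstrap_ci <- function(outcomes, resample_size = length(outcomes),
                         B = 2000, seed = 1) {
  if (!length(outcomes)) stop("empty outcomes", call. = FALSE)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  x <- as.numeric(outcomes)
  local_seed(seed)
  idx <- matrix(sample.int(length(x), resample_size * B, replace = TRUE),
    nrow = resample_size
  )
  rates <- colMeans(matrix(x[idx], nrow = resample_size))
  q <- stats::quantile(rates, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], lower = q[2], upper = q[3])
}

#' Pharmacokinetic exposure metrics of one concentration series
#'
#' Computes the peak, trough and trapezoid AUC over the first dosing
#' interval and over the steady-state interval starting at week 16, plus
#' the accumulation indices (steady state / first dose).
#'
#' @param conc Data frame with `time` (days) and `conc`.
#' @param regimen The dosing regimen (supplies the interval).
#' @param ss_start Start of the steady-state interval (day, default 112 =
#'   week 16).
#' @return Named vector: `Cmax1`, `Cmin1`, `AUC1`, `Cmax_ss`, `Cmin_ss`,
#'   `AUC_ss`, `R_Cmax`, `R_Cmin`, `R_AUC`.
#' @export
exposure_metrics <- function(conc, regimen = dose_regimen(), ss_start = 112) {
  tau <- regimen$interval
  t0 <- regimen$start
  if (max(conc$time) < t0 + tau) {
    stop("concentration series must cover the first dosing interval",
      call. = FALSE
    )
  }
  window <- function(from, to) {
    w <- conc[conc$time >= from & conc$time <= to, ]
    if (nrow(w) < 2) stop("too few samples in the dosing interval", call. = FALSE)
    auc <- sum(diff(w$time) * (utils::head(w$conc, -1) + utils::tail(w$conc, -1)) / 2)
    c(Cmax = max(w$conc), Cmin = min(w$conc), AUC = auc)
  }
  first <- window(t0, t0 + tau)
  ss_from <- t0 + floor((ss_start - t0) / tau) * tau
  ss <- if (max(conc$time) >= ss_from + tau) window(ss_from, ss_from + tau) else c(Cmax = NA, Cmin = NA, AUC = NA)
  c(
    Cmax1 = unname(first["Cmax"]), Cmin1 = unname(first["Cmin"]),
    AUC1 = unname(first["AUC"]),
    Cmax_ss = unname(ss["Cmax"]), Cmin_ss = unname(ss["Cmin"]),
    AUC_ss = unname(ss["AUC"]),
    R_Cmax = unname(ss["Cmax"] / first["Cmax"]),
    R_Cmin = unname(ss["Cmin"] / first["Cmin"]),
    R_AUC = unname(ss["AUC"] / first["AUC"])
  )
}

#' Run the in-silico trial on a virtual cohort
#'
#' Simulates treatment for every patient, classifies responses, and
#' collects the per-patient biomarker table (pre-treatment and day-14).
#'
#' @param cohort List of `vp_snapshot` objects.
#' @param pk_sets List of `vp_pk_parameters`, recycled if length 1.
#' @param regimen A [dose_regimen()].
#' @param horizon Follow-up (days, default 400).
#' @param constants A `vp_constants`.
#' @return List: `records` (responses), `summary` (from
#'   [trial_summary()]), `biomarkers` (data frame, see
#'   [biomarker_table()]), `trajectories`, `exposure` (per-patient
#'   exposure metrics).
#' @export
run_trial <- function(cohort, pk_sets, regimen = dose_regimen(),
                      horizon = 400, constants = model_constants()) {
  n <- length(cohort)
  if (length(pk_sets) == 1) pk_sets <- rep(pk_sets, n)
  stopifnot(length(pk_sets) == n)
  records <- vector("list", n)
  trajectories <- vector("list", n)
  expo <- matrix(NA_real_, n, 9)
  day14 <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("CD8_day14", "CD8_Treg_day14")))
  for (k in seq_len(n)) {
    sim <- simulate_treatment(cohort[[k]], pk_sets[[k]], regimen, horizon,
      constants = constants
    )
    records[[k]] <- classify_recist(sim$trajectory,
      detection_floor = constants$detection_floor
    )
    trajectories[[k]] <- sim$trajectory
    expo[k, ] <- exposure_metrics(sim$concentration, regimen)
    i14 <- which.min(abs(sim$states[, 1] - 14))
    st <- sim$states[i14, .state_names]
    V_mL <- assemble_tumor_volume(st, constants) * 1e-12
    day14[k, 1] <- st[["T8_T"]] / V_mL
    day14[k, 2] <- st[["T8_T"]] / st[["Treg_T"]]
  }
  colnames(expo) <- c(
    "Cmax1", "Cmin1", "AUC1", "Cmax_ss", "Cmin_ss", "AUC_ss",
    "R_Cmax", "R_Cmin", "R_AUC"
  )
  pdl1 <- vapply(cohort, `[[`, numeric(1), "pdl1_expression")
  list(
    records = records,
    summary = trial_summary(records, pdl1),
    biomarkers = cbind(biomarker_table(cohort, records), day14),
    trajectories = trajectories,
    exposure = as.data.frame(expo)
  )
}
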