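#' Default distribution spec for the synthetic immune-ratio table
#'
#' Log-scale medians, standard deviations and correlations of the three
#' immune subset ratios (M1/M2, CD8/Treg, CD8/CD4), with a small
#' zero-inflation fraction emulating patients in whom one subset estimate
#' is zero. The numerical values are fixture conventions chosen to be
#' order-of-magnitude consistent with immunogenomic cohort summaries for
#' lung cancer, and are never used as test oracles.
#'
#' @param meanlog Named length-3 vector of log-ratio means
#'   (`M1_M2`, `CD8_Treg`, `CD8_CD4`).
#' @param sdlog Length-3 vector of log-ratio standard deviations.
#' @param corr 3x3 positive-definite correlation matrix of the log-ratios.
#' @param zero_fraction Fraction of rows receiving a zero entry in one
#'   randomly chosen ratio column.
#' @param luad_fraction Probability a patient is labeled LUAD (vs LUSC).
#' @return A named list (`vp_ratio_config`).
#' @export
ratio_config <- function(meanlog = c(M1_M2 = log(0.45), CD8_Treg = log(4.7),
                                     CD8_CD4 = log(0.82)),
                         sdlog = c(0.38, 0.45, 0.34),
                         corr = rbind(
                           c(1, 0, 0),
                           c(0, 1, 0.4),
                           c(0, 0.4, 1)
                         ),
                         zero_fraction = 0.05,
                         luad_fraction = 0.55) {
  stopifnot(
    length(meanlog) == 3, length(sdlog) == 3, all(sdlog >= 0),
    is.matrix(corr), all(dim(corr) == 3),
    zero_fraction >= 0, zero_fraction < 1,
    luad_fraction >= 0, luad_fraction <= 1
  )
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("correlation matrix must be positive definite", call. = FALSE)
  }
  list(
    meanlog = meanlog, sdlog = sdlog, corr = corr,
    zero_fraction = zero_fraction, luad_fraction = luad_fraction
  )
}

#' Generate a synthetic immune-ratio dataset
#'
#' Draws log-ratios from a correlated trivariate normal, exponentiates, and
#' injects zero entries at the configured fraction. Stands in for the
#' per-patient immune cell proportion summaries an immunogenomic portal
#' would provide for LUAD/LUSC cohorts.
#'
#' @param n Number of patients (> 0).
#' @param config A [ratio_config()] list.
#' @param seed Integer seed; identical `n`, `config` and `seed` give a
#'   bit-identical dataset.
#' @return Data frame with columns `patient_id`, `subtype`
#'   (`"LUAD"`/`"LUSC"`), `M1_M2`, `CD8_Treg`, `CD8_CD4`.
#' @export
generate_immune_ratio_dataset <- function(n, config = ratio_config(),
                                          seed = 1) {
  stopifnot(n > 0)
  local_seed(seed)
  Sigma <- diag(config$sdlog) %*% config$corr %*% diag(config$sdlog)
  z <- MASS::mvrnorm(n, mu = unname(config$meanlog), Sigma = Sigma)
  z <- matrix(z, nrow = n)
  ratios <- exp(z)
  colnames(ratios) <- c("M1_M2", "CD8_Treg", "CD8_CD4")
  if (config$zero_fraction > 0) {
    hit <- stats::runif(n) < config$zero_fraction
    col <- sample.int(3, n, replace = TRUE)
    ratios[cbind(which(hit), col[hit])] <- 0
  }
  subtype <- ifelse(stats::runif(n) < config$luad_fraction, "LUAD", "LUSC")
  data.frame(
    patient_id = seq_len(n),
    subtype = subtype,
    ratios,
    stringsAsFactors = FALSE
  )
}

#' Remove zero-containing rows and natural-log transform the ratios
#'
#' Rows that contain a zero in any ratio column are removed to avoid
#' singularities; the remaining ratios are natural-log transformed.
#'
#' @param data Data frame with columns `M1_M2`, `CD8_Treg`, `CD8_CD4`.
#' @return A numeric matrix of ln-ratios with attribute `n_removed`.
#' @export
clean_and_log_transform <- function(data) {
  cols <- c("M1_M2", "CD8_Treg", "CD8_CD4")
  if (!all(cols %in% names(data))) {
    stop("data must contain the three ratio columns", call. = FALSE)
  }
  m <- as.matrix(data[, cols])
  keep <- apply(m > 0 & is.finite(m), 1, all)
  if (!any(keep)) stop("all rows removed: no positive ratios", call. = FALSE)
  out <- log(m[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Default covariate model for the two-compartment popPK pseudo-population
#'
#' Typical parameter values, covariate distributions and power-law/
#' proportional covariate effects used to generate pseudo-patients. The
#' covariate equations of the original population analysis are not public;
#' this mapping is a declared surrogate with conventional reference values
#' (70 kg body weight, 39 g/L albumin).
#'
#' @return A nested list (`typical`, `covariates`, `effects`, `iiv_sd`).
#' @export
poppk_covariate_config <- function() {
  list(
    typical = c(Cl = 0.23, Vmax = 1.0, Km = 0.45, V1 = 3.5, V2 = 3.4),
    Q = 0.476, # L/day, fixed for all patients
    covariates = list(
      weight = list(dist = "lognormal", median = 70, sdlog = 0.2), # kg
      albumin = list(dist = "lognormal", median = 39, sdlog = 0.12), # g/L
      spdl1 = list(dist = "lognormal", median = 1, sdlog = 0.5), # relative
      male = list(dist = "binomial", prob = 0.6),
      ecog1 = list(dist = "binomial", prob = 0.5)
    ),
    ## exponents (continuous, power law on covariate/reference) and
    ## proportional shifts (categorical)
    effects = list(
      Cl = c(weight = 0.6, albumin = -0.9, spdl1 = 0.15, male = 0.08, ecog1 = 0.12),
      Vmax = c(spdl1 = 0.3),
      V1 = c(weight = 0.6, male = 0.1),
      V2 = c(weight = 0.6)
    ),
    iiv_sd = c(Cl = 0.2, Vmax = 0.3, Km = 0, V1 = 0.15, V2 = 0.25)
  )
}

#' Generate a population of two-compartment popPK parameter sets
#'
#' Continuous covariates are sampled log-normally and categorical ones
#' binomially; parameters are mapped from covariates through the
#' configurable power-law/proportional model, with log-normal unexplained
#' interindividual variability. The intercompartmental clearance `Q` is
#' fixed at 0.476 L/day for all patients.
#'
#' @param n Number of pseudo-patients (> 0; 400 in the study design).
#' @param config A [poppk_covariate_config()] list.
#' @param seed Integer seed.
#' @return Data frame, one row per patient: `Cl`, `Vmax`, `Km`, `V1`,
#'   `V2`, `Q` plus the sampled covariates.
#' @export
generate_poppk_population <- function(n = 400,
                                      config = poppk_covariate_config(),
                                      seed = 1) {
  stopifnot(n > 0)
  required <- c("typical", "Q", "covariates", "effects", "iiv_sd")
  if (!all(required %in% names(config))) {
    stop("covariate config must provide: ",
      paste(setdiff(required, names(config)), collapse = ", "),
      call. = FALSE
    )
  }
  local_seed(seed)
  cov <- lapply(config$covariates, function(cv) {
    switch(cv$dist,
      lognormal = stats::rlnorm(n, log(cv$median), cv$sdlog),
      binomial = stats::rbinom(n, 1, cv$prob),
      stop("unknown covariate distribution: ", cv$dist, call. = FALSE)
    )
  })
  ref <- c(weight = 70, albumin = 39, spdl1 = 1, male = 0, ecog1 = 0)
  pars <- sapply(names(config$typical), function(pn) {
    val <- rep(config$typical[[pn]], n)
    eff <- config$effects[[pn]]
    for (cn in names(eff)) {
      x <- cov[[cn]]
      if (config$covariates[[cn]]$dist == "binomial") {
        val <- val * (1 + eff[[cn]] * x)
      } else {
        val <- val * (x / ref[[cn]])^eff[[cn]]
      }
    }
    sd <- config$iiv_sd[[pn]]
    if (!is.null(sd) && sd > 0) val <- val * stats::rlnorm(n, 0, sd)
    val
  })
  out <- data.frame(patient_id = seq_len(n), pars, Q = config$Q)
  cbind(out, as.data.frame(cov))
}

## two-compartment RHS (amounts in mg)
.rhs_2cpt <- function(t, y, p) {
  c1 <- y[[1]] / p$V1
  c2 <- y[[2]] / p$V2
  nl <- if (p$Vmax > 0) p$Vmax * c1 / (c1 + p$Km) else 0
  dA1 <- p$Q * (c2 - c1) - p$Cl * c1 - nl
  dA2 <- p$Q * (c1 - c2)
  list(c(dA1, dA2))
}

#' Simulate the two-compartment popPK model
#'
#' Integrates
#' `V1 d[A]1/dt = Q([A]2 - [A]1) - Cl [A]1 - Vmax [A]1 / ([A]1 + Km)` and
#' `V2 d[A]2/dt = Q([A]1 - [A]2)` with bolus doses into compartment 1, and
#' returns the central concentration.
#'
#' @param params One row of [generate_poppk_population()] output, or any
#'   list with `Cl`, `Vmax`, `Km`, `V1`, `V2`, `Q`.
#' @param regimen A [dose_regimen()]; weight-based dosing uses the
#'   patient's own `weight` column when `regimen$weight_kg` is `NULL`.
#' @param times Output times (days).
#' @return Data frame with `time` and central concentration `conc` (mg/L).
#' @export
simulate_2cpt <- function(params, regimen = dose_regimen(),
                          times = seq(0, 112, by = 0.5)) {
  p <- as.list(params)
  stopifnot(p$V1 > 0, p$V2 > 0, p$Q >= 0, p$Cl >= 0, p$Vmax >= 0)
  if (p$Vmax > 0 && p$Km <= 0) {
    stop("Km must be positive when Vmax > 0", call. = FALSE)
  }
  if (regimen$mode == "weight_based" && is.null(regimen$weight_kg)) {
    if (is.null(p$weight)) {
      stop("weight_based dosing requires a weight", call. = FALSE)
    }
    regimen$weight_kg <- p$weight
  }
  sched <- dose_schedule(regimen, max(times))
  sched <- sched[sched$amount_mg > 0, , drop = FALSE]
  events <- NULL
  if (nrow(sched)) {
    events <- data.frame(
      var = "A1", time = sched$time, value = sched$amount_mg, method = "add"
    )
  }
  out_times <- times
  if (!is.null(events)) out_times <- sort(unique(c(times, events$time)))
  out <- deSolve::ode(
    y = c(A1 = 0, A2 = 0), times = out_times, func = .rhs_2cpt, parms = p,
    method = "lsoda", rtol = 1e-8, atol = 1e-10,
    events = if (is.null(events)) NULL else list(data = events)
  )
  keep <- match(times, out[, "time"])
  data.frame(time = times, conc = out[keep, "A1"] / p$V1)
}

## seed the RNG for a generator stage (plain set.seed keeps the contract
## "identical config + seed => bit-identical output" simple and auditable)
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}
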