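#' Dosing regimen
#'
#' @param mode `"flat"` (amount in mg) or `"weight_based"` (amount in
#'   mg/kg, multiplied by `weight_kg` at administration).
#' @param amount Dose amount (mg or mg/kg); `0` is allowed and means sham
#'   (no-drug) dosing.
#' @param interval Days between doses (default 14, i.e. Q2W).
#' @param start First dose day (>= 0).
#' @param n_doses Number of doses; if `NULL`, doses continue to the
#'   simulation horizon.
#' @param weight_kg Body weight, required for `mode = "weight_based"`.
#' @return A `vp_regimen` object.
#' @export
dose_regimen <- function(mode = c("flat", "weight_based"), amount = 750,
                         interval = 14, start = 0, n_doses = NULL,
                         weight_kg = NULL) {
  mode <- match.arg(mode)
  if (amount < 0) stop("dose amount must be non-negative", call. = FALSE)
  if (interval <= 0) stop("dose interval must be positive", call. = FALSE)
  if (start < 0) stop("dose at t < 0 is not allowed", call. = FALSE)
  if (mode == "weight_based" && is.null(weight_kg)) {
    stop("weight_based dosing requires weight_kg", call. = FALSE)
  }
  structure(
    list(
      mode = mode, amount = amount, interval = interval,
      start = start, n_doses = n_doses, weight_kg = weight_kg
    ),
    class = "vp_regimen"
  )
}

#' Dose times and per-dose amounts (mg) of a regimen over a horizon
#' @param regimen A `vp_regimen` object.
#' @param horizon Simulation horizon (days).
#' @return Data frame with columns `time` (day) and `amount_mg`.
#' @export
dose_schedule <- function(regimen, horizon) {
  times <- seq(regimen$start, horizon, by = regimen$interval)
  if (!is.null(regimen$n_doses)) {
    times <- utils::head(times, regimen$n_doses)
  }
  amt <- if (regimen$mode == "flat") {
    regimen$amount
  } else {
    regimen$amount * regimen$weight_kg
  }
  data.frame(time = times, amount_mg = rep(amt, length(times)))
}

.integrate <- function(state, times, params, pk, constants,
                       events = NULL, root_target = NULL,
                       rtol = 1e-7,
                       compiled = getOption("vptrial.compiled", TRUE)) {
  args <- list(
    y = state, times = times,
    rtol = rtol, atol = .atol_vector(), maxsteps = 50000
  )
  if (compiled) {
    args$func <- "vptrial_derivs"
    args$initfunc <- "vptrial_initmod"
    args$dllname <- "vptrial"
    args$parms <- .pack_model_parms(
      params, pk, constants,
      root_target = if (is.null(root_target)) 0 else root_target
    )
    args$nout <- 1
    args$outnames <- "diameter"
    if (!is.null(root_target)) {
      args$rootfunc <- "vptrial_root"
      args$nroot <- 1
      args$method <- "lsodar"
    } else {
      args$method <- "lsoda"
    }
    if (!is.null(events)) {
      ev <- events
      ev$var <- match(ev$var, .state_names)
      args$events <- list(data = ev)
    }
  } else {
    args$func <- .rhs_desolve
    args$parms <- list(params = params, pk = pk, constants = constants)
    if (!is.null(root_target)) {
      args$rootfunc <- function(t, state, parms) {
        V <- assemble_tumor_volume(state, parms$constants)
        volume_to_diameter(V) - root_target
      }
      args$method <- "lsodar"
    } else {
      args$method <- "lsoda"
    }
    if (!is.null(events)) args$events <- list(data = events)
  }
  do.call(deSolve::ode, args)
}

#' Grow a patient's tumor from a single cell to its preset diameter
#'
#' Integrates the reduced model from one cancer cell until the tumor
#' diameter first crosses the patient's preset pre-treatment size
#' (`params$initial_tumour_size`), locating the crossing with the
#' integrator's root finder. The model state at the crossing is saved as
#' the patient's pre-treatment snapshot. Patients whose tumor never
#' reaches the preset size within `t_max` days (for example because the
#' immune response controls it) are reported as non-plausible.
#'
#' @param params A `vp_parameters` object.
#' @param pk A `vp_pk_parameters` object (no drug is present before
#'   treatment; these only parameterize the empty drug compartments).
#' @param constants A `vp_constants` object.
#' @param t_max Maximum growth time (days, default 7300 = 20 years).
#' @param patient_id Identifier stored in the snapshot.
#' @return A `vp_snapshot` object, or a `vp_non_plausible` object whose
#'   `$reason` is `"no_crossing"` or `"integrator_failure"`.
#' @export
run_to_pretreatment <- function(params, pk = qsp_pk_parameters(),
                                constants = model_constants(),
                                t_max = 7300, patient_id = NA) {
  stopifnot(t_max > 0)
  target <- params$initial_tumour_size
  if (target < constants$detection_floor) {
    stop("initial_tumour_size below the detection floor", call. = FALSE)
  }
  times <- seq(0, t_max, by = 25)
  out <- tryCatch(
    .integrate(initial_state(params), times, params, pk, constants,
      root_target = target
    ),
    error = function(e) e
  )
  if (inherits(out, "error")) {
    return(structure(
      list(patient_id = patient_id, reason = "integrator_failure",
        message = conditionMessage(out)),
      class = "vp_non_plausible"
    ))
  }
  t_end <- unname(out[nrow(out), 1])
  state <- out[nrow(out), .state_names]
  d_end <- volume_to_diameter(assemble_tumor_volume(state, constants))
  if (t_end >= t_max - 1e-8 || abs(d_end - target) > 1e-3) {
    return(structure(
      list(patient_id = patient_id, reason = "no_crossing",
        final_diameter = d_end),
      class = "vp_non_plausible"
    ))
  }
  make_snapshot(patient_id, params, state, t_end, constants)
}

#' @rdname run_to_pretreatment
#' @param x Object to test.
#' @return `is_plausible`: `TRUE` for a `vp_snapshot`.
#' @export
is_plausible <- function(x) inherits(x, "vp_snapshot")

#' Build a pre-treatment snapshot from a model state
#'
#' @param patient_id Identifier.
#' @param params A `vp_parameters` object.
#' @param state Named model state at treatment start.
#' @param time_to_preset Days from one cell to the preset diameter.
#' @param constants A `vp_constants` object.
#' @return A `vp_snapshot`: parameters, state, tumor diameter (cm),
#'   immune densities (cells/mL tumor), immune subset ratios, PD-L1
#'   expression fraction, and tumor-specific clone count (`tcc`).
#' @export
make_snapshot <- function(patient_id, params, state, time_to_preset,
                          constants = model_constants()) {
  V_mL <- assemble_tumor_volume(state, constants) * 1e-12
  dens <- c(
    CD8 = state[["T8_T"]] / V_mL,
    CD4 = state[["T4_T"]] / V_mL,
    Treg = state[["Treg_T"]] / V_mL,
    TAM = (state[["M1"]] + state[["M2"]]) / V_mL,
    MDSC = state[["MDSC"]] / V_mL
  )
  ratios <- c(
    CD8_Treg = unname(state[["T8_T"]] / state[["Treg_T"]]),
    CD8_CD4 = unname(state[["T8_T"]] / state[["T4_T"]]),
    M1_M2 = unname(state[["M1"]] / state[["M2"]])
  )
  structure(
    list(
      patient_id = patient_id,
      parameters = params,
      state = state,
      tumor_diameter = volume_to_diameter(V_mL * 1e12),
      densities = dens,
      ratios = ratios,
      pdl1_expression = pdl1_expression(state[["PDL1_avg"]], constants),
      tcc = params$n_T1_clones,
      time_to_preset = time_to_preset
    ),
    class = "vp_snapshot"
  )
}

#' Simulate treatment of one virtual patient
#'
#' Restarts the integration from a pre-treatment snapshot, applying bolus
#' doses into the central compartment at the regimen times, and records the
#' tumor diameter at every scheduled scan together with dense state and
#' serum-concentration series.
#'
#' @param snapshot A `vp_snapshot` from [run_to_pretreatment()].
#' @param pk A `vp_pk_parameters` object.
#' @param regimen A `vp_regimen` object, or `NULL` for no treatment.
#' @param horizon Days of follow-up (default 400); must cover the last
#'   scheduled measurement.
#' @param constants A `vp_constants` object.
#' @param measurement_times Scan days; defaults to
#'   [measurement_schedule()] over the horizon.
#' @param record_step Spacing of the dense state series (days).
#' @return A list with `trajectory` (a `vp_trajectory` data frame of scan
#'   times and diameters plus the baseline), `states` (dense deSolve
#'   matrix), and `concentration` (data frame of serum drug concentration,
#'   mg/L).
#' @export
simulate_treatment <- function(snapshot, pk = qsp_pk_parameters(),
                               regimen = dose_regimen(), horizon = 400,
                               constants = model_constants(),
                               measurement_times = NULL,
                               record_step = 1) {
  if (!inherits(snapshot, "vp_snapshot")) {
    stop("snapshot must be a vp_snapshot", call. = FALSE)
  }
  if (is.null(measurement_times)) {
    measurement_times <- measurement_schedule(horizon)
  }
  if (max(measurement_times) > horizon) {
    stop("horizon must cover the last scheduled measurement", call. = FALSE)
  }
  params <- snapshot$parameters
  times <- sort(unique(c(
    seq(0, horizon, by = record_step), measurement_times, horizon
  )))
  events <- NULL
  if (!is.null(regimen)) {
    sched <- dose_schedule(regimen, horizon)
    sched <- sched[sched$amount_mg > 0, , drop = FALSE]
    if (nrow(sched)) {
      dose_mol <- sched$amount_mg / 1e3 / params$MW_drug
      events <- data.frame(
        var = "A_C", time = sched$time, value = dose_mol, method = "add"
      )
      times <- sort(unique(c(times, sched$time)))
    }
  }
  out <- .integrate(snapshot$state, times, params, pk, constants,
    events = events
  )
  diam <- volume_to_diameter(apply(
    out[, .state_names, drop = FALSE], 1,
    assemble_tumor_volume,
    constants = constants
  ))
  scan_idx <- match(measurement_times, out[, 1])
  traj <- structure(
    data.frame(
      patient_id = rep(snapshot$patient_id, length(measurement_times)),
      time = measurement_times,
      diameter = diam[scan_idx]
    ),
    baseline = snapshot$tumor_diameter,
    class = c("vp_trajectory", "data.frame")
  )
  conc <- data.frame(
    time = out[, 1],
    conc_serum = out[, "A_C"] / pk$V_blood * params$MW_drug * 1e3 # mol/L -> mg/L
  )
  list(trajectory = traj, states = out, concentration = conc)
}
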