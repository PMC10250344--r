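# shared fixtures for the test suite (built in code, no stored data)

# closed-form logistic growth from C0 = 1 cell
logistic_cells <- function(t, k = 0.007, K = 1.5e11, C0 = 1) {
  K * C0 * exp(k * t) / (K + C0 * (exp(k * t) - 1))
}

# analytic inversion: time for logistic growth to reach C cells
logistic_time_to <- function(C, k = 0.007, K = 1.5e11, C0 = 1) {
  log(C * (K - C0) / (C0 * (K - C))) / k
}

# cells corresponding to an immune-free tumor of a given diameter
cells_for_diameter <- function(d_cm, constants = model_constants()) {
  diameter_to_volume(d_cm) * constants$V_e / constants$V_cell
}

# a handcrafted trajectory object for RECIST tests
make_traj <- function(diameters, baseline, times = NULL) {
  if (is.null(times)) times <- measurement_schedule(42 + 56 * length(diameters))[seq_along(diameters)]
  structure(
    data.frame(
      patient_id = rep(1L, length(diameters)),
      time = times[seq_along(diameters)],
      diameter = diameters
    ),
    baseline = baseline,
    class = c("vp_trajectory", "data.frame")
  )
}

# small, fast snapshot for treatment tests (default patient)
default_snapshot <- local({
  snap <- NULL
  function() {
    if (is.null(snap)) snap <<- run_to_pretreatment(patient_parameters(), patient_id = 1)
    snap
  }
})

# analytic biexponential solution of the linear two-compartment model
# (single bolus D into compartment 1 at t = 0)
# standard form: C1(t) = D/V1 * [ (alpha - k21)/(alpha - beta) e^{-alpha t}
#                               + (k21 - beta)/(alpha - beta) e^{-beta t} ]
biexp_2cpt <- function(t, D, Cl, V1, V2, Q) {
  k10 <- Cl / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  (D / V1) * ((alpha - k21) / (alpha - beta) * exp(-alpha * t) +
    (k21 - beta) / (alpha - beta) * exp(-beta * t))
}
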