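## drug-disposition submodel used for PK fitting: the four antibody
## compartments of the QSP model with the tumor frozen at a fixed diameter
.rhs_qsp_pk <- function(t, y, p) {
  pk <- p$pk
  conc_C <- y[[1]] / pk$V_blood
  conc_P <- y[[2]] / p$V_P_acc
  conc_T <- y[[3]] / p$V_T_acc
  conc_LN <- y[[4]] / p$V_LN_acc
  Q_P <- pk$k_filtration * 86400
  Q_T <- Q_P * p$V_T_L / p$V_per_tissue
  Q_LN <- Q_P * p$V_LN_L / p$V_per_tissue
  elim <- pk$Cl_lin * conc_C +
    if (conc_C > 0) p$Vmax_mol * conc_C / (conc_C + p$Km_mol) else 0
  f_P <- Q_P * (conc_C - conc_P)
  f_T <- Q_T * (conc_C - conc_T)
  f_LN <- Q_LN * (conc_C - conc_LN)
  list(c(-f_P - f_T - f_LN - elim, f_P, f_T, f_LN))
}

#' Serum drug concentration predicted by the QSP disposition submodel
#'
#' Simulates the four-compartment antibody disposition block of the QSP
#' model (central, peripheral, tumor, lymph node; linear plus
#' Michaelis-Menten elimination from central) with the tumor frozen at a
#' fixed diameter, and returns the serum concentration. This is the
#' forward simulator used by the compressed-latent PK fitting stage.
#'
#' @param pk A [qsp_pk_parameters()] object or named vector of the six
#'   parameters.
#' @param regimen A [dose_regimen()].
#' @param times Output times (days).
#' @param tumor_diameter Frozen tumor diameter (cm).
#' @param params `vp_parameters` supplying anatomy and drug constants.
#' @return Data frame with `time` and serum concentration `conc` (mg/L).
#' @export
qsp_pk_concentration <- function(pk, regimen = dose_regimen(),
                                 times = seq(0, 112, by = 0.5),
                                 tumor_diameter = 3.7,
                                 params = patient_parameters()) {
  if (!inherits(pk, "vp_pk_parameters")) {
    pk <- do.call(qsp_pk_parameters, as.list(pk))
  }
  V_T_L <- diameter_to_volume(tumor_diameter) * 1e-15
  p <- list(
    pk = pk,
    V_P_acc = params$V_per_tissue * pk$f_interstitial,
    V_T_acc = V_T_L * params$f_int_tumor,
    V_LN_acc = params$V_LN_total_mL * 1e-3 * pk$f_interstitial,
    V_T_L = V_T_L,
    V_LN_L = params$V_LN_total_mL * 1e-3,
    V_per_tissue = params$V_per_tissue,
    Vmax_mol = pk$Vmax_nl / (params$MW_drug * 1e3),
    Km_mol = pk$Km_nl / (params$MW_drug * 1e3)
  )
  sched <- dose_schedule(regimen, max(times))
  sched <- sched[sched$amount_mg > 0, , drop = FALSE]
  events <- NULL
  sim_times <- times
  if (nrow(sched)) {
    events <- data.frame(
      var = "A_C", time = sched$time,
      value = sched$amount_mg / 1e3 / params$MW_drug, method = "add"
    )
    sim_times <- sort(unique(c(times, sched$time)))
  }
  if (getOption("vptrial.compiled", TRUE)) {
    qparms <- c(
      pk$k_filtration, pk$V_blood, pk$Cl_lin, p$Vmax_mol, p$Km_mol,
      p$V_P_acc, p$V_T_acc, p$V_LN_acc,
      p$V_T_L / p$V_per_tissue, p$V_LN_L / p$V_per_tissue
    )
    if (!is.null(events)) events$var <- 1L
    out <- deSolve::ode(
      y = c(A_C = 0, A_P = 0, A_T = 0, A_LN = 0),
      times = sim_times, func = "vptrial_pk_derivs",
      initfunc = "vptrial_pk_initmod", dllname = "vptrial",
      parms = qparms,
      method = "lsoda", rtol = 1e-7, atol = 1e-14,
      events = if (is.null(events)) NULL else list(data = events)
    )
  } else {
    out <- deSolve::ode(
      y = c(A_C = 0, A_P = 0, A_T = 0, A_LN = 0),
      times = sim_times, func = .rhs_qsp_pk, parms = p,
      method = "lsoda", rtol = 1e-7, atol = 1e-14,
      events = if (is.null(events)) NULL else list(data = events)
    )
  }
  keep <- match(times, out[, "time"])
  data.frame(
    time = times,
    conc = out[keep, "A_C"] / pk$V_blood * params$MW_drug * 1e3
  )
}

.pk_names <- c(
  "k_filtration", "V_blood", "f_interstitial", "Cl_lin", "Vmax_nl", "Km_nl"
)

#' Default box bounds for the six drug-disposition parameters
#' @return List with `lower` and `upper` named vectors.
#' @export
default_pk_bounds <- function() {
  list(
    lower = c(
      k_filtration = 1e-6, V_blood = 3, f_interstitial = 0.03,
      Cl_lin = 0.05, Vmax_nl = 0.1, Km_nl = 0.05
    ),
    upper = c(
      k_filtration = 2e-5, V_blood = 9, f_interstitial = 0.12,
      Cl_lin = 0.6, Vmax_nl = 5, Km_nl = 2
    )
  )
}

.pk_simulator <- function(regimen, times, tumor_diameter, params,
                          log_scale = FALSE) {
  if (log_scale) {
    function(theta) {
      log(pmax(
        qsp_pk_concentration(theta, regimen, times, tumor_diameter, params)$conc,
        1e-6
      ))
    }
  } else {
    function(theta) {
      qsp_pk_concentration(theta, regimen, times, tumor_diameter, params)$conc
    }
  }
}

## residual function on log-theta for Levenberg-Marquardt; a simulator
## failure is penalized with large residuals so the candidate is rejected
.fit_residuals <- function(y, simulator, penalty_res = NULL) {
  function(log_theta) {
    theta <- stats::setNames(exp(log_theta), .pk_names)
    yhat <- tryCatch(simulator(theta), error = function(e) NULL)
    if (is.null(yhat) || any(!is.finite(yhat))) {
      return(rep(1e6, length(y)))
    }
    res <- y - yhat
    if (!is.null(penalty_res)) res <- c(res, penalty_res(theta))
    res
  }
}

#' Fit the group-average drug-disposition parameters
#'
#' Bounded least squares of the QSP disposition submodel against the
#' per-time median pseudo-patient concentration curve, with multi-start to
#' mitigate local minima. Optimization runs on the log scale of the
#' parameters.
#'
#' @param y_median Numeric vector: median concentration at each time.
#' @param simulator Function `theta -> concentration vector` on the same
#'   time grid (see [qsp_pk_concentration()]).
#' @param bounds List with `lower`/`upper` named vectors
#'   ([default_pk_bounds()]).
#' @param n_starts Number of optimizer starts (first at the log-midpoint,
#'   the rest random inside the box).
#' @param seed Integer seed for the random starts.
#' @return List: `theta_bar` (named vector), `residual` (RSS), and
#'   `starts` (per-start RSS).
#' @export
fit_group_average <- function(y_median, simulator,
                              bounds = default_pk_bounds(),
                              n_starts = 4, seed = 1) {
  lo <- log(bounds$lower[.pk_names])
  hi <- log(bounds$upper[.pk_names])
  if (all(lo == hi)) {
    th <- stats::setNames(exp(lo), .pk_names)
    return(list(theta_bar = th, residual = sum((y_median - simulator(th))^2),
      starts = numeric(0)))
  }
  local_seed(seed)
  fn <- .fit_residuals(y_median, simulator)
  starts <- rbind(
    (lo + hi) / 2,
    matrix(stats::runif((n_starts - 1) * length(lo), lo, hi),
      ncol = length(lo), byrow = FALSE
    )
  )
  best <- NULL
  start_rss <- numeric(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- minpack.lm::nls.lm(starts[s, ], lo, hi, fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    start_rss[s] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  list(
    theta_bar = stats::setNames(exp(best$par), .pk_names),
    residual = best$deviance,
    starts = start_rss
  )
}

#' Sensitivity-ordered orthonormal basis of the parameter space
#'
#' Generates `k` random local deviations around the group-average
#' parameters (log-scale, `scale` relative SD), simulates the
#' corresponding concentration changes, forms the covariance matrix
#' `C = Y_Theta %*% t(Theta)` between output and parameter deviations, and
#' returns its right singular vectors sorted by singular value.
#'
#' @param theta_bar Named group-average parameter vector.
#' @param simulator As in [fit_group_average()].
#' @param k Number of deviations (>= 6; 500 in the study design).
#' @param scale Relative (log-scale) perturbation SD (default 0.1).
#' @param seed Integer seed.
#' @return 6x6 orthonormal matrix `V` with singular values in attribute
#'   `singular_values`.
#' @export
latent_basis <- function(theta_bar, simulator, k = 500, scale = 0.1,
                         seed = 1) {
  stopifnot(k >= 6)
  local_seed(seed)
  th <- theta_bar[.pk_names]
  y0 <- simulator(th)
  Theta <- matrix(NA_real_, 6, k)
  Y <- matrix(NA_real_, length(y0), k)
  for (j in seq_len(k)) {
    pert <- th * exp(stats::rnorm(6, 0, scale))
    Theta[, j] <- pert - th
    Y[, j] <- simulator(pert) - y0
  }
  Theta <- Theta - rowMeans(Theta)
  Y <- Y - rowMeans(Y)
  C <- Y %*% t(Theta)
  sv <- svd(C, nu = 0, nv = 6) # full right basis even if C is short/rank deficient
  if (min(sv$d) < 1e-12 * max(sv$d)) {
    warning("covariance matrix is (near) rank deficient; ",
      "basis completed orthogonally by the SVD")
  }
  V <- sv$v
  rownames(V) <- .pk_names
  attr(V, "singular_values") <- sv$d
  V
}

#' Fit one patient's drug-disposition parameters with a latent L1 penalty
#'
#' Minimizes `||Y_i - Yhat(theta)||^2 + lambda * ||t(V) %*% (theta -
#' theta_bar)||_1` within bounds (the compressed-latent objective). The L1
#' term is smoothed with `sqrt(x^2 + eps)` for the quasi-Newton optimizer.
#'
#' @param y_i Patient concentration vector.
#' @param theta_bar Group-average parameters.
#' @param V Orthonormal basis from [latent_basis()].
#' @param lambda Penalty weight (>= 0).
#' @param simulator,bounds As in [fit_group_average()].
#' @return List: `theta` (named vector), `phi` (latent coordinates
#'   `t(V) %*% (theta - theta_bar)`), `objective`.
#' @export
fit_individual <- function(y_i, theta_bar, V, lambda, simulator,
                           bounds = default_pk_bounds()) {
  stopifnot(lambda >= 0)
  th_bar <- theta_bar[.pk_names]
  lo <- log(bounds$lower[.pk_names])
  hi <- log(bounds$upper[.pk_names])
  eps <- 1e-12
  ## encode the (smoothed) L1 latent penalty as extra residuals so the
  ## squared objective equals rss + lambda * sum |t(V)(theta - theta_bar)|
  penalty_res <- if (lambda > 0) {
    function(theta) {
      sqrt(lambda * sqrt(drop(crossprod(V, theta - th_bar))^2 + eps))
    }
  }
  fn <- .fit_residuals(y_i, simulator, penalty_res)
  fit <- minpack.lm::nls.lm(pmin(pmax(log(th_bar), lo), hi), lo, hi, fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  theta <- stats::setNames(exp(fit$par), .pk_names)
  list(
    theta = theta,
    phi = drop(crossprod(V, theta - th_bar)),
    objective = fit$deviance
  )
}

#' Assemble the latent parameter space from fitted individuals
#'
#' @param theta_matrix 6 x n matrix of fitted parameter sets (rows in the
#'   canonical order of [qsp_pk_parameters()]).
#' @param theta_bar Group-average parameters.
#' @param V Orthonormal basis.
#' @return A `vp_latent_space` with per-dimension empirical `phi_bounds`.
#' @export
latent_space <- function(theta_matrix, theta_bar, V) {
  stopifnot(nrow(theta_matrix) == 6)
  phi <- crossprod(V, theta_matrix - theta_bar[.pk_names])
  structure(
    list(
      theta_bar = theta_bar[.pk_names],
      V = V,
      phi = phi,
      phi_bounds = cbind(min = apply(phi, 1, min), max = apply(phi, 1, max)),
      theta_matrix = theta_matrix
    ),
    class = "vp_latent_space"
  )
}

#' Sample new drug-disposition parameter sets from the latent space
#'
#' Each latent coordinate is drawn uniformly within its empirical bounds
#' and mapped back via `theta = V %*% phi + theta_bar`. Draws violating
#' positivity or the interstitial-fraction range are rejected and redrawn
#' (at most 100 attempts each).
#'
#' @param space A [latent_space()].
#' @param n Number of parameter sets.
#' @param seed Integer seed.
#' @return List of `vp_pk_parameters`, with the 6 x n matrix in attribute
#'   `theta` and latent draws in attribute `phi`.
#' @export
sample_pk_parameters <- function(space, n, seed = 1) {
  local_seed(seed)
  lo <- space$phi_bounds[, "min"]
  hi <- space$phi_bounds[, "max"]
  th <- matrix(NA_real_, 6, n, dimnames = list(.pk_names, NULL))
  ph <- matrix(NA_real_, 6, n)
  for (k in seq_len(n)) {
    for (attempt in seq_len(100)) {
      phi <- stats::runif(6, lo, hi)
      theta <- drop(space$V %*% phi) + space$theta_bar
      ok <- all(theta > 0) && theta[["f_interstitial"]] < 1
      if (ok) break
    }
    if (!ok) {
      bad <- if (any(theta <= 0)) which(theta <= 0)[1] else which(.pk_names == "f_interstitial")
      stop("rejection sampling exhausted; offending dimension: ",
        .pk_names[bad],
        call. = FALSE
      )
    }
    th[, k] <- theta
    ph[, k] <- phi
  }
  out <- lapply(seq_len(n), function(k) do.call(qsp_pk_parameters, as.list(th[, k])))
  attr(out, "theta") <- th
  attr(out, "phi") <- ph
  out
}

#' Choose the latent penalty weight by held-out time points
#'
#' For each candidate `lambda`, fits a subset of pseudo-patients using 80%
#' of the time points and scores the residual on the held-out 20%; returns
#' the candidate minimizing the median held-out residual.
#'
#' @param curves Nt x n matrix of pseudo-patient concentrations.
#' @param times Time grid (days).
#' @param theta_bar,V,bounds As in [fit_individual()].
#' @param simulator_factory Function `times -> simulator` restricted to a
#'   time subset.
#' @param lambdas Candidate penalty weights.
#' @param n_patients Number of pseudo-patients scored per candidate.
#' @param seed Integer seed.
#' @return The selected `lambda`, with the score table in attribute
#'   `scores`.
#' @export
choose_lambda <- function(curves, times, theta_bar, V,
                          simulator_factory,
                          bounds = default_pk_bounds(),
                          lambdas = c(0, 1, 10, 100, 1000),
                          n_patients = 10, seed = 1) {
  local_seed(seed)
  n <- ncol(curves)
  pts <- sample.int(n, min(n_patients, n))
  hold <- seq(5, length(times), by = 5)
  train <- setdiff(seq_along(times), hold)
  sim_train <- simulator_factory(times[train])
  sim_hold <- simulator_factory(times[hold])
  scores <- sapply(lambdas, function(lam) {
    res <- vapply(pts, function(j) {
      fit <- fit_individual(
        curves[train, j], theta_bar, V, lam, sim_train, bounds
      )
      sum((curves[hold, j] - sim_hold(fit$theta))^2)
    }, numeric(1))
    stats::median(res)
  })
  out <- lambdas[which.min(scores)]
  attr(out, "scores") <- data.frame(lambda = lambdas, median_holdout = scores)
  out
}

#' Fit the whole pseudo-patient population and build the latent space
#'
#' Orchestrates the compressed-latent stage: group-average fit to the
#' median curve, sensitivity basis, per-patient penalized fits, latent
#' space assembly.
#'
#' @param curves Nt x n matrix of pseudo-patient serum concentrations.
#' @param times Time grid (days).
#' @param regimen Dosing regimen used to generate the curves.
#' @param lambda Latent L1 penalty weight.
#' @param k Number of basis deviations.
#' @param bounds Parameter box.
#' @param tumor_diameter,params Forwarded to the simulator.
#' @param n_starts,seed Optimizer settings.
#' @return A `vp_latent_space` with `theta_bar`, `V`, fitted
#'   `theta_matrix` and `phi_bounds`; group-average fit in attribute
#'   `group_fit`.
#' @export
fit_pk_population <- function(curves, times, regimen = dose_regimen(),
                              lambda = 0.1, k = 500,
                              bounds = default_pk_bounds(),
                              tumor_diameter = 3.7,
                              params = patient_parameters(),
                              n_starts = 4, seed = 1,
                              log_scale = TRUE) {
  ## concentrations are fitted on the log scale by default (proportional
  ## error), which keeps the terminal low-concentration phase informative
  ## and renders the Michaelis-Menten parameters identifiable
  simulator <- .pk_simulator(regimen, times, tumor_diameter, params,
    log_scale = log_scale
  )
  obs <- if (log_scale) log(pmax(curves, 1e-6)) else curves
  y_med <- apply(obs, 1, stats::median)
  grp <- fit_group_average(y_med, simulator, bounds, n_starts, seed)
  V <- latent_basis(grp$theta_bar, simulator, k = k, seed = seed + 1)
  th <- vapply(
    seq_len(ncol(obs)),
    function(j) {
      fit_individual(obs[, j], grp$theta_bar, V, lambda, simulator, bounds)$theta
    },
    numeric(6)
  )
  rownames(th) <- .pk_names
  sp <- latent_space(th, grp$theta_bar, V)
  attr(sp, "group_fit") <- grp
  sp
}
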