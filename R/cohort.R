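#' Specification of one varied patient parameter
#'
#' @param name Parameter name; must exist in [patient_parameters()].
#' @param dist One of `"uniform"`, `"log-uniform"`, `"log-normal"`.
#' @param min,max Bounds for (log-)uniform distributions; optional
#'   truncation bounds for log-normal.
#' @param meanlog,sdlog Log-scale mean and SD for `"log-normal"`.
#' @return A `vp_param_spec` list.
#' @export
param_spec <- function(name, dist = c("uniform", "log-uniform", "log-normal"),
                       min = NULL, max = NULL, meanlog = NULL, sdlog = NULL) {
  dist <- match.arg(dist)
  if (dist %in% c("uniform", "log-uniform")) {
    stopifnot(!is.null(min), !is.null(max), min < max)
    if (dist == "log-uniform") stopifnot(min > 0)
  } else {
    stopifnot(!is.null(meanlog), !is.null(sdlog), sdlog > 0)
    if (!is.null(min) || !is.null(max)) {
      stopifnot(!is.null(min), !is.null(max), min < max, min > 0)
    }
  }
  structure(
    list(name = name, dist = dist, min = min, max = max,
      meanlog = meanlog, sdlog = sdlog),
    class = "vp_param_spec"
  )
}

#' Map quantiles through a parameter spec's inverse CDF
#'
#' @param spec A [param_spec()].
#' @param u Quantiles in `[0, 1]`.
#' @return Parameter values on the spec's natural scale.
#' @export
param_spec_quantile <- function(spec, u) {
  if (any(u < 0 | u > 1)) stop("quantiles must lie in [0, 1]", call. = FALSE)
  switch(spec$dist,
    "uniform" = spec$min + u * (spec$max - spec$min),
    "log-uniform" = exp(log(spec$min) + u * (log(spec$max) - log(spec$min))),
    "log-normal" = {
      if (!is.null(spec$min)) {
        ## truncated log-normal: map u into the kept probability mass
        lo <- stats::plnorm(spec$min, spec$meanlog, spec$sdlog)
        hi <- stats::plnorm(spec$max, spec$meanlog, spec$sdlog)
        u <- lo + u * (hi - lo)
      }
      out <- stats::qlnorm(u, spec$meanlog, spec$sdlog)
      if (any(!is.finite(out))) {
        stop("quantile 0 or 1 for an unbounded log-normal parameter",
          call. = FALSE
        )
      }
      out
    }
  )
}

#' Default varied-parameter specifications for plausible patients
#'
#' The set of mechanistic parameters known to differ among patients, with
#' log-normal variation around the NSCLC baselines. The spreads are
#' package defaults (the study's original per-parameter statistics are not
#' public); the preset pre-treatment diameter is truncated to the 1.5-9.9
#' cm target-lesion range seen at NSCLC diagnosis.
#'
#' @return Named list of [param_spec()] objects.
#' @export
default_parameter_specs <- function() {
  ln <- function(name, median, sdlog, min = NULL, max = NULL) {
    param_spec(name, "log-normal",
      meanlog = log(median), sdlog = sdlog,
      min = min, max = max
    )
  }
  specs <- list(
    ln("k_growth", 0.007, 0.25),
    ln("initial_tumour_size", 3.7, 0.3, min = 1.5, max = 9.9),
    ln("n_T1_clones", 92, 0.45),
    ln("n_T0_clones", 100, 0.3),
    ln("k_P1_d1", 40, 0.4),
    ln("k_MDSC_rec", 2000, 0.5),
    ln("k_Mac_rec", 2e5, 0.5),
    ln("k_M1_pol", 0.02, 0.5),
    ln("T_PD1", 176, 0.3),
    ln("C_PDL1_base", 250, 0.3),
    ln("C_CD47", 100, 0.3),
    ln("k_T8_act", 1450, 0.4),
    ln("k_T4_act", 1200, 0.4),
    ln("k_Treg_act", 90, 0.4),
    ln("k_T8_kill", 0.08, 0.3)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Latin-hypercube sample of plausible-patient parameter sets
#'
#' Draws a stratified unit-hypercube sample (one point per row-stratum per
#' dimension) and maps it through each spec's inverse CDF; parameters not
#' listed in `specs` keep their baseline values.
#'
#' @param specs List of [param_spec()] objects.
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed.
#' @param baseline Baseline `vp_parameters` the varied values overwrite.
#' @return List of `vp_parameters`, with the sampled value matrix in
#'   attribute `values` and the unit-hypercube design in attribute
#'   `design`.
#' @export
lhs_sample <- function(specs, n, seed = 1,
                       baseline = patient_parameters()) {
  stopifnot(n >= 1, length(specs) >= 1)
  local_seed(seed)
  d <- length(specs)
  u <- lhs::randomLHS(n, d)
  vals <- vapply(
    seq_len(d),
    function(j) param_spec_quantile(specs[[j]], u[, j]),
    numeric(n)
  )
  vals <- matrix(vals, nrow = n)
  colnames(vals) <- vapply(specs, `[[`, "", "name")
  out <- lapply(seq_len(n), function(k) {
    ov <- as.list(vals[k, ])
    do.call(patient_parameters, utils::modifyList(
      unclass(baseline), ov
    ))
  })
  attr(out, "values") <- vals
  attr(out, "design") <- u
  out
}

#' k-nearest-neighbor density estimate
#'
#' For each query point `r`, estimates the density as
#' `rho(r) = N / (m * V_d(R_N(r)))`, where `R_N(r)` is the Euclidean
#' distance from `r` to its N-th nearest sample point,
#' `V_d(R) = pi^(d/2) R^d / Gamma(d/2 + 1)` is the d-dimensional
#' hypersphere volume, and `m` is the number of sample points. Dividing by
#' `m` normalizes the estimate to integrate to ~1; in the inclusion-
#' probability ratio this constant is absorbed by `beta`.
#'
#' @param points Numeric matrix of sample points (rows).
#' @param queries Numeric matrix of query points; defaults to `points`
#'   with self-exclusion.
#' @param N Neighbor order (1 <= N < number of usable points).
#' @param exclude_self If `TRUE`, `queries` must be `points` and each
#'   point's own row is excluded from its neighbor search.
#' @return Density estimate per query row.
#' @export
knn_density <- function(points, queries = points, N = 8,
                        exclude_self = missing(queries)) {
  exclude_self <- exclude_self # force before `queries` is touched
  points <- as.matrix(points)
  queries <- as.matrix(queries)
  if (ncol(points) != ncol(queries)) {
    stop("points and queries must have the same dimension", call. = FALSE)
  }
  m <- nrow(points)
  if (exclude_self && nrow(queries) != m) {
    stop("exclude_self requires queries to be the sample points themselves",
      call. = FALSE
    )
  }
  usable <- m - as.integer(exclude_self)
  if (N < 1 || N > usable - 0) stop("need 1 <= N < number of points", call. = FALSE)
  d <- ncol(points)
  pt_sq <- rowSums(points^2)
  RN <- numeric(nrow(queries))
  block <- 512L
  for (start in seq(1, nrow(queries), by = block)) {
    idx <- start:min(start + block - 1, nrow(queries))
    q <- queries[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), pt_sq, "+") - 2 * tcrossprod(q, points)
    d2[d2 < 0] <- 0
    if (exclude_self) {
      d2[cbind(seq_along(idx), idx)] <- Inf
    } else {
      ## a query that coincides with a sample point is that point's own
      ## image: drop one exact match (further duplicates still raise)
      for (r in seq_along(idx)) {
        z <- which(d2[r, ] == 0)
        if (length(z)) d2[r, z[1]] <- Inf
      }
    }
    RN[idx] <- apply(d2, 1, function(v) sqrt(sort(v, partial = N)[N]))
  }
  if (any(RN == 0)) {
    stop("degenerate distances: >= N duplicate points at a query",
      call. = FALSE
    )
  }
  V <- pi^(d / 2) * RN^d / gamma(d / 2 + 1)
  N / (m * V)
}

#' Build the probability-of-inclusion selection model
#'
#' Precomputes, at every plausible patient's ln-ratio triplet, the
#' kNN density of the observed data and of the plausible pool; the ratio
#' drives the inclusion probability `p_i = min(1, beta *
#' rho_obs(r_i) / rho_sim(r_i))`.
#'
#' @param observed Matrix of ln-ratio rows from the observed cohort.
#' @param simulated Matrix of ln-ratio rows from the plausible patients.
#' @param N Neighbor order (5-10 is typical; default 8).
#' @param beta Scale constant.
#' @return A `vp_selection_model` list with the density ratio cached.
#' @export
selection_model <- function(observed, simulated, N = 8, beta = 1) {
  observed <- as.matrix(observed)
  simulated <- as.matrix(simulated)
  if (!nrow(observed) || !nrow(simulated)) {
    stop("observed and simulated matrices must be non-empty", call. = FALSE)
  }
  if (ncol(observed) != ncol(simulated)) {
    stop("observed and simulated must have the same dimension", call. = FALSE)
  }
  if (N >= min(nrow(observed), nrow(simulated))) {
    stop("N must be smaller than both sample sizes", call. = FALSE)
  }
  rho_obs <- knn_density(observed, simulated, N = N, exclude_self = FALSE)
  rho_sim <- knn_density(simulated, N = N)
  structure(
    list(
      observed = observed, simulated = simulated, N = N, beta = beta,
      rho_obs = rho_obs, rho_sim = rho_sim,
      ratio = rho_obs / rho_sim
    ),
    class = "vp_selection_model"
  )
}

#' @rdname selection_model
#' @param model A `vp_selection_model`.
#' @return `inclusion_probabilities`: per-patient probability vector.
#' @export
inclusion_probabilities <- function(model, beta = model$beta) {
  if (any(!is.finite(model$ratio))) {
    stop("degenerate density estimates in selection model", call. = FALSE)
  }
  pmin(1, beta * model$ratio)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the D statistic and
#' the asymptotic p-value (ties tolerated silently).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Optimize the inclusion-probability scale by simulated annealing
#'
#' Minimizes the mean (over the three ln-ratio dimensions) two-sample KS
#' statistic between the observed data and a seeded Bernoulli realization
#' of the cohort selected at candidate `beta`. Candidates whose expected
#' cohort size falls below `min_cohort` are rejected. `beta` is explored
#' on the log scale; the starting value is capped so the maximal pre-clip
#' probability is 1.
#'
#' @param model A [selection_model()].
#' @param config List: `n_iter` (annealing steps; 0 returns the initial
#'   beta), `temp0` initial temperature, `cooling` geometric factor,
#'   `step` SD of the log-beta proposal, `min_cohort` minimum expected
#'   cohort size, `beta_init` optional starting value.
#' @param seed Integer seed for the proposal chain and the per-run
#'   selection realization.
#' @return List: `beta_star`, `objective` (mean KS D), `ks` per-dimension
#'   statistics at the optimum, `trace` of accepted values.
#' @export
optimize_beta <- function(model,
                          config = list(),
                          seed = 1) {
  cfg <- utils::modifyList(
    list(
      n_iter = 150, temp0 = 0.1, cooling = 0.95, step = 0.5,
      min_cohort = 50, beta_init = NULL
    ),
    config
  )
  ratio <- model$ratio
  n_sim <- length(ratio)
  if (cfg$min_cohort > n_sim) {
    stop("infeasible: pool smaller than the minimum cohort size", call. = FALSE)
  }
  local_seed(seed)
  u_sel <- stats::runif(n_sim) # one selection realization shared across candidates
  ks_at <- function(sel) {
    mean(vapply(
      seq_len(ncol(model$observed)),
      function(j) {
        ks_two_sample(model$observed[, j], model$simulated[sel, j])$statistic
      },
      numeric(1)
    ))
  }
  objective <- function(beta) {
    p <- pmin(1, beta * ratio)
    if (sum(p) < cfg$min_cohort) return(Inf)
    sel <- u_sel < p
    if (sum(sel) < 2) return(Inf)
    ks_at(sel)
  }
  beta_cap <- 1 / max(ratio)
  beta <- if (is.null(cfg$beta_init)) beta_cap else min(cfg$beta_init, beta_cap)
  ## lift beta until the expected cohort is feasible
  while (sum(pmin(1, beta * ratio)) < cfg$min_cohort && beta < 1e12) {
    beta <- beta * 1.5
  }
  f <- objective(beta)
  if (!is.finite(f)) {
    stop("infeasible: no beta achieves the minimum expected cohort size",
      call. = FALSE
    )
  }
  best <- list(beta = beta, f = f)
  temp <- cfg$temp0
  trace <- numeric(0)
  if (cfg$n_iter > 0) {
    for (it in seq_len(cfg$n_iter)) {
      cand <- beta * exp(stats::rnorm(1, 0, cfg$step))
      fc <- objective(cand)
      if (is.finite(fc) &&
        (fc <= f || stats::runif(1) < exp(-(fc - f) / temp))) {
        beta <- cand
        f <- fc
        if (f < best$f) best <- list(beta = beta, f = f)
      }
      temp <- temp * cfg$cooling
      trace[it] <- beta
    }
  }
  p <- pmin(1, best$beta * ratio)
  sel <- u_sel < p
  ks <- vapply(
    seq_len(ncol(model$observed)),
    function(j) ks_two_sample(model$observed[, j], model$simulated[sel, j])$statistic,
    numeric(1)
  )
  list(beta_star = best$beta, objective = best$f, ks = ks, trace = trace)
}

#' Draw the virtual cohort from inclusion probabilities
#'
#' Independent Bernoulli retention per plausible patient.
#'
#' @param probabilities Vector of inclusion probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Sorted integer indices of the selected patients, with the
#'   probabilities in attribute `probabilities`.
#' @export
select_cohort <- function(probabilities, seed = 1) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  local_seed(seed)
  sel <- which(stats::runif(length(probabilities)) < probabilities)
  if (!length(sel)) warning("empty cohort: all patients rejected")
  structure(sort(sel), probabilities = probabilities)
}

#' Extract the ln-ratio matrix from a list of snapshots
#'
#' @param snapshots List of `vp_snapshot` objects.
#' @return Matrix with columns `M1_M2`, `CD8_Treg`, `CD8_CD4` of natural-
#'   log ratios; rows with non-finite ratios are dropped (attribute
#'   `kept` holds the surviving snapshot indices).
#' @export
snapshot_log_ratios <- function(snapshots) {
  m <- t(vapply(
    snapshots,
    function(s) c(s$ratios[["M1_M2"]], s$ratios[["CD8_Treg"]], s$ratios[["CD8_CD4"]]),
    numeric(3)
  ))
  colnames(m) <- c("M1_M2", "CD8_Treg", "CD8_CD4")
  keep <- apply(m, 1, function(r) all(is.finite(r) & r > 0))
  out <- log(m[keep, , drop = FALSE])
  attr(out, "kept") <- which(keep)
  out
}

#' Generate plausible patients by LHS and pre-treatment simulation
#'
#' Samples parameter sets with [lhs_sample()] and grows each tumor to its
#' preset diameter with [run_to_pretreatment()]; patients that never reach
#' it are excluded and counted.
#'
#' @param n Number of parameter sets to draw.
#' @param specs Varied-parameter specs ([default_parameter_specs()]).
#' @param seed Integer seed.
#' @param pk,constants,t_max Forwarded to [run_to_pretreatment()].
#' @return List: `snapshots` (plausible patients), `n_non_plausible`,
#'   `reasons` (table of exclusion reasons).
#' @export
generate_plausible_patients <- function(n, specs = default_parameter_specs(),
                                        seed = 1,
                                        pk = qsp_pk_parameters(),
                                        constants = model_constants(),
                                        t_max = 7300) {
  params <- lhs_sample(specs, n, seed = seed)
  res <- vector("list", n)
  for (k in seq_len(n)) {
    res[[k]] <- run_to_pretreatment(params[[k]],
      pk = pk, constants = constants,
      t_max = t_max, patient_id = k
    )
  }
  ok <- vapply(res, is_plausible, logical(1))
  reasons <- vapply(
    res[!ok], function(x) x$reason, character(1)
  )
  list(
    snapshots = res[ok],
    n_non_plausible = sum(!ok),
    reasons = table(reasons)
  )
}

#' Select the virtual cohort matching an observed immune-ratio table
#'
#' End-to-end selection stage: clean and log-transform the observed table,
#' build the kNN selection model against the plausible snapshots, optimize
#' `beta` by simulated annealing, and draw the Bernoulli cohort.
#'
#' @param observed Data frame with the three ratio columns (zeros allowed;
#'   removed here).
#' @param snapshots Plausible-patient snapshots.
#' @param N Neighbor order.
#' @param annealing Config list for [optimize_beta()].
#' @param seed Integer seed.
#' @return List: `cohort` (snapshots of selected patients), `indices`,
#'   `beta_star`, `ks` (per-dimension D at the optimum), `probabilities`.
#' @export
select_virtual_cohort <- function(observed, snapshots, N = 8,
                                  annealing = list(), seed = 1) {
  obs_ln <- clean_and_log_transform(observed)
  sim_ln <- snapshot_log_ratios(snapshots)
  kept <- attr(sim_ln, "kept")
  model <- selection_model(obs_ln, sim_ln, N = N)
  opt <- optimize_beta(model, config = annealing, seed = seed)
  probs <- inclusion_probabilities(model, opt$beta_star)
  idx_local <- select_cohort(probs, seed = seed + 1)
  idx <- kept[idx_local]
  list(
    cohort = snapshots[idx],
    indices = idx,
    beta_star = opt$beta_star,
    ks = opt$ks,
    probabilities = probs
  )
}
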