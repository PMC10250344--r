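#' Build Morris elementary-effect trajectories on the unit hypercube
#'
#' Generates random one-at-a-time trajectories on a `levels`-point grid
#' in `[0,1]^d`: a random grid base point, a random coordinate order and
#' random +/- `delta` steps. Trajectories with any point outside the
#' hypercube are discarded, as are trajectories containing a 0 or 1
#' coordinate for a parameter with an (untruncated) log-normal
#' distribution, whose quantile transform would be unbounded there.
#'
#' @param specs Named list of [param_spec()] objects (defines `d` and
#'   which coordinates are log-normal).
#' @param n_requested Number of random trajectories to generate before
#'   filtering (1000 in the study design).
#' @param levels Grid levels (default 11, i.e. quantiles 0, 0.1, ..., 1).
#' @param delta Step size (default 1/10; must be a multiple of the grid
#'   spacing).
#' @param seed Integer seed.
#' @return A `vp_morris_design`: list with `trajectories` (each a
#'   `(d+1) x d` matrix), `d`, `levels`, `delta`, `n_requested`,
#'   `n_accepted`, `specs`.
#' @export
build_trajectories <- function(specs, n_requested = 1000, levels = 11,
                               delta = 1 / 10, seed = 1) {
  stopifnot(levels >= 2, n_requested >= 1)
  spacing <- 1 / (levels - 1)
  if (abs(delta / spacing - round(delta / spacing)) > 1e-9) {
    stop("delta must be a multiple of the grid spacing", call. = FALSE)
  }
  d <- length(specs)
  lognormal_unbounded <- vapply(
    specs,
    function(s) s$dist == "log-normal" && is.null(s$min),
    logical(1)
  )
  local_seed(seed)
  grid <- seq(0, 1, by = spacing)
  keep <- list()
  for (tr in seq_len(n_requested)) {
    base <- grid[sample.int(levels, d, replace = TRUE)]
    ord <- sample.int(d)
    sgn <- sample(c(-1, 1), d, replace = TRUE)
    pts <- matrix(NA_real_, d + 1, d)
    pts[1, ] <- base
    x <- base
    for (s in seq_len(d)) {
      x[ord[s]] <- x[ord[s]] + sgn[s] * delta
      pts[s + 1, ] <- x
    }
    if (any(pts < -1e-12 | pts > 1 + 1e-12)) next
    pts <- pmin(pmax(pts, 0), 1)
    boundary <- pts[, lognormal_unbounded, drop = FALSE]
    if (length(boundary) && any(boundary <= 1e-12 | boundary >= 1 - 1e-12)) next
    keep[[length(keep) + 1]] <- structure(pts, order = ord, sign = sgn)
  }
  if (!length(keep)) {
    stop("no trajectory survived filtering; request more trajectories",
      call. = FALSE
    )
  }
  structure(
    list(
      trajectories = keep, d = d, levels = levels, delta = delta,
      n_requested = n_requested, n_accepted = length(keep), specs = specs
    ),
    class = "vp_morris_design"
  )
}

#' Map a unit-hypercube point to parameter values
#'
#' Treats each coordinate as a quantile of the corresponding parameter's
#' distribution and applies the inverse CDF.
#'
#' @param u Numeric vector (or matrix of row points) in `[0,1]^d`.
#' @param specs Named list of [param_spec()] objects, one per coordinate.
#' @return Vector (or matrix) of parameter values.
#' @export
quantile_transform <- function(u, specs) {
  if (is.matrix(u)) {
    out <- vapply(
      seq_len(ncol(u)),
      function(j) param_spec_quantile(specs[[j]], u[, j]),
      numeric(nrow(u))
    )
    out <- matrix(out, nrow = nrow(u))
    colnames(out) <- names(specs)
    return(out)
  }
  stats::setNames(
    vapply(
      seq_along(u),
      function(j) param_spec_quantile(specs[[j]], u[j]),
      numeric(1)
    ),
    names(specs)
  )
}

#' Elementary effects from trajectory outputs
#'
#' For every trajectory step that changes coordinate `i` by `+/- delta`,
#' the elementary effect is `EE_i = (y_after - y_before) / (+/- delta)`;
#' `mu_star` is the mean absolute EE and `sigma2` the variance of the EEs
#' per parameter across trajectories. Trajectories with any non-finite
#' output are dropped with a warning.
#'
#' @param outputs List (one element per trajectory) of numeric vectors of
#'   length `d + 1`: the model output at each trajectory point.
#' @param design A `vp_morris_design` from [build_trajectories()].
#' @return A `vp_morris_result` data frame: `parameter`, `mu_star`,
#'   `sigma2`, `n_effects`, with the raw effects in attribute `effects`.
#' @export
elementary_effects <- function(outputs, design) {
  stopifnot(length(outputs) == length(design$trajectories))
  d <- design$d
  ee <- vector("list", d)
  dropped <- 0
  for (k in seq_along(outputs)) {
    y <- outputs[[k]]
    if (length(y) != d + 1) {
      stop("one output per trajectory point required", call. = FALSE)
    }
    if (any(!is.finite(y))) {
      dropped <- dropped + 1
      next
    }
    tr <- design$trajectories[[k]]
    ord <- attr(tr, "order")
    sgn <- attr(tr, "sign")
    for (s in seq_len(d)) {
      i <- ord[s]
      ee[[i]] <- c(ee[[i]], (y[s + 1] - y[s]) / (sgn[s] * design$delta))
    }
  }
  if (dropped > 0) {
    warning(dropped, " trajectory(ies) dropped due to non-finite outputs")
  }
  res <- data.frame(
    parameter = names(design$specs),
    mu_star = vapply(ee, function(e) if (length(e)) mean(abs(e)) else NA_real_, numeric(1)),
    sigma2 = vapply(
      ee,
      function(e) if (length(e) > 1) stats::var(e) else 0,
      numeric(1)
    ),
    n_effects = vapply(ee, length, integer(1))
  )
  attr(res, "effects") <- ee
  class(res) <- c("vp_morris_result", "data.frame")
  res
}

#' Morris screening of the tumor-immune model
#'
#' End-to-end elementary-effects screening: builds and filters
#' trajectories, maps points through the parameter distributions, runs the
#' model (pre-treatment growth followed by treatment) for each point, and
#' summarizes `mu_star` / `sigma2` on the configured observable (tumor
#' diameter at the end of treatment by default).
#'
#' @param specs Named list of [param_spec()] objects over mechanistic
#'   (and, via `pk_specs`, drug-disposition) parameters.
#' @param n_requested,levels,delta,seed Design settings
#'   ([build_trajectories()]).
#' @param regimen,horizon Treatment settings.
#' @param pk Baseline `vp_pk_parameters` (overridden per point by any
#'   spec named after a PK parameter).
#' @param constants A `vp_constants`.
#' @param t_max Pre-treatment growth cap (days).
#' @return List: `result` (a `vp_morris_result`), `design`,
#'   `n_non_plausible` (trajectory points whose tumor never reached its
#'   preset size; their outputs are non-finite and the trajectory is
#'   dropped).
#' @export
morris_screen <- function(specs, n_requested = 100, levels = 11,
                          delta = 1 / 10, seed = 1,
                          regimen = dose_regimen(), horizon = 400,
                          pk = qsp_pk_parameters(),
                          constants = model_constants(), t_max = 7300) {
  design <- build_trajectories(specs, n_requested, levels, delta, seed)
  pk_names <- .pk_names
  n_bad <- 0
  outputs <- lapply(design$trajectories, function(tr) {
    apply(tr, 1, function(u) {
      vals <- quantile_transform(u, specs)
      mech <- vals[setdiff(names(vals), pk_names)]
      pkv <- unclass(pk)
      pkv[intersect(names(vals), pk_names)] <-
        vals[intersect(names(vals), pk_names)]
      pars <- do.call(patient_parameters, as.list(mech))
      pk_i <- do.call(qsp_pk_parameters, pkv[pk_names])
      snap <- run_to_pretreatment(pars, pk_i, constants, t_max = t_max)
      if (!is_plausible(snap)) {
        n_bad <<- n_bad + 1
        return(NA_real_)
      }
      sim <- simulate_treatment(snap, pk_i, regimen, horizon,
        constants = constants,
        measurement_times = horizon, record_step = horizon
      )
      sim$trajectory$diameter[nrow(sim$trajectory)]
    })
  })
  list(
    result = elementary_effects(outputs, design),
    design = design,
    n_non_plausible = n_bad
  )
}
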