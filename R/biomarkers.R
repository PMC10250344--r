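#' Per-patient biomarker table for responder analyses
#'
#' @param cohort List of `vp_snapshot` objects.
#' @param records Matched list of `vp_response` objects.
#' @return Data frame: densities (cells/mL), immune subset ratios, PD-L1
#'   expression, tumor-specific clone count (`tcc`) and the responder
#'   flag.
#' @export
biomarker_table <- function(cohort, records) {
  stopifnot(length(cohort) == length(records))
  d <- t(vapply(cohort, `[[`, numeric(5), "densities"))
  r <- t(vapply(cohort, `[[`, numeric(3), "ratios"))
  data.frame(
    patient_id = vapply(cohort, function(s) as.integer(s$patient_id), integer(1)),
    d, r,
    pdl1_expression = vapply(cohort, `[[`, numeric(1), "pdl1_expression"),
    tcc = vapply(cohort, `[[`, numeric(1), "tcc"),
    responder = vapply(records, `[[`, logical(1), "responder"),
    best_response = vapply(records, `[[`, character(1), "best_response")
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two groups: exact enumeration for small
#' samples (combined n <= 12, no ties), normal approximation with tie
#' correction otherwise.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  if (length(unique(c(a, b))) == 1) {
    warning("all values identical across both groups; p = 1")
    return(1)
  }
  exact <- (length(a) + length(b)) <= 12 && !any(duplicated(c(a, b)))
  suppressWarnings(
    stats::wilcox.test(a, b,
      exact = exact, correct = !exact,
      alternative = "two.sided"
    )$p.value
  )
}

#' Quintile response table
#'
#' Sorts patients by a biomarker in ascending order, splits them into 5
#' contiguous groups of size `floor(n/5)` with the remainder given to the
#' first groups, and reports each group's median biomarker value and
#' response fractions.
#'
#' @param values Biomarker values (one per patient, >= 5 patients).
#' @param records Matched list of `vp_response` objects.
#' @return Data frame with 5 rows: `median_value`, `n`, `orr`, `dcr`,
#'   `pd_rate`.
#' @export
quintile_response <- function(values, records) {
  n <- length(values)
  if (n < 5) stop("at least 5 patients required", call. = FALSE)
  stopifnot(length(records) == n)
  ord <- order(values)
  sizes <- rep(floor(n / 5), 5)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  resp <- vapply(records, `[[`, logical(1), "responder")[ord]
  best <- vapply(records, `[[`, character(1), "best_response")[ord]
  v <- values[ord]
  stops <- cumsum(sizes)
  starts <- c(1, utils::head(stops, -1) + 1)
  out <- t(vapply(seq_len(5), function(g) {
    idx <- starts[g]:stops[g]
    c(
      median_value = stats::median(v[idx]),
      n = length(idx),
      orr = mean(resp[idx]),
      dcr = mean(resp[idx] | best[idx] == "SD"),
      pd_rate = mean(best[idx] == "PD")
    )
  }, numeric(5)))
  as.data.frame(out)
}

#' Random-forest variable importance for response prediction
#'
#' Trains an ensemble of classification trees (default 500), each on a
#' random two-thirds subsample drawn without replacement, and reports the
#' permutation importance (mean decrease in out-of-bag accuracy) per
#' feature together with the ensemble out-of-bag error.
#'
#' @param features Data frame or matrix of numeric predictors.
#' @param labels Binary outcome (logical or factor with 2 levels).
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @return List: `importance` (named vector, mean decrease in accuracy),
#'   `importance_sd`, `oob_error`, and the fitted `model`.
#' @export
rf_importance <- function(features, labels, n_trees = 500, seed = 1) {
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("at least 2 features required", call. = FALSE)
  y <- factor(labels)
  if (nlevels(y) != 2) stop("both classes must be present", call. = FALSE)
  local_seed(seed)
  n <- nrow(features)
  fit <- randomForest::randomForest(
    x = features, y = y,
    ntree = n_trees,
    replace = FALSE, sampsize = floor(2 * n / 3),
    importance = TRUE
  )
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  list(
    importance = imp,
    importance_sd = fit$importanceSD[, "MeanDecreaseAccuracy"],
    oob_error = unname(fit$err.rate[n_trees, "OOB"]),
    model = fit
  )
}

#' ROC analysis with threshold selection at a target sensitivity
#'
#' Computes the empirical ROC curve (score >= threshold predicts
#' responder), the trapezoid area under it, and the largest threshold
#' whose sensitivity reaches the target.
#'
#' @param scores Numeric biomarker scores (larger = more responder-like;
#'   negate a biomarker whose low values predict response).
#' @param labels Binary outcome (TRUE/1 = responder).
#' @param target_sens Target sensitivity in (0, 1].
#' @return List: `threshold`, `sensitivity` and `specificity` attained at
#'   it, `auroc`, and the full `roc` data frame.
#' @export
roc_at_sensitivity <- function(scores, labels, target_sens = 0.8) {
  lab <- as.logical(labels)
  if (!any(lab) || all(lab)) stop("both classes must be present", call. = FALSE)
  if (target_sens <= 0 || target_sens > 1) {
    stop("target_sens must lie in (0, 1]", call. = FALSE)
  }
  if (length(unique(scores)) == 1) {
    warning("degenerate scores (all equal): auROC 0.5, threshold undefined")
    return(list(
      threshold = NA_real_, sensitivity = NA_real_,
      specificity = NA_real_, auroc = 0.5, roc = NULL
    ))
  }
  cuts <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cuts, function(c) mean(scores[lab] >= c), numeric(1))
  spec <- vapply(cuts, function(c) mean(scores[!lab] < c), numeric(1))
  ## trapezoid over (FPR, TPR) with the (0,0) and (1,1) endpoints
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  ok <- which(sens >= target_sens)
  i <- ok[1] # largest cut reaching the target (cuts are decreasing)
  list(
    threshold = cuts[i],
    sensitivity = sens[i],
    specificity = spec[i],
    auroc = auroc,
    roc = data.frame(threshold = cuts, sensitivity = sens, specificity = spec)
  )
}

#' Convert a volumetric immune cell density to an areal (section) density
#'
#' Digital pathology reports cells per mm^2 of a stained section; the
#' model predicts cells per mL of tumor. A linear effective-thickness
#' model converts between them:
#' `cells/mm^2 = (cells/mL / 1000 mm^3/mL) * t_eff`, with the effective
#' thickness defaulting to the slide thickness plus the mean cell
#' diameter (0.004 + 0.00694 mm). This is a declared surrogate for
#' stereological conversion formulas.
#'
#' @param rho3d Density in cells/mL (>= 0).
#' @param t_eff Effective section thickness (mm, > 0).
#' @return Density in cells/mm^2.
#' @export
density_3d_to_2d <- function(rho3d, t_eff = 0.004 + 0.00694) {
  if (t_eff <= 0) stop("t_eff must be positive", call. = FALSE)
  if (any(rho3d < 0)) stop("rho3d must be non-negative", call. = FALSE)
  rho3d / 1000 * t_eff
}

#' @rdname density_3d_to_2d
#' @param rho2d Density in cells/mm^2.
#' @return `density_2d_to_3d`: density in cells/mL.
#' @export
density_2d_to_3d <- function(rho2d, t_eff = 0.004 + 0.00694) {
  if (t_eff <= 0) stop("t_eff must be positive", call. = FALSE)
  rho2d * 1000 / t_eff
}

#' Spearman correlation matrix of a biomarker panel
#'
#' Rank-based correlations (robust to the log-scale spread of immune
#' densities); constant columns give NA rows/columns.
#'
#' @param features Data frame or matrix with >= 2 numeric columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(features) {
  m <- as.matrix(features)
  if (ncol(m) < 2) stop("at least 2 features required", call. = FALSE)
  suppressWarnings(stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
}
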