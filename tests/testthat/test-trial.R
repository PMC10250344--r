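test_that("the scan schedule is 6, 12, 16 weeks then every 8 weeks", {
  expect_equal(measurement_schedule(120), c(42, 84, 112))
  expect_equal(
    measurement_schedule(400),
    c(42, 84, 112, 168, 224, 280, 336, 392)
  )
  expect_equal(measurement_schedule(42), 42)
  expect_error(measurement_schedule(41), "first scan")
})

test_that("handcrafted trajectories classify as PR, PD, SD and CR", {
  # >= 30% decrease from baseline at the first scan
  pr <- classify_recist(make_traj(c(3.4, 3.2, 3.0), baseline = 5))
  expect_identical(pr$best_response, "PR")
  expect_true(pr$responder)
  expect_equal(pr$best_change, 3.0 / 5 - 1)
  expect_equal(pr$time_of_response, 42)

  # >= 20% and >= 0.5 cm above the nadir at the first scan
  pd <- classify_recist(make_traj(c(6.1, 6.5), baseline = 5))
  expect_identical(pd$best_response, "PD")
  expect_false(pd$responder)
  expect_equal(pd$time_of_progression, 42)

  # the nadir rule fires on later scans too (both conditions needed)
  late <- classify_recist(make_traj(c(5.0, 6.1), baseline = 5))
  expect_identical(late$scans$response, c("SD", "PD"))
  expect_identical(late$best_response, "SD") # SD achieved before progression

  # no meaningful change through week 16
  sd <- classify_recist(make_traj(c(5.0, 5.0, 5.0), baseline = 5))
  expect_identical(sd$best_response, "SD")

  # disappearance below the detection floor
  cr <- classify_recist(make_traj(c(3.4, 0.05), baseline = 5))
  expect_identical(cr$best_response, "CR")
  expect_true(cr$responder)

  expect_error(classify_recist(make_traj(numeric(0), baseline = 5)), "empty")
  expect_error(classify_recist(make_traj(5, baseline = 0)), "baseline")
})

test_that("PD needs both the relative and the absolute nadir increase", {
  # +22% but only +0.44 cm: not PD for a small tumor
  x <- classify_recist(make_traj(c(2.44), baseline = 2))
  expect_identical(x$scans$response, "SD")
  # +0.6 cm but only +12%: not PD either
  y <- classify_recist(make_traj(c(5.6), baseline = 5))
  expect_identical(y$scans$response, "SD")
})

test_that("classification is invariant to a consistent unit rescaling", {
  set.seed(1)
  for (i in 1:20) {
    base <- runif(1, 2, 8)
    d <- base * exp(cumsum(rnorm(6, 0, 0.15)))
    a <- classify_recist(make_traj(d, baseline = base))
    b <- classify_recist(make_traj(d * 10, baseline = base * 10),
      detection_floor = 1, pd_abs = 5
    ) # cm -> mm
    expect_identical(a$best_response, b$best_response)
  }
})

test_that("trial summary computes ORR and DCR by PD-L1 subgroup", {
  rec <- function(best) {
    structure(
      list(best_response = best, responder = best %in% c("CR", "PR")),
      class = "vp_response"
    )
  }
  records <- lapply(c("PR", "PR", "PR", "SD", "SD", "PD", "PD", "SD", "PD", "PD"), rec)
  s <- trial_summary(records, pdl1 = rep(c(0.5, 0.1), 5), pdl1_threshold = 0.25)
  ov <- s[s$group == "overall", ]
  expect_equal(ov$orr, 0.3)
  expect_equal(ov$dcr, 0.6)
  expect_true(all(s$dcr >= s$orr, na.rm = TRUE))

  # all stable: ORR 0, DCR 1
  s2 <- suppressWarnings(trial_summary(lapply(rep("SD", 4), rec), rep(0.5, 4)))
  expect_equal(s2$orr[s2$group == "overall"], 0)
  expect_equal(s2$dcr[s2$group == "overall"], 1)

  # threshold 0 puts everyone in the high group
  s3 <- suppressWarnings(trial_summary(records, rep(0.5, 10), pdl1_threshold = 0))
  expect_equal(
    s3$orr[s3$group == "PD-L1 high"],
    s3$orr[s3$group == "overall"]
  )
  expect_warning(trial_summary(records, rep(0.5, 10), pdl1_threshold = 1), "empty subgroup")
})

test_that("bootstrap percentiles behave on degenerate and ordered cases", {
  expect_equal(
    bootstrap_ci(rep(1, 20), B = 200, seed = 1),
    c(median = 1, lower = 1, upper = 1)
  )
  set.seed(2)
  x <- rbinom(200, 1, 0.3)
  ci <- bootstrap_ci(x, B = 500, seed = 3)
  expect_true(ci[["lower"]] <= ci[["median"]] && ci[["median"]] <= ci[["upper"]])
  # resample size controls the interval width
  ci_small <- bootstrap_ci(x, resample_size = 50, B = 500, seed = 3)
  expect_gt(ci_small[["upper"]] - ci_small[["lower"]], ci[["upper"]] - ci[["lower"]])
  expect_error(bootstrap_ci(numeric(0)), "empty")
  expect_error(bootstrap_ci(x, B = 10), "at least 100")
})

test_that("exposure metrics reduce correctly on analytic cases", {
  # constant concentration: peak = trough, AUC = 14c, accumulation 1
  conc <- data.frame(time = seq(0, 140, 0.5), conc = 7)
  m <- exposure_metrics(conc, dose_regimen())
  expect_equal(unname(m[c("Cmax1", "Cmin1")]), c(7, 7))
  expect_equal(m[["AUC1"]], 14 * 7)
  expect_equal(unname(m[c("R_Cmax", "R_Cmin", "R_AUC")]), c(1, 1, 1))

  # one-compartment single dose: AUC(0-inf) = Dose / Cl
  # sampling starts just after the bolus so the trapezoid covers the curve
  p1 <- list(Cl = 0.4, Vmax = 0, Km = 1, V1 = 3, V2 = 4, Q = 0)
  tt <- seq(0.05, 400, by = 0.05)
  sim <- simulate_2cpt(p1, dose_regimen(amount = 600, n_doses = 1), tt)
  auc <- sum(diff(tt) * (head(sim$conc, -1) + tail(sim$conc, -1)) / 2)
  expect_equal(auc, 600 / 0.4, tolerance = 0.01)

  # superposition: a second dose cannot lower the steady trough
  p2 <- list(Cl = 0.25, Vmax = 0, Km = 1, V1 = 3.5, V2 = 3.4, Q = 0.476)
  tmany <- seq(0, 140, 0.5)
  multi <- simulate_2cpt(p2, dose_regimen(), tmany)
  single <- simulate_2cpt(p2, dose_regimen(n_doses = 1), tmany)
  m_multi <- exposure_metrics(data.frame(time = tmany, conc = multi$conc), dose_regimen())
  expect_gte(m_multi[["Cmin_ss"]], m_multi[["Cmin1"]])
  expect_gte(m_multi[["R_Cmin"]], 1)

  expect_error(
    exposure_metrics(data.frame(time = 0:5, conc = 1:6), dose_regimen()),
    "first dosing interval"
  )
})

test_that("run_trial assembles records, biomarkers and exposure", {
  snap <- default_snapshot()
  out <- suppressWarnings(
    run_trial(list(snap, snap), list(qsp_pk_parameters()), horizon = 200)
  )
  expect_length(out$records, 2)
  expect_equal(nrow(out$biomarkers), 2)
  expect_true(all(c("CD8", "CD8_Treg", "pdl1_expression", "tcc", "responder",
    "CD8_day14", "CD8_Treg_day14") %in% names(out$biomarkers)))
  expect_true(all(out$exposure$Cmax1 > out$exposure$Cmin1))
  expect_s3_class(out$summary, "data.frame")
})
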