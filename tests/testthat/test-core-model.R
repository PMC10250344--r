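cst <- model_constants()

test_that("tumor volume assembly matches the cellular bookkeeping formula", {
  s0 <- initial_state(patient_parameters())
  s0["C_total"] <- 0
  expect_equal(assemble_tumor_volume(s0, cst), 0)

  s1 <- s0
  s1["C_total"] <- 1
  v_cell <- pi / 6 * 16.9^3
  expect_equal(assemble_tumor_volume(s1, cst), v_cell / 0.75, tolerance = 1e-12)
  expect_equal(assemble_tumor_volume(s1, cst), 3369.5, tolerance = 1e-4)

  # mixed state: every population contributes with its own cell volume
  s2 <- s0
  s2[c("C_total", "C_x", "T8_T", "T4_T", "Treg_T", "T_exh", "M1", "M2")] <-
    c(10, 2, 5, 4, 3, 1, 6, 7)
  manual <- (cst$V_cell * 12 + cst$V_Tcell * 13 + cst$V_Mcell * 13) / cst$V_e
  expect_equal(assemble_tumor_volume(s2, cst), manual, tolerance = 1e-12)

  # blood-compartment cells do not add tumor volume
  s3 <- s1
  s3[c("T8_C", "nT8", "mAPC")] <- 1e9
  expect_equal(assemble_tumor_volume(s3, cst), assemble_tumor_volume(s1, cst))

  s_bad <- s1
  s_bad["C_total"] <- NaN
  expect_error(assemble_tumor_volume(s_bad, cst), "non-finite")
})

test_that("a tumor at carrying capacity is ~10 cm in diameter", {
  s <- initial_state(patient_parameters())
  s["C_total"] <- 1.5e11
  d <- volume_to_diameter(assemble_tumor_volume(s, cst))
  expect_equal(d, 9.9, tolerance = 0.01)
  # round trip volume <-> diameter
  expect_equal(volume_to_diameter(diameter_to_volume(3.7)), 3.7, tolerance = 1e-12)
})

test_that("PD-L1 expression is the density normalized by the theoretical max", {
  expect_equal(pdl1_expression(1770, cst), 1)
  expect_equal(pdl1_expression(250, cst), 250 / 1770)
  expect_equal(round(pdl1_expression(250, cst), 4), 0.1412)
  expect_equal(pdl1_expression(5000, cst), 1) # clipped
  expect_error(pdl1_expression(-1, cst), "non-negative")
  expect_error(model_constants(PDL1_max = -1))
})

test_that("tumor volume doubling time follows its defining formula", {
  expect_equal(tvdt(2, 4, 56), 56) # doubling over delta-t
  expect_equal(tvdt(4, 2, 56), -56) # halving symmetry
  # exponential growth: TVDT = ln2 / k regardless of delta-t
  k <- 0.007
  for (dt in c(14, 56, 200)) {
    expect_equal(tvdt(1, exp(k * dt), dt), log(2) / k, tolerance = 1e-12)
  }
  expect_equal(log(2) / 0.007, 99.0, tolerance = 1e-3)
  expect_error(tvdt(0, 1, 56), "positive")
  expect_error(tvdt(1, 1, 56), "differ")
})

test_that("immune-free derivatives collapse to pure logistic growth", {
  p <- immune_free_parameters()
  s <- initial_state(p)
  for (C in c(1, 1e6, 1e10, 1.5e11)) {
    s["C_total"] <- C
    d <- vp_derivatives(0, s, p)[[1]]
    expect_equal(d[[1]], 0.007 * C * (1 - C / 1.5e11), tolerance = 1e-12)
    expect_equal(sum(abs(d[-1])), 0) # nothing else moves
  }
})

test_that("all rate constants zero gives a zero derivative vector", {
  p <- patient_parameters(
    k_growth = 0, k_T8_act = 0, k_T4_act = 0, k_Treg_act = 0,
    k_T8_kill = 0, k_M1_kill = 0, k_MDSC_rec = 0, k_Mac_rec = 0,
    k_M1_pol = 0, k_APC_mat = 0, k_IFN_sec = 0, k_nT_repl = 0,
    k_PDL1_ind = 0, k_PDL1_dec = 0
  )
  s <- initial_state(p)
  s["C_total"] <- 1e8
  d <- vp_derivatives(0, s, p)[[1]]
  expect_equal(max(abs(d)), 0)
  expect_error(vp_derivatives(0, s * NA, p), "non-finite")
  expect_error(patient_parameters(not_a_parameter = 1), "unknown parameter")
})

test_that("tumor CD8 cells secrete IFN-gamma at 3x the per-cell CD4 rate", {
  p <- patient_parameters()
  base <- initial_state(p)
  base["C_total"] <- 1e9
  i_ifn <- which(names(base) == "IFNg")
  s8 <- base
  s8["T8_T"] <- 1e7
  s4 <- base
  s4["T4_T"] <- 1e7
  d8 <- vp_derivatives(0, s8, p)[[1]][i_ifn]
  d4 <- vp_derivatives(0, s4, p)[[1]][i_ifn]
  # equal counts, same secretion constant: CD8 contribution is exactly 3x,
  # after accounting for the (tiny) volume difference of the two states
  v8 <- assemble_tumor_volume(s8, cst)
  v4 <- assemble_tumor_volume(s4, cst)
  expect_equal(d8 * v8, 3 * d4 * v4, tolerance = 1e-10)
})

test_that("compiled and R right-hand sides agree along a trajectory", {
  p <- patient_parameters()
  pk <- qsp_pk_parameters()
  snap <- default_snapshot()
  reg <- dose_regimen()
  run <- function(compiled) {
    withr::with_options(list(vptrial.compiled = compiled), {
      simulate_treatment(snap, pk, reg, 100, record_step = 5)
    })
  }
  a <- run(TRUE)
  b <- run(FALSE)
  sa <- a$states[, vptrial:::.state_names]
  sb <- b$states[, vptrial:::.state_names]
  scale <- pmax(abs(sa), 1e-6)
  expect_lt(max(abs(sa - sb) / scale), 1e-4)
  # PK submodel parity
  conc_c <- withr::with_options(list(vptrial.compiled = TRUE), {
    qsp_pk_concentration(pk, reg, seq(0, 56, 1))$conc
  })
  conc_r <- withr::with_options(list(vptrial.compiled = FALSE), {
    qsp_pk_concentration(pk, reg, seq(0, 56, 1))$conc
  })
  expect_equal(conc_c, conc_r, tolerance = 1e-6)
})

test_that("immune-free growth matches the logistic closed form", {
  p <- immune_free_parameters()
  out <- vptrial:::.integrate(
    initial_state(p), seq(0, 3000, by = 50), p,
    qsp_pk_parameters(), cst
  )
  expect_lt(
    max(abs(out[, "C_total"] - logistic_cells(out[, "time"])) /
      logistic_cells(out[, "time"])),
    1e-3
  )
})

test_that("pre-treatment growth stops at the preset diameter", {
  p <- immune_free_parameters()
  snap <- run_to_pretreatment(p, patient_id = 7)
  expect_true(is_plausible(snap))
  expect_equal(snap$tumor_diameter, 3.7, tolerance = 1e-3)
  t_star <- logistic_time_to(cells_for_diameter(3.7))
  expect_equal(snap$time_to_preset, t_star, tolerance = 0.01)
  expect_identical(snap$patient_id, 7)

  # snapshot densities are counts over tumor volume in mL
  V_mL <- assemble_tumor_volume(snap$state, cst) * 1e-12
  expect_equal(snap$densities[["CD8"]], snap$state[["T8_T"]] / V_mL)
  expect_equal(snap$densities[["TAM"]],
    (snap$state[["M1"]] + snap$state[["M2"]]) / V_mL)
  expect_equal(snap$ratios[["CD8_Treg"]],
    snap$state[["T8_T"]] / snap$state[["Treg_T"]])
})

test_that("a non-growing tumor is reported as non-plausible", {
  res <- run_to_pretreatment(patient_parameters(k_growth = 0), t_max = 500)
  expect_false(is_plausible(res))
  expect_identical(res$reason, "no_crossing")
})

test_that("increasing the dose never increases the tumor at any scan", {
  snap <- default_snapshot()
  pk <- qsp_pk_parameters()
  diam <- sapply(c(0, 187.5, 750, 3000), function(amt) {
    simulate_treatment(snap, pk, dose_regimen(amount = amt), 200,
      record_step = 10
    )$trajectory$diameter
  })
  for (j in seq_len(ncol(diam) - 1)) {
    expect_true(all(diam[, j + 1] <= diam[, j] + 1e-8))
  }
})

test_that("PD-L1 density stays within [baseline, theoretical max]", {
  snap <- default_snapshot()
  sim <- simulate_treatment(snap, qsp_pk_parameters(), dose_regimen(), 400,
    record_step = 2
  )
  pdl1 <- sim$states[, "PDL1_avg"]
  p <- snap$parameters
  expect_true(all(pdl1 >= p$C_PDL1_base - 1e-6))
  expect_true(all(pdl1 <= cst$PDL1_max + 1e-6))
})

test_that("state positivity holds along treated trajectories", {
  snap <- default_snapshot()
  sim <- simulate_treatment(snap, qsp_pk_parameters(), dose_regimen(), 400,
    record_step = 2
  )
  st <- sim$states[, vptrial:::.state_names]
  scale <- apply(abs(st), 2, max)
  expect_true(all(t(st) >= -1e-9 * pmax(scale, 1)))
})

test_that("zero-dose treatment equals untreated continuation bitwise", {
  snap <- default_snapshot()
  pk <- qsp_pk_parameters()
  a <- simulate_treatment(snap, pk, dose_regimen(amount = 0), 150, record_step = 10)
  b <- simulate_treatment(snap, pk, NULL, 150, record_step = 10)
  expect_identical(a$states, b$states)
})

test_that("with drug binding disabled the trajectory is dose-independent", {
  snap <- default_snapshot()
  p0 <- patient_parameters(k_drug_bind = 0)
  snap0 <- make_snapshot(snap$patient_id, p0, snap$state, snap$time_to_preset)
  pk <- qsp_pk_parameters()
  a <- simulate_treatment(snap0, pk, dose_regimen(amount = 750), 150, record_step = 10)
  b <- simulate_treatment(snap0, pk, dose_regimen(amount = 3000), 150, record_step = 10)
  expect_equal(a$trajectory$diameter, b$trajectory$diameter, tolerance = 1e-9)
})

test_that("a bolus adds exactly dose/MW moles to the central compartment", {
  snap <- default_snapshot()
  reg <- dose_regimen(amount = 750, start = 14, n_doses = 1)
  sim <- simulate_treatment(snap, qsp_pk_parameters(), reg, 42,
    measurement_times = 42, record_step = 0.25
  )
  st <- sim$states
  before <- st[st[, "time"] == 13.75, "A_C"]
  after <- st[st[, "time"] == 14, "A_C"]
  dose_mol <- 750 / 1e3 / 148000
  expect_equal(unname(after - before), dose_mol, tolerance = 0.01)
  expect_error(dose_regimen(start = -1), "t < 0")
})

test_that("measured diameters are consistent with assembled volumes", {
  snap <- default_snapshot()
  sim <- simulate_treatment(snap, qsp_pk_parameters(), dose_regimen(), 120,
    record_step = 6
  )
  idx <- match(sim$trajectory$time, sim$states[, "time"])
  v <- apply(
    sim$states[idx, vptrial:::.state_names], 1,
    assemble_tumor_volume,
    constants = cst
  )
  expect_equal(sim$trajectory$diameter, volume_to_diameter(v), tolerance = 1e-9)
})
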