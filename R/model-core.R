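## canonical state ordering of the reduced model
.state_names <- c(
  "C_total", "C_x",
  "nT8", "nT4", "nTreg",
  "mAPC",
  "aT8_LN", "aT4_LN", "aTreg_LN",
  "T8_C", "T4_C", "Treg_C",
  "T8_T", "T4_T", "Treg_T", "T_exh",
  "M1", "M2", "MDSC",
  "IFNg", "PDL1_avg",
  "A_C", "A_P", "A_T", "A_LN"
)

#' Assemble tumor volume from cellular counts
#'
#' Tumor volume is the volume of all cells it contains, scaled by the
#' intracellular volume fraction:
#' `V_T = (1/V_e) * (V_cell*(C_total + C_x) + V_Tcell*(T_total + T_exh) +
#' V_Mcell*M_total)`,
#' where `T_total` sums the tumor-infiltrating effector, helper and
#' regulatory T cells and `M_total = M1 + M2`.
#'
#' @param state Named model state vector (see [initial_state()]).
#' @param constants A `vp_constants` object.
#' @return Tumor volume in cubic micrometers.
#' @export
assemble_tumor_volume <- function(state, constants = model_constants()) {
  comp <- state[c(
    "C_total", "C_x", "T8_T", "T4_T", "Treg_T", "T_exh",
    "M1", "M2"
  )]
  if (any(!is.finite(comp))) {
    stop("invalid state: non-finite cell count", call. = FALSE)
  }
  T_total <- state[["T8_T"]] + state[["T4_T"]] + state[["Treg_T"]]
  M_total <- state[["M1"]] + state[["M2"]]
  (constants$V_cell * (state[["C_total"]] + state[["C_x"]]) +
    constants$V_Tcell * (T_total + state[["T_exh"]]) +
    constants$V_Mcell * M_total) / constants$V_e
}

#' Convert a volume to the diameter of the equivalent sphere
#'
#' @param volume_um3 Volume in cubic micrometers.
#' @return Diameter in centimeters (1 cm = 1e4 um).
#' @export
volume_to_diameter <- function(volume_um3) {
  (6 * volume_um3 / pi)^(1 / 3) / 1e4
}

#' @rdname volume_to_diameter
#' @param diameter_cm Diameter in centimeters.
#' @return `diameter_to_volume`: volume in cubic micrometers.
#' @export
diameter_to_volume <- function(diameter_cm) {
  pi / 6 * (diameter_cm * 1e4)^3
}

#' PD-L1 expression score
#'
#' Converts the model's average PD-L1 surface density to the percent-style
#' expression score used clinically, by normalizing with the theoretical
#' maximal PD-L1 density (1770 molecules/um^2 by default). Patients with a
#' score above 0.25 form the PD-L1-high subgroup.
#'
#' @param pdl1_avg Average PD-L1 density (molecules/um^2), non-negative.
#' @param constants A `vp_constants` object (supplies `PDL1_max`).
#' @return Expression fraction, clipped to `[0, 1]`.
#' @export
pdl1_expression <- function(pdl1_avg, constants = model_constants()) {
  if (constants$PDL1_max <= 0) stop("PDL1_max must be positive", call. = FALSE)
  if (any(pdl1_avg < 0)) stop("pdl1_avg must be non-negative", call. = FALSE)
  pmin(1, pmax(0, pdl1_avg / constants$PDL1_max))
}

#' Tumor volume doubling time
#'
#' `TVDT = delta_t * log(2) / (log(V_t2) - log(V_t1))` for two volume
#' measurements `delta_t` days apart. Shrinking tumors give negative
#' values, which are passed through (and can be flagged by the caller).
#'
#' @param V_t1,V_t2 Tumor volumes (any common unit), strictly positive.
#' @param delta_t Time between the two measurements (days).
#' @return Doubling time in days (vectorized).
#' @export
tvdt <- function(V_t1, V_t2, delta_t) {
  if (any(V_t1 <= 0) || any(V_t2 <= 0)) {
    stop("volumes must be strictly positive", call. = FALSE)
  }
  if (any(V_t1 == V_t2)) {
    stop("volumes must differ for a finite doubling time", call. = FALSE)
  }
  delta_t * log(2) / (log(V_t2) - log(V_t1))
}

## fast positional indices into the canonical state vector
.si <- as.list(stats::setNames(seq_along(.state_names), .state_names))

#' Right-hand side of the reduced tumor-immune ODE system
#'
#' Implements the reduced four-compartment (central, peripheral, tumor,
#' tumor-draining lymph node) cancer-immunity-cycle model:
#' logistic cancer growth; CD8- and M1-mediated cancer killing inhibited by
#' PD-1/PD-L1 engagement, Treg/MDSC suppression and (for phagocytosis)
#' CD47; antigen-driven T-cell activation in the lymph nodes with
#' trafficking through blood into the tumor; CD8 exhaustion under
#' checkpoint engagement; MDSC/macrophage recruitment and M2-to-M1
#' polarization; IFN-gamma secretion (CD8 at 3x the per-cell CD4 rate)
#' driving PD-L1 induction; and four-compartment antibody disposition with
#' linear plus Michaelis-Menten elimination.
#'
#' @param t Time (day).
#' @param state Named (or canonically ordered) numeric state vector.
#' @param params A `vp_parameters` object.
#' @param pk A `vp_pk_parameters` object.
#' @param constants A `vp_constants` object.
#' @return A list whose first element is the derivative vector (deSolve
#'   convention), followed by the instantaneous tumor diameter (cm).
#' @export
vp_derivatives <- function(t, state, params, pk = qsp_pk_parameters(),
                           constants = model_constants()) {
  if (any(!is.finite(state))) {
    stop("invalid state: non-finite component", call. = FALSE)
  }
  p <- params
  s <- pmax(state, 0) # rates evaluated on the non-negative part
  i <- .si

  C <- s[[i$C_total]]
  Cx <- s[[i$C_x]]
  T8T <- s[[i$T8_T]]
  T4T <- s[[i$T4_T]]
  TregT <- s[[i$Treg_T]]
  Texh <- s[[i$T_exh]]
  M1 <- s[[i$M1]]
  M2 <- s[[i$M2]]
  MDSC <- s[[i$MDSC]]
  IFN <- s[[i$IFNg]]
  PDL1 <- s[[i$PDL1_avg]]

  ## geometry
  V_um3 <- (constants$V_cell * (C + Cx) +
    constants$V_Tcell * (T8T + T4T + TregT + Texh) +
    constants$V_Mcell * (M1 + M2)) / constants$V_e
  V_mL <- V_um3 * 1e-12
  V_L <- V_um3 * 1e-15

  ## drug concentrations (mol/L) in each compartment's accessible space
  conc_C <- s[[i$A_C]] / pk$V_blood
  V_P_acc <- p$V_per_tissue * pk$f_interstitial
  conc_P <- s[[i$A_P]] / V_P_acc
  V_T_acc <- max(V_L * p$f_int_tumor, 1e-12)
  conc_T <- s[[i$A_T]] / V_T_acc
  V_LN_acc <- p$V_LN_total_mL * 1e-3 * pk$f_interstitial
  conc_LN <- s[[i$A_LN]] / V_LN_acc

  ## checkpoint engagement: free PD-L1 after reversible drug binding
  occ <- p$k_drug_bind * conc_T / (conc_T + p$K_d_drug)
  PDL1_free <- PDL1 * (1 - occ)
  engage <- PDL1_free * p$T_PD1
  H_PD1 <- engage / (engage + p$K_checkpoint)

  ## suppression factors (density-based, saturating)
  dens_Treg <- TregT / V_mL
  dens_MDSC <- MDSC / V_mL
  S_Treg <- p$K_Treg_supp / (p$K_Treg_supp + dens_Treg)
  S_MDSC <- p$K_MDSC_supp / (p$K_MDSC_supp + dens_MDSC)
  S_CD47 <- p$K_CD47 / (p$K_CD47 + p$C_CD47)

  ## cancer killing
  kill_T8 <- if (T8T > 0) {
    p$k_T8_kill * C * T8T / (C + T8T) * (1 - H_PD1) * S_Treg * S_MDSC
  } else {
    0
  }
  kill_M1 <- if (M1 > 0) {
    p$k_M1_kill * C * M1 / (C + M1) * (1 - H_PD1) * S_CD47
  } else {
    0
  }
  kill_total <- kill_T8 + kill_M1

  ## antigen release and presentation
  antigen_flux <- p$k_antigen_shed * C + kill_total
  A_factor <- antigen_flux / (antigen_flux + p$K_antigen)
  MHC <- p$K_MHC / (p$K_MHC + p$k_P1_d1)

  ## lymph node: APC maturation and T cell activation
  d_mAPC <- p$k_APC_mat * A_factor * p$APC_pool - p$k_APC_death * s[[i$mAPC]]
  ln_scale <- p$nLNs / 21
  act8 <- p$k_T8_act * s[[i$mAPC]] * (p$n_T1_clones / 92) * MHC * ln_scale *
    (s[[i$nT8]] / p$nT8_0)
  act4 <- p$k_T4_act * s[[i$mAPC]] * (p$n_T1_clones / 92) * MHC * ln_scale *
    (s[[i$nT4]] / p$nT4_0)
  actR <- p$k_Treg_act * s[[i$mAPC]] * (p$n_T0_clones / 100) * ln_scale *
    (s[[i$nTreg]] / p$nTreg_0)

  ## trafficking: LN -> blood -> tumor (entry scales with vascular fraction
  ## and saturating tumor size)
  size_fac <- V_mL / (V_mL + p$K_T_vol)
  enter <- p$k_T_enter * constants$gamma_T * size_fac
  egress8 <- p$k_LN_out * s[[i$aT8_LN]]
  egress4 <- p$k_LN_out * s[[i$aT4_LN]]
  egressR <- p$k_LN_out * s[[i$aTreg_LN]]
  in8 <- enter * s[[i$T8_C]]
  in4 <- enter * s[[i$T4_C]]
  inR <- enter * s[[i$Treg_C]]

  exhaust <- p$k_exhaust * H_PD1 * T8T

  ## IFN-gamma and PD-L1 induction
  d_IFN <- p$k_IFN_sec * (p$IFN_CD8_factor * T8T + T4T) / max(V_mL, 1e-12) -
    p$k_IFN_deg * IFN
  H_IFN <- IFN / (IFN + p$K_IFN)
  d_PDL1 <- p$k_PDL1_ind * H_IFN * (constants$PDL1_max - PDL1) -
    p$k_PDL1_dec * (PDL1 - p$C_PDL1_base)

  ## drug disposition (amounts in mol)
  Q_P <- pk$k_filtration * 86400
  Q_T <- Q_P * V_L / p$V_per_tissue
  Q_LN <- Q_P * (p$V_LN_total_mL * 1e-3) / p$V_per_tissue
  Vmax_mol <- pk$Vmax_nl / (p$MW_drug * 1e3) # mg/day -> mol/day
  Km_mol <- pk$Km_nl / (p$MW_drug * 1e3) # mg/L -> mol/L
  elim <- pk$Cl_lin * conc_C +
    if (conc_C > 0) Vmax_mol * conc_C / (conc_C + Km_mol) else 0
  flux_P <- Q_P * (conc_C - conc_P)
  flux_T <- Q_T * (conc_C - conc_T)
  flux_LN <- Q_LN * (conc_C - conc_LN)

  d <- numeric(length(.state_names))
  d[i$C_total] <- p$k_growth * C * (1 - C / p$C_max) - kill_total
  d[i$C_x] <- kill_total - p$k_Cx_clear * Cx
  d[i$nT8] <- p$k_nT_repl * (p$nT8_0 - s[[i$nT8]]) - act8 / p$n_clone_expand
  d[i$nT4] <- p$k_nT_repl * (p$nT4_0 - s[[i$nT4]]) - act4 / p$n_clone_expand
  d[i$nTreg] <- p$k_nT_repl * (p$nTreg_0 - s[[i$nTreg]]) - actR / p$n_clone_expand
  d[i$mAPC] <- d_mAPC
  d[i$aT8_LN] <- act8 - egress8
  d[i$aT4_LN] <- act4 - egress4
  d[i$aTreg_LN] <- actR - egressR
  d[i$T8_C] <- egress8 - in8 - p$k_T_blood_death * s[[i$T8_C]]
  d[i$T4_C] <- egress4 - in4 - p$k_T_blood_death * s[[i$T4_C]]
  d[i$Treg_C] <- egressR - inR - p$k_T_blood_death * s[[i$Treg_C]]
  d[i$T8_T] <- in8 - p$k_T_tumor_death * T8T - exhaust
  d[i$T4_T] <- in4 - p$k_T_tumor_death * T4T
  d[i$Treg_T] <- inR - p$k_T_tumor_death * TregT
  d[i$T_exh] <- exhaust - p$k_Texh_death * Texh
  d[i$M1] <- p$k_M1_pol * M2 - p$k_M2_pol * M1 - p$k_M1_death * M1
  d[i$M2] <- p$k_Mac_rec * V_mL - p$k_M1_pol * M2 + p$k_M2_pol * M1 -
    p$k_M2_death * M2
  d[i$MDSC] <- p$k_MDSC_rec * V_mL - p$k_MDSC_death * MDSC
  d[i$IFNg] <- d_IFN
  d[i$PDL1_avg] <- d_PDL1
  d[i$A_C] <- -flux_P - flux_T - flux_LN - elim
  d[i$A_P] <- flux_P
  d[i$A_T] <- flux_T
  d[i$A_LN] <- flux_LN

  ## pull clipped-at-zero states back toward the admissible region
  neg <- state < 0
  if (any(neg)) d[neg] <- d[neg] + (0 - state[neg])

  list(d, diameter = volume_to_diameter(V_um3))
}

## deSolve-facing wrapper
.rhs_desolve <- function(t, state, parms) {
  vp_derivatives(t, state, parms$params, parms$pk, parms$constants)
}

## packing order shared with the compiled RHS (src/model_rhs.c)
.model_parm_order <- c(
  "k_growth", "C_max", "T_PD1", "C_PDL1_base", "C_CD47",
  "n_T1_clones", "n_T0_clones", "k_P1_d1", "k_MDSC_rec", "k_Mac_rec",
  "k_M1_pol", "nLNs",
  "k_T8_act", "k_T4_act", "k_Treg_act", "k_LN_out", "k_T_enter",
  "k_T_blood_death", "k_T_tumor_death", "k_T8_kill", "k_M1_kill",
  "k_exhaust", "k_Texh_death", "k_Cx_clear", "k_antigen_shed",
  "K_antigen", "K_MHC", "k_APC_mat", "APC_pool", "k_APC_death",
  "nT8_0", "nT4_0", "nTreg_0", "k_nT_repl", "n_clone_expand",
  "K_T_vol", "K_Treg_supp", "K_MDSC_supp", "K_CD47", "k_MDSC_death",
  "k_M1_death", "k_M2_death", "k_M2_pol", "k_IFN_sec", "k_IFN_deg",
  "IFN_CD8_factor", "K_IFN", "k_PDL1_ind", "k_PDL1_dec", "K_checkpoint",
  "k_drug_bind", "K_d_drug", "MW_drug", "V_per_tissue", "V_LN_total_mL",
  "f_int_tumor"
)

.pack_model_parms <- function(params, pk, constants, root_target = 0) {
  c(
    as.numeric(unlist(params[.model_parm_order])),
    pk$k_filtration, pk$V_blood, pk$f_interstitial,
    pk$Cl_lin, pk$Vmax_nl, pk$Km_nl,
    constants$V_cell, constants$V_Tcell, constants$V_Mcell,
    constants$V_e, constants$gamma_T, constants$PDL1_max,
    root_target
  )
}

## per-species absolute tolerances, scaled to typical magnitudes
.atol_vector <- function() {
  a <- stats::setNames(rep(1e-8, length(.state_names)), .state_names)
  a[c("IFNg")] <- 1e-10
  a[c("PDL1_avg")] <- 1e-6
  a[c("A_C", "A_P", "A_T", "A_LN")] <- 1e-15
  a
}
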