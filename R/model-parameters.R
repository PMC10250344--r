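#' Physical and measurement constants of the reduced tumor-immune model
#'
#' Returns the fixed physical constants used to assemble tumor volume from
#' cell counts and to convert model readouts to clinically reported scales.
#' The cancer-cell volume is derived from the NSCLC cell diameter assuming a
#' sphere, `V_cell = (pi/6) * D_cell^3`.
#'
#' @param D_cell Diameter of a single NSCLC cancer cell (micrometers).
#' @param D_Tcell Diameter of a T cell (micrometers).
#' @param D_Mcell Diameter of a macrophage (micrometers).
#' @param V_e Volume fraction of intracellular space in the tumor
#'   (dimensionless, in (0,1)).
#' @param gamma_T Volume fraction of vascular space in the tumor
#'   (dimensionless, in (0,1)).
#' @param PDL1_max Theoretical maximal PD-L1 surface density
#'   (molecules/um^2), used to convert density to a percent-style
#'   expression score.
#' @param detection_floor Minimum measurable tumor diameter (cm); diameters
#'   below this count as tumor disappearance (complete response).
#'
#' @return An object of class `vp_constants`: a named list with the inputs
#'   plus the derived single-cell volumes `V_cell`, `V_Tcell`, `V_Mcell`
#'   (um^3).
#' @export
#' @examples
#' cst <- model_constants()
#' cst$V_cell # ~2527 um^3 for a 16.9 um cell
model_constants <- function(D_cell = 16.9,
                            D_Tcell = 6.94,
                            D_Mcell = 21,
                            V_e = 0.75,
                            gamma_T = 0.05,
                            PDL1_max = 1770,
                            detection_floor = 0.1) {
  stopifnot(
    D_cell > 0, D_Tcell > 0, D_Mcell > 0,
    V_e > 0, V_e < 1, gamma_T > 0, gamma_T < 1,
    PDL1_max > 0, detection_floor > 0
  )
  out <- list(
    D_cell = D_cell,
    V_cell = pi / 6 * D_cell^3,
    V_Tcell = pi / 6 * D_Tcell^3,
    V_Mcell = pi / 6 * D_Mcell^3,
    V_e = V_e,
    gamma_T = gamma_T,
    PDL1_max = PDL1_max,
    detection_floor = detection_floor
  )
  class(out) <- "vp_constants"
  out
}

#' Mechanistic parameter set of one (plausible or virtual) patient
#'
#' Assembles the full parameter list for the reduced cancer-immunity-cycle
#' model. The NSCLC-specific baseline values (proliferation rate, carrying
#' capacity, checkpoint densities, clone counts, recruitment rates, lymph
#' node count, preset pre-treatment diameter) follow the published NSCLC
#' parameterization; the remaining rate constants are the reduced model's
#' own, calibrated once so that pre-treatment immune densities fall in the
#' ranges reported by digital pathology analyses of NSCLC tumors (see the
#' methods vignette).
#'
#' @param ... Named overrides for any parameter listed below.
#'
#' @return An object of class `vp_parameters` (named list).
#'
#' @section Varied-by-default parameters:
#' `k_growth`, `initial_tumour_size`, `n_T1_clones`, `n_T0_clones`,
#' `k_P1_d1`, `k_MDSC_rec`, `k_Mac_rec`, `k_M1_pol`, `T_PD1`,
#' `C_PDL1_base`, `C_CD47`, `k_T8_act`, `k_T4_act`, `k_Treg_act`,
#' `k_T8_kill` are the parameters varied across plausible patients by
#' [default_parameter_specs()].
#' @export
patient_parameters <- function(...) {
  p <- list(
    ## NSCLC-specific baseline values
    k_growth = 0.007,          # cancer proliferation rate (1/day)
    C_max = 1.5e11,            # carrying capacity (cells), ~10 cm tumor
    T_PD1 = 176,               # PD-1 density on T cells (molecules/um^2)
    C_PDL1_base = 250,         # baseline PD-L1 density (molecules/um^2)
    C_CD47 = 100,              # CD47 density on cancer cells (molecules/um^2)
    n_T1_clones = 92,          # tumor-specific T cell clones (TCC)
    n_T0_clones = 100,         # self-antigen-specific (Treg) clones
    k_P1_d1 = 40,              # neoantigen-MHC binding affinity (nmol/L)
    k_MDSC_rec = 2000,         # MDSC recruitment (cell/(mL*day))
    k_Mac_rec = 2e5,           # macrophage recruitment (cell/(mL*day))
    k_M1_pol = 0.02,           # M2 -> M1 polarization (1/day)
    nLNs = 21,                 # draining lymph nodes
    initial_tumour_size = 3.7, # preset pre-treatment diameter (cm)

    ## reduced-model rate constants (surrogate block, calibrated defaults)
    k_T8_act = 1450,           # CD8 activation scale in LN (cell/day per mAPC unit)
    k_T4_act = 1200,           # CD4 helper activation scale
    k_Treg_act = 90,          # Treg activation scale (self antigens, no MHC factor)
    k_LN_out = 0.5,            # LN egress of activated T cells (1/day)
    k_T_enter = 10,            # blood -> tumor entry scale (1/day, x gamma_T x size factor)
    k_T_blood_death = 0.3,     # clearance of activated T cells in blood (1/day)
    k_T_tumor_death = 0.1,     # death of activated T cells in tumor (1/day)
    k_T8_kill = 0.08,           # maximal CD8-mediated cancer kill rate (1/day)
    k_M1_kill = 0.2,           # maximal M1 phagocytosis rate (1/day)
    k_exhaust = 0.05,          # CD8 exhaustion scale (1/day, x checkpoint engagement)
    k_Texh_death = 0.05,       # clearance of exhausted T cells (1/day)
    k_Cx_clear = 0.05,         # clearance of dying cancer cells (1/day)
    k_antigen_shed = 1e-4,     # antigen release per cancer cell (1/day)
    K_antigen = 1e6,           # half-saturation of antigen flux (cell/day)
    K_MHC = 40,                # half-effect affinity for MHC presentation (nmol/L)
    k_APC_mat = 1,             # mAPC maturation scale (1/day)
    APC_pool = 1e5,            # immature APC pool feeding maturation (cells)
    k_APC_death = 0.2,         # mAPC turnover (1/day)
    nT8_0 = 1e9,               # naive CD8 pool size (cells)
    nT4_0 = 1e9,               # naive CD4 pool size (cells)
    nTreg_0 = 2.5e8,           # naive Treg pool size (cells)
    k_nT_repl = 0.01,          # naive pool replenishment (1/day)
    n_clone_expand = 100,      # progeny per activated naive T cell
    K_T_vol = 30,              # tumor-size half-saturation for T entry (mL)
    K_Treg_supp = 2e7,         # Treg suppression half-effect (cell/mL)
    K_MDSC_supp = 1e5,         # MDSC suppression half-effect (cell/mL)
    K_CD47 = 100,              # CD47 'do not eat me' half-effect (molecules/um^2)
    k_MDSC_death = 0.05,       # MDSC turnover (1/day)
    k_M1_death = 0.04,         # M1 macrophage turnover (1/day)
    k_M2_death = 0.05,         # M2 macrophage turnover (1/day)
    k_M2_pol = 0,              # optional M1 -> M2 back-polarization (1/day)
    k_IFN_sec = 1e-8,          # IFNg secretion per CD4 helper cell (conc mL/day)
    k_IFN_deg = 1,             # IFNg degradation (1/day)
    IFN_CD8_factor = 3,        # CD8 secrete IFNg at 3x the CD4 per-cell rate
    K_IFN = 5,              # IFNg half-effect for PD-L1 induction (conc units)
    k_PDL1_ind = 0.1,          # PD-L1 induction rate toward max (1/day)
    k_PDL1_dec = 0.1,          # PD-L1 relaxation toward baseline (1/day)
    K_checkpoint = 2e4,        # PD-1 x PD-L1 half-effect ((molecules/um^2)^2)
    k_drug_bind = 1,           # drug-PD-L1 binding scale (0 disables efficacy)
    K_d_drug = 5e-9,           # effective drug-PD-L1 dissociation constant (mol/L)
    MW_drug = 148000,          # drug molecular weight (g/mol), IgG1 antibody
    V_per_tissue = 60,         # lumped peripheral tissue volume (L)
    V_LN_total_mL = 3,         # total draining lymph node volume (mL)
    f_int_tumor = 0.2          # tumor interstitial fraction available to drug
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    p[names(dots)] <- dots
  }
  rates <- setdiff(names(p), c("initial_tumour_size"))
  bad <- vapply(p[rates], function(x) !is.numeric(x) || !is.finite(x) || x < 0, logical(1))
  if (any(bad)) {
    stop("parameters must be finite and non-negative: ",
      paste(rates[bad], collapse = ", "),
      call. = FALSE
    )
  }
  p$n_T1_clones <- max(1L, as.integer(round(p$n_T1_clones)))
  p$n_T0_clones <- max(1L, as.integer(round(p$n_T0_clones)))
  if (p$initial_tumour_size < 0 || p$initial_tumour_size > 10) {
    stop("initial_tumour_size must lie in [detection floor, 10] cm", call. = FALSE)
  }
  class(p) <- "vp_parameters"
  p
}

#' Parameter set with all immune and drug mechanisms switched off
#'
#' Convenience constructor for the immune-free limit in which cancer growth
#' is exactly logistic: all immune recruitment, activation, killing and drug
#' binding constants are zero. Useful for analytic oracle checks.
#'
#' @param ... Overrides forwarded to [patient_parameters()] after zeroing.
#' @return A `vp_parameters` object.
#' @export
immune_free_parameters <- function(...) {
  patient_parameters(
    k_T8_act = 0, k_T4_act = 0, k_Treg_act = 0,
    k_T8_kill = 0, k_M1_kill = 0,
    k_MDSC_rec = 0, k_Mac_rec = 0,
    k_APC_mat = 0, k_IFN_sec = 0,
    k_drug_bind = 0,
    ...
  )
}

#' Drug-disposition (pharmacokinetic) parameters of the QSP model
#'
#' The six fitted drug-disposition parameters governing antibody transport
#' between the four model compartments and elimination from the central
#' compartment.
#'
#' @param k_filtration Capillary filtration rate (L/s).
#' @param V_blood Blood (central) volume (L).
#' @param f_interstitial Peripheral interstitial volume fraction available
#'   to the drug (dimensionless, in (0,1)).
#' @param Cl_lin Linear clearance (L/day).
#' @param Vmax_nl Maximum non-linear (target-mediated) elimination rate
#'   (mg/day).
#' @param Km_nl Michaelis constant of non-linear elimination (mg/L).
#' @return An object of class `vp_pk_parameters` (named list).
#' @export
qsp_pk_parameters <- function(k_filtration = 5.6e-6,
                              V_blood = 5.8,
                              f_interstitial = 0.055,
                              Cl_lin = 0.23,
                              Vmax_nl = 1.0,
                              Km_nl = 0.45) {
  stopifnot(
    k_filtration > 0, V_blood > 0,
    f_interstitial > 0, f_interstitial < 1,
    Cl_lin > 0, Vmax_nl >= 0, Km_nl > 0
  )
  out <- list(
    k_filtration = k_filtration, V_blood = V_blood,
    f_interstitial = f_interstitial, Cl_lin = Cl_lin,
    Vmax_nl = Vmax_nl, Km_nl = Km_nl
  )
  class(out) <- "vp_pk_parameters"
  out
}

#' Initial model state: a single cancer cell
#'
#' @param params A `vp_parameters` object; supplies the naive pool sizes and
#'   the patient's baseline PD-L1 density.
#' @return Named numeric state vector in the model's canonical ordering.
#' @export
initial_state <- function(params = patient_parameters()) {
  s <- stats::setNames(numeric(length(.state_names)), .state_names)
  s["C_total"] <- 1
  s["nT8"] <- params$nT8_0
  s["nT4"] <- params$nT4_0
  s["nTreg"] <- params$nTreg_0
  s["PDL1_avg"] <- params$C_PDL1_base
  s
}
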