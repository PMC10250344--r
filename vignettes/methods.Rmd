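---
title: "Methods: virtual patient generation and in-silico PD-L1 inhibition trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual patient generation and in-silico PD-L1 inhibition trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`vptrial` implements, at desk scale, the virtual-patient workflow used
in quantitative systems pharmacology (QSP) studies of checkpoint
inhibition in non-small cell lung cancer (NSCLC): a mechanistic
tumor–immune ODE model, Latin-hypercube generation of plausible
patients, probability-of-inclusion selection of a virtual cohort guided
by immune subset ratios, compressed latent parameterization of drug
disposition, a RECIST v1.1 trial engine, biomarker analytics and Morris
sensitivity screening. This vignette documents the model, its
assumptions, the tunable parameters, the synthetic data generators, and
the numerical and design choices, so that a reader can judge what a
passing test suite does and does not establish.

# The reduced tumor–immune model

Full QSP immuno-oncology platforms couple hundreds of parameters over a
hundred-plus ODEs. `vptrial` deliberately implements a *reduced*
surrogate with ~25 states across four compartments — central (blood),
peripheral tissue, tumor, and tumor-draining lymph nodes — that
reproduces the mechanisms named in the main text of published NSCLC
analyses and exposes the same downstream interface (pre-treatment
snapshots of densities, ratios and PD-L1 expression). It is a faithful
mechanistic skeleton, not a claim of equivalence to any full platform.

States: viable and dying cancer cells; naive CD8/CD4/Treg pools; mature
antigen-presenting cells (lymph node); activated CD8/CD4/Treg in lymph
node, blood and tumor; exhausted CD8; M1/M2 macrophages and MDSCs in
tumor; tumor IFN-γ; average PD-L1 density; antibody amounts in the four
compartments.

Mechanisms, in the order they appear in `vp_derivatives()`:

* **Logistic cancer growth.** `dC/dt = k_growth C (1 − C/C_max)` with
  `k_growth = 0.007`/day and `C_max = 1.5e11` cells (a ~10 cm tumor).
  With all immune and drug mechanisms zeroed the growth is *exactly*
  logistic; the test suite exploits the closed form as an oracle.
* **Killing.** Tumor CD8 effectors kill cancer cells with an
  effector–target saturating form `k_T8_kill · C · T8/(C + T8)`; M1
  macrophages phagocytose analogously. Both are multiplied by
  `1 − H_PD1`, where `H_PD1` is a Hill-1 occupancy factor in the product
  of free PD-L1 and PD-1 densities, and by saturating Treg and MDSC
  suppression factors; phagocytosis also carries a CD47 "don't eat me"
  factor. Drug in the tumor interstitium binds PD-L1 reversibly
  (quasi-equilibrium occupancy with effective Kd `K_d_drug`), reducing
  free PD-L1.
* **Antigen and activation.** Antigen flux is `k_antigen_shed · C` plus
  the treatment-induced kill flux. The shedding term represents the cell
  turnover that is implicit in the *net* logistic growth term; an
  explicit separate death term would break the exact logistic limit, so
  it is deliberately absent. Antigen saturably matures APCs; activation
  of naive T cells scales with mature APCs, clone counts (tumor-specific
  clones for CD8/CD4, self-antigen clones for Treg), an MHC presentation
  factor saturating in the neoantigen–MHC affinity, and the number of
  draining lymph nodes.
* **Trafficking.** Activated cells egress to blood and enter the tumor
  at a rate proportional to the tumor vascular fraction `gamma_T` and a
  saturating function of tumor volume, so small lesions recruit little.
* **Exhaustion.** Tumor CD8 convert to exhausted cells in proportion to
  checkpoint engagement; exhausted cells occupy volume but do not kill.
* **Myeloid compartment.** MDSCs and macrophages are recruited in
  proportion to tumor volume (2000 and 2e5 cells/mL/day); macrophages
  arrive M2 and polarize to M1 at `k_M1_pol = 0.02`/day.
* **IFN-γ and PD-L1.** Tumor CD8 secrete IFN-γ at three times the
  per-cell CD4 helper rate; IFN-γ decays first order and drives PD-L1
  from the patient's baseline toward the theoretical maximum
  (1770 molecules/µm²) through a saturating induction term, balanced by
  relaxation toward baseline. PD-L1 therefore stays in
  `[C_PDL1_base, PDL1_max]` by construction.
* **Drug disposition.** Four-compartment antibody transport driven by a
  capillary filtration rate (scaled to each tissue's volume), with
  linear plus Michaelis–Menten elimination from the central compartment;
  doses are boluses into central blood, converted to moles with a
  configurable antibody molecular weight (148 kDa default — a generic
  IgG1 value, used because the study drug's weight is not part of the
  public parameter tables).

Tumor volume is assembled from counts,
`V_T = (1/V_e)(V_cell (C_total + C_x) + V_Tcell (T_total + T_exh) + V_Mcell M_total)`,
and diameters always assume a sphere.

## Calibration of the surrogate rate constants

The NSCLC-specific baselines (Table of `patient_parameters()`:
densities, clone counts, recruitment rates, lymph node count, cell
diameter, 3.7 cm preset size) are literature-anchored values. The
surrogate-only rate constants (activation scales, trafficking, death
rates, killing rate, IFN-γ/PD-L1 kinetics, half-effect constants) were
calibrated once, as part of the model's construction, so that the
baseline patient's pre-treatment snapshot lands in the ranges reported
by digital pathology of NSCLC tumors (CD8 ~2.6e7, CD4 ~3.2e7, Treg
~5.4e6, TAM ~3.7e6, MDSC ~4.2e4 cells/mL), the PD-L1-high fraction at
the 25% threshold is roughly balanced, and treatment produces a
realistic split of responders and progressors. This calibration is a
fixture of the package — a definition of the study conditions — and is
never used as a test oracle.

# Plausible patients and cohort selection

`default_parameter_specs()` varies 15 mechanistic parameters log-normally
around their baselines (spreads 0.25–0.5 on the log scale; the original
study's per-parameter statistics are not public, so these are package
defaults). The preset tumor diameter is a truncated log-normal on
1.5–9.9 cm with median 3.7 cm, matching target-lesion sizes at NSCLC
diagnosis. Each parameter set is grown from one cancer cell with the
stiff-capable `lsodar` integrator; the preset-diameter crossing is
located by the integrator's root finder (the snapshot diameter is
checked to 1e-3 cm). Patients that never reach their preset size within
20 years — typically strong-immunity draws whose tumor is controlled —
are excluded as non-plausible, which mirrors how such workflows behave
in practice and induces a favorable correlation between tolerated tumor
growth and high PD-L1/T-cell infiltration.

Selection uses the probability of inclusion
`p_i = min(1, β ρ_obs(r_i)/ρ_sim(r_i))` at each plausible patient's
ln-ratio triplet. Densities are kNN estimates
`ρ(r) = N/(m V_d(R_N(r)))`; we divide by the sample count `m` so the
estimate integrates to ≈1 — a pure normalization that β absorbs, leaving
the selection unchanged. `N = 8` by default (5–10 is the sensible
range). β is optimized by simulated annealing on the log scale with
geometric cooling; the objective evaluates a *seeded Bernoulli
realization* of the selection shared across candidate β values, which
makes the objective deterministic in β, and rejects candidates whose
expected cohort is below `min_cohort` (default 50). The annealing
schedule is a package choice; published descriptions of this step do not
fix one. The additional plausible-patient optimization step proposed in
the general probability-of-inclusion literature is intentionally not
implemented: physiologically plausible ranges for tumor-immune states
are not established well enough to constrain it.

# Synthetic data generators

The generators define the study conditions and remove any dependency on
external portals:

* `generate_immune_ratio_dataset()` draws correlated trivariate
  log-normal ratio triplets (M1/M2, CD8/Treg, CD8/CD4) with a
  configurable zero-inflation fraction (default 5%) emulating patients
  with a zero subset estimate; zeros are removed (and counted) by
  `clean_and_log_transform()`, as ratio data must be before
  log-transformation. The default medians (0.45, 4.7, 0.82) and log-SDs
  (0.38, 0.45, 0.34) are fixture conventions chosen to be
  order-of-magnitude consistent with immunogenomic cohort summaries for
  lung cancer and to overlap the model's own snapshot distribution; they
  are never test oracles. What the generator does *not* emulate: real
  inter-feature dependence beyond one correlation matrix, batch effects,
  subtype-specific distributions (the LUAD/LUSC label is a coin flip),
  and measurement error in deconvolution-based proportions. Passing
  tests therefore demonstrate that the selection machinery matches a
  known distribution — not that the model matches TCGA.
* `generate_poppk_population()` samples covariates (weight, albumin,
  soluble PD-L1, sex, ECOG) log-normally/binomially and maps them to
  two-compartment PK parameters through a configurable power-law/
  proportional covariate model with log-normal unexplained variability.
  The published covariate equations for the reference antibody are not
  public; the mapping is a declared surrogate with conventional
  reference values (70 kg, 39 g/L). `Q` is fixed at 0.476 L/day for all
  patients. Covariates are constant over time.
* `simulate_2cpt()` integrates the two-compartment model with bolus
  dosing; its linear special case is validated against the closed-form
  biexponential solution.

# Compressed latent PK parameterization

The six QSP disposition parameters (capillary filtration rate, blood
volume, peripheral interstitial fraction, linear clearance, maximal
nonlinear clearance, Michaelis constant) are fitted to pseudo-patient
curves in three steps: a multi-start Levenberg–Marquardt fit of the
median curve (group average θ̄); an SVD basis `V` from the covariance
`C = Ŷ_Θ Θᵀ` of k random local deviations (default k = 500, 10%
log-scale perturbations — "local deviations" without a published size);
and per-patient fits penalized by `λ ‖Vᵀ(θ − θ̄)‖₁` (smoothed for the
quasi-Newton step). New parameter sets are sampled uniformly within the
per-dimension empirical bounds of the fitted latent coordinates and
mapped back by `θ = Vφ + θ̄`, with rejection of draws violating
positivity or the interstitial-fraction range.

Two numerical choices matter:

* **Log-scale residuals.** Fits minimize residuals of log-concentration
  (proportional error), the standard choice in population PK. On the
  absolute scale the Michaelis–Menten parameters are practically
  unidentifiable — nonlinear elimination is a few percent of total
  clearance at therapeutic concentrations — whereas the log scale keeps
  the terminal phase informative; noise-free parameter recovery is then
  exact, which the test suite verifies on a single-dose washout design.
* **λ = 0.1 by default.** `choose_lambda()` implements a held-out
  time-point sweep; in the regimes exercised here the held-out residual
  is essentially flat for λ ≤ ~10 (differences well below the
  concentration scale), so the default is chosen jointly with the
  envelope requirement that curves simulated from sampled virtual
  patients stay within the fitted-patient min/max envelope at ≥95% of
  time points. Larger λ narrows the latent box (better containment,
  slightly worse individual fit); 0.1 satisfies both comfortably in the
  packaged configurations.

# Trial engine

Dosing is 750 mg flat every 14 days by default. Published descriptions
of comparable studies state a weight-based 10 mg/kg Q2W in methods but
simulate flat 750 mg Q2W; both modes are supported
(`dose_regimen(mode = "weight_based")` requires a weight), and flat
dosing is the default because the immunogenomic cohort carries no body
weights. Tumor diameters are recorded at weeks 6, 12, 16, then every 8
weeks. RECIST v1.1 is applied per scan: CR below the 0.1 cm detection
floor (a package convention — tumor disappearance has no standard
simulated definition), PR at ≥30% decrease from baseline, PD at ≥20%
*and* ≥5 mm increase from the nadir, SD otherwise; stable disease
requires a qualifying scan at ≥42 days (the week-6 scan satisfies this
by construction), and no confirmation scan is required. Best overall
response is the best category at or before the first PD. A consequence
worth knowing: a steadily growing tumor is SD at week 6 and progresses
later, so its *best overall* response is SD — best-response PD occurs
only when progression is established at the first scan, and the disease
control rate of simulated cohorts is accordingly high.

ORR and DCR are reported overall and in PD-L1 subgroups split at 25%
expression (PD-L1 expression = average density / 1770). Percentile
bootstrap CIs use B = 2000 resamples; the resample size can be matched
to an external trial's subgroup sizes. Exposure metrics (Cmax, Cmin,
AUC over the first interval and the steady-state interval from week 16,
accumulation indices) are trapezoid-based.

# Biomarker analytics

Wilcoxon rank-sum tests compare responders and non-responders (exact
enumeration for combined n ≤ 12 without ties, continuity-corrected
normal approximation otherwise; the two branches agree to ~0.02 at the
boundary). Quintile response tables split patients into five contiguous
groups (remainder to the first groups). Random forests use 500 trees,
each trained on a two-thirds subsample drawn *without* replacement, with
permutation (mean-decrease-accuracy) importance and out-of-bag error;
tree depth and variables-per-split are the `randomForest` defaults, as
no tuning is published for this use. ROC analysis reports the trapezoid
auROC and the largest threshold achieving the target sensitivity (80%
default); MDSC density is negated before ROC because low MDSC predicts
response. CD8 densities can be converted to the 2-D (cells/mm²) scale of
digital pathology with a linear effective-thickness model
(`t_eff = 0.004 + 0.00694` mm, slide thickness plus a mean cell
diameter) — a declared surrogate for stereological conversion formulas,
exact only up to that linear approximation. The correlation screen is
Spearman, robust to the log-scale spread of densities.

# Morris screening

Elementary-effects trajectories are built on an 11-level grid with
Δ = 1/10 — a deliberate fixed-step choice, even though the classical
Morris recommendation is Δ = p/(2(p−1)) — with random base
points, coordinate orders and step signs. Trajectories leaving the unit
hypercube are discarded, as are trajectories containing quantile 0 or 1
for an unbounded log-normal parameter (whose inverse CDF is infinite
there); acceptance fractions of a few percent at d ≈ 15–30 are expected.
Points are mapped to parameters by treating coordinates as quantiles.
EEs are raw quantile-space finite differences (no rescaling by parameter
magnitude), summarized by μ* (mean |EE|) and σ² per parameter. The
default screened set is the varied mechanistic parameters; the default
observable is tumor diameter at day 400 of treatment.

# Numerical settings and problem sizes

Integration uses `lsoda`/`lsodar` with rtol 1e-7 and per-species
absolute tolerances (1e-8 cells; tighter for drug amounts, IFN-γ and
PD-L1); the compiled C right-hand sides in `src/` are bit-compatible
with the R reference implementations within integration tolerance, which
the suite asserts. State positivity is maintained by evaluating rates on
the non-negative part of the state and pulling any negative excursion
back toward zero; recorded states stay above −1e-9 of their scale. kNN
ties are broken by index order; a query coinciding with a sample point
excludes one exact match (its own image), and duplicate sample points at
zero distance raise an error.

The packaged configurations are sized for a single CPU:
`study_config()` carries the full-study design (30,000 plausible
patients, 400 pseudo-patients, k = 500), while `smoke_study_config()` —
used by the examples, the acceptance script and the end-to-end tests —
runs 2,000 plausible patients, 40 pseudo-patients and k = 60, completing
in well under a minute. These sizes are the package's choice of
desk-scale defaults; all of them are configuration, not constants.

# Limitations

* The reduced model is a surrogate: it reproduces named mechanisms and
  headline parameterizations, not the full reaction network of any
  published platform, and its surrogate rate constants are calibrated
  conventions.
* No spatial structure, no new-lesion (metastasis) events — a steadily
  documented limitation of single-lesion RECIST simulation — and no
  coupling between PK covariates and the immunogenomic cohort (the two
  data sources are independent by construction).
* Synthetic generators match marginal/correlation structure only;
  conclusions about real TCGA/popPK data require substituting real
  tables, which the CSV-based stage interfaces support directly.
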