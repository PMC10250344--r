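/* Compiled right-hand sides of the reduced tumor-immune model and of the
 * four-compartment drug-disposition submodel, for use through deSolve's
 * compiled-code interface. These mirror the R reference implementations
 * (vp_derivatives, .rhs_qsp_pk) exactly; parity is asserted in the test
 * suite. Parameter packing order must match .pack_model_parms() /
 * .pack_pk_parms() on the R side. */

#include <R.h>
#include <math.h>

/* ---------------- full tumor-immune model ---------------- */

#define N_MODEL_PARMS 69
static double mp[N_MODEL_PARMS];

/* patient parameters */
#define k_growth mp[0]
#define C_max mp[1]
#define T_PD1 mp[2]
#define C_PDL1_base mp[3]
#define C_CD47 mp[4]
#define n_T1_clones mp[5]
#define n_T0_clones mp[6]
#define k_P1_d1 mp[7]
#define k_MDSC_rec mp[8]
#define k_Mac_rec mp[9]
#define k_M1_pol mp[10]
#define nLNs mp[11]
#define k_T8_act mp[12]
#define k_T4_act mp[13]
#define k_Treg_act mp[14]
#define k_LN_out mp[15]
#define k_T_enter mp[16]
#define k_T_blood_death mp[17]
#define k_T_tumor_death mp[18]
#define k_T8_kill mp[19]
#define k_M1_kill mp[20]
#define k_exhaust mp[21]
#define k_Texh_death mp[22]
#define k_Cx_clear mp[23]
#define k_antigen_shed mp[24]
#define K_antigen mp[25]
#define K_MHC mp[26]
#define k_APC_mat mp[27]
#define APC_pool mp[28]
#define k_APC_death mp[29]
#define nT8_0 mp[30]
#define nT4_0 mp[31]
#define nTreg_0 mp[32]
#define k_nT_repl mp[33]
#define n_clone_expand mp[34]
#define K_T_vol mp[35]
#define K_Treg_supp mp[36]
#define K_MDSC_supp mp[37]
#define K_CD47 mp[38]
#define k_MDSC_death mp[39]
#define k_M1_death mp[40]
#define k_M2_death mp[41]
#define k_M2_pol mp[42]
#define k_IFN_sec mp[43]
#define k_IFN_deg mp[44]
#define IFN_CD8_factor mp[45]
#define K_IFN mp[46]
#define k_PDL1_ind mp[47]
#define k_PDL1_dec mp[48]
#define K_checkpoint mp[49]
#define k_drug_bind mp[50]
#define K_d_drug mp[51]
#define MW_drug mp[52]
#define V_per_tissue mp[53]
#define V_LN_total_mL mp[54]
#define f_int_tumor mp[55]
/* drug-disposition parameters */
#define k_filtration mp[56]
#define V_blood mp[57]
#define f_interstitial mp[58]
#define Cl_lin mp[59]
#define Vmax_nl mp[60]
#define Km_nl mp[61]
/* physical constants */
#define V_cell mp[62]
#define V_Tcell mp[63]
#define V_Mcell mp[64]
#define V_e mp[65]
#define gamma_T mp[66]
#define PDL1_max mp[67]
/* event-location target */
#define root_target mp[68]

/* state indices (canonical ordering) */
#define iC 0
#define iCx 1
#define inT8 2
#define inT4 3
#define inTreg 4
#define imAPC 5
#define iaT8 6
#define iaT4 7
#define iaTreg 8
#define iT8C 9
#define iT4C 10
#define iTregC 11
#define iT8T 12
#define iT4T 13
#define iTregT 14
#define iTexh 15
#define iM1 16
#define iM2 17
#define iMDSC 18
#define iIFN 19
#define iPDL1 20
#define iAC 21
#define iAP 22
#define iAT 23
#define iALN 24
#define NSTATE 25

void vptrial_initmod(void (*odeparms)(int *, double *))
{
    int n = N_MODEL_PARMS;
    odeparms(&n, mp);
}

static double tumor_volume_um3(const double *s)
{
    double T_total = s[iT8T] + s[iT4T] + s[iTregT];
    return (V_cell * (s[iC] + s[iCx]) +
            V_Tcell * (T_total + s[iTexh]) +
            V_Mcell * (s[iM1] + s[iM2])) / V_e;
}

void vptrial_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double s[NSTATE];
    int k;
    for (k = 0; k < NSTATE; k++) s[k] = y[k] > 0 ? y[k] : 0;

    double C = s[iC], Cx = s[iCx];
    double T8T = s[iT8T], T4T = s[iT4T], TregT = s[iTregT], Texh = s[iTexh];
    double M1 = s[iM1], M2 = s[iM2], MDSC = s[iMDSC];
    double IFN = s[iIFN], PDL1 = s[iPDL1];

    double V_um3 = tumor_volume_um3(s);
    double V_mL = V_um3 * 1e-12;
    double V_L = V_um3 * 1e-15;

    double conc_C = s[iAC] / V_blood;
    double V_P_acc = V_per_tissue * f_interstitial;
    double conc_P = s[iAP] / V_P_acc;
    double V_T_acc = V_L * f_int_tumor;
    if (V_T_acc < 1e-12) V_T_acc = 1e-12;
    double conc_T = s[iAT] / V_T_acc;
    double V_LN_acc = V_LN_total_mL * 1e-3 * f_interstitial;
    double conc_LN = s[iALN] / V_LN_acc;

    double occ = k_drug_bind * conc_T / (conc_T + K_d_drug);
    double PDL1_free = PDL1 * (1 - occ);
    double engage = PDL1_free * T_PD1;
    double H_PD1 = engage / (engage + K_checkpoint);

    double dens_Treg = TregT / V_mL;
    double dens_MDSC = MDSC / V_mL;
    double S_Treg = K_Treg_supp / (K_Treg_supp + dens_Treg);
    double S_MDSC = K_MDSC_supp / (K_MDSC_supp + dens_MDSC);
    double S_CD47 = K_CD47 / (K_CD47 + C_CD47);

    double kill_T8 = T8T > 0 ?
        k_T8_kill * C * T8T / (C + T8T) * (1 - H_PD1) * S_Treg * S_MDSC : 0;
    double kill_M1 = M1 > 0 ?
        k_M1_kill * C * M1 / (C + M1) * (1 - H_PD1) * S_CD47 : 0;
    double kill_total = kill_T8 + kill_M1;

    double antigen_flux = k_antigen_shed * C + kill_total;
    double A_factor = antigen_flux / (antigen_flux + K_antigen);
    double MHC = K_MHC / (K_MHC + k_P1_d1);

    double d_mAPC = k_APC_mat * A_factor * APC_pool - k_APC_death * s[imAPC];
    double ln_scale = nLNs / 21.0;
    double act8 = k_T8_act * s[imAPC] * (n_T1_clones / 92.0) * MHC * ln_scale *
        (s[inT8] / nT8_0);
    double act4 = k_T4_act * s[imAPC] * (n_T1_clones / 92.0) * MHC * ln_scale *
        (s[inT4] / nT4_0);
    double actR = k_Treg_act * s[imAPC] * (n_T0_clones / 100.0) * ln_scale *
        (s[inTreg] / nTreg_0);

    double size_fac = V_mL / (V_mL + K_T_vol);
    double enter = k_T_enter * gamma_T * size_fac;
    double egress8 = k_LN_out * s[iaT8];
    double egress4 = k_LN_out * s[iaT4];
    double egressR = k_LN_out * s[iaTreg];
    double in8 = enter * s[iT8C];
    double in4 = enter * s[iT4C];
    double inR = enter * s[iTregC];

    double exhaust = k_exhaust * H_PD1 * T8T;

    double Vm = V_mL > 1e-12 ? V_mL : 1e-12;
    double d_IFN = k_IFN_sec * (IFN_CD8_factor * T8T + T4T) / Vm -
        k_IFN_deg * IFN;
    double H_IFN = IFN / (IFN + K_IFN);
    double d_PDL1 = k_PDL1_ind * H_IFN * (PDL1_max - PDL1) -
        k_PDL1_dec * (PDL1 - C_PDL1_base);

    double Q_P = k_filtration * 86400;
    double Q_T = Q_P * V_L / V_per_tissue;
    double Q_LN = Q_P * (V_LN_total_mL * 1e-3) / V_per_tissue;
    double Vmax_mol = Vmax_nl / (MW_drug * 1e3);
    double Km_mol = Km_nl / (MW_drug * 1e3);
    double elim = Cl_lin * conc_C +
        (conc_C > 0 ? Vmax_mol * conc_C / (conc_C + Km_mol) : 0);
    double flux_P = Q_P * (conc_C - conc_P);
    double flux_T = Q_T * (conc_C - conc_T);
    double flux_LN = Q_LN * (conc_C - conc_LN);

    ydot[iC] = k_growth * C * (1 - C / C_max) - kill_total;
    ydot[iCx] = kill_total - k_Cx_clear * Cx;
    ydot[inT8] = k_nT_repl * (nT8_0 - s[inT8]) - act8 / n_clone_expand;
    ydot[inT4] = k_nT_repl * (nT4_0 - s[inT4]) - act4 / n_clone_expand;
    ydot[inTreg] = k_nT_repl * (nTreg_0 - s[inTreg]) - actR / n_clone_expand;
    ydot[imAPC] = d_mAPC;
    ydot[iaT8] = act8 - egress8;
    ydot[iaT4] = act4 - egress4;
    ydot[iaTreg] = actR - egressR;
    ydot[iT8C] = egress8 - in8 - k_T_blood_death * s[iT8C];
    ydot[iT4C] = egress4 - in4 - k_T_blood_death * s[iT4C];
    ydot[iTregC] = egressR - inR - k_T_blood_death * s[iTregC];
    ydot[iT8T] = in8 - k_T_tumor_death * T8T - exhaust;
    ydot[iT4T] = in4 - k_T_tumor_death * T4T;
    ydot[iTregT] = inR - k_T_tumor_death * TregT;
    ydot[iTexh] = exhaust - k_Texh_death * Texh;
    ydot[iM1] = k_M1_pol * M2 - k_M2_pol * M1 - k_M1_death * M1;
    ydot[iM2] = k_Mac_rec * V_mL - k_M1_pol * M2 + k_M2_pol * M1 -
        k_M2_death * M2;
    ydot[iMDSC] = k_MDSC_rec * V_mL - k_MDSC_death * MDSC;
    ydot[iIFN] = d_IFN;
    ydot[iPDL1] = d_PDL1;
    ydot[iAC] = -flux_P - flux_T - flux_LN - elim;
    ydot[iAP] = flux_P;
    ydot[iAT] = flux_T;
    ydot[iALN] = flux_LN;

    /* pull clipped-at-zero states back toward the admissible region */
    for (k = 0; k < NSTATE; k++)
        if (y[k] < 0) ydot[k] += (0 - y[k]);

    if (ip[0] >= 1) {
        double d_cm = pow(6 * V_um3 / M_PI, 1.0 / 3.0) / 1e4;
        yout[0] = d_cm;
    }
}

/* event location: tumor diameter crosses the preset pre-treatment size */
void vptrial_root(int *neq, double *t, double *y, int *ng, double *gout,
                  double *out, int *ip)
{
    double s[NSTATE];
    int k;
    for (k = 0; k < NSTATE; k++) s[k] = y[k] > 0 ? y[k] : 0;
    double V_um3 = tumor_volume_um3(s);
    gout[0] = pow(6 * V_um3 / M_PI, 1.0 / 3.0) / 1e4 - root_target;
}

/* ---------------- drug-disposition submodel (frozen tumor) ----------- */

#define N_PK_PARMS 10
static double qp[N_PK_PARMS];
#define pk_kf qp[0]         /* k_filtration, L/s */
#define pk_Vb qp[1]         /* V_blood, L */
#define pk_Cl qp[2]         /* Cl_lin, L/day */
#define pk_Vmax_mol qp[3]   /* mol/day */
#define pk_Km_mol qp[4]     /* mol/L */
#define pk_VPacc qp[5]      /* peripheral accessible volume, L */
#define pk_VTacc qp[6]      /* tumor accessible volume, L */
#define pk_VLNacc qp[7]     /* lymph node accessible volume, L */
#define pk_VT_over_VP qp[8] /* V_T_L / V_per_tissue */
#define pk_VLN_over_VP qp[9] /* V_LN_L / V_per_tissue */

void vptrial_pk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PK_PARMS;
    odeparms(&n, qp);
}

void vptrial_pk_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double conc_C = y[0] / pk_Vb;
    double conc_P = y[1] / pk_VPacc;
    double conc_T = y[2] / pk_VTacc;
    double conc_LN = y[3] / pk_VLNacc;
    double Q_P = pk_kf * 86400;
    double Q_T = Q_P * pk_VT_over_VP;
    double Q_LN = Q_P * pk_VLN_over_VP;
    double elim = pk_Cl * conc_C +
        (conc_C > 0 ? pk_Vmax_mol * conc_C / (conc_C + pk_Km_mol) : 0);
    double fP = Q_P * (conc_C - conc_P);
    double fT = Q_T * (conc_C - conc_T);
    double fLN = Q_LN * (conc_C - conc_LN);
    ydot[0] = -fP - fT - fLN - elim;
    ydot[1] = fP;
    ydot[2] = fT;
    ydot[3] = fLN;
}
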