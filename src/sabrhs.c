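/* Compiled right-hand side of the subaerial-biofilm ODE model.
 *
 * Mirrors the R reference implementation sab_rhs() exactly (the two are
 * held equal by tests); exists because a multi-day stiff integration
 * evaluates the derivative hundreds of thousands of times.
 *
 * deSolve compiled-model conventions: parameters arrive through sab_init(),
 * the four forcing channels (T_air, T_stone, RH_air, light) are interpolated
 * by deSolve and exposed through sab_forc().
 */
#include <R.h>
#include <math.h>

#define N_PARMS 68
static double parms[N_PARMS];

/* kinetic block */
#define k_nc parms[0]
#define k_cy parms[1]
#define dk_cy parms[2]
#define k_fix parms[3]
#define k_Nfix parms[4]
#define k_growth_C parms[5]
#define k_growth_H parms[6]
#define k_pol parms[7]
#define k_resp parms[8]
#define k_uptake parms[9]
#define k_scav parms[10]
#define gamma_spec parms[11]
#define K_I parms[12]
#define K_I_inh parms[13]
#define K_I_dark parms[14]
#define K_DIC parms[15]
#define K_TOA parms[16]
#define K_POL parms[17]
#define K_CDB parms[18]
#define K_NDB parms[19]
#define Q_SOC_min parms[20]
#define Q_SOC_max parms[21]
#define Q_N_min parms[22]
#define Q_N_max parms[23]
#define Q_ATP_max parms[24]
#define Q_NADPH_max parms[25]
#define K_ATP parms[26]
#define K_NADPH parms[27]
#define a_w_min parms[28]
#define a_w_peak parms[29]
#define pH_L parms[30]
#define pH_U parms[31]
#define m0 parms[32]
#define m1 parms[33]
#define k_d parms[34]
#define rho parms[35]
#define q_N_bio parms[36]
#define y_ATP_nc parms[37]
#define y_ATP_fix parms[38]
#define y_NADPH_fix parms[39]
#define y_ATP_Nfix parms[40]
#define y_NADPH_Nfix parms[41]
#define y_ATP_growth parms[42]
#define y_NADPH_growth parms[43]
#define y_ATP_pol parms[44]
#define y_ATP_resp parms[45]
#define y_ATP_scav parms[46]
#define strict_hetero_decay parms[47]
#define strict_decay_gamma parms[48]
/* chemistry block */
#define KH_CO2_ref parms[49]
#define vantHoff_CO2 parms[50]
#define KH_O2_ref parms[51]
#define vantHoff_O2 parms[52]
#define T_ref parms[53]
#define pCO2 parms[54]
#define pO2 parms[55]
#define Ka_CO2 parms[56]
#define k_AB_CO2 parms[57]
#define Ka_OA parms[58]
#define k_AB_OA parms[59]
#define Kw parms[60]
#define S_An parms[61]
#define S_Cat parms[62]
/* microclimate block */
#define mag_b parms[63]
#define mag_c parms[64]
#define w_air parms[65]
#define w_film parms[66]
/* run block */
#define extinct_mass parms[67]

static double forc[4]; /* T_air, T_stone, RH_air, light */

void sab_init(void (*odeparms)(int *, double *)) {
  int n = N_PARMS;
  odeparms(&n, parms);
}

void sab_forc(void (*odeforcs)(int *, double *)) {
  int n = 4;
  odeforcs(&n, forc);
}

static double clip01(double x) {
  return x < 0 ? 0 : (x > 1 ? 1 : x);
}
static double dmin2(double a, double b) { return a < b ? a : b; }

void sab_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  double yc[18];
  int j;
  for (j = 0; j < 18; j++) yc[j] = y[j] > 0 ? y[j] : 0;

  double M_C = yc[0], M_H = yc[5];
  double M = M_C + yc[1] + M_H + yc[6] + yc[9] + yc[10];
  double V = M / rho;
  if (V <= 0) {
    for (j = 0; j < 18; j++) ydot[j] = 0;
    return;
  }

  double T_a = forc[0], T_s = forc[1];
  double RH_a = clip01(forc[2]);
  double I = forc[3] > 0 ? forc[3] : 0;
  double T_star = (T_a * w_air + T_s * w_film) / (w_air + w_film);
  double a_w = clip01(RH_a * exp(mag_b * T_a / (mag_c + T_a)
                                 - mag_b * T_star / (mag_c + T_star)));

  double Q_SOC_C = 0, Q_N_C = 0, Q_ATP_C = 0, Q_NADPH_C = 0;
  if (M_C > 1e-12) {
    Q_SOC_C = yc[1] / M_C; Q_N_C = yc[2] / M_C;
    Q_ATP_C = yc[3] / M_C; Q_NADPH_C = yc[4] / M_C;
  }
  double Q_SOC_H = 0, Q_N_H = 0, Q_ATP_H = 0;
  if (M_H > 1e-12) {
    Q_SOC_H = yc[6] / M_H; Q_N_H = yc[7] / M_H; Q_ATP_H = yc[8] / M_H;
  }

  double S_TOA = yc[12] / V;
  double S_OA = yc[13] / V; if (S_OA > S_TOA) S_OA = S_TOA;
  double S_HCO3 = yc[14] / V;
  double T_K = T_star + 273.15;
  double S_CO2 = KH_CO2_ref * exp(vantHoff_CO2 * (1 / T_K - 1 / T_ref)) * pCO2;
  double S_O2 = KH_O2_ref * exp(vantHoff_O2 * (1 / T_K - 1 / T_ref)) * pO2;
  double S_DIC = S_CO2 + S_HCO3;
  double B = S_HCO3 + S_OA + S_An - S_Cat;
  double S_H = (B + sqrt(B * B + 4 * Kw)) / 2;
  double pH = -log10(S_H / 1000);

  double ramp = clip01((a_w - a_w_min) / (1 - a_w_min));
  double tent = clip01(dmin2((a_w - a_w_min) / (a_w_peak - a_w_min),
                             (1 - a_w) / (1 - a_w_peak)));
  double L_mono = I / (K_I + I);
  double I_opt = sqrt(K_I * K_I_inh);
  double L_hald = (I / (K_I + I + I * I / K_I_inh)) /
    (I_opt / (K_I + I_opt + I_opt * I_opt / K_I_inh));
  if (L_hald > 1) L_hald = 1;
  double dark = K_I_dark / (K_I_dark + I);
  double half = (pH_U - pH_L) / 2;
  double phi_pH = clip01((pH - pH_L) * (pH_U - pH) / (half * half));
  double room_ATP = clip01(1 - Q_ATP_C / Q_ATP_max);
  double room_NADPH = clip01(1 - Q_NADPH_C / Q_NADPH_max);
  double room_SOC = clip01(1 - Q_SOC_C / Q_SOC_max);
  double room_N = clip01(1 - Q_N_C / Q_N_max);
  double mono_ATP = Q_ATP_C / (K_ATP + Q_ATP_C);
  double mono_NADPH = Q_NADPH_C / (K_NADPH + Q_NADPH_C);
  double dro_SOC = Q_SOC_C <= 0 ? 0 : clip01(1 - Q_SOC_min / Q_SOC_C);
  double dro_N = Q_N_C <= 0 ? 0 : clip01(1 - Q_N_min / Q_N_C);

  double g_fix = S_DIC <= 0 ? 0 : 1 / (1 + gamma_spec * S_O2 / S_DIC);
  double f_fix = ramp;
  f_fix = dmin2(f_fix, L_mono);
  f_fix = dmin2(f_fix, S_DIC / (K_DIC + S_DIC));
  f_fix = dmin2(f_fix, mono_ATP);
  f_fix = dmin2(f_fix, mono_NADPH);
  f_fix = dmin2(f_fix, room_SOC);
  f_fix = dmin2(f_fix, phi_pH);

  double r1 = k_nc * M_C *
    dmin2(dmin2(ramp, L_hald), dmin2(room_ATP, room_NADPH));
  double r2 = k_cy * M_C * dmin2(dmin2(ramp, L_mono), room_ATP) +
    dk_cy * M_C * dmin2(dmin2(tent, L_mono), room_ATP);
  double r3 = g_fix * k_fix * M_C * f_fix;
  double r4 = (1 - g_fix) * k_fix * M_C * f_fix;
  double r5 = k_Nfix * M_C *
    dmin2(dmin2(ramp, mono_ATP), dmin2(mono_NADPH, room_N));
  double r6 = k_growth_C * M_C *
    dmin2(dmin2(dmin2(dro_SOC, dro_N), dmin2(mono_ATP, mono_NADPH)),
          dmin2(L_mono, ramp));
  double r7 = k_pol * M_C * dmin2(tent, dro_SOC);
  double r8 = k_resp * M_C *
    dmin2(dmin2(ramp, dark), dmin2(dro_SOC, room_ATP));
  double r9 = k_uptake * M_C *
    dmin2(dmin2(ramp, dark), dmin2(S_TOA / (K_TOA + S_TOA), room_SOC));

  double f_star = m0 + m1 * (1 - a_w);
  double omega_C = M_C > 0 ? (y_ATP_nc * r1 + r2 + y_ATP_resp * r8) / M_C : 0;
  double sigma_C = Q_ATP_C / (K_ATP + Q_ATP_C);
  double s_C = f_star > 0 ? dmin2(1, (omega_C / f_star) * sigma_C) : 1;
  double r10 = M_C * (s_C >= 1 ? f_star : omega_C * sigma_C);
  double f_d_C = strict_decay_gamma > 0.5 ? k_d * dmin2(1, s_C)
    : k_d * (1 - s_C);
  double r11 = M_C * f_d_C;

  double room_SOC_H = clip01(1 - Q_SOC_H / Q_SOC_max);
  double room_N_H = clip01(1 - Q_N_H / Q_N_max);
  double room_ATP_H = clip01(1 - Q_ATP_H / Q_ATP_max);
  double mono_ATP_H = Q_ATP_H / (K_ATP + Q_ATP_H);
  double dro_SOC_H = Q_SOC_H <= 0 ? 0 : clip01(1 - Q_SOC_min / Q_SOC_H);
  double dro_N_H = Q_N_H <= 0 ? 0 : clip01(1 - Q_N_min / Q_N_H);
  double S_POL = yc[9] / V, S_CDB = yc[10] / V, S_NDB = yc[11] / V;

  double r12 = k_scav * M_H *
    dmin2(dmin2(ramp, S_POL / (K_POL + S_POL)), room_SOC_H);
  double r13 = k_scav * M_H *
    dmin2(dmin2(ramp, S_CDB / (K_CDB + S_CDB)), room_SOC_H);
  double r14 = k_scav * M_H *
    dmin2(dmin2(ramp, S_NDB / (K_NDB + S_NDB)), room_N_H);
  double r15 = k_uptake * M_H *
    dmin2(dmin2(ramp, S_TOA / (K_TOA + S_TOA)), room_SOC_H);
  double r16 = k_resp * M_H * dmin2(dmin2(ramp, dro_SOC_H), room_ATP_H);
  double r17 = k_growth_H * M_H *
    dmin2(dmin2(dro_SOC_H, dro_N_H), dmin2(mono_ATP_H, ramp));
  double omega_H = M_H > 0 ? y_ATP_resp * r16 / M_H : 0;
  double sigma_H = Q_ATP_H / (K_ATP + Q_ATP_H);
  double s_H = f_star > 0 ? dmin2(1, (omega_H / f_star) * sigma_H) : 1;
  double r18 = M_H * (s_H >= 1 ? f_star : omega_H * sigma_H);
  double f_d_H = strict_decay_gamma > 0.5 ? k_d * dmin2(1, s_H)
    : k_d * (1 - s_H);
  double r19 = (strict_hetero_decay > 0.5 ? M_C : M_H) * f_d_H;

  double beta = S_DIC > 0 ? S_HCO3 / S_DIC : 0;
  double alpha = S_TOA > 0 ? S_OA / S_TOA : 0;
  double r_hyd = k_AB_CO2 * (S_CO2 - S_H * S_HCO3 / Ka_CO2);
  double r_oa = k_AB_OA * (S_OA * (Ka_OA + S_H) - Ka_OA * S_TOA);

  ydot[0] = r6 - r11;                                        /* M_C */
  ydot[1] = r3 - r6 - r7 - r8 + r9 - Q_SOC_C * r11;          /* E_SOC_C */
  ydot[2] = r5 - q_N_bio * r6 - Q_N_C * r11;                 /* E_N_C */
  ydot[3] = y_ATP_nc * r1 + r2 - y_ATP_fix * (r3 + r4)
    - y_ATP_Nfix * r5 - y_ATP_growth * r6 - y_ATP_pol * r7
    + y_ATP_resp * r8 - r10 - Q_ATP_C * r11;                 /* E_ATP_C */
  ydot[4] = r1 - y_NADPH_fix * (r3 + r4) - y_NADPH_Nfix * r5
    - y_NADPH_growth * r6 - Q_NADPH_C * r11;                 /* E_NADPH_C */
  ydot[5] = r17 - r19;                                       /* M_H */
  ydot[6] = r12 + r13 + r15 - r16 - r17 - Q_SOC_H * r19;     /* E_SOC_H */
  ydot[7] = r14 - q_N_bio * r17 - Q_N_H * r19;               /* E_N_H */
  ydot[8] = -y_ATP_scav * (r12 + r13 + r14) + y_ATP_resp * r16
    - y_ATP_growth * r17 - r18 - Q_ATP_H * r19;              /* E_ATP_H */
  ydot[9] = r7 - r12;                                        /* M_POL */
  ydot[10] = (1 + Q_SOC_C) * r11 + (1 + Q_SOC_H) * r19 - r13; /* M_CDB */
  ydot[11] = (Q_N_C + q_N_bio) * r11 + (Q_N_H + q_N_bio) * r19
    - r14;                                                   /* M_NDB */
  ydot[12] = r4 - r9 - r15;                                  /* A_TOA */
  ydot[13] = -alpha * (r9 + r15) - V * r_oa;                 /* A_OA */
  ydot[14] = -beta * (r3 + r4) + r8 + V * r_hyd;             /* A_HCO3 */
  ydot[15] = -(1 - beta) * (r3 + r4) + r16 - V * r_hyd;      /* G_CO2 */
  ydot[16] = 0.5 * r1 - r4 - r8 - r16;                       /* G_O2 */
  ydot[17] = -r5;                                            /* G_N2 */
}

/* extinction root: living biomass (functional + stored carbon of both
 * guilds) crossing the threshold; decayed biomass and polysaccharides are
 * inert leftovers, so they do not count toward viability */
void sab_root(int *neq, double *t, double *y, int *ng, double *gout,
              double *out, int *ip) {
  double M_live = (y[0] > 0 ? y[0] : 0) + (y[1] > 0 ? y[1] : 0)
    + (y[5] > 0 ? y[5] : 0) + (y[6] > 0 ? y[6] : 0);
  gout[0] = M_live - extinct_mass;
}
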