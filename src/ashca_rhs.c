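/* Compiled right-hand side of the 10-state ASH Ca2+ model, in the deSolve
 * compiled-model convention (initmod/derivs + dllname lookup).
 *
 * States (order fixed): c, c_ER, O, I, P0, P1, P2, y, p, V.
 * Parameters (order fixed, see .ash_parms_vector() on the R side):
 *   [0..22]  the 23 free parameters in canonical order
 *   [23..27] gamma, V_max, V_rest, c_ES, RT_zF
 *   [28..34] K1, K2, K3, K4, K5, k2_minus, k4_minus
 *   [35..36] J_Leak, J_Leak_ER
 *   [37..38] stimulus S(t) = a + b*t within the current integration segment
 */
#include <R.h>
#include <math.h>

#define N_PARMS 39
static double parms[N_PARMS];

void initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* x / (exp(x) - 1) with a series guard at the removable singularity */
static double expm1_ratio(double x)
{
    if (fabs(x) < 1e-4)
        return 1.0 - x / 2.0 + x * x / 12.0;
    return x / expm1(x);
}

void derivs(int *neq, double *t, double *y, double *ydot,
            double *yout, int *ip)
{
    const double G_PMCA = parms[0],  K_PMCA = parms[1];
    const double G_SERCA = parms[2], K_SERCA = parms[3];
    const double G_TRPV = parms[4],  G_IPR = parms[5], G_VGCC = parms[6];
    const double k_O = parms[7], k_Om = parms[8];
    const double k_I = parms[9], k_Im = parms[10];
    const double k_P1 = parms[11], k_P1m = parms[12];
    const double k_P2 = parms[13], k_P2m = parms[14], K_P2 = parms[15];
    const double k_P0 = parms[16], k_P0m = parms[17], K_P0 = parms[18];
    const double k_p = parms[19], k_pm = parms[20];
    const double K_p = parms[21], K_c = parms[22];
    const double gamma = parms[23], V_max = parms[24], V_rest = parms[25];
    const double c_ES = parms[26], RT_zF = parms[27];
    const double K1 = parms[28], K2 = parms[29], K3 = parms[30];
    const double K4 = parms[31], K5 = parms[32];
    const double k2m = parms[33], k4m = parms[34];
    const double J_Leak = parms[35], J_Leak_ER = parms[36];
    const double stim_a = parms[37], stim_b = parms[38];

    const double c = y[0], c_ER = y[1], O = y[2], I = y[3];
    const double P0 = y[4], P1 = y[5], P2 = y[6];
    const double yy = y[7], p = y[8], V = y[9];

    const double S = stim_a + stim_b * (*t);

    /* pumps */
    const double J_PMCA = G_PMCA * c * c / (c * c + K_PMCA);
    const double J_SERCA = G_SERCA * c * c / (c * c + K_SERCA);

    /* TRPV */
    const double J_TRPV = G_TRPV * O * I * (c_ES - c);

    /* IPR, reduced De Young-Keizer */
    double frac = p * c * (1.0 - yy) / ((p + K1) * (c + K5));
    const double O_IPR = frac * frac * frac;
    const double J_IPR = G_IPR * O_IPR * (c_ER - c);
    const double phi1 = c * (k4m * K1 * K2 + k2m * K4 * p) /
                        (K4 * K2 * (K1 + p));
    const double phi2 = (k2m * p + k4m * K3) / (K3 + p);

    /* VGCC: GHK with quasi-steady L-type activation */
    const double alpha = 1.6 / (1.0 + exp(-0.072 * (V - 5.0)));
    const double beta = 0.02 * 5.36 * expm1_ratio((V - 1.31) / 5.36);
    const double minf = alpha / (alpha + beta);
    const double x = V / RT_zF;
    double ghk;
    if (fabs(x) < 1e-4)
        ghk = (c_ES * exp(-x) - c) * (1.0 + x / 2.0 + x * x / 12.0);
    else
        ghk = x * (c_ES * exp(-x) - c) / (-expm1(-x));
    const double J_VGCC = G_VGCC * minf * minf * RT_zF * ghk;

    /* graded voltage rates */
    const double ap = expm1_ratio(-26.0 * c + 4.0);
    const double bp = 20.0 * expm1_ratio(13.0 * c - 1.0);

    ydot[0] = J_IPR + J_Leak_ER - J_PMCA - J_SERCA + J_TRPV + J_VGCC + J_Leak;
    ydot[1] = gamma * (J_SERCA - (J_IPR + J_Leak_ER));
    ydot[2] = k_O * P1 * (1.0 - O) - k_Om * O;
    ydot[3] = k_I * (1.0 - I) - k_Im * P2 * I;
    ydot[4] = k_P0 * S / (S + K_P0) - k_P0m * P0;
    ydot[5] = k_P1 * P0 - k_P1m * P1;
    ydot[6] = k_P2 * P0 / (P0 + K_P2) - k_P2m * P2;
    double kp4 = K_p * P2;
    kp4 = kp4 * kp4;
    kp4 = kp4 * kp4;
    ydot[7] = phi1 * (1.0 - yy) - phi2 * yy;
    ydot[8] = k_p * P1 / (1.0 + kp4) * c * c / (c * c + K_c * K_c) - k_pm * p;
    ydot[9] = ap * (V_max - V) - bp * (V - V_rest);
}
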