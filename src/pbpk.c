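/* Right-hand side of the irinotecan PBPK system, in the calling convention
 * of deSolve's compiled-code interface.
 *
 * Five compounds (CPT-11 and metabolites SN-38, SN-38G, NPC, APC), each with
 * compartments: rapid equilibrium, late equilibrium, liver, a serial chain
 * of NT bile-transit compartments, small intestine, large intestine, and
 * cumulative urine, feces and biliary T-tube.  Amounts are parent-mass
 * equivalents (ug/kg): metabolism moves mass 1:1 between compound pools so
 * the total tracks infused radioactivity.
 *
 * State layout, per compound c (block size 8 + NT):
 *   [0] rapid  [1] late  [2] liver  [3..3+NT-1] bile transit
 *   [3+NT] small intestine  [4+NT] large intestine
 *   [5+NT] urine  [6+NT] feces  [7+NT] T-tube
 *
 * Parameter vector (length 61):
 *   [0] Q_H (ml/min/kg)    [1] V_liver (ml/kg)
 *   [2] infusion rate (ug/kg/min)  [3] infusion duration (min)
 *   [4] NT (number of bile transit compartments)
 *   [5] r_T = CL_bile,T / CL_bile,transit (shared across compounds)
 *   [6] CL_CES,1  [7] CL_CES,2  [8] CL_3A4,1  [9] CL_3A4,2  [10] CL_UGT
 *   [11 + 10*c + j], j = 0..9: per-compound Kp_liver, CL_r, CL_bile,
 *     k_feces, k_a, k_LI, k_transit, CL_12, k_21, V_rapid
 * Compound order: 0 CPT-11, 1 SN-38, 2 SN-38G, 3 NPC, 4 APC.
 */

#include <R.h>

#define NPARMS 61
static double parms[NPARMS];

void cnmpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

void cnmpk_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double QH    = parms[0];
    const double VH    = parms[1];
    const double krate = parms[2];
    const double tinf  = parms[3];
    const int    NT    = (int) parms[4];
    const double rT    = parms[5];
    const double CL_CES1 = parms[6], CL_CES2 = parms[7];
    const double CL_3A4_1 = parms[8], CL_3A4_2 = parms[9];
    const double CL_UGT = parms[10];
    const int blk = 8 + NT;

    double Cu[5];              /* liver outflow concentration A/(VH*Kp) */
    double form[5] = {0, 0, 0, 0, 0};
    int c, i;

    for (c = 0; c < 5; c++) {
        double Kp = parms[11 + 10 * c + 0];
        Cu[c] = y[blk * c + 2] / (VH * Kp);
    }
    /* metabolic formation, driven by the source compound's liver conc */
    form[1] = CL_CES1 * Cu[0] + CL_CES2 * Cu[3];   /* SN-38  <- CPT-11, NPC */
    form[2] = CL_UGT * Cu[1];                      /* SN-38G <- SN-38 */
    form[3] = CL_3A4_2 * Cu[0];                    /* NPC    <- CPT-11 */
    form[4] = CL_3A4_1 * Cu[0];                    /* APC    <- CPT-11 */

    for (c = 0; c < 5; c++) {
        const double *p = parms + 11 + 10 * c;
        const double CLr = p[1], CLbile = p[2], kfec = p[3], ka = p[4];
        const double kLI = p[5], ktr = p[6], CL12 = p[7], k21 = p[8];
        const double Vr = p[9];
        double *yc = y + blk * c, *dc = ydot + blk * c;
        double Cr = yc[0] / Vr;
        double CLmet_out =
            (c == 0) ? CL_CES1 + CL_3A4_1 + CL_3A4_2 :
            (c == 1) ? CL_UGT :
            (c == 3) ? CL_CES2 : 0.0;
        double infus = (c == 0 && *t < tinf) ? krate : 0.0;

        /* rapid equilibrium */
        dc[0] = infus + QH * Cu[c] - QH * Cr - CLr * Cr - CL12 * Cr
                + k21 * yc[1];
        /* late equilibrium */
        dc[1] = CL12 * Cr - k21 * yc[1];
        /* liver (well-stirred) */
        dc[2] = QH * Cr - QH * Cu[c]
                - (CLbile * (1.0 + rT) + CLmet_out) * Cu[c]
                + form[c] + ka * yc[3 + NT];
        /* bile transit chain */
        dc[3] = CLbile * Cu[c] - ktr * yc[3];
        for (i = 1; i < NT; i++)
            dc[3 + i] = ktr * (yc[2 + i] - yc[3 + i]);
        /* small intestine */
        dc[3 + NT] = ktr * yc[2 + NT] - (ka + kLI) * yc[3 + NT];
        /* large intestine */
        dc[4 + NT] = kLI * yc[3 + NT] - kfec * yc[4 + NT];
        /* cumulative excreta */
        dc[5 + NT] = CLr * Cr;
        dc[6 + NT] = kfec * yc[4 + NT];
        dc[7 + NT] = rT * CLbile * Cu[c];
    }
}
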