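/* Right-hand side of the glucose -> ROS / metabolic-memory / adaptation
 * system, in the deSolve compiled-model convention.
 *
 * States (y): 0 = ROS, 1 = MM, 2 = AD.
 * Parameters (parms), set per integration segment:
 *   0 GLU_basal  1 ROS_basal  2 ktu_MM  3 ktu_AD  4 ktu_ROS
 *   5 a_rosmm    6 a_gluros   7 Fmax_ad 8 EC50_ad 9 Nh_ad
 *  10 GLU (constant glucose level of the current protocol segment, mM)
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

static double parms[11];

void rosmm_initparms(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void rosmm_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double ROS = y[0], MM = y[1], AD = y[2];
    double glu_ex = parms[10] - parms[0];
    double ros_ex = ROS - parms[1];
    double ad_ef, hill;

    if (glu_ex < 0.0) glu_ex = 0.0;
    if (ros_ex < 0.0) ros_ex = 0.0;

    if (AD <= 0.0) {              /* AD^Nh defined as 0 at AD = 0 (Nh >= 1) */
        ad_ef = 1.0;
    } else {
        hill = pow(AD, parms[9]);
        ad_ef = 1.0 - parms[7] * hill / (hill + pow(parms[8], parms[9]));
    }

    ydot[0] = parms[4] * ((1.0 + (glu_ex * parms[6] + MM) * ad_ef) - ROS);
    ydot[1] = parms[2] * (ros_ex * parms[5] - MM);
    ydot[2] = parms[3] * (glu_ex - AD);

    if (ip[0] >= 1) yout[0] = ad_ef;
}

extern SEXP rosmm_c_solve(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CMethodDef cMethods[] = {
    {"rosmm_initparms", (DL_FUNC) &rosmm_initparms, 1},
    {"rosmm_derivs",    (DL_FUNC) &rosmm_derivs,    6},
    {NULL, NULL, 0}
};

static const R_CallMethodDef callMethods[] = {
    {"rosmm_c_solve", (DL_FUNC) &rosmm_c_solve, 7},
    {NULL, NULL, 0}
};

void R_init_rosmm(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
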