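/* Lorenz vector field in the deSolve compiled-model convention.
   Parameters (a, b, c) are passed once through the init hook. */

static double parms[3];
#define LORENZ_A parms[0]
#define LORENZ_B parms[1]
#define LORENZ_C parms[2]

void lorenz_init(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, parms);
}

void lorenz_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    ydot[0] = LORENZ_A * (y[1] - y[0]);
    ydot[1] = y[0] * (LORENZ_C - y[2]) - y[1];
    ydot[2] = y[0] * y[1] - LORENZ_B * y[2];
}
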