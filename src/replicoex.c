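/* Mass-action right-hand side and analytic Jacobian for template-replicator
 * competition systems.
 *
 * The system descriptor is packed into one numeric vector so that deSolve can
 * call the derivative function directly in compiled code:
 *
 *   p[0] = m   number of monomer types
 *   p[1] = S   number of strand blocks
 *   p[2] = L   sequence length (stages per block)
 *   p[3 .. 3+S-1]            partner block index, 0-based (== s for self-paired)
 *   next S*L doubles         inserted-monomer index per (block, stage), 0-based
 *   next S*L doubles         intermediate degradation rate per (block, stage)
 *   next m doubles           elongation rate constant per monomer
 *   next m doubles           monomer influx per monomer
 *   next m doubles           monomer decay per monomer
 *
 * State layout: for each block s, stages r = 0..L-1 at index s*L + r
 * (r = number of monomers already incorporated into the nascent copy;
 * r = 0 is the free single strand), then the m monomer concentrations.
 *
 * Completion of the last elongation step of block s releases the free
 * template strand (stage 0 of s) and the free copy strand (stage 0 of the
 * partner block); for self-paired strands partner == s, so the block's own
 * stage 0 receives the flux twice.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define RX_MAX_BLOCKS 1024

static double *rx_p = NULL;
static int rx_np = 0;

void rx_init(void (*odeparms)(int *, double *))
{
    static SEXP (*get_gparms)(void) = NULL;
    if (get_gparms == NULL)
        get_gparms = (SEXP (*)(void)) R_GetCCallable("deSolve", "get_deSolve_gparms");
    SEXP gp = get_gparms();
    rx_np = LENGTH(gp);
    rx_p = REAL(gp);
}

static void rx_rhs_core(const double *p, const double *y, double *ydot)
{
    const int m = (int) p[0], S = (int) p[1], L = (int) p[2];
    const double *partner = p + 3;
    const double *ins = partner + S;
    const double *idec = ins + (size_t) S * L;
    const double *elong = idec + (size_t) S * L;
    const double *influx = elong + m;
    const double *mdec = influx + m;
    const int nb = S * L;
    const double *mono = y + nb;
    double *mdot = ydot + nb;
    double J[RX_MAX_BLOCKS];

    for (int j = 0; j < m; j++)
        mdot[j] = influx[j] - mdec[j] * mono[j];

    for (int s = 0; s < S; s++) {
        const int base = s * L;
        double prev = 0.0;
        for (int r = 0; r < L; r++) {
            const int mi = (int) ins[base + r];
            const double flux = elong[mi] * mono[mi] * y[base + r];
            ydot[base + r] = prev - flux - idec[base + r] * y[base + r];
            mdot[mi] -= flux;
            prev = flux;
        }
        J[s] = prev;
    }
    for (int s = 0; s < S; s++) {
        ydot[s * L] += J[s];
        ydot[((int) partner[s]) * L] += J[s];
    }
}

/* deSolve-facing derivative routine */
void rx_deriv(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
    rx_rhs_core(rx_p, y, ydot);
}

/* .Call interface for direct evaluation from R */
SEXP rx_rhs(SEXP parms, SEXP state)
{
    const double *p = REAL(parms);
    const int m = (int) p[0], S = (int) p[1], L = (int) p[2];
    const int n = S * L + m;
    if (LENGTH(state) != n)
        error("state length %d does not match system layout (%d variables)",
              LENGTH(state), n);
    if (S > RX_MAX_BLOCKS)
        error("too many strand blocks (max %d)", RX_MAX_BLOCKS);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    rx_rhs_core(p, REAL(state), REAL(out));
    UNPROTECT(1);
    return out;
}

/* Analytic Jacobian of the mass-action rhs (dense, column-major n x n). */
SEXP rx_jacobian(SEXP parms, SEXP state)
{
    const double *p = REAL(parms);
    const int m = (int) p[0], S = (int) p[1], L = (int) p[2];
    const double *partner = p + 3;
    const double *ins = partner + S;
    const double *idec = ins + (size_t) S * L;
    const double *elong = idec + (size_t) S * L;
    const double *mdec = elong + m + m; /* skip influx */
    const int nb = S * L;
    const int n = nb + m;
    if (LENGTH(state) != n)
        error("state length %d does not match system layout (%d variables)",
              LENGTH(state), n);
    const double *y = REAL(state);
    const double *mono = y + nb;

    SEXP out = PROTECT(allocMatrix(REALSXP, n, n));
    double *jac = REAL(out);
    for (int i = 0; i < (int) ((size_t) n * n); i++)
        jac[i] = 0.0;
#define JAC(i, j) jac[(size_t) (j) * n + (i)]

    for (int s = 0; s < S; s++) {
        const int base = s * L;
        for (int r = 0; r < L; r++) {
            const int mi = (int) ins[base + r];
            const double k = elong[mi] * mono[mi];
            const int row = base + r;
            /* outflow of stage r plus its own decay */
            JAC(row, row) += -k - idec[base + r];
            JAC(row, nb + mi) += -elong[mi] * y[base + r];
            /* inflow into stage r+1 (or completion flux) */
            if (r < L - 1) {
                JAC(row + 1, row) += k;
                JAC(row + 1, nb + mi) += elong[mi] * y[base + r];
            } else {
                const int pb = ((int) partner[s]) * L;
                JAC(base, row) += k;
                JAC(base, nb + mi) += elong[mi] * y[base + r];
                JAC(pb, row) += k;
                JAC(pb, nb + mi) += elong[mi] * y[base + r];
            }
            /* monomer consumption */
            JAC(nb + mi, row) += -k;
            JAC(nb + mi, nb + mi) += -elong[mi] * y[base + r];
        }
    }
    for (int j = 0; j < m; j++)
        JAC(nb + j, nb + j) += -mdec[j];
#undef JAC
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"rx_rhs",      (DL_FUNC) &rx_rhs,      2},
    {"rx_jacobian", (DL_FUNC) &rx_jacobian, 2},
    {NULL, NULL, 0}
};

void R_init_replicoex(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
    /* rx_deriv / rx_init are looked up by name from deSolve */
}
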