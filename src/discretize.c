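#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

/* x*log2(x) with 0 log 0 = 0 */
static double xlog2d(double x) { return x > 0 ? x * log2(x) : 0.0; }

/* count-weighted entropy (count x bits) of class counts cnt[m], total n */
static double went(const double *cnt, int m, double n)
{
    double h = xlog2d(n);
    for (int c = 0; c < m; c++) h -= xlog2d(cnt[c]);
    return h;
}

typedef struct {
    int lo, hi;        /* 0-based inclusive range in the sorted arrays */
    int at;            /* last index of the best left part, -1 if none  */
    double cut;        /* midpoint of the best split                    */
    double delta;     /* best-split entropy minus segment entropy      */
} segment;

/* evaluate a segment: best single split by weighted entropy; ties go to the
 * earliest candidate midpoint.  With mdl != 0 the split must additionally
 * pass the Fayyad-Irani minimum-description-length acceptance test, which
 * rejects cuts whose entropy gain does not beat their coding cost —
 * features holding no class signal then receive no cutoffs at all. */
static void eval_segment(segment *s, const double *v, const int *y, int m,
                         double *cnt, double *lcnt, int mdl)
{
    int lo = s->lo, hi = s->hi;
    double n = (double) (hi - lo + 1);
    for (int c = 0; c < m; c++) cnt[c] = 0.0;
    for (int i = lo; i <= hi; i++) cnt[y[i] - 1] += 1.0;
    double h = went(cnt, m, n);
    s->at = -1;
    s->cut = NA_REAL;
    s->delta = R_PosInf;
    if (hi <= lo) return;
    for (int c = 0; c < m; c++) lcnt[c] = 0.0;
    double best = R_PosInf;
    for (int i = lo; i < hi; i++) {
        lcnt[y[i] - 1] += 1.0;
        if (v[i] >= v[i + 1]) continue;        /* not a distinct-value edge */
        double nl = (double) (i - lo + 1), nr = n - nl;
        double wl = xlog2d(nl), wr = xlog2d(nr);
        for (int c = 0; c < m; c++) {
            wl -= xlog2d(lcnt[c]);
            wr -= xlog2d(cnt[c] - lcnt[c]);
        }
        double w = wl + wr;
        if (w < best) {
            best = w;
            s->at = i;
            s->cut = (v[i] + v[i + 1]) / 2.0;
        }
    }
    if (s->at < 0) return;
    if (mdl) {
        /* recompute class counts of the best left part */
        for (int c = 0; c < m; c++) lcnt[c] = 0.0;
        for (int i = lo; i <= s->at; i++) lcnt[y[i] - 1] += 1.0;
        double nl = (double) (s->at - lo + 1), nr = n - nl;
        int k = 0, k1 = 0, k2 = 0;
        double e = 0.0, e1 = 0.0, e2 = 0.0;
        for (int c = 0; c < m; c++) {
            double rc = cnt[c] - lcnt[c];
            if (cnt[c] > 0) k++;
            if (lcnt[c] > 0) k1++;
            if (rc > 0) k2++;
        }
        e = went(cnt, m, n) / n;
        e1 = went(lcnt, m, nl) / (nl > 0 ? nl : 1);
        for (int c = 0; c < m; c++) lcnt[c] = cnt[c] - lcnt[c];
        e2 = went(lcnt, m, nr) / (nr > 0 ? nr : 1);
        double gain = e - (nl * e1 + nr * e2) / n;
        double delta = log2(pow(3.0, (double) k) - 2.0)
            - (k * e - k1 * e1 - k2 * e2);
        double thr = (log2(n - 1.0) + delta) / n;
        if (gain <= thr) {
            s->at = -1;
            s->cut = NA_REAL;
            return;
        }
    }
    s->delta = best - h;
}

/* greedy top-down entropy cutoffs for one pre-sorted feature */
SEXP C_feature_cutoffs(SEXP v_, SEXP y_, SEXP m_, SEXP maxbins_, SEXP mdl_)
{
    const double *v = REAL(v_);
    const int *y = INTEGER(y_);
    int n = LENGTH(v_);
    int m = asInteger(m_);
    int maxb = asInteger(maxbins_);
    int mdl = asInteger(mdl_);
    if (n < 2 || maxb < 2) return allocVector(REALSXP, 0);

    int maxseg = maxb + 2;
    segment *segs = (segment *) R_alloc(maxseg, sizeof(segment));
    double *cnt = (double *) R_alloc(m, sizeof(double));
    double *lcnt = (double *) R_alloc(m, sizeof(double));
    double *cuts = (double *) R_alloc(maxb, sizeof(double));
    int nseg = 0, ncut = 0;

    segs[0].lo = 0;
    segs[0].hi = n - 1;
    eval_segment(&segs[0], v, y, m, cnt, lcnt, mdl);
    nseg = 1;

    while (ncut < maxb - 1) {
        int k = -1;
        double bestd = -1e-9;               /* require a real reduction */
        for (int i = 0; i < nseg; i++) {
            if (segs[i].delta < bestd) { bestd = segs[i].delta; k = i; }
        }
        if (k < 0) break;
        cuts[ncut++] = segs[k].cut;
        segment parent = segs[k];
        segs[k].lo = parent.lo;
        segs[k].hi = parent.at;
        eval_segment(&segs[k], v, y, m, cnt, lcnt, mdl);
        segs[nseg].lo = parent.at + 1;
        segs[nseg].hi = parent.hi;
        eval_segment(&segs[nseg], v, y, m, cnt, lcnt, mdl);
        nseg++;
    }

    /* sort ascending (ncut <= maxb - 1, insertion sort is plenty) */
    for (int i = 1; i < ncut; i++) {
        double x = cuts[i];
        int j = i - 1;
        while (j >= 0 && cuts[j] > x) { cuts[j + 1] = cuts[j]; j--; }
        cuts[j + 1] = x;
    }
    SEXP out = allocVector(REALSXP, ncut);
    for (int i = 0; i < ncut; i++) REAL(out)[i] = cuts[i];
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_feature_cutoffs", (DL_FUNC) &C_feature_cutoffs, 5},
    {NULL, NULL, 0}
};

void R_init_logiclm(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
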