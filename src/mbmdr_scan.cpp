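#include <Rcpp.h>
#include <Rmath.h>
#include <cstring>

using namespace Rcpp;

// Two-group test from summary statistics. Returns squared statistic (the
// ANOVA-style F for two groups); sign of the mean difference is handled by
// the caller. Writes the decision at level alpha via tcrit2 bracketing for
// Welch (df varies with the variances) or a single critical value for
// Student (df = n - 2 for a two-group partition of all n individuals).
struct TestCtx {
    int kind;          // 0 = pooled-variance Student, 1 = Welch
    double alpha;      // two-sided labeling level
    double critS2;     // Student: qt(1 - alpha/2, n - 2)^2
    double critLo2;    // Welch: qt(...)^2 at df = n - 2 (smallest crit)
    double critHi2;    // Welch: qt(...)^2 at df = minCell - 1 (largest crit)
};

// F value of group A (nA, sumA, ssqA) vs complement within totals
// (n, sumT, ssqT). Returns 0 when the statistic is undefined (zero
// variance); *ok set accordingly.
static inline double two_group_f(int kind, int nA, double sumA, double ssqA,
                                 int n, double sumT, double ssqT,
                                 double *dmean, double *df, bool *ok) {
    const int nB = n - nA;
    const double sumB = sumT - sumA, ssqB = ssqT - ssqA;
    const double mA = sumA / nA, mB = sumB / nB;
    double vA = (ssqA - sumA * mA) / (nA - 1);
    double vB = (ssqB - sumB * mB) / (nB - 1);
    if (vA < 0) vA = 0;  // guard against cancellation
    if (vB < 0) vB = 0;
    const double dm = mA - mB;
    *dmean = dm;
    if (kind == 0) {
        const double sp2 = ((nA - 1) * vA + (nB - 1) * vB) / (n - 2);
        *df = (double)(n - 2);
        if (sp2 <= 0) { *ok = false; return 0.0; }
        *ok = true;
        return dm * dm / (sp2 * (1.0 / nA + 1.0 / nB));
    } else {
        const double a = vA / nA, b = vB / nB, se2 = a + b;
        if (se2 <= 0) { *ok = false; *df = (double)(n - 2); return 0.0; }
        *df = se2 * se2 / (a * a / (nA - 1) + b * b / (nB - 1));
        *ok = true;
        return dm * dm / se2;
    }
}

// Labeling decision: two-sided p <= alpha  <=>  t^2 >= qt(1-alpha/2, df)^2.
static inline bool label_significant(const TestCtx &ctx, double f, double df) {
    if (ctx.kind == 0) return f >= ctx.critS2;
    if (f >= ctx.critHi2) return true;
    if (f < ctx.critLo2) return false;
    const double tc = Rf_qt(1.0 - ctx.alpha / 2.0, df, 1, 0);
    return f >= tc * tc;
}

// MB-MDR scan over all SNP pairs for a set of trait columns.
//
// G: n x m integer matrix of minor-allele counts (0/1/2).
// Y: n x K matrix; column 0 is the observed trait, further columns are
//    permuted copies. Each column is analyzed independently (labeling redone
//    per column), which is what makes the permutation null honest.
// Returns a K x P matrix of step-2 statistics (P = m(m-1)/2 pairs in
// lexicographic order) and, when exportCell >= 0, a K x P matrix of the
// cell-vs-rest F values for that fixed cell (NA where the min-cell rule or
// a degenerate variance makes the test undefined).
// [[Rcpp::export(name = ".mbmdrScanKernel")]]
List mbmdr_scan_kernel(IntegerMatrix G, NumericMatrix Y, int testKind,
                       int minCell, double alphaLabel, int exportCell) {
    const int n = G.nrow(), m = G.ncol(), K = Y.ncol();
    if (Y.nrow() != n) stop("genotype and trait dimensions disagree");
    if (m < 2) stop("need at least two SNPs");
    const int P = m * (m - 1) / 2;

    TestCtx ctx;
    ctx.kind = testKind;
    ctx.alpha = alphaLabel;
    const double q = 1.0 - alphaLabel / 2.0;
    double tc = Rf_qt(q, (double)(n - 2), 1, 0);
    ctx.critS2 = tc * tc;
    ctx.critLo2 = ctx.critS2;
    tc = Rf_qt(q, (double)(minCell > 2 ? minCell - 1 : 1), 1, 0);
    ctx.critHi2 = tc * tc;

    // per-column totals
    std::vector<double> colSum(K), colSsq(K);
    for (int k = 0; k < K; ++k) {
        double s = 0, ss = 0;
        const double *y = &Y(0, k);
        for (int r = 0; r < n; ++r) { s += y[r]; ss += y[r] * y[r]; }
        colSum[k] = s; colSsq[k] = ss;
    }

    NumericMatrix stats(K, P);
    NumericMatrix cellF;
    const bool doCell = exportCell >= 0;
    if (doCell) cellF = NumericMatrix(K, P);

    std::vector<unsigned char> idx(n);
    int pair = 0;
    for (int i = 0; i < m - 1; ++i) {
        const int *gi = &G(0, i);
        for (int j = i + 1; j < m; ++j, ++pair) {
            const int *gj = &G(0, j);
            int nc[9] = {0};
            for (int r = 0; r < n; ++r) {
                const int c = 3 * gi[r] + gj[r];
                idx[r] = (unsigned char)c;
                ++nc[c];
            }
            // cells that can never be tested (size rule) are O for every
            // permutation; mark them once
            bool testable[9];
            for (int c = 0; c < 9; ++c)
                testable[c] = nc[c] >= minCell && n - nc[c] >= minCell;

            for (int k = 0; k < K; ++k) {
                const double *y = &Y(0, k);
                double s[9] = {0}, ssq[9] = {0};
                for (int r = 0; r < n; ++r) {
                    const int c = idx[r];
                    const double v = y[r];
                    s[c] += v;
                    ssq[c] += v * v;
                }
                const double T = colSum[k], Q = colSsq[k];
                // label cells, pool H and L on the fly
                int nH = 0, nL = 0;
                double sH = 0, ssqH = 0, sL = 0, ssqL = 0;
                double dm, df; bool ok;
                for (int c = 0; c < 9; ++c) {
                    if (!testable[c]) {
                        if (doCell && c == exportCell)
                            cellF(k, pair) = NA_REAL;
                        continue;
                    }
                    const double f = two_group_f(testKind, nc[c], s[c],
                                                 ssq[c], n, T, Q,
                                                 &dm, &df, &ok);
                    if (doCell && c == exportCell)
                        cellF(k, pair) = ok ? f : NA_REAL;
                    if (!ok) continue;
                    if (label_significant(ctx, f, df)) {
                        if (dm > 0) { nH += nc[c]; sH += s[c]; ssqH += ssq[c]; }
                        else if (dm < 0) { nL += nc[c]; sL += s[c]; ssqL += ssq[c]; }
                    }
                }
                double fH = 0, fL = 0;
                if (nH >= minCell && n - nH >= minCell) {
                    const double f = two_group_f(testKind, nH, sH, ssqH,
                                                 n, T, Q, &dm, &df, &ok);
                    if (ok) fH = f;
                }
                if (nL >= minCell && n - nL >= minCell) {
                    const double f = two_group_f(testKind, nL, sL, ssqL,
                                                 n, T, Q, &dm, &df, &ok);
                    if (ok) fL = f;
                }
                stats(k, pair) = fH > fL ? fH : fL;
            }
        }
    }

    List out = List::create(_["stats"] = stats);
    if (doCell) out["cellF"] = cellF;
    return out;
}
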