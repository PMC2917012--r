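#include <Rcpp.h>
#include <R_ext/Random.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Maximal squared two-sample t statistic over all circular arcs of x[lo..hi).
// An arc is the index range (i, j] (local, 0-based cumsum indices); its
// complement wraps around. The full circle (i=0, j=n) is excluded.
// Returns {tsq, i, j} with local indices into the piece.
static void max_arc_tsq(const double *x, int n, double &best, int &bi, int &bj) {
    std::vector<double> cs(n + 1), cq(n + 1);
    cs[0] = 0.0; cq[0] = 0.0;
    for (int m = 0; m < n; ++m) {
        cs[m + 1] = cs[m] + x[m];
        cq[m + 1] = cq[m] + x[m] * x[m];
    }
    const double T = cs[n], Q = cq[n];
    const double eps = 1e-12;
    best = -1.0; bi = 0; bj = 0;
    for (int i = 0; i < n; ++i) {
        const double ci = cs[i];
        for (int j = i + 1; j <= n; ++j) {
            const int k = j - i, h = n - k;
            if (h == 0) continue;  // full circle
            const double S = cs[j] - ci;
            const double m1 = S / k, m2 = (T - S) / h;
            const double ss = Q - S * m1 - (T - S) * m2;
            const double d = m1 - m2;
            double tsq;
            if (ss <= eps) {
                tsq = (d * d <= eps) ? 0.0 : R_PosInf;
            } else {
                tsq = d * d * (double)(n - 2) * (double)k * (double)h /
                      (ss * (double)n);
            }
            if (tsq > best) { best = tsq; bi = i; bj = j; }
        }
    }
}

// Permutation p-value decision for the best split of x[0..n): shuffle the
// values, recompute the max arc statistic, count exceedances b.  The add-one
// estimate (b+1)/(B+1) is compared against alpha; the loop stops as soon as
// the estimate can no longer fall below alpha (the decision is then identical
// to the full run because b only grows).
static bool split_significant(const double *x, int n, double tsq_obs,
                              double alpha, int nperm) {
    if (!(tsq_obs > 0)) return false;
    std::vector<double> perm(x, x + n);
    int b = 0;
    for (int p = 0; p < nperm; ++p) {
        for (int m = n - 1; m > 0; --m) {
            int k = (int)R_unif_index((double)(m + 1));
            std::swap(perm[m], perm[k]);
        }
        double t; int i, j;
        max_arc_tsq(perm.data(), n, t, i, j);
        if (t >= tsq_obs) ++b;
        if ((double)(b + 1) >= alpha * (double)(nperm + 1)) return false;
    }
    return (double)(b + 1) < alpha * (double)(nperm + 1);
}

// [[Rcpp::export]]
IntegerVector cbs_chrom_cpp(NumericVector x, double alpha, int nperm) {
    const int n = x.size();
    std::vector<int> bounds;           // split positions: between m-1 and m
    std::vector<std::pair<int,int>> stack;  // [lo, hi) pieces to examine
    if (n >= 3) stack.push_back(std::make_pair(0, n));
    while (!stack.empty()) {
        int lo = stack.back().first, hi = stack.back().second;
        stack.pop_back();
        int len = hi - lo;
        if (len < 3) continue;
        double tsq; int bi, bj;
        max_arc_tsq(&x[lo], len, tsq, bi, bj);
        if (!split_significant(&x[lo], len, tsq, alpha, nperm)) continue;
        // accepted: arc boundaries at local bi and bj (0 or len mean no cut)
        if (bi > 0) bounds.push_back(lo + bi);
        if (bj < len) bounds.push_back(lo + bj);
        int cut1 = lo + (bi > 0 ? bi : bj);
        int cut2 = lo + (bj < len ? bj : bi);
        if (cut1 > cut2) std::swap(cut1, cut2);
        if (cut1 - lo >= 3) stack.push_back(std::make_pair(lo, cut1));
        if (cut2 - cut1 >= 3 && cut2 > cut1)
            stack.push_back(std::make_pair(cut1, cut2));
        if (hi - cut2 >= 3) stack.push_back(std::make_pair(cut2, hi));
    }
    std::sort(bounds.begin(), bounds.end());
    bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
    return wrap(bounds);  // 0-based positions: split before index b
}

// Exhaustive best single circular split (statistic and local arc indices);
// used by the R layer for diagnostics and by tests as a direct handle on the
// search kernel.
// [[Rcpp::export]]
NumericVector max_arc_stat_cpp(NumericVector x) {
    double t; int i, j;
    max_arc_tsq(&x[0], x.size(), t, i, j);
    return NumericVector::create(t, (double)i, (double)j);
}

// GISTIC-style permutation null: each sample's marker-level contribution
// vector is cyclically shifted by an independent uniform offset and the
// shifted columns are summed into a null G vector; all B*M null values are
// pooled.  Returns the pooled null, sorted ascending.
// [[Rcpp::export]]
NumericVector gistic_null_pool_cpp(NumericMatrix contrib, int nperm) {
    const int M = contrib.nrow(), S = contrib.ncol();
    NumericVector pool((R_xlen_t)nperm * M);
    std::vector<double> g(M);
    R_xlen_t out = 0;
    for (int p = 0; p < nperm; ++p) {
        std::fill(g.begin(), g.end(), 0.0);
        for (int s = 0; s < S; ++s) {
            int off = (int)R_unif_index((double)M);
            const double *col = &contrib(0, s);
            int dst = off;
            for (int m = 0; m < M; ++m) {
                g[dst] += col[m];
                if (++dst == M) dst = 0;
            }
        }
        for (int m = 0; m < M; ++m) pool[out++] = g[m];
    }
    std::sort(pool.begin(), pool.end());
    return pool;
}
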