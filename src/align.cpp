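#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap run of length L costs
// gap_open + L * gap_ext (every gap column pays the extension cost, the
// first one additionally pays the opening cost). 'N' never counts as a
// match. Layers: 0 = M (diagonal), 1 = X (gap in b, consumes a),
// 2 = Y (gap in a, consumes b). Traceback tie-break prefers M, then X,
// then Y at every step, which fixes a unique optimal alignment.

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

static inline double sub_score(char x, char y, double match, double mismatch) {
    return (x == y && x != 'N') ? match : mismatch;
}

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b, double match,
                     double mismatch, double gap_open, double gap_ext,
                     bool free_end_gaps) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n == 0 || m == 0) stop("sequences must be non-empty");
    const int W = m + 1;
    std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
    std::vector<double> X((size_t)(n + 1) * W, NEG_INF);
    std::vector<double> Y((size_t)(n + 1) * W, NEG_INF);
    M[0] = 0.0;
    for (int i = 1; i <= n; ++i)
        X[(size_t)i * W] = free_end_gaps ? 0.0 : -(gap_open + i * gap_ext);
    for (int j = 1; j <= m; ++j)
        Y[j] = free_end_gaps ? 0.0 : -(gap_open + j * gap_ext);

    for (int i = 1; i <= n; ++i) {
        const size_t row = (size_t)i * W, up = (size_t)(i - 1) * W;
        for (int j = 1; j <= m; ++j) {
            double s = sub_score(a[i - 1], b[j - 1], match, mismatch);
            double d = std::max(M[up + j - 1], std::max(X[up + j - 1], Y[up + j - 1]));
            M[row + j] = d + s;
            X[row + j] = std::max(M[up + j] - gap_open - gap_ext,
                         std::max(X[up + j] - gap_ext,
                                  Y[up + j] - gap_open - gap_ext));
            Y[row + j] = std::max(M[row + j - 1] - gap_open - gap_ext,
                         std::max(X[row + j - 1] - gap_open - gap_ext,
                                  Y[row + j - 1] - gap_ext));
        }
    }

    // End point: corner for true global; best cell on the last row/column
    // (trailing gaps free) otherwise. Scanned corner-outward so ties keep
    // the fewest free end gaps; layer ties prefer M, then X, then Y.
    int ei = n, ej = m, elayer = 0;
    double best = NEG_INF;
    auto consider = [&](int i, int j) {
        size_t o = (size_t)i * W + j;
        double vals[3] = {M[o], X[o], Y[o]};
        for (int L = 0; L < 3; ++L)
            if (vals[L] > best + EPS) { best = vals[L]; ei = i; ej = j; elayer = L; }
    };
    consider(n, m);
    if (free_end_gaps) {
        for (int j = m - 1; j >= 0; --j) consider(n, j);
        for (int i = n - 1; i >= 0; --i) consider(i, m);
    }

    std::string ra, rb;  // built in reverse
    for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
    for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

    auto pick_layer = [&](int i, int j, double target) {
        size_t o = (size_t)i * W + j;
        double vals[3] = {M[o], X[o], Y[o]};
        for (int L = 0; L < 3; ++L)
            if (std::abs(vals[L] - target) < EPS) return L;
        // numeric fallback: closest layer
        int bl = 0;
        for (int L = 1; L < 3; ++L)
            if (std::abs(vals[L] - target) < std::abs(vals[bl] - target)) bl = L;
        return bl;
    };

    int i = ei, j = ej, layer = elayer;
    while (i > 0 || j > 0) {
        if (j == 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; continue; }
        if (i == 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; continue; }
        size_t o = (size_t)i * W + j;
        if (layer == 0) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
            double target = M[o] - sub_score(a[i - 1], b[j - 1], match, mismatch);
            --i; --j;
            if (i == 0 && j == 0) break;
            layer = pick_layer(i, j, target);
        } else if (layer == 1) {
            ra.push_back(a[i - 1]); rb.push_back('-');
            double v = X[o];
            size_t up = (size_t)(i - 1) * W + j;
            --i;
            if (std::abs(M[up] - gap_open - gap_ext - v) < EPS) layer = 0;
            else if (std::abs(X[up] - gap_ext - v) < EPS) layer = 1;
            else layer = 2;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]);
            double v = Y[o];
            size_t left = (size_t)i * W + j - 1;
            --j;
            if (std::abs(M[left] - gap_open - gap_ext - v) < EPS) layer = 0;
            else if (std::abs(X[left] - gap_open - gap_ext - v) < EPS) layer = 1;
            else layer = 2;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = best);
}

// Exhaustive enumeration of every global alignment (no dynamic
// programming): test oracle for short sequences only.
static double exh(const std::string& a, const std::string& b, int i, int j,
                  int last, double match, double mismatch, double go,
                  double ge) {
    const int n = (int)a.size(), m = (int)b.size();
    if (i == n && j == m) return 0.0;
    double best = NEG_INF;
    if (i < n && j < m) {
        double s = sub_score(a[i], b[j], match, mismatch);
        best = std::max(best, s + exh(a, b, i + 1, j + 1, 0, match, mismatch, go, ge));
    }
    if (i < n) {
        double c = ge + (last == 1 ? 0.0 : go);
        best = std::max(best, -c + exh(a, b, i + 1, j, 1, match, mismatch, go, ge));
    }
    if (j < m) {
        double c = ge + (last == 2 ? 0.0 : go);
        best = std::max(best, -c + exh(a, b, i, j + 1, 2, match, mismatch, go, ge));
    }
    return best;
}

// [[Rcpp::export(name = ".exhaustive_align_score_cpp")]]
double exhaustive_align_score_cpp(std::string a, std::string b, double match,
                                  double mismatch, double gap_open,
                                  double gap_ext) {
    if (a.size() > 12 || b.size() > 12)
        stop("exhaustive search is limited to sequences of length <= 12");
    if (a.empty() || b.empty()) stop("sequences must be non-empty");
    return exh(a, b, 0, 0, 0, match, mismatch, gap_open, gap_ext);
}
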