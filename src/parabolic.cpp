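#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D min-plus transform d(p) = min_q f(q) + kappa * (p - q)^2,
// computed in O(n) via the lower envelope of the parabola family
// (Felzenszwalb-Huttenlocher generalized distance transform).
static void lower_envelope_1d(const double *f, double *d, int n, double kappa) {
    if (n == 1) { d[0] = f[0]; return; }
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double s;
        for (;;) {
            int vk = v[k];
            s = ((f[q] + kappa * q * q) - (f[vk] + kappa * vk * vk)) /
                (2.0 * kappa * (q - vk));
            if (s <= z[k]) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int p = 0; p < n; ++p) {
        while (z[k + 1] < p) ++k;
        double dp = p - v[k];
        d[p] = f[v[k]] + kappa * dp * dp;
    }
}

// Separable parabolic (grayscale) erosion of a matrix:
// e(x) = min_u f(x + u) + kappa * |u|^2, with |u|^2 = du_row^2 + du_col^2
// in pixel units. Columns first, then rows; min-plus transforms commute
// across axes for additively separable structuring functions.
// [[Rcpp::export(name = ".cpp_parabolic_erode")]]
NumericMatrix cpp_parabolic_erode(NumericMatrix x, double kappa) {
    int nr = x.nrow(), nc = x.ncol();
    NumericMatrix out(nr, nc);
    std::vector<double> buf_in(std::max(nr, nc)), buf_out(std::max(nr, nc));

    // pass 1: along each column (varying row index)
    for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) buf_in[i] = x(i, j);
        lower_envelope_1d(buf_in.data(), buf_out.data(), nr, kappa);
        for (int i = 0; i < nr; ++i) out(i, j) = buf_out[i];
    }
    // pass 2: along each row (varying column index)
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) buf_in[j] = out(i, j);
        lower_envelope_1d(buf_in.data(), buf_out.data(), nc, kappa);
        for (int j = 0; j < nc; ++j) out(i, j) = buf_out[j];
    }
    return out;
}
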