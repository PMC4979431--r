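#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grid-bucket spatial index shared by the nearest-neighbour and Matern
// kernels. Bucket width is chosen so buckets hold ~1-2 points on average;
// ring-by-ring scanning guarantees exactness (a point outside Chebyshev
// ring k of the query's bucket is at least k*cell away).
struct PointGrid {
    int nx, ny;
    double xmin, ymin, cell;
    std::vector<std::vector<int> > buckets;
    std::vector<int> cx, cy;

    PointGrid(const NumericVector& x, const NumericVector& y, double cell_) {
        int n = x.size();
        xmin = Rcpp::min(x);
        ymin = Rcpp::min(y);
        double w = Rcpp::max(x) - xmin, h = Rcpp::max(y) - ymin;
        cell = cell_;
        nx = std::max(1, (int)std::floor(w / cell) + 1);
        ny = std::max(1, (int)std::floor(h / cell) + 1);
        buckets.resize((size_t)nx * (size_t)ny);
        cx.resize(n); cy.resize(n);
        for (int i = 0; i < n; i++) {
            int ix = std::min(nx - 1, (int)((x[i] - xmin) / cell));
            int iy = std::min(ny - 1, (int)((y[i] - ymin) / cell));
            cx[i] = ix; cy[i] = iy;
            buckets[(size_t)ix + (size_t)nx * iy].push_back(i);
        }
    }
};

// [[Rcpp::export(name = ".nnd_grid")]]
NumericVector nnd_grid(NumericVector x, NumericVector y) {
    int n = x.size();
    if (n < 2) stop("need at least 2 points");
    double w = Rcpp::max(x) - Rcpp::min(x), h = Rcpp::max(y) - Rcpp::min(y);
    double area = w * h;
    double cell = area > 0 ? std::sqrt(area / n) : 1.0;
    if (cell <= 0) cell = 1.0;
    PointGrid g(x, y, cell);
    int maxring = std::max(g.nx, g.ny);
    NumericVector out(n);
    for (int i = 0; i < n; i++) {
        double best = R_PosInf;
        for (int k = 0; k <= maxring; k++) {
            int lo_x = g.cx[i] - k, hi_x = g.cx[i] + k;
            int lo_y = g.cy[i] - k, hi_y = g.cy[i] + k;
            for (int ix = std::max(0, lo_x); ix <= std::min(g.nx - 1, hi_x); ix++) {
                for (int iy = std::max(0, lo_y); iy <= std::min(g.ny - 1, hi_y); iy++) {
                    int cheb = std::max(std::abs(ix - g.cx[i]), std::abs(iy - g.cy[i]));
                    if (cheb != k) continue;
                    const std::vector<int>& b = g.buckets[(size_t)ix + (size_t)g.nx * iy];
                    for (size_t m = 0; m < b.size(); m++) {
                        int j = b[m];
                        if (j == i) continue;
                        double dx = x[j] - x[i], dy = y[j] - y[i];
                        double d2 = dx * dx + dy * dy;
                        if (d2 < best) best = d2;
                    }
                }
            }
            double guard = (double)k * cell;
            if (best <= guard * guard) break;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}

// Matern type-II dependent thinning: point i survives iff no other proposal
// point with a strictly smaller birth mark lies within distance r.
// [[Rcpp::export(name = ".matern_keep")]]
LogicalVector matern_keep(NumericVector x, NumericVector y,
                          NumericVector mark, double r) {
    int n = x.size();
    LogicalVector keep(n, true);
    if (n < 2 || r <= 0) return keep;
    PointGrid g(x, y, r);
    double r2 = r * r;
    for (int i = 0; i < n; i++) {
        bool ok = true;
        for (int ix = std::max(0, g.cx[i] - 1); ok && ix <= std::min(g.nx - 1, g.cx[i] + 1); ix++) {
            for (int iy = std::max(0, g.cy[i] - 1); ok && iy <= std::min(g.ny - 1, g.cy[i] + 1); iy++) {
                const std::vector<int>& b = g.buckets[(size_t)ix + (size_t)g.nx * iy];
                for (size_t m = 0; m < b.size(); m++) {
                    int j = b[m];
                    if (j == i) continue;
                    double dx = x[j] - x[i], dy = y[j] - y[i];
                    if (dx * dx + dy * dy <= r2 && mark[j] < mark[i]) { ok = false; break; }
                }
            }
        }
        keep[i] = ok;
    }
    return keep;
}
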