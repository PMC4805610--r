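#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Average ranks (ties share the mean rank) and the tie-correction term
// T = sum(t^3 - t) over tie groups, for one series.
static void rank_with_ties(const double *x, int n, double *ranks, double *tieT) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    double T = 0.0;
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
        double avg = 0.5 * (i + j) + 1.0;  // mean of ranks i+1..j+1
        for (int k = i; k <= j; ++k) ranks[idx[k]] = avg;
        double t = j - i + 1;
        T += t * t * t - t;
        i = j + 1;
    }
    *tieT = T;
}

static void neighbor_offsets(int connectivity, std::vector<int> &dx,
                             std::vector<int> &dy, std::vector<int> &dz) {
    for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
            for (int c = -1; c <= 1; ++c) {
                int s = std::abs(a) + std::abs(b) + std::abs(c);
                if (s == 0) continue;
                if (connectivity == 6 && s > 1) continue;
                if (connectivity == 18 && s > 2) continue;
                dx.push_back(a); dy.push_back(b); dz.push_back(c);
            }
}

// Voxel-wise Kendall's coefficient of concordance over each in-mask voxel
// and its in-mask neighbors. data: nx*ny*nz*nt array; mask: nx*ny*nz.
// Returns the raw W map (0 outside mask) and the neighborhood size map k.
// [[Rcpp::export]]
List cpp_reho_map(NumericVector data, LogicalVector mask, IntegerVector dims,
                  int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

    // ranks and tie terms for in-mask voxels only
    std::vector<double> ranks((size_t)nvox * nt, 0.0);
    std::vector<double> tieT(nvox, 0.0);
    std::vector<double> series(nt);
    for (R_xlen_t v = 0; v < nvox; ++v) {
        if (!mask[v]) continue;
        for (int t = 0; t < nt; ++t) series[t] = data[v + nvox * t];
        rank_with_ties(series.data(), nt, &ranks[(size_t)v * nt], &tieT[v]);
    }

    std::vector<int> dx, dy, dz;
    neighbor_offsets(connectivity, dx, dy, dz);
    const int noff = (int)dx.size();

    NumericVector W(nvox);
    IntegerVector K(nvox);
    std::vector<double> rsum(nt);
    const double n3n = (double)nt * nt * nt - nt;

    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
                if (!mask[v]) continue;
                for (int t = 0; t < nt; ++t) rsum[t] = ranks[(size_t)v * nt + t];
                double Tsum = tieT[v];
                int k = 1;
                for (int o = 0; o < noff; ++o) {
                    int xx = x + dx[o], yy = y + dy[o], zz = z + dz[o];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                        zz < 0 || zz >= nz) continue;
                    R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                    if (!mask[u]) continue;
                    const double *ru = &ranks[(size_t)u * nt];
                    for (int t = 0; t < nt; ++t) rsum[t] += ru[t];
                    Tsum += tieT[u];
                    ++k;
                }
                double mean_r = k * (nt + 1) * 0.5;
                double S = 0.0;
                for (int t = 0; t < nt; ++t) {
                    double d = rsum[t] - mean_r;
                    S += d * d;
                }
                double denom = (double)k * k * n3n - k * Tsum;
                W[v] = denom > 0 ? 12.0 * S / denom : 0.0;
                K[v] = k;
            }

    W.attr("dim") = IntegerVector::create(nx, ny, nz);
    K.attr("dim") = IntegerVector::create(nx, ny, nz);
    return List::create(_["W"] = W, _["k"] = K);
}

// In-mask neighbors of one voxel (0-based flat indices in, 0-based out).
// [[Rcpp::export]]
IntegerVector cpp_neighbors(int x, int y, int z, LogicalVector mask,
                            IntegerVector dims, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    std::vector<int> dx, dy, dz_;
    neighbor_offsets(connectivity, dx, dy, dz_);
    std::vector<int> out;
    for (size_t o = 0; o < dx.size(); ++o) {
        int xx = x + dx[o], yy = y + dy[o], zz = z + dz_[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
        R_xlen_t u = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[u]) out.push_back((int)u);
    }
    return wrap(out);
}

// Connected-component labeling of a binary 3D image under 6/18/26
// connectivity. Labels are 1..n in order of first (column-major) voxel.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector bin, IntegerVector dims,
                                 int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
    std::vector<int> dx, dy, dz;
    neighbor_offsets(connectivity, dx, dy, dz);
    IntegerVector labels(nvox, 0);
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t v = 0; v < nvox; ++v) {
        if (!bin[v] || labels[v] != 0) continue;
        ++next;
        labels[v] = next;
        stack.push_back(v);
        while (!stack.empty()) {
            R_xlen_t u = stack.back(); stack.pop_back();
            int x = u % nx, y = (u / nx) % ny, z = u / ((R_xlen_t)nx * ny);
            for (size_t o = 0; o < dx.size(); ++o) {
                int xx = x + dx[o], yy = y + dy[o], zz = z + dz[o];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz) continue;
                R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (bin[w] && labels[w] == 0) {
                    labels[w] = next;
                    stack.push_back(w);
                }
            }
        }
    }
    labels.attr("dim") = IntegerVector::create(nx, ny, nz);
    return labels;
}
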