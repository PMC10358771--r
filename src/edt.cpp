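#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) on a
// regular 3D lattice with anisotropic step sizes. Distances are exact for
// point sets living on the lattice, which is why surface elements are
// addressed on the half-integer (doubled) lattice: voxel-face centres have
// coordinates that are integer multiples of half the voxel spacing, so the
// transform returns the true nearest-neighbour distance, not a grid
// approximation.

static const double BIG = 1e30;

// 1D squared-distance transform along a line sampled at spacing `step`.
// Lower envelope of parabolas rooted at physical positions x_q = step * q.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n,
                 double step) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; q++) {
        double xq = step * q, s;
        for (;;) {
            int p = v[k];
            double xp = step * p;
            s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
            if (s > z[k]) break;
            k--;
        }
        k++;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        double xq = step * q;
        while (z[k + 1] < xq) k++;
        double dx = xq - step * v[k];
        d[q] = dx * dx + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector seed, IntegerVector dims,
                    NumericVector step) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
    if (seed.size() != ntot)
        stop("seed length does not match dims");
    NumericVector out(ntot);
    // initialise squared distances: 0 at seeds, +inf elsewhere
    for (R_xlen_t i = 0; i < ntot; i++) out[i] = seed[i] ? 0.0 : BIG;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying index)
    if (nx > 1) {
        for (int kz = 0; kz < nz; kz++)
            for (int jy = 0; jy < ny; jy++) {
                R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)jy * nx;
                for (int i = 0; i < nx; i++) f[i] = out[base + i];
                dt1d(f, d, v, z, nx, step[0]);
                for (int i = 0; i < nx; i++) out[base + i] = d[i];
            }
    }
    // pass along y
    if (ny > 1) {
        for (int kz = 0; kz < nz; kz++)
            for (int ix = 0; ix < nx; ix++) {
                R_xlen_t base = (R_xlen_t)kz * nx * ny + ix;
                for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)j * nx];
                dt1d(f, d, v, z, ny, step[1]);
                for (int j = 0; j < ny; j++) out[base + (R_xlen_t)j * nx] = d[j];
            }
    }
    // pass along z
    if (nz > 1) {
        R_xlen_t planesz = (R_xlen_t)nx * ny;
        for (int jy = 0; jy < ny; jy++)
            for (int ix = 0; ix < nx; ix++) {
                R_xlen_t base = (R_xlen_t)jy * nx + ix;
                for (int kk = 0; kk < nz; kk++) f[kk] = out[base + kk * planesz];
                dt1d(f, d, v, z, nz, step[2]);
                for (int kk = 0; kk < nz; kk++) out[base + kk * planesz] = d[kk];
            }
    }
    for (R_xlen_t i = 0; i < ntot; i++)
        out[i] = (out[i] >= BIG) ? R_PosInf : std::sqrt(out[i]);
    return out;
}
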