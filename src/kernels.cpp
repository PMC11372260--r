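#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Neighbor offsets for 6/18/26 3-D connectivity.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
    std::vector<std::array<int, 3>> offs;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (m == 0) continue;
                if (connectivity == 6 && m > 1) continue;
                if (connectivity == 18 && m > 2) continue;
                offs.push_back({dx, dy, dz});
            }
    return offs;
}

// Label connected foreground (!= 0) voxels of a 3-D volume.
// Returns integer labels 1..K in first-encounter (scan) order; relabeling
// by component size is done on the R side.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dims,
                           int connectivity) {
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");

    IntegerVector labels(n, 0);
    std::vector<std::array<int, 3>> offs = neighbor_offsets(connectivity);
    std::vector<R_xlen_t> stack;
    int next_label = 0;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (mask[i] == 0 || labels[i] != 0) continue;
        ++next_label;
        labels[i] = next_label;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int x = (int)(cur % nx);
            int y = (int)((cur / nx) % ny);
            int z = (int)(cur / ((R_xlen_t)nx * ny));
            for (size_t k = 0; k < offs.size(); ++k) {
                int xx = x + offs[k][0];
                int yy = y + offs[k][1];
                int zz = z + offs[k][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny ||
                    zz < 0 || zz >= nz)
                    continue;
                R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
                if (mask[j] != 0 && labels[j] == 0) {
                    labels[j] = next_label;
                    stack.push_back(j);
                }
            }
        }
    }
    labels.attr("n_components") = next_label;
    return labels;
}

// 1-D convolution along a chosen axis (0 = x, 1 = y, 2 = z) with
// reflective boundary handling; kernel is assumed normalized.
static void conv_axis(std::vector<double>& v, int nx, int ny, int nz,
                      const std::vector<double>& kern, int axis) {
    const int r = ((int)kern.size() - 1) / 2;
    const int len = axis == 0 ? nx : (axis == 1 ? ny : nz);
    if (len == 1 || r == 0) return;
    std::vector<double> line(len), out(len);
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    R_xlen_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
    // iterate over all lines orthogonal to `axis`
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    R_xlen_t st1 = axis == 0 ? sy : sx;
    R_xlen_t st2 = axis == 2 ? sy : sz;
    for (int b = 0; b < n2; ++b) {
        for (int a = 0; a < n1; ++a) {
            R_xlen_t base = (R_xlen_t)a * st1 + (R_xlen_t)b * st2;
            for (int i = 0; i < len; ++i) line[i] = v[base + i * stride];
            for (int i = 0; i < len; ++i) {
                double acc = 0.0;
                for (int k = -r; k <= r; ++k) {
                    int j = i + k;
                    // reflect (half-sample symmetric, repeated as needed)
                    while (j < 0 || j >= len) {
                        if (j < 0) j = -j - 1;
                        if (j >= len) j = 2 * len - j - 1;
                    }
                    acc += line[j] * kern[k + r];
                }
                out[i] = acc;
            }
            for (int i = 0; i < len; ++i) v[base + i * stride] = out[i];
        }
    }
}

// Separable Gaussian blur; sigma_vox gives the per-axis standard deviation
// in voxel units (0 skips that axis).
// [[Rcpp::export(name = ".gauss_blur_cpp")]]
NumericVector gauss_blur_cpp(NumericVector vol, IntegerVector dims,
                             NumericVector sigma_vox) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (vol.size() != n) stop("volume length does not match dims");
    std::vector<double> v(vol.begin(), vol.end());
    for (int axis = 0; axis < 3; ++axis) {
        double s = sigma_vox[axis];
        if (s <= 0) continue;
        int r = (int)std::ceil(4.0 * s);
        std::vector<double> kern(2 * r + 1);
        double sum = 0.0;
        for (int k = -r; k <= r; ++k) {
            kern[k + r] = std::exp(-0.5 * (k / s) * (k / s));
            sum += kern[k + r];
        }
        for (double& w : kern) w /= sum;
        conv_axis(v, nx, ny, nz, kern, axis);
    }
    NumericVector out(n);
    std::copy(v.begin(), v.end(), out.begin());
    return out;
}
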