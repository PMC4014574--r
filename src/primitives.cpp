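// Low-level grid primitives: trilinear / nearest-neighbour sampling of a 3D
// volume at arbitrary voxel coordinates, separable Gaussian smoothing,
// Jacobian determinant of a displacement field, and a per-voxel symmetric
// 3x3 eigensolver for diffusion tensors.
//
// Coordinate contract: points are 1-based voxel-centred coordinates (R array
// convention); a point is out of bounds when any coordinate falls outside
// [1, n_axis], in which case the declared fill value is returned.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double get3(const double* v, int nx, int ny, int i, int j, int k) {
  return v[i + nx * (j + (long long)ny * k)];
}

// [[Rcpp::export(name = ".cpp_interp3")]]
NumericVector cpp_interp3(NumericVector vol, IntegerVector dim,
                          NumericMatrix pts, int mode, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  for (int p = 0; p < n; ++p) {
    double x = pts(p, 0) - 1.0, y = pts(p, 1) - 1.0, z = pts(p, 2) - 1.0;
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0 ||
        !std::isfinite(x) || !std::isfinite(y) || !std::isfinite(z)) {
      out[p] = fill;
      continue;
    }
    if (mode == 1) { // nearest, round half away from interior ties -> lround
      int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
      out[p] = get3(v, nx, ny, i, j, k);
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--; if (j0 == ny - 1) j0--; if (k0 == nz - 1) k0--;
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c000 = get3(v, nx, ny, i0,     j0,     k0);
    double c100 = get3(v, nx, ny, i0 + 1, j0,     k0);
    double c010 = get3(v, nx, ny, i0,     j0 + 1, k0);
    double c110 = get3(v, nx, ny, i0 + 1, j0 + 1, k0);
    double c001 = get3(v, nx, ny, i0,     j0,     k0 + 1);
    double c101 = get3(v, nx, ny, i0 + 1, j0,     k0 + 1);
    double c011 = get3(v, nx, ny, i0,     j0 + 1, k0 + 1);
    double c111 = get3(v, nx, ny, i0 + 1, j0 + 1, k0 + 1);
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable Gaussian smoothing with replicated (nearest) boundary.
// sigma in voxel units per axis.
// [[Rcpp::export(name = ".cpp_smooth3")]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim, NumericVector sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end()), b(a.size());
  const int ns[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis % sigma.size()];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0;
    for (int t = -r; t <= r; ++t) { k[t + r] = std::exp(-0.5 * t * t / (s * s)); ksum += k[t + r]; }
    for (auto& kv : k) kv /= ksum;
    const int n = ns[axis];
    for (long long idx = 0; idx < (long long)nx * ny * nz; ++idx) {
      int i = idx % nx, j = (idx / nx) % ny, kk = idx / ((long long)nx * ny);
      int pos[3] = {i, j, kk};
      double acc = 0;
      for (int t = -r; t <= r; ++t) {
        int q = pos[axis] + t;
        if (q < 0) q = 0; if (q > n - 1) q = n - 1;
        int c[3] = {pos[0], pos[1], pos[2]};
        c[axis] = q;
        acc += k[t + r] * a[c[0] + nx * (c[1] + (long long)ny * c[2])];
      }
      b[idx] = acc;
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Minimum Jacobian determinant of x -> x + u(x) over interior voxels
// (central differences). disp is nx*ny*nz*3.
// [[Rcpp::export(name = ".cpp_jacobian_min")]]
double cpp_jacobian_min(NumericVector disp, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long long nv = (long long)nx * ny * nz;
  const double* u = disp.begin();
  double mn = R_PosInf;
  for (int k = 1; k < nz - 1; ++k)
    for (int j = 1; j < ny - 1; ++j)
      for (int i = 1; i < nx - 1; ++i) {
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* uc = u + c * nv;
          J[0][c] = 0.5 * (get3(uc, nx, ny, i + 1, j, k) - get3(uc, nx, ny, i - 1, j, k));
          J[1][c] = 0.5 * (get3(uc, nx, ny, i, j + 1, k) - get3(uc, nx, ny, i, j - 1, k));
          J[2][c] = 0.5 * (get3(uc, nx, ny, i, j, k + 1) - get3(uc, nx, ny, i, j, k - 1));
        }
        // dT_c/dx_r = delta + dU_c/dx_r ; J[r][c] holds dU_c/dx_r
        double a11 = 1 + J[0][0], a12 = J[0][1], a13 = J[0][2];
        double a21 = J[1][0], a22 = 1 + J[1][1], a23 = J[1][2];
        double a31 = J[2][0], a32 = J[2][1], a33 = 1 + J[2][2];
        double det = a11 * (a22 * a33 - a23 * a32)
                   - a12 * (a21 * a33 - a23 * a31)
                   + a13 * (a21 * a32 - a22 * a31);
        if (det < mn) mn = det;
      }
  return mn;
}

// Central-difference gradient of a 3D volume; one-sided at faces.
// Returns nvox x 3 matrix in voxel units.
// [[Rcpp::export(name = ".cpp_gradient3")]]
NumericMatrix cpp_gradient3(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  NumericMatrix g((long long)nx * ny * nz, 3);
  long long idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
        int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
        g(idx, 0) = (get3(v, nx, ny, ip, j, k) - get3(v, nx, ny, im, j, k)) / (ip - im > 0 ? ip - im : 1);
        g(idx, 1) = (get3(v, nx, ny, i, jp, k) - get3(v, nx, ny, i, jm, k)) / (jp - jm > 0 ? jp - jm : 1);
        g(idx, 2) = (get3(v, nx, ny, i, j, kp) - get3(v, nx, ny, i, j, km)) / (kp - km > 0 ? kp - km : 1);
      }
  return g;
}

// Eigen-decomposition of symmetric diffusion tensors.
// d6: n x 6 matrix, upper-triangular row order (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
// Returns eigenvalues (descending, n x 3) and the principal eigenvector (n x 3).
// [[Rcpp::export(name = ".cpp_tensor_eig")]]
List cpp_tensor_eig(NumericMatrix d6) {
  const int n = d6.nrow();
  NumericMatrix evals(n, 3), pev(n, 3);
  arma::mat33 D;
  arma::vec3 lam;
  arma::mat33 V;
  for (int r = 0; r < n; ++r) {
    D(0, 0) = d6(r, 0); D(0, 1) = d6(r, 1); D(0, 2) = d6(r, 2);
    D(1, 0) = d6(r, 1); D(1, 1) = d6(r, 3); D(1, 2) = d6(r, 4);
    D(2, 0) = d6(r, 2); D(2, 1) = d6(r, 4); D(2, 2) = d6(r, 5);
    arma::eig_sym(lam, V, D); // ascending
    evals(r, 0) = lam(2); evals(r, 1) = lam(1); evals(r, 2) = lam(0);
    pev(r, 0) = V(0, 2); pev(r, 1) = V(1, 2); pev(r, 2) = V(2, 2);
  }
  return List::create(_["values"] = evals, _["vector"] = pev);
}
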