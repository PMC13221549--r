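#include <Rcpp.h>
using namespace Rcpp;

// Per-row minimum squared Euclidean distance from each point of `a` to the
// point set `b`. Points are rows of n x 3 matrices in physical (mm) units.
// Brute force on purpose: boundary point sets in this package are small
// (10^3-10^4 points) and the inner loop vectorises well.
// [[Rcpp::export]]
NumericVector nn_dist_sq(const NumericMatrix& a, const NumericMatrix& b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double x = a(i, 0), y = a(i, 1), z = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = x - b(j, 0), dy = y - b(j, 1), dz = z - b(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// Discrete 3-D convolution with zero padding outside the lattice.
// `x` and `k` are flattened column-major (R array layout); kernel extents
// must be odd so the kernel has a well-defined centre voxel.
// [[Rcpp::export]]
NumericVector conv3d_zero(const NumericVector& x, const IntegerVector& dx,
                          const NumericVector& k, const IntegerVector& dk) {
  const int n1 = dx[0], n2 = dx[1], n3 = dx[2];
  const int k1 = dk[0], k2 = dk[1], k3 = dk[2];
  const int h1 = k1 / 2, h2 = k2 / 2, h3 = k3 / 2;
  NumericVector out(n1 * n2 * n3);

  // scatter formulation: each source voxel deposits the kernel around itself
  for (int c = 0; c < n3; ++c) {
    for (int b = 0; b < n2; ++b) {
      for (int a = 0; a < n1; ++a) {
        const double src = x[a + n1 * (b + n2 * c)];
        if (src == 0.0) continue;
        for (int kc = 0; kc < k3; ++kc) {
          const int oc = c + kc - h3;
          if (oc < 0 || oc >= n3) continue;
          for (int kb = 0; kb < k2; ++kb) {
            const int ob = b + kb - h2;
            if (ob < 0 || ob >= n2) continue;
            for (int ka = 0; ka < k1; ++ka) {
              const int oa = a + ka - h1;
              if (oa < 0 || oa >= n1) continue;
              out[oa + n1 * (ob + n2 * oc)] +=
                src * k[ka + k1 * (kb + k2 * kc)];
            }
          }
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation of a 3-D lattice at arbitrary fractional voxel
// coordinates (0-based, voxel-centre convention). Samples outside the
// lattice use the nearest edge value, clamped per axis.
// [[Rcpp::export]]
NumericVector trilinear_sample(const NumericVector& x, const IntegerVector& dx,
                               const NumericVector& ci, const NumericVector& cj,
                               const NumericVector& ck) {
  const int n1 = dx[0], n2 = dx[1], n3 = dx[2];
  const int n = ci.size();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double fi = ci[p], fj = cj[p], fk = ck[p];
    if (fi < 0) fi = 0; if (fi > n1 - 1) fi = n1 - 1;
    if (fj < 0) fj = 0; if (fj > n2 - 1) fj = n2 - 1;
    if (fk < 0) fk = 0; if (fk > n3 - 1) fk = n3 - 1;
    const int i0 = (int)fi, j0 = (int)fj, k0 = (int)fk;
    const int i1 = i0 + 1 < n1 ? i0 + 1 : i0;
    const int j1 = j0 + 1 < n2 ? j0 + 1 : j0;
    const int k1 = k0 + 1 < n3 ? k0 + 1 : k0;
    const double wi = fi - i0, wj = fj - j0, wk = fk - k0;
    double acc = 0.0;
    for (int kk = 0; kk < 2; ++kk) {
      const int kc = kk ? k1 : k0;
      const double wkk = kk ? wk : 1.0 - wk;
      if (wkk == 0.0) continue;
      for (int jj = 0; jj < 2; ++jj) {
        const int jc = jj ? j1 : j0;
        const double wjj = jj ? wj : 1.0 - wj;
        if (wjj == 0.0) continue;
        for (int ii = 0; ii < 2; ++ii) {
          const int ic = ii ? i1 : i0;
          const double wii = ii ? wi : 1.0 - wi;
          if (wii == 0.0) continue;
          acc += wii * wjj * wkk * x[ic + n1 * (jc + n2 * kc)];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}
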