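#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Centred finite-difference coefficients, 10th order, unit spacing.
// Second derivative (half-width 5) and first derivative.
static const double D2C[6] = {-5269.0 / 1800.0, 5.0 / 3.0, -5.0 / 21.0,
                              5.0 / 126.0, -5.0 / 1008.0, 1.0 / 3150.0};
static const double D1C[5] = {5.0 / 6.0, -5.0 / 21.0, 5.0 / 84.0,
                              -5.0 / 504.0, 1.0 / 1260.0};

// Von Neumann stability limit c*dt/dx for the 2nd-order-time /
// 10th-order-space scheme in 2D: the spatial operator's spectral radius is
// attained at the Nyquist wavenumber in both dimensions, where the symbol
// equals the alternating-sign coefficient sum per dimension.
// [[Rcpp::export]]
double courant_limit_cpp() {
  double s = std::fabs(D2C[0]);
  for (int k = 1; k <= 5; ++k) s += 2.0 * std::fabs(D2C[k]);
  return 2.0 / std::sqrt(2.0 * s);
}

// 10th-order Laplacian with zero (Dirichlet) padding outside the grid.
// Interior is fully unrolled so the compiler can vectorise the i-loop;
// a 5-cell boundary band falls back to the bounds-checked path.
static void lap_cell_checked(const double* u, double* out, int i, int j,
                             int nz, int nx, double inv_dx2) {
  const double* col = u + (size_t)j * nz;
  double acc = 2.0 * D2C[0] * col[i];
  for (int k = 1; k <= 5; ++k) {
    double s = 0.0;
    if (i - k >= 0) s += col[i - k];
    if (i + k < nz) s += col[i + k];
    if (j - k >= 0) s += u[i + (size_t)(j - k) * nz];
    if (j + k < nx) s += u[i + (size_t)(j + k) * nz];
    acc += D2C[k] * s;
  }
  out[i + (size_t)j * nz] = acc * inv_dx2;
}

static void lap_into(const double* u, double* out, int nz, int nx,
                     double inv_dx2) {
  const double a0 = 2.0 * D2C[0], a1 = D2C[1], a2 = D2C[2], a3 = D2C[3],
               a4 = D2C[4], a5 = D2C[5];
  for (int j = 5; j < nx - 5; ++j) {
    const double* c0 = u + (size_t)j * nz;
    const double *l1 = c0 - nz, *l2 = c0 - 2 * nz, *l3 = c0 - 3 * nz,
                 *l4 = c0 - 4 * nz, *l5 = c0 - 5 * nz;
    const double *r1 = c0 + nz, *r2 = c0 + 2 * nz, *r3 = c0 + 3 * nz,
                 *r4 = c0 + 4 * nz, *r5 = c0 + 5 * nz;
    double* o = out + (size_t)j * nz;
    for (int i = 5; i < nz - 5; ++i) {
      double acc = a0 * c0[i] +
                   a1 * (c0[i - 1] + c0[i + 1] + l1[i] + r1[i]) +
                   a2 * (c0[i - 2] + c0[i + 2] + l2[i] + r2[i]) +
                   a3 * (c0[i - 3] + c0[i + 3] + l3[i] + r3[i]) +
                   a4 * (c0[i - 4] + c0[i + 4] + l4[i] + r4[i]) +
                   a5 * (c0[i - 5] + c0[i + 5] + l5[i] + r5[i]);
      o[i] = acc * inv_dx2;
    }
    for (int i = 0; i < 5; ++i) lap_cell_checked(u, out, i, j, nz, nx, inv_dx2);
    for (int i = nz - 5; i < nz; ++i)
      lap_cell_checked(u, out, i, j, nz, nx, inv_dx2);
  }
  for (int j = 0; j < 5; ++j)
    for (int i = 0; i < nz; ++i) lap_cell_checked(u, out, i, j, nz, nx, inv_dx2);
  for (int j = nx - 5; j < nx; ++j)
    for (int i = 0; i < nz; ++i) lap_cell_checked(u, out, i, j, nz, nx, inv_dx2);
}

// out += -(glz * du/dz + glx * du/dx), 10th-order centred first derivatives,
// zero padding. Used for the variable-density term -grad(ln rho).grad(p).
static void vd_term_into(const double* u, const double* glz, const double* glx,
                         double* out, int nz, int nx, double inv_dx) {
  for (int j = 0; j < nx; ++j) {
    for (int i = 0; i < nz; ++i) {
      size_t idx = i + (size_t)j * nz;
      if (glz[idx] == 0.0 && glx[idx] == 0.0) continue;
      double dz = 0.0, dxd = 0.0;
      for (int k = 1; k <= 5; ++k) {
        double sz = 0.0, sx = 0.0;
        if (i + k < nz) sz += u[idx + k];
        if (i - k >= 0) sz -= u[idx - k];
        if (j + k < nx) sx += u[i + (size_t)(j + k) * nz];
        if (j - k >= 0) sx -= u[i + (size_t)(j - k) * nz];
        dz += D1C[k - 1] * sz;
        dxd += D1C[k - 1] * sx;
      }
      out[idx] -= (glz[idx] * dz + glx[idx] * dxd) * inv_dx;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix laplacian_cpp(NumericMatrix field, double dx) {
  int nz = field.nrow(), nx = field.ncol();
  NumericMatrix out(nz, nx);
  lap_into(REAL(field), REAL(out), nz, nx, 1.0 / (dx * dx));
  return out;
}

static bool finite_max(const double* u, size_t n, double* mx) {
  double m = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double a = std::fabs(u[i]);
    if (a > m) m = a;
  }
  *mx = m;
  return std::isfinite(m);
}

// Explicit time stepping of the (optionally variable-density) acoustic wave
// equation on the padded grid:
//   u[n+1] = A (2 u[n] + dt^2 C (L u[n] + vd(u[n]) + s[n])) - AB u[n-1]
// with C = c^2 (diagonal) and A = 1/(1 + g dt), AB = (1 - g dt)/(1 + g dt)
// implementing the friction sponge u_tt = c^2 lap(u) - 2 g u_t (g = damping
// rate, zero in the imaging region), s[n] the injected source
// (amp row n scaled by weight / dx^2 at each source cell). Traces record
// u[n] at the receiver stencils for n = 1..nt (u[1] = 0). Optionally stores
// every snapshot u[1..nt] for the imaging condition.
// [[Rcpp::export]]
List fd_forward_cpp(NumericMatrix c2, Nullable<NumericMatrix> glz_,
                    Nullable<NumericMatrix> glx_, double dx, double dt, int nt,
                    IntegerVector src_cell, IntegerVector src_grp,
                    NumericVector src_w, NumericMatrix amp,
                    IntegerVector rec_cell, IntegerVector rec_grp,
                    NumericVector rec_w, int n_rec, NumericMatrix dampA,
                    NumericMatrix dampAB, bool store) {
  const int nz = c2.nrow(), nx = c2.ncol();
  const size_t N = (size_t)nz * nx;
  const double dt2 = dt * dt;
  const double inv_dx2 = 1.0 / (dx * dx), inv_dx = 1.0 / dx;
  const double* C = REAL(c2);
  const double* A = REAL(dampA);
  const double* AB = REAL(dampAB);
  const bool vd = glz_.isNotNull();
  NumericMatrix glzM, glxM;
  const double *glz = NULL, *glx = NULL;
  if (vd) {
    glzM = NumericMatrix(glz_);
    glxM = NumericMatrix(glx_);
    glz = REAL(glzM);
    glx = REAL(glxM);
  }
  NumericMatrix traces(nt, n_rec);
  NumericVector ust;
  double* us = NULL;
  if (store) {
    ust = NumericVector(Dimension(nz, nx, nt));
    us = REAL(ust);
  }
  std::vector<double> b0(N, 0.0), b1(N, 0.0), tmp(N, 0.0);
  double* up = b0.data();  // u[n-1]
  double* uc = b1.data();  // u[n]
  bool ok = true;
  int bad_step = -1;
  for (int n = 1; n <= nt; ++n) {
    for (int e = 0; e < rec_cell.size(); ++e)
      traces(n - 1, rec_grp[e]) += rec_w[e] * uc[rec_cell[e]];
    if (store) std::copy(uc, uc + N, us + (size_t)(n - 1) * N);
    if (n == nt) break;
    lap_into(uc, tmp.data(), nz, nx, inv_dx2);
    if (vd) vd_term_into(uc, glz, glx, tmp.data(), nz, nx, inv_dx);
    for (int e = 0; e < src_cell.size(); ++e)
      tmp[src_cell[e]] += amp(n - 1, src_grp[e]) * src_w[e] * inv_dx2;
    for (size_t i = 0; i < N; ++i) {
      double un = A[i] * (2.0 * uc[i] + dt2 * C[i] * tmp[i]) - AB[i] * up[i];
      up[i] = un;  // overwrite u[n-1] with u[n+1]
    }
    std::swap(up, uc);
    if ((n & 31) == 0) {
      double mx;
      if (!finite_max(uc, N, &mx) || mx > 1e30) {
        ok = false;
        bad_step = n;
        break;
      }
    }
  }
  List out = List::create(_["traces"] = traces, _["ok"] = ok,
                          _["bad_step"] = bad_step);
  if (store) out["wavefield"] = ust;
  return out;
}

// Discrete adjoint (transpose) of fd_forward_cpp's linear time stepping.
// Backward recursion, n = nt..1 with w[nt+1] = w[nt+2] = 0:
//   w[n] = 2 A w[n+1] + dt^2 L (C A w[n+1]) - AB w[n+2] + R^T r[n]
// where r is injected at the receiver stencils without scaling (R samples u
// directly in the forward map). Also extracts the adjoint-mapped source
// series dt^2 * (C A w[n+1]) at the source stencils (the exact transpose of
// the wavelet-to-traces map, used by the dot-product test). Stores w[1..nt].
// [[Rcpp::export]]
List fd_adjoint_cpp(NumericMatrix c2, double dx, double dt, int nt,
                    NumericMatrix res, IntegerVector rec_cell,
                    IntegerVector rec_grp, NumericVector rec_w,
                    IntegerVector src_cell, IntegerVector src_grp,
                    NumericVector src_w, int n_src, NumericMatrix dampA,
                    NumericMatrix dampAB, bool store) {
  const int nz = c2.nrow(), nx = c2.ncol();
  const size_t N = (size_t)nz * nx;
  const double dt2 = dt * dt;
  const double inv_dx2 = 1.0 / (dx * dx);
  const double* C = REAL(c2);
  const double* A = REAL(dampA);
  const double* AB = REAL(dampAB);
  NumericVector wst;
  double* ws = NULL;
  if (store) {
    wst = NumericVector(Dimension(nz, nx, nt));
    ws = REAL(wst);
  }
  NumericMatrix adjsrc(nt, n_src);
  std::vector<double> w1(N, 0.0), w2(N, 0.0), gcw(N, 0.0), lapb(N, 0.0);
  double* wn1 = w1.data();  // w[n+1]
  double* wn2 = w2.data();  // w[n+2]
  bool ok = true;
  int bad_step = -1;
  for (int n = nt; n >= 1; --n) {
    // gcw = C * (A * w[n+1]); adjoint source extraction uses it too
    for (size_t i = 0; i < N; ++i) gcw[i] = C[i] * A[i] * wn1[i];
    for (int e = 0; e < src_cell.size(); ++e)
      adjsrc(n - 1, src_grp[e]) += dt2 * src_w[e] * gcw[src_cell[e]] * inv_dx2;
    lap_into(gcw.data(), lapb.data(), nz, nx, inv_dx2);
    // w[n] written into the w[n+2] buffer, then rotate
    for (size_t i = 0; i < N; ++i)
      wn2[i] = 2.0 * A[i] * wn1[i] + dt2 * lapb[i] - AB[i] * wn2[i];
    for (int e = 0; e < rec_cell.size(); ++e)
      wn2[rec_cell[e]] += rec_w[e] * res(n - 1, rec_grp[e]);
    std::swap(wn1, wn2);  // now wn1 = w[n], wn2 = old w[n+1]
    if (store) std::copy(wn1, wn1 + N, ws + (size_t)(n - 1) * N);
    if ((n & 31) == 0) {
      double mx;
      if (!finite_max(wn1, N, &mx) || mx > 1e30) {
        ok = false;
        bad_step = n;
        break;
      }
    }
  }
  List out = List::create(_["adjsrc"] = adjsrc, _["ok"] = ok,
                          _["bad_step"] = bad_step);
  if (store) out["wavefield"] = wst;
  return out;
}

// Zero-lag imaging condition, exact discrete gradient of the misfit with
// respect to sound speed c on the padded grid:
//   g = -2 c dt^2 A * sum_{n=1}^{nt-1} w[n+1] .* (L u[n] + s[n])
// u slices are u[1..nt] (slice n-1 holds u[n]); w slices likewise.
// Also accumulates the source-illumination map sum_n u[n]^2, the standard
// diagonal preconditioner compensating geometric spreading.
// [[Rcpp::export]]
List grad_correlate_cpp(NumericVector ustore, NumericVector wstore,
                        NumericMatrix c2, NumericMatrix dampA,
                        double dx, double dt, int nt,
                        IntegerVector src_cell, IntegerVector src_grp,
                        NumericVector src_w, NumericMatrix amp) {
  const int nz = c2.nrow(), nx = c2.ncol();
  const size_t N = (size_t)nz * nx;
  const double dt2 = dt * dt;
  const double inv_dx2 = 1.0 / (dx * dx);
  const double* C = REAL(c2);
  const double* A = REAL(dampA);
  const double* us = REAL(ustore);
  const double* ws = REAL(wstore);
  std::vector<double> acc(N, 0.0), lapb(N, 0.0);
  NumericMatrix illum(nz, nx);
  double* ip = REAL(illum);
  for (int n = 1; n <= nt - 1; ++n) {
    const double* un = us + (size_t)(n - 1) * N;   // u[n]
    const double* wn1 = ws + (size_t)n * N;        // w[n+1]
    lap_into(un, lapb.data(), nz, nx, inv_dx2);
    for (int e = 0; e < src_cell.size(); ++e)
      lapb[src_cell[e]] += amp(n - 1, src_grp[e]) * src_w[e] * inv_dx2;
    for (size_t i = 0; i < N; ++i) {
      acc[i] += wn1[i] * lapb[i];
      ip[i] += un[i] * un[i];
    }
  }
  NumericMatrix g(nz, nx);
  double* gp = REAL(g);
  for (size_t i = 0; i < N; ++i)
    gp[i] = -2.0 * std::sqrt(C[i]) * dt2 * A[i] * acc[i];
  return List::create(_["grad"] = g, _["illum"] = illum);
}
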