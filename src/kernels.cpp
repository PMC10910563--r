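#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grid convention: square n x n raster, pixel size px (cm), centred on the
// isocentre. R matrix element (row, col) maps to x = (col - 1 + 0.5 - n/2) px,
// y = (row - 1 + 0.5 - n/2) px; angles are CCW from +x.

// Exact radiological path through the raster for one ray (Siddon-style
// incremental traversal). Accumulates intersection length per material label
// (labels 1..nmat; 0 is background) into out; returns total in-grid length.
static double trace_ray(const IntegerMatrix &labels, double px, int nmat,
                        double sx, double sy, double dx, double dy,
                        double *acc) {
  const int n = labels.nrow();
  const double half = 0.5 * n * px;
  const double inf = std::numeric_limits<double>::infinity();

  double tmin = -inf, tmax = inf;
  if (std::fabs(dx) < 1e-14) {
    if (sx <= -half || sx >= half) return 0.0;
  } else {
    double t1 = (-half - sx) / dx, t2 = (half - sx) / dx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  }
  if (std::fabs(dy) < 1e-14) {
    if (sy <= -half || sy >= half) return 0.0;
  } else {
    double t1 = (-half - sy) / dy, t2 = (half - sy) / dy;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
  }
  if (tmax <= tmin) return 0.0;

  double t = tmin;
  // entry cell
  double ex = sx + (t + 1e-12) * dx, ey = sy + (t + 1e-12) * dy;
  int ix = (int)std::floor((ex + half) / px);
  int iy = (int)std::floor((ey + half) / px);
  if (ix < 0) ix = 0; if (ix > n - 1) ix = n - 1;
  if (iy < 0) iy = 0; if (iy > n - 1) iy = n - 1;

  int step_x = (dx > 0) - (dx < 0);
  int step_y = (dy > 0) - (dy < 0);
  double tdx = (step_x != 0) ? px / std::fabs(dx) : inf;
  double tdy = (step_y != 0) ? px / std::fabs(dy) : inf;
  double tmx = inf, tmy = inf;
  if (step_x > 0)      tmx = ((ix + 1) * px - half - sx) / dx;
  else if (step_x < 0) tmx = (ix * px - half - sx) / dx;
  if (step_y > 0)      tmy = ((iy + 1) * px - half - sy) / dy;
  else if (step_y < 0) tmy = (iy * px - half - sy) / dy;

  double total = 0.0;
  while (t < tmax - 1e-12) {
    double tnext = std::min(std::min(tmx, tmy), tmax);
    double seg = tnext - t;
    if (seg > 0) {
      int lab = labels(iy, ix);
      if (lab > 0 && lab <= nmat) acc[lab - 1] += seg;
      total += seg;
    }
    if (tmx <= tmy && tmx <= tmax) { ix += step_x; tmx += tdx; }
    else if (tmy < tmx && tmy <= tmax) { iy += step_y; tmy += tdy; }
    t = tnext;
    if (ix < 0 || ix >= n || iy < 0 || iy >= n) break;
  }
  return total;
}

// [[Rcpp::export]]
List cpp_siddon_all(IntegerMatrix labels, double px, int nmat,
                    NumericVector sx, NumericVector sy,
                    NumericVector dx, NumericVector dy) {
  const int nr = sx.size();
  NumericMatrix out(nr, nmat);
  NumericVector total(nr);
  std::vector<double> acc(nmat);
  for (int r = 0; r < nr; ++r) {
    std::fill(acc.begin(), acc.end(), 0.0);
    total[r] = trace_ray(labels, px, nmat, sx[r], sy[r], dx[r], dy[r],
                         acc.data());
    for (int m = 0; m < nmat; ++m) out(r, m) = acc[m];
  }
  return List::create(_["lengths"] = out, _["total"] = total);
}

// Weighted line integral of a continuous image (value x length, cm units).
// [[Rcpp::export]]
NumericVector cpp_project_image(NumericMatrix img, double px,
                                NumericVector sx, NumericVector sy,
                                NumericVector dx, NumericVector dy) {
  const int n = img.nrow(), nr = sx.size();
  const double half = 0.5 * n * px;
  const double inf = std::numeric_limits<double>::infinity();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    double Sx = sx[r], Sy = sy[r], Dx = dx[r], Dy = dy[r];
    double tmin = -inf, tmax = inf;
    bool miss = false;
    if (std::fabs(Dx) < 1e-14) { if (Sx <= -half || Sx >= half) miss = true; }
    else {
      double t1 = (-half - Sx) / Dx, t2 = (half - Sx) / Dx;
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
    }
    if (std::fabs(Dy) < 1e-14) { if (Sy <= -half || Sy >= half) miss = true; }
    else {
      double t1 = (-half - Sy) / Dy, t2 = (half - Sy) / Dy;
      if (t1 > t2) std::swap(t1, t2);
      tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
    }
    if (miss || tmax <= tmin) { out[r] = 0.0; continue; }
    double t = tmin;
    double ex = Sx + (t + 1e-12) * Dx, ey = Sy + (t + 1e-12) * Dy;
    int ix = (int)std::floor((ex + half) / px);
    int iy = (int)std::floor((ey + half) / px);
    if (ix < 0) ix = 0; if (ix > n - 1) ix = n - 1;
    if (iy < 0) iy = 0; if (iy > n - 1) iy = n - 1;
    int step_x = (Dx > 0) - (Dx < 0);
    int step_y = (Dy > 0) - (Dy < 0);
    double tdx = (step_x != 0) ? px / std::fabs(Dx) : inf;
    double tdy = (step_y != 0) ? px / std::fabs(Dy) : inf;
    double tmx = inf, tmy = inf;
    if (step_x > 0)      tmx = ((ix + 1) * px - half - Sx) / Dx;
    else if (step_x < 0) tmx = (ix * px - half - Sx) / Dx;
    if (step_y > 0)      tmy = ((iy + 1) * px - half - Sy) / Dy;
    else if (step_y < 0) tmy = (iy * px - half - Sy) / Dy;
    double s = 0.0;
    while (t < tmax - 1e-12) {
      double tnext = std::min(std::min(tmx, tmy), tmax);
      double seg = tnext - t;
      if (seg > 0) s += seg * img(iy, ix);
      if (tmx <= tmy && tmx <= tmax) { ix += step_x; tmx += tdx; }
      else if (tmy < tmx && tmy <= tmax) { iy += step_y; tmy += tdy; }
      t = tnext;
      if (ix < 0 || ix >= n || iy < 0 || iy >= n) break;
    }
    out[r] = s;
  }
  return out;
}

// Polychromatic detected signal per ray. lengths: nrays x nmat (cm);
// mulin: nbins x nmat linear attenuation (1/cm) per packaged label material;
// srcw: photons-per-bin x eta; dw: detector weight D(E). With noise, each
// energy bin draws an independent Poisson count (compound Poisson model),
// using R's RNG so set.seed() makes runs reproducible.
// [[Rcpp::export]]
List cpp_poly_signal(NumericMatrix lengths, NumericMatrix mulin,
                     NumericVector srcw, NumericVector dw, bool noise) {
  const int nr = lengths.nrow(), nmat = lengths.ncol(), nb = mulin.nrow();
  NumericVector lam(nr), var(nr);
  for (int r = 0; r < nr; ++r) {
    double s = 0.0, v = 0.0;
    for (int b = 0; b < nb; ++b) {
      double expo = 0.0;
      for (int m = 0; m < nmat; ++m) expo += mulin(b, m) * lengths(r, m);
      double mean_b = srcw[b] * std::exp(-expo);
      if (noise) {
        double cnt = R::rpois(mean_b);
        s += dw[b] * cnt;
      } else {
        s += dw[b] * mean_b;
      }
      v += dw[b] * dw[b] * mean_b;
    }
    lam[r] = s; var[r] = v;
  }
  return List::create(_["lambda"] = lam, _["variance"] = var);
}

struct GnModel {
  const NumericMatrix &mu1, &mu2;
  const NumericVector &c1, &d1, &c2, &d2;
  // moments and analytic Jacobian at (At, Ab)
  void eval(double At, double Ab, double lam[2], double var[2],
            double jt[2], double jb[2]) const {
    lam[0] = lam[1] = var[0] = var[1] = 0;
    jt[0] = jt[1] = jb[0] = jb[1] = 0;
    const int nb1 = mu1.nrow(), nb2 = mu2.nrow();
    // skip zero-fluence bins (0 x exp(huge) would poison the sums) and cap
    // the exponent so negative iterates stay finite for the line search
    for (int b = 0; b < nb1; ++b) {
      if (c1[b] <= 0) continue;
      double ex = -mu1(b, 0) * At - mu1(b, 1) * Ab;
      double w = c1[b] * std::exp(ex > 500 ? 500 : ex);
      double wl = d1[b] * w;
      lam[0] += wl; var[0] += d1[b] * wl;
      jt[0] -= wl * mu1(b, 0); jb[0] -= wl * mu1(b, 1);
    }
    for (int b = 0; b < nb2; ++b) {
      if (c2[b] <= 0) continue;
      double ex = -mu2(b, 0) * At - mu2(b, 1) * Ab;
      double w = c2[b] * std::exp(ex > 500 ? 500 : ex);
      double wl = d2[b] * w;
      lam[1] += wl; var[1] += d2[b] * wl;
      jt[1] -= wl * mu2(b, 0); jb[1] -= wl * mu2(b, 1);
    }
  }
  // weighted objective at fixed variance weights
  double objective(double At, double Ab, const double mh[2],
                   const double wgt[2]) const {
    double lam[2], var[2], jt[2], jb[2];
    eval(At, Ab, lam, var, jt, jb);
    if (!std::isfinite(lam[0]) || !std::isfinite(lam[1]))
      return std::numeric_limits<double>::infinity();
    double r0 = mh[0] - lam[0], r1 = mh[1] - lam[1];
    return r0 * r0 * wgt[0] + r1 * r1 * wgt[1];
  }
};

// Per-ray Gauss-Newton two-material decomposition of a dual-energy
// measurement pair. Forward model per spectrum: lambda(A) = sum_b c_b D_b
// exp(-mt_b At - mb_b Ab); objective sum_i (mhat_i - lambda_i)^2 / sigma_i^2
// with sigma^2 recomputed from the current iterate (iteratively reweighted)
// and a backtracking line search on each step. Warm start from the previous
// ray's solution when it converged.
// [[Rcpp::export]]
List cpp_gn_decompose(NumericVector m1, NumericVector m2,
                      NumericMatrix mu1, NumericVector c1, NumericVector d1,
                      NumericMatrix mu2, NumericVector c2, NumericVector d2,
                      NumericVector init_t, NumericVector init_b,
                      int max_iter, double tol) {
  const int nr = m1.size();
  NumericVector at(nr), ab(nr), resid(nr);
  IntegerVector iters(nr);
  LogicalVector conv(nr);
  GnModel mod{mu1, mu2, c1, d1, c2, d2};
  const double a_cap = 2000.0;   // |A| bound (g/cm^2), guards overflow

  bool have_prev = false;
  double prev_t = 0.0, prev_b = 0.0;

  for (int r = 0; r < nr; ++r) {
    double At = have_prev ? prev_t : init_t[r];
    double Ab = have_prev ? prev_b : init_b[r];
    double mh[2] = { m1[r], m2[r] };
    bool ok = false;
    double rnorm = NA_REAL;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      double lam[2], var[2], jt[2], jb[2];
      mod.eval(At, Ab, lam, var, jt, jb);
      double wgt[2], h11 = 0, h12 = 0, h22 = 0, g1 = 0, g2 = 0, obj = 0;
      bool bad = false;
      for (int i = 0; i < 2; ++i) {
        if (!std::isfinite(var[i]) || var[i] <= 0) { bad = true; break; }
        wgt[i] = 1.0 / var[i];
        double res = mh[i] - lam[i];
        obj += res * res * wgt[i];
        h11 += wgt[i] * jt[i] * jt[i];
        h12 += wgt[i] * jt[i] * jb[i];
        h22 += wgt[i] * jb[i] * jb[i];
        g1 += wgt[i] * jt[i] * res;
        g2 += wgt[i] * jb[i] * res;
      }
      if (bad) break;
      rnorm = obj;
      double det = h11 * h22 - h12 * h12;
      if (!std::isfinite(det) || std::fabs(det) < 1e-300) break;
      double st = (h22 * g1 - h12 * g2) / det;
      double sb = (h11 * g2 - h12 * g1) / det;
      // backtracking: halve the step until the (frozen-weight) objective
      // does not increase
      double step = 1.0;
      double At2 = At + st, Ab2 = Ab + sb;
      for (int ls = 0; ls < 30; ++ls) {
        At2 = At + step * st; Ab2 = Ab + step * sb;
        if (std::fabs(At2) < a_cap && std::fabs(Ab2) < a_cap &&
            mod.objective(At2, Ab2, mh, wgt) <= obj * (1 + 1e-12)) break;
        step *= 0.5;
      }
      At = At2; Ab = Ab2;
      double rel = step * std::sqrt(st * st + sb * sb) /
        std::max(1.0, std::sqrt(At * At + Ab * Ab));
      if (rel < tol) { ok = true; ++it; break; }
    }
    at[r] = At; ab[r] = Ab; iters[r] = it; conv[r] = ok; resid[r] = rnorm;
    if (ok) { prev_t = At; prev_b = Ab; have_prev = true; }
    else have_prev = false;
  }
  return List::create(_["a_tissue"] = at, _["a_bone"] = ab,
                      _["iterations"] = iters, _["converged"] = conv,
                      _["residual"] = resid);
}

// Equiangular fan-beam backprojection with inverse-square distance weighting.
// q: n_views x n_channels filtered projections; beta: source angles (rad);
// channel k has fan angle gamma0 + k * dgamma; source at Rsi (cos b, sin b).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix q, NumericVector beta,
                              double gamma0, double dgamma, double Rsi,
                              int n, double px) {
  const int nv = q.nrow(), nc = q.ncol();
  NumericMatrix img(n, n);
  const double dbeta = 2.0 * M_PI / nv;
  for (int v = 0; v < nv; ++v) {
    double cb = std::cos(beta[v]), sb = std::sin(beta[v]);
    double Sx = Rsi * cb, Sy = Rsi * sb;
    // central-ray direction (unit, toward isocentre)
    double ux = -cb, uy = -sb;
    for (int iy = 0; iy < n; ++iy) {
      double y = (iy + 0.5 - 0.5 * n) * px;
      double vy = y - Sy;
      for (int ix = 0; ix < n; ++ix) {
        double x = (ix + 0.5 - 0.5 * n) * px;
        double vx = x - Sx;
        double L2 = vx * vx + vy * vy;
        double gam = std::atan2(ux * vy - uy * vx, ux * vx + uy * vy);
        double u = (gam - gamma0) / dgamma;
        int k = (int)std::floor(u);
        if (k < 0 || k >= nc - 1) continue;
        double fr = u - k;
        double val = (1.0 - fr) * q(v, k) + fr * q(v, k + 1);
        img(iy, ix) += dbeta * val / L2;
      }
    }
  }
  return img;
}
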