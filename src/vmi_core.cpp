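#include <Rcpp.h>
using namespace Rcpp;

// Shell-projection geometry used by both the forward model and the peeling
// inversion.  A unit shell occupies radii [R-1/2, R+1/2] with volume density
// 1/(4 pi r^2 w); its line-of-sight projection onto the detector plane at
// in-plane radius rho has the closed-form radial factor below (the angular
// Legendre factor is evaluated at cos(theta) = z/R, the thin-shell limit).

static inline double P2(double x) { return 0.5 * (3.0 * x * x - 1.0); }
static inline double P4(double x) {
  double x2 = x * x;
  return 0.125 * (35.0 * x2 * x2 - 30.0 * x2 + 3.0);
}

// integral of dr / (r sqrt(r^2 - rho^2)) over [max(R-1/2, rho), R+1/2]
static double radint(double rho, double R) {
  double Rlo = R - 0.5, Rhi = R + 0.5;
  if (rho >= Rhi) return 0.0;
  double lo = Rlo > rho ? Rlo : rho;
  if (rho < 1e-9) return 1.0 / lo - 1.0 / Rhi;
  double a = rho / Rhi;
  double b = rho / lo;
  if (b > 1.0) b = 1.0;
  return (std::acos(a) - std::acos(b)) / rho;
}

// Forward-project a radial spectrum (counts per unit-width shell at integer
// radii 1..nR) with per-shell beta2/beta4 onto an nx x ny pixel grid.
// Polarisation axis is the image vertical; centre (cx, cy) in fractional
// pixel coordinates, pixel (0,0) top-left, x rightward, y downward.
// [[Rcpp::export]]
NumericMatrix cpp_project_shells(NumericVector S, NumericVector beta2,
                                 NumericVector beta4, int nx, int ny,
                                 double cx, double cy) {
  int nR = S.size();
  const double inv2pi = 1.0 / (2.0 * M_PI);
  NumericMatrix img(ny, nx);
  for (int j = 0; j < nx; ++j) {
    double dx = j - cx;
    for (int i = 0; i < ny; ++i) {
      double dz = -(i - cy);  // vertical = polarisation axis
      double rho = std::sqrt(dx * dx + dz * dz);
      int Rmin = (int)std::floor(rho - 0.5) + 1;
      if (Rmin < 1) Rmin = 1;
      double acc = 0.0;
      for (int R = Rmin; R <= nR; ++R) {
        double sR = S[R - 1];
        if (sR == 0.0 && beta2[R - 1] == 0.0 && beta4[R - 1] == 0.0) continue;
        double w = radint(rho, (double)R);
        if (w <= 0.0) continue;
        double u = dz / R;
        if (u > 1.0) u = 1.0; else if (u < -1.0) u = -1.0;
        acc += sR * w * (1.0 + beta2[R - 1] * P2(u) + beta4[R - 1] * P4(u));
      }
      img(i, j) = acc * inv2pi;
    }
  }
  return img;
}

static inline double bilinear(const NumericMatrix &img, double x, double y) {
  int nx = img.ncol(), ny = img.nrow();
  if (x < 0.0) x = 0.0; if (x > nx - 1.0) x = nx - 1.0;
  if (y < 0.0) y = 0.0; if (y > ny - 1.0) y = ny - 1.0;
  int ix = (int)std::floor(x); if (ix > nx - 2) ix = nx - 2;
  int iy = (int)std::floor(y); if (iy > ny - 2) iy = ny - 2;
  double fx = x - ix, fy = y - iy;
  return img(iy, ix) * (1 - fx) * (1 - fy) + img(iy, ix + 1) * fx * (1 - fy) +
         img(iy + 1, ix) * (1 - fx) * fy + img(iy + 1, ix + 1) * fx * fy;
}

// Resample onto an (r, theta) grid, theta measured from the (vertical)
// polarisation axis over [0, pi/2], averaging the four reflection-symmetric
// quadrant samples.
// [[Rcpp::export]]
NumericMatrix cpp_to_polar(NumericMatrix img, double cx, double cy, int nr,
                           int ntheta) {
  NumericMatrix polar(nr, ntheta);
  for (int it = 0; it < ntheta; ++it) {
    double theta = (it + 0.5) * (M_PI / 2.0) / ntheta;
    double ct = std::cos(theta), st = std::sin(theta);
    for (int ir = 0; ir < nr; ++ir) {
      double r = ir + 1.0;
      double dh = r * st;  // horizontal offset
      double dv = r * ct;  // vertical offset (along polarisation)
      double v = bilinear(img, cx + dh, cy + dv) +
                 bilinear(img, cx + dh, cy - dv) +
                 bilinear(img, cx - dh, cy + dv) +
                 bilinear(img, cx - dh, cy - dv);
      polar(ir, it) = 0.25 * v;
    }
  }
  return polar;
}

// Solve the small (2x2 or 3x3) weighted normal equations by Gaussian
// elimination with partial pivoting; returns false if singular.
static bool solve_sym(std::vector<std::vector<double> > A,
                      std::vector<double> b, std::vector<double> &x) {
  int n = (int)b.size();
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
    if (std::fabs(A[piv][c]) < 1e-300) return false;
    std::swap(A[piv], A[c]);
    std::swap(b[piv], b[c]);
    for (int r = c + 1; r < n; ++r) {
      double f = A[r][c] / A[c][c];
      for (int k = c; k < n; ++k) A[r][k] -= f * A[c][k];
      b[r] -= f * b[c];
    }
  }
  x.assign(n, 0.0);
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < n; ++k) s -= A[r][k] * x[k];
    x[r] = s / A[r][r];
  }
  return true;
}

static bool invert_sym(const std::vector<std::vector<double> > &A,
                       std::vector<std::vector<double> > &Ainv) {
  int n = (int)A.size();
  Ainv.assign(n, std::vector<double>(n, 0.0));
  for (int c = 0; c < n; ++c) {
    std::vector<double> e(n, 0.0), x;
    e[c] = 1.0;
    if (!solve_sym(A, e, x)) return false;
    for (int r = 0; r < n; ++r) Ainv[r][c] = x[r];
  }
  return true;
}

// Polar onion peeling: iterate radii from the outermost ring inward, fit the
// residual angular slice with {P0, P2, P4}(cos theta), record the shell
// coefficients, and subtract the shell's forward projection from all interior
// rings using the same shell basis as cpp_project_shells.
// [[Rcpp::export]]
List cpp_peel(NumericMatrix polar, bool freeze_beta4) {
  int nr = polar.nrow(), nt = polar.ncol();
  std::vector<double> ct(nt), p2t(nt), p4t(nt);
  for (int j = 0; j < nt; ++j) {
    double theta = (j + 0.5) * (M_PI / 2.0) / nt;
    ct[j] = std::cos(theta);
    p2t[j] = P2(ct[j]);
    p4t[j] = P4(ct[j]);
  }
  int np = freeze_beta4 ? 2 : 3;
  NumericVector S(nr), b2(nr), b4(nr), Serr(nr), b2err(nr), b4err(nr);
  std::fill(b2.begin(), b2.end(), NA_REAL);
  std::fill(b4.begin(), b4.end(), NA_REAL);
  std::fill(b2err.begin(), b2err.end(), NA_REAL);
  std::fill(b4err.begin(), b4err.end(), NA_REAL);
  int clipped = 0, negwarn = 0;
  NumericMatrix work = clone(polar);
  const double inv2pi = 1.0 / (2.0 * M_PI);

  for (int r = nr; r >= 1; --r) {
    double K = radint((double)r, (double)r) * inv2pi;  // self-projection weight
    // normal equations
    std::vector<std::vector<double> > G(np, std::vector<double>(np, 0.0));
    std::vector<double> rhs(np, 0.0), coef;
    for (int j = 0; j < nt; ++j) {
      double X[3] = {K, K * p2t[j], K * p4t[j]};
      double y = work(r - 1, j);
      for (int a = 0; a < np; ++a) {
        rhs[a] += X[a] * y;
        for (int b = 0; b < np; ++b) G[a][b] += X[a] * X[b];
      }
    }
    bool ok = solve_sym(G, rhs, coef);
    double a0 = ok ? coef[0] : 0.0;
    double a2 = ok ? coef[1] : 0.0;
    double a4 = (ok && np == 3) ? coef[2] : 0.0;
    // residual variance and coefficient covariance
    double ssr = 0.0;
    for (int j = 0; j < nt; ++j) {
      double fit = K * (a0 + a2 * p2t[j] + a4 * p4t[j]);
      double e = work(r - 1, j) - fit;
      ssr += e * e;
    }
    double s2 = (nt > np) ? ssr / (nt - np) : 0.0;
    std::vector<std::vector<double> > Ginv;
    bool okc = ok && invert_sym(G, Ginv);
    double v00 = okc ? s2 * Ginv[0][0] : NA_REAL;
    double v11 = okc ? s2 * Ginv[1][1] : NA_REAL;
    double v01 = okc ? s2 * Ginv[0][1] : NA_REAL;
    double v22 = (okc && np == 3) ? s2 * Ginv[2][2] : NA_REAL;
    double v02 = (okc && np == 3) ? s2 * Ginv[0][2] : NA_REAL;

    if (a0 <= 0.0) {
      if (a0 < 0.0) ++clipped;
      S[r - 1] = 0.0;
      Serr[r - 1] = okc ? std::sqrt(v00) : NA_REAL;
      a0 = a2 = a4 = 0.0;  // nothing to subtract
    } else {
      S[r - 1] = a0;
      Serr[r - 1] = okc ? std::sqrt(v00) : NA_REAL;
      b2[r - 1] = a2 / a0;
      if (okc) {
        double var_b2 = v11 / (a0 * a0) + a2 * a2 * v00 / (a0 * a0 * a0 * a0) -
                        2.0 * a2 * v01 / (a0 * a0 * a0);
        b2err[r - 1] = var_b2 > 0 ? std::sqrt(var_b2) : 0.0;
      }
      if (np == 3) {
        b4[r - 1] = a4 / a0;
        if (okc) {
          double var_b4 = v22 / (a0 * a0) + a4 * a4 * v00 / (a0 * a0 * a0 * a0) -
                          2.0 * a4 * v02 / (a0 * a0 * a0);
          b4err[r - 1] = var_b4 > 0 ? std::sqrt(var_b4) : 0.0;
        }
      } else {
        b4[r - 1] = 0.0;
      }
    }
    // subtract this shell from the interior rings
    if (a0 > 0.0) {
      for (int rho = 1; rho < r; ++rho) {
        double w = radint((double)rho, (double)r) * inv2pi;
        if (w <= 0.0) continue;
        for (int j = 0; j < nt; ++j) {
          double u = rho * ct[j] / r;
          double sub = w * (a0 + a2 * P2(u) + a4 * P4(u));
          work(rho - 1, j) -= sub;
          if (work(rho - 1, j) < 0.0) ++negwarn;
        }
      }
    }
  }
  return List::create(_["S"] = S, _["beta2"] = b2, _["beta4"] = b4,
                      _["S_err"] = Serr, _["beta2_err"] = b2err,
                      _["beta4_err"] = b4err,
                      _["clip_fraction"] = (double)clipped / nr,
                      _["negative_residuals"] = negwarn);
}
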