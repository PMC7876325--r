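// Core numerics: right-hand side of the governing phase equations and the
// two integration schemes (fixed-step RK4 with optional Euler-Maruyama
// frequency noise, and an adaptive embedded Dormand-Prince 5(4) scheme with
// cubic-Hermite dense output on a uniform sampling grid).
//
// State layout throughout: y = [theta_G (N), theta_GO (N), theta_O (M),
// theta_MO (M)], all phases unwrapped (never reduced modulo 2*pi).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Piecewise-quadratic coupling schedule: one row per segment, columns
// (t_start, t_end, a, b, c), value a*t^2 + b*t + c on [t_start, t_end).
// Times before the first segment use the first, times at or beyond the last
// segment's end use the last. Negative evaluations are clamped to zero and
// counted so the caller can warn.
static inline double sched_val(const mat& seg, double t, long long& clamped) {
  const uword n = seg.n_rows;
  uword k = n - 1;
  for (uword i = 0; i < n; ++i) {
    if (t < seg(i, 1)) { k = i; break; }
  }
  const double v = seg(k, 2) * t * t + seg(k, 3) * t + seg(k, 4);
  if (v < 0.0) { ++clamped; return 0.0; }
  return v;
}

struct MetabSystem {
  int N, M;
  mat Wgo, Wmo;           // ring-weight matrices, N x N and M x M
  double K_GO, K_MO;      // intra-network coupling strengths
  mat eG, eO, fGO, fMO;   // schedules for eps_G, eps_O, F_GO, F_MO
  // frequency parameters, order: (omega, A, omega_m) for G, O, GO, MO
  vec fp;
  vec offG, offO, offGO, offMO;  // per-oscillator modulation offsets t_i
  double sgn_mo_go;       // +1: attractive MO<-GO mean field; -1: printed form
  long long clamped = 0;

  // scratch buffers to avoid per-call allocation
  vec sGO, cGO, sMO, cMO;

  MetabSystem(int N_, int M_) : N(N_), M(M_),
    sGO(N_), cGO(N_), sMO(M_), cMO(M_) {}

  void deriv(double t, const vec& y, vec& dy) {
    const double epsG = sched_val(eG, t, clamped);
    const double epsO = sched_val(eO, t, clamped);
    const double FGO  = sched_val(fGO, t, clamped);
    const double FMO  = sched_val(fMO, t, clamped);

    const subview_col<double> thG  = y.subvec(0, N - 1);
    const subview_col<double> thGO = y.subvec(N, 2 * N - 1);
    const subview_col<double> thO  = y.subvec(2 * N, 2 * N + M - 1);
    const subview_col<double> thMO = y.subvec(2 * N + M, 2 * N + 2 * M - 1);

    // drivers: pure non-autonomous frequencies
    dy.subvec(0, N - 1) = fp(0) + fp(1) * sin(fp(2) * t + offG);
    dy.subvec(2 * N, 2 * N + M - 1) = fp(3) + fp(4) * sin(fp(5) * t + offO);

    sGO = sin(thGO); cGO = cos(thGO);
    sMO = sin(thMO); cMO = cos(thMO);

    // mean fields r * exp(i * Psi) as complex components
    const double zrGO = mean(cGO), ziGO = mean(sGO);
    const double zrMO = mean(cMO), ziMO = mean(sMO);

    // glycolysis network: modulated frequency + weighted ring coupling
    // - glucose driving + attractive mean field of the OXPHOS network
    dy.subvec(N, 2 * N - 1) =
      fp(6) + fp(7) * sin(fp(8) * t + offGO)
      + (K_GO / N) * (cGO % (Wgo * sGO) - sGO % (Wgo * cGO))
      - epsG * sin(thGO - thG)
      + FGO * (ziMO * cGO - zrMO * sGO);

    // OXPHOS network: the MO<-GO mean-field term carries sgn_mo_go
    dy.subvec(2 * N + M, 2 * N + 2 * M - 1) =
      fp(9) + fp(10) * sin(fp(11) * t + offMO)
      + (K_MO / M) * (cMO % (Wmo * sMO) - sMO % (Wmo * cMO))
      - epsO * sin(thMO - thO)
      + sgn_mo_go * FMO * (ziGO * cMO - zrGO * sMO);
  }
};

static MetabSystem make_system(int N, int M, const mat& Wgo, const mat& Wmo,
                               double K_GO, double K_MO,
                               const mat& eG, const mat& eO,
                               const mat& fGO, const mat& fMO,
                               const vec& fp,
                               const vec& offG, const vec& offO,
                               const vec& offGO, const vec& offMO,
                               double sgn_mo_go) {
  MetabSystem sys(N, M);
  sys.Wgo = Wgo; sys.Wmo = Wmo;
  sys.K_GO = K_GO; sys.K_MO = K_MO;
  sys.eG = eG; sys.eO = eO; sys.fGO = fGO; sys.fMO = fMO;
  sys.fp = fp;
  sys.offG = offG; sys.offO = offO; sys.offGO = offGO; sys.offMO = offMO;
  sys.sgn_mo_go = sgn_mo_go;
  return sys;
}

// [[Rcpp::export]]
Rcpp::List rhs_cpp(double t, arma::vec y, int N, int M,
                   arma::mat Wgo, arma::mat Wmo, double K_GO, double K_MO,
                   arma::mat eG, arma::mat eO, arma::mat fGO, arma::mat fMO,
                   arma::vec fp, arma::vec offG, arma::vec offO,
                   arma::vec offGO, arma::vec offMO, double sgn_mo_go) {
  MetabSystem sys = make_system(N, M, Wgo, Wmo, K_GO, K_MO, eG, eO, fGO, fMO,
                                fp, offG, offO, offGO, offMO, sgn_mo_go);
  vec dy(y.n_elem, fill::zeros);
  sys.deriv(t, y, dy);
  return Rcpp::List::create(Rcpp::Named("dtheta") = dy,
                            Rcpp::Named("clamped") = (double) sys.clamped);
}

// Fixed-step classical RK4; when sigma > 0 an Euler-Maruyama noise increment
// sigma * sqrt(h) * xi is added to the GO and MO phases after each step
// (drivers are noise-free, matching the individual-oscillator model).
static void rk4_march(MetabSystem& sys, vec& y, double t0, double t1,
                      double h, double sigma) {
  const int nstep = (int) std::lround((t1 - t0) / h);
  const int N = sys.N, M = sys.M;
  const uword dim = y.n_elem;
  vec k1(dim), k2(dim), k3(dim), k4(dim), tmp(dim);
  for (int s = 0; s < nstep; ++s) {
    const double t = t0 + s * h;
    sys.deriv(t, y, k1);
    tmp = y + 0.5 * h * k1; sys.deriv(t + 0.5 * h, tmp, k2);
    tmp = y + 0.5 * h * k2; sys.deriv(t + 0.5 * h, tmp, k3);
    tmp = y + h * k3;       sys.deriv(t + h, tmp, k4);
    y += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (sigma > 0.0) {
      const double sq = sigma * std::sqrt(h);
      Rcpp::NumericVector xi = Rcpp::rnorm(N + M);
      for (int i = 0; i < N; ++i) y(N + i) += sq * xi[i];
      for (int i = 0; i < M; ++i) y(2 * N + M + i) += sq * xi[N + i];
    }
  }
}

// [[Rcpp::export]]
Rcpp::List integrate_rk4_cpp(arma::vec theta0, int N, int M,
                             arma::mat Wgo, arma::mat Wmo,
                             double K_GO, double K_MO,
                             arma::mat eG, arma::mat eO,
                             arma::mat fGO, arma::mat fMO,
                             arma::vec fp, arma::vec offG, arma::vec offO,
                             arma::vec offGO, arma::vec offMO,
                             double sgn_mo_go,
                             double t_total, double sample_interval,
                             double rk4_step, double sigma) {
  MetabSystem sys = make_system(N, M, Wgo, Wmo, K_GO, K_MO, eG, eO, fGO, fMO,
                                fp, offG, offO, offGO, offMO, sgn_mo_go);
  const int nsamp = (int) std::floor(t_total / sample_interval + 1e-9) + 1;
  // actual step divides the sampling interval exactly
  const int nsub = std::max(1, (int) std::lround(sample_interval / rk4_step));
  const double h = sample_interval / nsub;

  mat out(nsamp, theta0.n_elem);
  vec times(nsamp);
  vec y = theta0;
  out.row(0) = y.t(); times(0) = 0.0;
  for (int k = 1; k < nsamp; ++k) {
    const double ta = (k - 1) * sample_interval;
    const double tb = k * sample_interval;
    rk4_march(sys, y, ta, tb, h, sigma);
    out.row(k) = y.t(); times(k) = tb;
    if (k % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("theta") = out,
                            Rcpp::Named("clamped") = (double) sys.clamped,
                            Rcpp::Named("step") = h);
}

// Adaptive embedded Dormand-Prince 5(4) with FSAL, PI-free standard step
// control, steps aligned to schedule breakpoints, and cubic Hermite dense
// output onto the uniform sampling grid. The phase equations are non-stiff;
// accuracy is governed by rel_tol / abs_tol.
// [[Rcpp::export]]
Rcpp::List integrate_dp45_cpp(arma::vec theta0, int N, int M,
                              arma::mat Wgo, arma::mat Wmo,
                              double K_GO, double K_MO,
                              arma::mat eG, arma::mat eO,
                              arma::mat fGO, arma::mat fMO,
                              arma::vec fp, arma::vec offG, arma::vec offO,
                              arma::vec offGO, arma::vec offMO,
                              double sgn_mo_go,
                              double t_total, double sample_interval,
                              double rtol, double atol, double h_max,
                              arma::vec breakpoints) {
  MetabSystem sys = make_system(N, M, Wgo, Wmo, K_GO, K_MO, eG, eO, fGO, fMO,
                                fp, offG, offO, offGO, offMO, sgn_mo_go);
  const uword dim = theta0.n_elem;
  const int nsamp = (int) std::floor(t_total / sample_interval + 1e-9) + 1;
  mat out(nsamp, dim);
  vec times(nsamp);
  for (int k = 0; k < nsamp; ++k) times(k) = k * sample_interval;

  // Dormand-Prince tableau
  const double a21 = 1.0 / 5;
  const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
               a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
               a64 = 49.0 / 176, a65 = -5103.0 / 18656;
  const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
               b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  // 5th-minus-4th order error weights
  const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
               e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;
  const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;

  vec y = theta0;
  vec k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim), k7(dim);
  vec ynew(dim), err(dim), tmp(dim);
  double t = 0.0;
  sys.deriv(t, y, k1);

  out.row(0) = y.t();
  int next_sample = 1;
  uword next_bp = 0;
  vec bp = sort(breakpoints(find(breakpoints > 0 && breakpoints < t_total)));

  double h = std::min(h_max, sample_interval);
  const double h_min = std::max(1e-12, 1e-13 * t_total);
  long long nacc = 0, nrej = 0;

  while (t < t_total - 1e-12) {
    if (h > h_max) h = h_max;
    if (t + h > t_total) h = t_total - t;
    // land exactly on schedule breakpoints
    while (next_bp < bp.n_elem && bp(next_bp) <= t + 1e-12) ++next_bp;
    if (next_bp < bp.n_elem && t + h > bp(next_bp)) h = bp(next_bp) - t;
    if (h < h_min)
      Rcpp::stop("adaptive step size underflow at t = %f", t);

    tmp = y + h * (a21 * k1);
    sys.deriv(t + c2 * h, tmp, k2);
    tmp = y + h * (a31 * k1 + a32 * k2);
    sys.deriv(t + c3 * h, tmp, k3);
    tmp = y + h * (a41 * k1 + a42 * k2 + a43 * k3);
    sys.deriv(t + c4 * h, tmp, k4);
    tmp = y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4);
    sys.deriv(t + c5 * h, tmp, k5);
    tmp = y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 + a65 * k5);
    sys.deriv(t + h, tmp, k6);
    ynew = y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6);
    sys.deriv(t + h, ynew, k7);  // FSAL

    err = h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7);
    double sum = 0.0;
    for (uword i = 0; i < dim; ++i) {
      const double sc = atol + rtol * std::max(std::fabs(y(i)),
                                               std::fabs(ynew(i)));
      const double r = err(i) / sc;
      sum += r * r;
    }
    const double enorm = std::sqrt(sum / dim);

    if (enorm <= 1.0) {
      // dense output: cubic Hermite on [t, t+h] using k1 and k7
      const double tnew = t + h;
      while (next_sample < nsamp && times(next_sample) <= tnew + 1e-9) {
        const double th = (times(next_sample) - t) / h;
        const double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
        const double h10 = th * (1 - th) * (1 - th);
        const double h01 = th * th * (3 - 2 * th);
        const double h11 = th * th * (th - 1);
        out.row(next_sample) =
          (h00 * y + h * h10 * k1 + h01 * ynew + h * h11 * k7).t();
        ++next_sample;
      }
      t = tnew;
      y = ynew;
      k1 = k7;
      ++nacc;
      const double fac = (enorm == 0.0)
        ? 5.0 : std::min(5.0, std::max(0.2, 0.9 * std::pow(enorm, -0.2)));
      h *= fac;
      if (nacc % 4096 == 0) Rcpp::checkUserInterrupt();
    } else {
      ++nrej;
      h *= std::max(0.2, 0.9 * std::pow(enorm, -0.2));
    }
  }

  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("theta") = out,
                            Rcpp::Named("clamped") = (double) sys.clamped,
                            Rcpp::Named("n_accepted") = (double) nacc,
                            Rcpp::Named("n_rejected") = (double) nrej);
}
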