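// Forward model core shared by all four architectures (LN, STP, GC, GC+STP).
// Kept in C++ because the STP vesicle-availability update is a per-bin
// recursion evaluated inside the optimizer's objective many thousand times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Double-exponential output nonlinearity, evaluated bin-wise.  Total
// function: exp overflow saturates to 0/Inf without producing NaN for
// finite parameters.
static inline double dexp_nl(double x, double b, double a, double s, double k) {
  return b + a * std::exp(-std::exp(-k * (x - s)));
}

// Vesicle availability d_i(t) for one synapse.  d(0) = 1.  The release
// drive uses the rectified input (depletion is defined for non-negative
// stimulation) but the caller scales the *raw* signal by d, so u = 0
// reproduces the input bitwise (LN nesting).
static arma::rowvec stp_avail_row(const arma::rowvec& s, double u, double tau,
                                  double bin_s) {
  const arma::uword T = s.n_elem;
  arma::rowvec d(T);
  double dc = 1.0;
  const double rec = bin_s / tau;
  d(0) = dc;
  for (arma::uword t = 1; t < T; ++t) {
    double sp = s(t - 1) > 0.0 ? s(t - 1) : 0.0;
    if (u >= 0.0) {
      dc = dc - u * sp * dc + (1.0 - dc) * rec;        // depression
    } else {
      dc = dc - u * sp * (2.0 - dc) + (1.0 - dc) * rec; // facilitation
    }
    if (dc < 0.0) dc = 0.0;
    if (dc > 2.0) dc = 2.0;
    d(t) = dc;
  }
  return d;
}

// [[Rcpp::export]]
arma::mat stp_availability_cpp(const arma::mat& X, const arma::vec& u,
                               const arma::vec& tau, double bin_s) {
  arma::mat D(X.n_rows, X.n_cols);
  for (arma::uword i = 0; i < X.n_rows; ++i)
    D.row(i) = stp_avail_row(X.row(i), u(i), tau(i), bin_s);
  return D;
}

// Shared forward pass.  spec: F x T log-level spectrogram; W: F x R spectral
// weights; H: R x U temporal filters; nl = (b, a, s, k); theta1 = endpoint
// parameters at K = 1; K: normalized frequency-summed contrast (length T,
// ignored unless use_gc).  linear_only returns the pre-nonlinearity drive.
static arma::vec forward_one(const arma::mat& spec, const arma::mat& W,
                             const arma::mat& H, const arma::vec& nl,
                             const arma::vec& stp_u, const arma::vec& stp_tau,
                             const arma::vec& theta1, const arma::vec& K,
                             bool use_stp, bool use_gc, double bin_s,
                             bool linear_only) {
  const arma::uword T = spec.n_cols;
  const arma::uword R = W.n_cols;
  const arma::uword U = H.n_cols;
  arma::mat X = W.t() * spec;  // R x T spectrally weighted channels

  if (use_stp) {
    for (arma::uword i = 0; i < R; ++i) {
      arma::rowvec d = stp_avail_row(X.row(i), stp_u(i), stp_tau(i), bin_s);
      X.row(i) %= d;
    }
  }

  arma::vec ylin(T, arma::fill::zeros);
  for (arma::uword i = 0; i < R; ++i) {
    for (arma::uword u = 0; u < U; ++u) {
      double h = H(i, u);
      if (h == 0.0) continue;
      for (arma::uword t = u; t < T; ++t) ylin(t) += h * X(i, t - u);
    }
  }
  if (linear_only) return ylin;

  arma::vec y(T);
  const double b0 = nl(0), a0 = nl(1), s0 = nl(2), k0 = nl(3);
  if (use_gc) {
    const double db = theta1(0) - b0, da = theta1(1) - a0,
                 ds = theta1(2) - s0, dk = theta1(3) - k0;
    for (arma::uword t = 0; t < T; ++t) {
      double kt = K(t);
      double at = a0 + da * kt;
      if (at < 0.0) at = 0.0;  // rate amplitude stays non-negative when K
                               // extrapolates beyond the calibrated range
      y(t) = dexp_nl(ylin(t), b0 + db * kt, at, s0 + ds * kt, k0 + dk * kt);
    }
  } else {
    for (arma::uword t = 0; t < T; ++t)
      y(t) = dexp_nl(ylin(t), b0, a0, s0, k0);
  }
  // firing rates are non-negative
  for (arma::uword t = 0; t < T; ++t) if (y(t) < 0.0) y(t) = 0.0;
  return y;
}

// [[Rcpp::export]]
arma::vec forward_predict_cpp(const arma::mat& spec, const arma::mat& W,
                              const arma::mat& H, const arma::vec& nl,
                              const arma::vec& stp_u, const arma::vec& stp_tau,
                              const arma::vec& theta1, const arma::vec& K,
                              bool use_stp, bool use_gc, double bin_s,
                              bool linear_only) {
  return forward_one(spec, W, H, nl, stp_u, stp_tau, theta1, K, use_stp,
                     use_gc, bin_s, linear_only);
}

// Unpack the flat parameter vector used by the optimizer.
// Layout: W (F*R, column-major) | H (R*U) | nl (4) | u (3) | tau (3) | theta1 (4)
struct ParSet {
  arma::mat W, H;
  arma::vec nl, u, tau, theta1;
};

static ParSet unpack(const arma::vec& par, int F, int R, int U) {
  ParSet p;
  arma::uword off = 0;
  p.W = arma::reshape(par.subvec(off, off + F * R - 1), F, R); off += F * R;
  p.H = arma::reshape(par.subvec(off, off + R * U - 1), R, U); off += R * U;
  p.nl = par.subvec(off, off + 3); off += 4;
  p.u = par.subvec(off, off + 2); off += 3;
  p.tau = par.subvec(off, off + 2); off += 3;
  p.theta1 = par.subvec(off, off + 3);
  return p;
}

struct FitData {
  std::vector<arma::mat> stims;
  std::vector<arma::vec> resps;
  std::vector<arma::vec> Ks;
};

static FitData make_fit_data(const List& stims, const List& resps,
                             const List& Ks, bool use_gc) {
  FitData d;
  for (int j = 0; j < stims.size(); ++j) {
    d.stims.push_back(as<arma::mat>(stims[j]));
    d.resps.push_back(as<arma::vec>(resps[j]));
    d.Ks.push_back(use_gc ? as<arma::vec>(Ks[j]) : arma::vec());
  }
  return d;
}

static double objective_impl(const arma::vec& par, const FitData& dat, int F,
                             int R, int U, bool use_stp, bool use_gc,
                             bool linear_only, double bin_s) {
  ParSet p = unpack(par, F, R, U);
  double sse = 0.0;
  double n = 0.0;
  for (size_t j = 0; j < dat.stims.size(); ++j) {
    arma::vec pred =
        forward_one(dat.stims[j], p.W, p.H, p.nl, p.u, p.tau, p.theta1,
                    dat.Ks[j], use_stp, use_gc, bin_s, linear_only);
    arma::vec d = pred - dat.resps[j];
    sse += arma::dot(d, d);
    n += static_cast<double>(d.n_elem);
  }
  return sse / n;
}

// [[Rcpp::export]]
double fit_objective_cpp(const arma::vec& par, List stims, List resps, List Ks,
                         int F, int R, int U, bool use_stp, bool use_gc,
                         bool linear_only, double bin_s) {
  FitData dat = make_fit_data(stims, resps, Ks, use_gc);
  return objective_impl(par, dat, F, R, U, use_stp, use_gc, linear_only,
                        bin_s);
}

// Central-difference gradient over the free parameters only (free_idx is
// 0-based into the flat vector).  Step scales with parameter magnitude.
// [[Rcpp::export]]
arma::vec fit_gradient_cpp(const arma::vec& par, const arma::uvec& free_idx,
                           List stims, List resps, List Ks, int F, int R,
                           int U, bool use_stp, bool use_gc, bool linear_only,
                           double bin_s) {
  FitData dat = make_fit_data(stims, resps, Ks, use_gc);
  arma::vec g(free_idx.n_elem);
  arma::vec work = par;
  for (arma::uword j = 0; j < free_idx.n_elem; ++j) {
    arma::uword idx = free_idx(j);
    double x0 = work(idx);
    double h = 1e-6 * (1.0 + std::abs(x0));
    work(idx) = x0 + h;
    double fp = objective_impl(work, dat, F, R, U, use_stp, use_gc,
                               linear_only, bin_s);
    work(idx) = x0 - h;
    double fm = objective_impl(work, dat, F, R, U, use_stp, use_gc,
                               linear_only, bin_s);
    work(idx) = x0;
    g(j) = (fp - fm) / (2.0 * h);
  }
  return g;
}

// Analytic reverse-mode gradient of SSE for one stimulus, accumulated into
// g (full parameter layout). Returns the stimulus's SSE. Kinks (output
// rectifier, availability clamp, rectified release drive) use zero
// subgradient at the kink.
static double fwd_bwd_one(const arma::mat& spec, const ParSet& p,
                          const arma::vec& K, const arma::vec& resp,
                          bool use_stp, bool use_gc, double bin_s,
                          bool linear_only, int F, int R, int U,
                          arma::vec& g) {
  const arma::uword T = spec.n_cols;
  arma::mat X = p.W.t() * spec;  // R x T pre-STP drive
  arma::mat D, clamped;
  arma::mat Xs = X;
  if (use_stp) {
    D.set_size(R, T);
    clamped.zeros(R, T);
    for (int i = 0; i < R; ++i) {
      double u = p.u(i), rec = bin_s / p.tau(i);
      double dc = 1.0;
      D(i, 0) = dc;
      for (arma::uword t = 1; t < T; ++t) {
        double sp = X(i, t - 1) > 0.0 ? X(i, t - 1) : 0.0;
        double dn;
        if (u >= 0.0) dn = dc - u * sp * dc + (1.0 - dc) * rec;
        else dn = dc - u * sp * (2.0 - dc) + (1.0 - dc) * rec;
        if (dn < 0.0) { dn = 0.0; clamped(i, t) = 1.0; }
        if (dn > 2.0) { dn = 2.0; clamped(i, t) = 1.0; }
        D(i, t) = dn;
        dc = dn;
      }
    }
    Xs = D % X;
  }
  arma::vec ylin(T, arma::fill::zeros);
  for (int i = 0; i < R; ++i)
    for (int u = 0; u < U; ++u) {
      double h = p.H(i, u);
      if (h == 0.0) continue;
      for (arma::uword t = u; t < T; ++t) ylin(t) += h * Xs(i, t - u);
    }

  arma::vec gylin(T, arma::fill::zeros);
  double sse = 0.0;
  if (linear_only) {
    for (arma::uword t = 0; t < T; ++t) {
      double res = ylin(t) - resp(t);
      sse += res * res;
      gylin(t) = 2.0 * res;
    }
  } else {
    const double b0 = p.nl(0), a0 = p.nl(1), s0 = p.nl(2), k0 = p.nl(3);
    const double db = p.theta1(0) - b0, da = p.theta1(1) - a0,
                 ds = p.theta1(2) - s0, dk = p.theta1(3) - k0;
    // gradient accumulators for base and endpoint nonlinearity parameters
    double gb0 = 0, ga0 = 0, gs0 = 0, gk0 = 0;
    double gb1 = 0, ga1 = 0, gs1 = 0, gk1 = 0;
    for (arma::uword t = 0; t < T; ++t) {
      double kt_ = use_gc ? K(t) : 0.0;
      double bt = use_gc ? b0 + db * kt_ : b0;
      double at = use_gc ? a0 + da * kt_ : a0;
      bool a_clamped = at < 0.0;
      if (a_clamped) at = 0.0;
      double st = use_gc ? s0 + ds * kt_ : s0;
      double kk = use_gc ? k0 + dk * kt_ : k0;
      double z = -kk * (ylin(t) - st);
      double e1 = std::exp(z);
      double E = std::exp(-e1);
      double y0 = bt + at * E;
      double y = y0 > 0.0 ? y0 : 0.0;
      double res = y - resp(t);
      sse += res * res;
      if (y0 <= 0.0) continue;          // rectified: zero gradient
      double gy = 2.0 * res;
      double Ee1 = (e1 > 700.0) ? 0.0 : E * e1;  // E*e1 -> 0 as z -> +Inf
      double gz = gy * at * (-Ee1);
      double gbt = gy;
      double gat = a_clamped ? 0.0 : gy * E;
      double gst = gz * kk;
      double gkt = gz * (st - ylin(t));
      gylin(t) = gz * (-kk);
      if (use_gc) {
        double w0 = 1.0 - kt_;
        gb0 += gbt * w0; gb1 += gbt * kt_;
        ga0 += gat * w0; ga1 += gat * kt_;
        gs0 += gst * w0; gs1 += gst * kt_;
        gk0 += gkt * w0; gk1 += gkt * kt_;
      } else {
        gb0 += gbt; ga0 += gat; gs0 += gst; gk0 += gkt;
      }
    }
    arma::uword off = (arma::uword)(F * R + R * U);
    g(off + 0) += gb0; g(off + 1) += ga0; g(off + 2) += gs0; g(off + 3) += gk0;
    arma::uword off1 = off + 4 + 2 * R;
    g(off1 + 0) += gb1; g(off1 + 1) += ga1; g(off1 + 2) += gs1; g(off1 + 3) += gk1;
  }

  // temporal filter gradient and back-propagated channel gradient
  arma::mat gXs(R, T, arma::fill::zeros);
  arma::uword offH = (arma::uword)(F * R);
  for (int i = 0; i < R; ++i)
    for (int u = 0; u < U; ++u) {
      double acc = 0.0;
      double h = p.H(i, u);
      for (arma::uword t = u; t < T; ++t) {
        acc += gylin(t) * Xs(i, t - u);
        gXs(i, t - u) += h * gylin(t);
      }
      g(offH + i + (arma::uword)u * R) += acc;
    }

  arma::mat gX(R, T);
  if (use_stp) {
    arma::uword offU = (arma::uword)(F * R + R * U + 4);
    for (int i = 0; i < R; ++i) {
      double u = p.u(i), tau = p.tau(i), rec = bin_s / tau;
      double gu = 0.0, grec = 0.0;
      // direct parts
      for (arma::uword t = 0; t < T; ++t)
        gX(i, t) = gXs(i, t) * D(i, t);
      double lam = 0.0;  // adjoint of d(i, t)
      for (arma::uword t = T; t-- > 1;) {
        lam += gXs(i, t) * X(i, t);
        if (clamped(i, t)) { lam = 0.0; continue; }
        double dprev = D(i, t - 1);
        double sp = X(i, t - 1) > 0.0 ? X(i, t - 1) : 0.0;
        double dd_ddprev, dd_du, dd_dsp;
        if (u >= 0.0) {
          dd_ddprev = 1.0 - u * sp - rec;
          dd_du = -sp * dprev;
          dd_dsp = -u * dprev;
        } else {
          dd_ddprev = 1.0 + u * sp - rec;
          dd_du = -sp * (2.0 - dprev);
          dd_dsp = -u * (2.0 - dprev);
        }
        double dd_drec = 1.0 - dprev;
        gu += lam * dd_du;
        grec += lam * dd_drec;
        if (X(i, t - 1) > 0.0) gX(i, t - 1) += lam * dd_dsp;
        lam *= dd_ddprev;
      }
      g(offU + i) += gu;
      g(offU + R + i) += grec * (-bin_s / (tau * tau));
    }
  } else {
    gX = gXs;
  }

  // spectral weight gradient: gW = S * gX'
  arma::mat gW = spec * gX.t();  // F x R
  for (int j = 0; j < R; ++j)
    for (int f = 0; f < F; ++f)
      g((arma::uword)(j * F + f)) += gW(f, j);

  return sse;
}

// Analytic gradient of the MSE objective over the full parameter layout.
// [[Rcpp::export]]
arma::vec model_gradient_cpp(const arma::vec& par, List stims, List resps,
                             List Ks, int F, int R, int U, bool use_stp,
                             bool use_gc, bool linear_only, double bin_s) {
  FitData dat = make_fit_data(stims, resps, Ks, use_gc);
  ParSet p = unpack(par, F, R, U);
  arma::vec g(par.n_elem, arma::fill::zeros);
  double n = 0.0;
  for (size_t j = 0; j < dat.stims.size(); ++j) {
    fwd_bwd_one(dat.stims[j], p, dat.Ks[j], dat.resps[j], use_stp, use_gc,
                bin_s, linear_only, F, R, U, g);
    n += static_cast<double>(dat.resps[j].n_elem);
  }
  return g / n;
}

// Rolling coefficient of variation per channel.  For bin t (0-based) the
// window is [t - off - win + 1, t - off]; bins whose window is incomplete
// get contrast 0, as do windows whose mean falls below the floor guard.
// [[Rcpp::export]]
arma::mat contrast_cpp(const arma::mat& levels, int win, int off,
                       double floor_guard) {
  const arma::uword Fch = levels.n_rows, T = levels.n_cols;
  arma::mat C(Fch, T, arma::fill::zeros);
  for (arma::uword f = 0; f < Fch; ++f) {
    for (arma::uword t = 0; t < T; ++t) {
      int hi = static_cast<int>(t) - off;
      int lo = hi - win + 1;
      if (lo < 0) continue;
      double m = 0.0;
      for (int i = lo; i <= hi; ++i) m += levels(f, i);
      m /= win;
      if (m <= floor_guard) continue;
      double ss = 0.0;
      for (int i = lo; i <= hi; ++i) {
        double d = levels(f, i) - m;
        ss += d * d;
      }
      C(f, t) = std::sqrt(ss / (win - 1)) / m;
    }
  }
  return C;
}
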