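// Euler-integrated network simulation cores. Both models share the
// synaptic activation dynamics and the block-structured recurrent input;
// they differ in how rates/spikes are produced (threshold-linear renewal
// process vs conductance-based membrane dynamics).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Drop entries below a relative threshold and store sparse: the weight
// profiles are Gaussian-banded, so most entries are numerically zero.
static arma::sp_mat sparsify(const arma::mat& W) {
  double thr = 1e-10 * arma::abs(W).max();
  arma::mat Wc = W;
  Wc.clean(thr);
  return arma::sp_mat(Wc);
}

// [[Rcpp::export]]
List lnp_core(const arma::mat& W, const arma::vec& A, const arma::vec& G0p,
              const arma::vec& dirs, double G0, double beta_vel,
              int vel_additive, double W_vel, const arma::vec& v,
              double dt, double tau_syn, double CV, int frame_every,
              int max_frames) {
  const int n = W.n_rows;
  const int T = v.n_elem;
  const double a = 1.0 / (CV * CV);   // gamma renewal order
  const double decay = 1.0 - dt / tau_syn;

  arma::vec s(n, arma::fill::zeros);
  arma::vec H(n, arma::fill::zeros);
  arma::vec thr(n);
  for (int i = 0; i < n; ++i) thr(i) = R::rgamma(a, 1.0 / a);

  std::vector<int> sp_cell, sp_step;
  arma::mat frames(n, max_frames > 0 ? max_frames : 1);
  std::vector<double> ftime(max_frames > 0 ? max_frames : 1);
  int fcount = 0;

  arma::sp_mat Ws = sparsify(W);
  arma::vec spikes(n);
  for (int t = 0; t < T; ++t) {
    arma::vec alpha = 1.0 + beta_vel * v(t) * dirs;
    arma::vec Grec = Ws * s;
    arma::vec G;
    if (vel_additive)
      G = (W_vel * alpha + Grec + G0 + G0p) % A;
    else
      G = (alpha % (Grec + G0) + G0p) % A;
    arma::vec r = arma::clamp(G, 0.0, arma::datum::inf);
    if (!r.is_finite() || r.max() > 1e7)
      stop("rate diverged at step %d (max rate %g)", t, r.max());

    spikes.zeros();
    H += r * dt / 1000.0;
    for (int i = 0; i < n; ++i) {
      while (H(i) >= thr(i)) {
        spikes(i) += 1.0;
        sp_cell.push_back(i);
        sp_step.push_back(t);
        thr(i) += R::rgamma(a, 1.0 / a);
      }
    }
    s = decay * s + spikes;

    if (max_frames > 0 && (t % frame_every) == 0) {
      int fi = fcount % max_frames;
      frames.col(fi) = r;
      ftime[fi] = t * dt;
      ++fcount;
    }
  }

  // reorder the circular frame buffer chronologically
  int kept = std::min(fcount, max_frames);
  arma::mat outf(n, kept);
  NumericVector outt(kept);
  for (int k = 0; k < kept; ++k) {
    int src = (fcount - kept + k) % max_frames;
    outf.col(k) = frames.col(src);
    outt[k] = ftime[src];
  }

  return List::create(_["spike_cell"] = wrap(sp_cell),
                      _["spike_step"] = wrap(sp_step),
                      _["frames"] = outf,
                      _["frame_times"] = outt);
}

// Regular-spiking cortical gate kinetics (Traub-type rate functions with
// threshold shift VT; slow non-inactivating K gate q with voltage-dependent
// time constant capped at tau_max).
static inline double vtrap(double x, double y) {
  // x / (exp(x / y) - 1), stable near x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / y / 2.0);
  return x / (std::exp(x / y) - 1.0);
}

// [[Rcpp::export]]
List chh_core(const arma::mat& WE, const arma::mat& WI, const arma::vec& A,
              const arma::vec& dirs, double beta_vel, const arma::vec& v,
              double dt, double tau_syn, const arma::vec& par,
              int bin_steps) {
  const int n = WE.n_rows;
  const int T = v.n_elem;
  const double Cm = par(0), gL = par(1), gK = par(2), gM = par(3),
               gNa = par(4), VL = par(5), VK = par(6), VNa = par(7),
               VE = par(8), VI = par(9), I0 = par(10), VT = par(11),
               tau_max_q = par(12), ftau = par(13);
  const double decay = 1.0 - dt / tau_syn;

  arma::vec V(n), gn(n), gm(n), gh(n), gq(n), s(n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    V(i) = VL + R::runif(0.0, 5.0);
    double u = V(i) - VT;
    double an = 0.032 * vtrap(-(u - 15.0), 5.0);
    double bn = 0.5 * std::exp(-(u - 10.0) / 40.0);
    double am = 0.32 * vtrap(-(u - 13.0), 4.0);
    double bm = 0.28 * vtrap(u - 40.0, 5.0);
    double ah = 0.128 * std::exp(-(u - 17.0) / 18.0);
    double bh = 4.0 / (1.0 + std::exp(-(u - 40.0) / 5.0));
    gn(i) = an / (an + bn);
    gm(i) = am / (am + bm);
    gh(i) = ah / (ah + bh);
    gq(i) = 1.0 / (1.0 + std::exp(-(V(i) + 35.0) / 10.0));
  }

  std::vector<int> sp_cell, sp_step;
  const int nbins = (T + bin_steps - 1) / bin_steps;
  arma::mat counts(n, nbins, arma::fill::zeros);
  double gate_min = 1.0, gate_max = 0.0;

  arma::sp_mat WEs = sparsify(WE), WIs = sparsify(WI);
  arma::vec spikes(n);
  for (int t = 0; t < T; ++t) {
    arma::vec alpha = 1.0 + beta_vel * v(t) * dirs;
    arma::vec gEr = WEs * s;
    arma::vec gIr = WIs * s;
    spikes.zeros();
    int bin = t / bin_steps;
    for (int i = 0; i < n; ++i) {
      double Vi = V(i);
      double u = Vi - VT;
      double an = 0.032 * vtrap(-(u - 15.0), 5.0);
      double bn = 0.5 * std::exp(-(u - 10.0) / 40.0);
      double am = 0.32 * vtrap(-(u - 13.0), 4.0);
      double bm = 0.28 * vtrap(u - 40.0, 5.0);
      double ah = 0.128 * std::exp(-(u - 17.0) / 18.0);
      double bh = 4.0 / (1.0 + std::exp(-(u - 40.0) / 5.0));
      double qinf = 1.0 / (1.0 + std::exp(-(Vi + 35.0) / 10.0));
      double tq = tau_max_q /
        (3.3 * std::exp((Vi + 35.0) / 20.0) + std::exp(-(Vi + 35.0) / 20.0));

      gn(i) += dt * ftau * (an * (1.0 - gn(i)) - bn * gn(i));
      gm(i) += dt * ftau * (am * (1.0 - gm(i)) - bm * gm(i));
      gh(i) += dt * ftau * (ah * (1.0 - gh(i)) - bh * gh(i));
      gq(i) += dt * ftau * (qinf - gq(i)) / tq;

      double Iion = gL * (Vi - VL) + gK * std::pow(gn(i), 4) * (Vi - VK) +
        gM * gq(i) * (Vi - VK) +
        gNa * gm(i) * gm(i) * gm(i) * gh(i) * (Vi - VNa);
      // I0 is a depolarizing bias: it enters the voltage equation with
      // the opposite sign to the conductance terms
      double Isyn = alpha(i) *
        (gEr(i) * (Vi - VE) + gIr(i) * (Vi - VI) - I0) * A(i);
      double Vnew = Vi + dt * (-Iion - Isyn) / Cm;
      if (!std::isfinite(Vnew) || std::fabs(Vnew) > 500.0)
        stop("membrane potential diverged at step %d", t);
      if (Vi < 0.0 && Vnew >= 0.0) {
        spikes(i) = 1.0;
        sp_cell.push_back(i);
        sp_step.push_back(t);
        counts(i, bin) += 1.0;
      }
      V(i) = Vnew;
    }
    s = decay * s + spikes;
    double lo = std::min(std::min(gn.min(), gm.min()),
                         std::min(gh.min(), gq.min()));
    double hi = std::max(std::max(gn.max(), gm.max()),
                         std::max(gh.max(), gq.max()));
    gate_min = std::min(gate_min, lo);
    gate_max = std::max(gate_max, hi);
  }

  return List::create(_["spike_cell"] = wrap(sp_cell),
                      _["spike_step"] = wrap(sp_step),
                      _["counts"] = counts,
                      _["gate_min"] = gate_min,
                      _["gate_max"] = gate_max);
}
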