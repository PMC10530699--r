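// Core numerical kernels: LIF input encoder, batched SRNN forward dynamics,
// and the matching backpropagation-through-time pass with the SuperSpike
// fast-sigmoid surrogate standing in for the threshold derivative.
//
// Conventions:
//  * voltages in mV, currents in nA, time in ms; r_eff = R in mV/nA
//  * the surrogate argument is converted to volts (beta_mv = beta / 1000)
//  * state cubes are (n_rec x n_batch x n_step); slice t holds step t
//  * spikes entering step t are those emitted at step t-1 (initially zero)
//  * the surrogate cube H is 0 exactly where a unit is refractory-clamped,
//    so (H != 0) doubles as the gradient gate on the membrane path

#include <RcppArmadillo.h>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

// ---- self-contained fast RNG (xoshiro256++, Box-Muller normals) so that
// noise generation is cheap and bit-reproducible given a seed ----
struct FastRng {
  std::uint64_t s[4];
  bool has_cached = false;
  double cached = 0.0;

  explicit FastRng(std::uint64_t seed) {
    // splitmix64 seeding
    std::uint64_t x = seed + 0x9E3779B97F4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      std::uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline std::uint64_t next() {
    const std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const std::uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {            // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_cached) { has_cached = false; return cached; }
    const double u = unif(), v = unif();
    const double r = std::sqrt(-2.0 * std::log(u));
    const double a = 6.283185307179586 * v;
    cached = r * std::sin(a);
    has_cached = true;
    return r * std::cos(a);
  }
};

// Exponential-Euler LIF encoder: currents (n_channels x n_step) -> binary
// spikes. Threshold crossing resets to v_rest; no refractory period.
// [[Rcpp::export]]
arma::mat cpp_lif_encode(const arma::mat& I, double tau_m, double v_rest,
                         double v_th, double r, double dt) {
  const uword nc = I.n_rows, nt = I.n_cols;
  const double a = std::exp(-dt / tau_m);
  vec V(nc, fill::value(v_rest));
  mat S(nc, nt, fill::zeros);
  for (uword t = 0; t < nt; ++t) {
    V = v_rest + a * (V - v_rest) + (1.0 - a) * r * I.col(t);
    for (uword i = 0; i < nc; ++i) {
      if (V(i) >= v_th) { S(i, t) = 1.0; V(i) = v_rest; }
    }
  }
  return S;
}

struct StepParams {
  double alpha_m, one_minus_alpha_m, r_eff, v_rest, v_th, psi, phi_a;
  double beta_mv, sigma_m, sigma_base;
  int ref_steps;
  double dec_alpha_syn, dec_alpha_m;
  uword n_exc;
};

static StepParams unpack_params(const List& p) {
  StepParams sp;
  double dt = as<double>(p["dt"]);
  sp.alpha_m = std::exp(-dt / as<double>(p["tau_m"]));
  sp.one_minus_alpha_m = 1.0 - sp.alpha_m;
  sp.r_eff = as<double>(p["r_eff"]);
  sp.v_rest = as<double>(p["v_rest"]);
  sp.v_th = as<double>(p["v_th"]);
  sp.psi = as<double>(p["psi"]);
  sp.phi_a = std::exp(-dt / as<double>(p["tau_a"]));
  sp.beta_mv = as<double>(p["beta"]) * 1e-3;
  sp.sigma_m = as<double>(p["sigma_m"]);
  sp.sigma_base = as<double>(p["sigma_base"]);
  sp.ref_steps = as<int>(p["ref_steps"]);
  sp.dec_alpha_syn = std::exp(-dt / as<double>(p["dec_tau_syn"]));
  sp.dec_alpha_m = std::exp(-dt / as<double>(p["dec_tau_m"]));
  sp.n_exc = as<uword>(p["n_exc"]);
  return sp;
}

// sparse accumulation of presynaptic weight columns (spikes are a few
// percent dense, so this beats a dense matrix product)
static void add_weighted_spikes(mat& acc, const mat& W, const double* Sp,
                                uword n, uword nb) {
  for (uword j = 0; j < nb; ++j) {
    const double* sc = Sp + j * n;
    double* ac = acc.colptr(j);
    for (uword k = 0; k < n; ++k) {
      if (sc[k] != 0.0) {
        const double* wc = W.colptr(k);
        for (uword i = 0; i < n; ++i) ac[i] += wc[i];
      }
    }
  }
}

// full-trial forward dynamics; writes spike/surrogate/decoder trajectories
// into caller-allocated cubes. Vtr/Itr are filled only if non-null.
static void forward_core(const cube& X, const mat& w_in, const mat& w_rec,
                         const mat& w_out, const vec& a_mask,
                         const vec& alpha_syn, const vec& i_base0,
                         const StepParams& sp, bool smooth,
                         double noise_scale, unsigned int seed,
                         const mat& v0, cube& S, cube& H, cube& VdecTr,
                         cube* Vtr, cube* Itr) {
  const uword nb = X.n_cols, nt = X.n_slices;
  const uword n = w_rec.n_rows;

  FastRng rng(seed);

  mat V(n, nb);
  if (v0.n_rows == n && v0.n_cols == nb) {
    V = v0;
  } else {
    double* vp = V.memptr();
    for (uword k = 0; k < n * nb; ++k)
      vp[k] = sp.v_rest + (sp.v_th - sp.v_rest) * rng.unif();
  }

  mat I(n, nb, fill::zeros), A(n, nb, fill::zeros);
  mat Ibase = repmat(i_base0, 1, nb);
  Mat<int> refrac(n, nb, fill::zeros);
  const mat Szero(n, nb, fill::zeros);
  mat SprevE(sp.n_exc, nb, fill::zeros);
  mat Idec(w_out.n_rows, nb, fill::zeros), Vdec(w_out.n_rows, nb,
                                                fill::zeros);
  mat Iin(n, nb);
  const bool noisy = noise_scale > 0.0;
  const double sm = sp.sigma_m * noise_scale;
  const double sb = sp.sigma_base * noise_scale;
  const uword ntot = n * nb;
  const double c_i = sp.one_minus_alpha_m * sp.r_eff;

  for (uword t = 0; t < nt; ++t) {
    const double* sprev = (t == 0) ? Szero.memptr() : S.slice_memptr(t - 1);

    // decoder integrates last step's excitatory spikes
    for (uword j = 0; j < nb; ++j)
      for (uword i = 0; i < sp.n_exc; ++i)
        SprevE(i, j) = sprev[i + j * n];
    Idec = sp.dec_alpha_syn * Idec + w_out * SprevE;
    Vdec = sp.dec_alpha_m * Vdec + (1.0 - sp.dec_alpha_m) * Idec;
    VdecTr.slice(t) = Vdec;

    // synaptic current: decay + weighted presynaptic spikes + baseline
    Iin = w_in * X.slice(t);
    {
      double* ip = I.memptr();
      const double* xp = Iin.memptr();
      const double* bp = Ibase.memptr();
      const double* ap = alpha_syn.memptr();
      for (uword k = 0; k < ntot; ++k)
        ip[k] = ap[k % n] * ip[k] + xp[k] + bp[k];
    }
    if (smooth) I += w_rec * mat(const_cast<double*>(sprev), n, nb, false);
    else add_weighted_spikes(I, w_rec, sprev, n, nb);

    // membrane potential (exponential Euler) + noise, adaptation,
    // effective threshold and spike emission, fused elementwise
    double* vp = V.memptr();
    double* ap_ = A.memptr();
    double* ip = I.memptr();
    const double* amp = a_mask.memptr();
    double* hp = H.slice_memptr(t);
    double* sn = S.slice_memptr(t);
    int* rp = refrac.memptr();
    for (uword k = 0; k < ntot; ++k) {
      const uword i = k % n;
      double v = sp.v_rest + sp.alpha_m * (vp[k] - sp.v_rest) + c_i * ip[k];
      if (noisy) v += rng.norm() * sm;
      ap_[k] = sp.phi_a * ap_[k] + (1.0 - sp.phi_a) * sprev[k];
      const double th = sp.v_th + sp.psi * amp[i] * ap_[k];
      if (!smooth && rp[k] > 0) {
        // clamped at rest; cannot spike, no gradient through V
        v = sp.v_rest;
        rp[k] -= 1;
        sn[k] = 0.0;
        hp[k] = 0.0;
      } else {
        const double dv = v - th;
        const double dn = 1.0 + sp.beta_mv * std::fabs(dv);
        hp[k] = 1.0 / (dn * dn);
        if (smooth) {
          // fast-sigmoid soft spike g(x) = x / (1 + beta|x|); g' is the
          // surrogate, making this model exactly differentiable
          sn[k] = dv / dn;
        } else if (dv >= 0.0) {
          sn[k] = 1.0;
          v = sp.v_rest;                    // reset (detached in backward)
          rp[k] = sp.ref_steps;
        } else {
          sn[k] = 0.0;
        }
      }
      vp[k] = v;
    }

    if (Vtr) Vtr->slice(t) = V;
    if (Itr) Itr->slice(t) = I;

    // baseline current random walk
    if (noisy) {
      double* bp = Ibase.memptr();
      for (uword k = 0; k < ntot; ++k) bp[k] += rng.norm() * sb;
    }

    if (!V.is_finite())
      stop("non-finite membrane potential at step %d", (int)(t + 1));
  }
}

// BPTT through a recorded trajectory. Gradients of
//   L = 1/(2 * scored * nb) * sum_{trials, outputs, last `scored` steps}
//       (y - Vdec)^2  +  lambda * sum_bins (mean instantaneous rate, Hz)^2
// with respect to w_in, w_rec (signed effective matrix) and w_out.
// `hard` replays the detached-reset/refractory gating of the spiking
// forward pass; the smoothed model uses hard = false.
static void backward_core(const cube& X, const cube& S, const cube& H,
                          const cube& VdecTr, const mat& y, const mat& w_rec,
                          const mat& w_out, const vec& a_mask,
                          const vec& alpha_syn, const StepParams& sp,
                          double dt, double lambda, int scored,
                          int bin_steps, bool hard, mat& g_in, mat& g_rec,
                          mat& g_out) {
  const uword nb = X.n_cols, nt = X.n_slices;
  const uword n = w_rec.n_rows;
  const double bin_sec = bin_steps * dt / 1000.0;

  // per-bin mean instantaneous rate (Hz) across units and trials
  const uword n_bin = nt / bin_steps;
  vec mbin(n_bin, fill::zeros);
  if (lambda > 0) {
    for (uword b = 0; b < n_bin; ++b) {
      double s = 0.0;
      for (uword k = 0; k < (uword)bin_steps; ++k)
        s += accu(S.slice(b * bin_steps + k));
      mbin(b) = s / (bin_sec * n * nb);
    }
  }

  g_in.zeros(n, X.n_rows);
  g_rec.zeros(n, n);
  g_out.zeros(w_out.n_rows, sp.n_exc);
  const mat w_rec_t = w_rec.t();
  const mat w_out_t = w_out.t();

  mat dV(n, nb, fill::zeros);      // adjoint of post-reset V(t)
  mat dI(n, nb, fill::zeros);      // adjoint of I(t+1), decayed on use
  mat dA(n, nb, fill::zeros);      // adjoint of A(t+1)
  mat dSfut(n, nb, fill::zeros);   // accumulated gradient into S(t)
  mat dI_t(n, nb);
  mat SprevE(sp.n_exc, nb);
  mat dIdec(w_out.n_rows, nb, fill::zeros);
  mat dVdec(w_out.n_rows, nb, fill::zeros);

  const double inv_scored_nb = 1.0 / ((double)scored * nb);
  const double c_i = sp.one_minus_alpha_m * sp.r_eff;

  for (uword tt = nt; tt-- > 0;) {
    // ---- decoder ----
    mat dVd = sp.dec_alpha_m * dVdec;
    if (tt >= nt - (uword)scored)
      dVd += (VdecTr.slice(tt) - y) * inv_scored_nb;
    mat dId = (1.0 - sp.dec_alpha_m) * dVd + sp.dec_alpha_syn * dIdec;
    dIdec = dId;
    dVdec = dVd;

    const double* sprev = (tt == 0) ? nullptr : S.slice_memptr(tt - 1);
    if (sprev) {
      // decoder at step tt consumed excitatory S(tt - 1)
      for (uword j = 0; j < nb; ++j)
        for (uword i = 0; i < sp.n_exc; ++i)
          SprevE(i, j) = sprev[i + j * n];
      g_out += dId * SprevE.t();
    }

    // ---- recurrent population: fused elementwise adjoint updates ----
    const double reg = (lambda > 0 && tt / bin_steps < n_bin)
      ? lambda * 2.0 * mbin(tt / bin_steps) / (bin_sec * n * nb) : 0.0;
    {
      const double* hp = H.slice_memptr(tt);
      const double* sp_ = S.slice_memptr(tt);
      const double* fp = dSfut.memptr();
      const double* amp = a_mask.memptr();
      const double* ap = alpha_syn.memptr();
      double* dvp = dV.memptr();
      double* dip = dI.memptr();
      double* dap = dA.memptr();
      double* dtp = dI_t.memptr();
      const uword ntot = n * nb;
      for (uword k = 0; k < ntot; ++k) {
        const uword i = k % n;
        const double ds = fp[k] + reg;
        const double hds = hp[k] * ds;
        dap[k] = sp.phi_a * dap[k] - sp.psi * amp[i] * hds;
        double dvpre = hds + (hard ? (1.0 - sp_[k]) * dvp[k] : dvp[k]);
        if (hard && hp[k] == 0.0) dvpre = 0.0;   // refractory clamp
        dtp[k] = c_i * dvpre + ap[i] * dip[k];
        dvp[k] = sp.alpha_m * dvpre;
        dip[k] = dtp[k];
      }
    }

    g_in += dI_t * X.slice(tt).t();
    if (sprev) {
      if (hard) {
        // spikes are sparse binary: accumulate columns of the outer product
        for (uword j = 0; j < nb; ++j) {
          const double* sc = sprev + j * n;
          const double* dc = dI_t.colptr(j);
          for (uword k = 0; k < n; ++k) {
            if (sc[k] != 0.0) {
              double* gc = g_rec.colptr(k);
              for (uword i = 0; i < n; ++i) gc[i] += dc[i];
            }
          }
        }
      } else {
        g_rec += dI_t * mat(const_cast<double*>(sprev), n, nb, false).t();
      }
      dSfut = w_rec_t * dI_t + (1.0 - sp.phi_a) * dA;
      dSfut.rows(0, sp.n_exc - 1) += w_out_t * dId;
    }
  }
}

static void loss_core(const cube& S, const cube& VdecTr, const mat& y,
                      double lambda, int scored, int bin_steps, double dt,
                      double& mse, double& fr) {
  const uword nt = VdecTr.n_slices, nb = VdecTr.n_cols;
  mse = 0.0;
  for (uword t = nt - scored; t < nt; ++t)
    mse += accu(square(y - VdecTr.slice(t)));
  mse /= (2.0 * scored * nb);

  fr = 0.0;
  const double bin_sec = bin_steps * dt / 1000.0;
  const uword n_bin = nt / bin_steps, n = S.n_rows;
  for (uword b = 0; b < n_bin; ++b) {
    double s = 0.0;
    for (uword k = 0; k < (uword)bin_steps; ++k)
      s += accu(S.slice(b * bin_steps + k));
    const double m = s / (bin_sec * n * nb);
    fr += m * m;
  }
}

// ---- exported wrappers ----

// [[Rcpp::export]]
List cpp_srnn_forward(const arma::cube& X, const arma::mat& w_in,
                      const arma::mat& w_rec, const arma::mat& w_out,
                      const arma::vec& a_mask, const arma::vec& alpha_syn,
                      const arma::vec& i_base0, const List& params,
                      bool smooth, double noise_scale, bool want_grad,
                      bool want_state, unsigned int seed,
                      const arma::mat& v0) {
  const StepParams sp = unpack_params(params);
  const uword nb = X.n_cols, nt = X.n_slices, n = w_rec.n_rows;
  cube S(n, nb, nt), H(n, nb, nt), VdecTr(w_out.n_rows, nb, nt);
  cube Vtr, Itr;
  if (want_state) { Vtr.set_size(n, nb, nt); Itr.set_size(n, nb, nt); }
  forward_core(X, w_in, w_rec, w_out, a_mask, alpha_syn, i_base0, sp,
               smooth, noise_scale, seed, v0, S, H, VdecTr,
               want_state ? &Vtr : nullptr, want_state ? &Itr : nullptr);
  List out = List::create(_["S"] = S, _["v_dec"] = VdecTr,
                          _["v_dec_final"] = VdecTr.slice(nt - 1));
  if (want_grad) out["H"] = H;
  if (want_state) { out["V"] = Vtr; out["I"] = Itr; }
  return out;
}

// [[Rcpp::export]]
List cpp_srnn_backward(const arma::cube& X, const arma::cube& S,
                       const arma::cube& H, const arma::cube& VdecTr,
                       const arma::mat& y, const arma::mat& w_rec,
                       const arma::mat& w_out, const arma::vec& a_mask,
                       const arma::vec& alpha_syn, const List& params,
                       double lambda, int scored, int bin_steps,
                       bool hard) {
  const StepParams sp = unpack_params(params);
  const double dt = as<double>(params["dt"]);
  mat g_in, g_rec, g_out;
  backward_core(X, S, H, VdecTr, y, w_rec, w_out, a_mask, alpha_syn, sp,
                dt, lambda, scored, bin_steps, hard, g_in, g_rec, g_out);
  return List::create(_["g_in"] = g_in, _["g_rec"] = g_rec,
                      _["g_out"] = g_out);
}

// fused training step: forward (hard threshold, noise on) + surrogate BPTT
// without round-tripping the state cubes through R
// [[Rcpp::export]]
List cpp_srnn_grad(const arma::cube& X, const arma::mat& w_in,
                   const arma::mat& w_rec, const arma::mat& w_out,
                   const arma::vec& a_mask, const arma::vec& alpha_syn,
                   const arma::vec& i_base0, const List& params,
                   const arma::mat& y, double lambda, int scored,
                   int bin_steps, double noise_scale, unsigned int seed) {
  const StepParams sp = unpack_params(params);
  const double dt = as<double>(params["dt"]);
  const uword nb = X.n_cols, nt = X.n_slices, n = w_rec.n_rows;
  cube S(n, nb, nt), H(n, nb, nt), VdecTr(w_out.n_rows, nb, nt);
  mat v0(0, 0);
  forward_core(X, w_in, w_rec, w_out, a_mask, alpha_syn, i_base0, sp,
               false, noise_scale, seed, v0, S, H, VdecTr, nullptr,
               nullptr);
  mat g_in, g_rec, g_out;
  backward_core(X, S, H, VdecTr, y, w_rec, w_out, a_mask, alpha_syn, sp,
                dt, lambda, scored, bin_steps, true, g_in, g_rec, g_out);
  double mse, fr;
  loss_core(S, VdecTr, y, lambda, scored, bin_steps, dt, mse, fr);
  return List::create(_["g_in"] = g_in, _["g_rec"] = g_rec,
                      _["g_out"] = g_out, _["mse"] = mse, _["fr"] = fr,
                      _["total"] = mse + lambda * fr);
}

// [[Rcpp::export]]
List cpp_srnn_loss(const arma::cube& S, const arma::cube& VdecTr,
                   const arma::mat& y, double lambda, int scored,
                   int bin_steps, double dt) {
  double mse, fr;
  loss_core(S, VdecTr, y, lambda, scored, bin_steps, dt, mse, fr);
  return List::create(_["mse"] = mse, _["fr"] = fr,
                      _["total"] = mse + lambda * fr);
}
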