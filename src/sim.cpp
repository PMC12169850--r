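// Fused Euler loops for the three network variants. The R functions in
// R/dynamics.R and R/plasticity.R implement the same single-step operations;
// test-engine.R asserts bit-identical trajectories (both sides consume R's
// RNG stream in the same order: K input uniforms, then N spike uniforms per
// step, E before I in the two-population model).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// static sigmoid phi(v) = phi0 / (1 + exp(a * (th - v))), a = g*beta0, th = g*theta0
static inline arma::vec phi_static(const arma::vec& v, double a, double th,
                                   double phi0) {
  return phi0 / (1.0 + arma::exp(a * (th - v)));
}

// shared prediction-error factor phi0^-1 (1 - phi/phi0) (f - phi)
static inline arma::vec err_term(const arma::vec& f, const arma::vec& v,
                                 double a, double th, double phi0) {
  arma::vec p = phi_static(v, a, th, phi0);
  return (1.0 / phi0) * (1.0 - p / phi0) % (f - p);
}

// h is a two-timescale envelope of u in units of the resting threshold
// g*theta0: rises toward u/(g*theta0) with tau_r, decays with tau_h,
// clamped at h_floor
static inline long update_h_vec(arma::vec& h, const arma::vec& u, double th,
                                double decay_h, double rise_r,
                                double h_floor) {
  const arma::uword n = h.n_elem;
  long clamps = 0;
  for (arma::uword i = 0; i < n; ++i) {
    double un = u[i] / th;
    if (h[i] > un) h[i] *= decay_h; else h[i] += (un - h[i]) * rise_r;
    if (h[i] < h_floor) { h[i] = h_floor; ++clamps; }
  }
  return clamps;
}

static inline void draw_input(arma::vec& x, const arma::mat& prob, int prog,
                              double decay) {
  const arma::uword K = x.n_elem;
  for (arma::uword k = 0; k < K; ++k) {
    double s = (R::unif_rand() < prob(k, prog)) ? 1.0 : 0.0;
    x[k] = x[k] * decay + s;
  }
}

static inline void draw_spikes(arma::vec& spikes, const arma::vec& f,
                               double p_scale) {
  const arma::uword n = f.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    spikes[i] = (R::unif_rand() < f[i] * p_scale) ? 1.0 : 0.0;
}

struct Recorder {
  int bin_steps, trace_every, max_raster;
  bool record_raster;
  arma::vec counts;
  arma::mat bins;     // N x nbins spike counts
  arma::mat traces;   // nrec x 6: t, errW, errM, errG, hbar, fbar
  std::vector<double> ras_id, ras_t;
  bool raster_truncated = false;
  int irec = 0;

  Recorder(int N, int steps, int bin_steps_, int trace_every_,
           bool record_raster_, int max_raster_)
      : bin_steps(bin_steps_), trace_every(trace_every_),
        max_raster(max_raster_), record_raster(record_raster_) {
    counts.zeros(N);
    if (bin_steps > 0) bins.zeros(N, (steps + bin_steps - 1) / bin_steps);
    if (trace_every > 0) traces.zeros(steps / trace_every, 6);
  }

  void spikes(const arma::vec& s, int step, double t_ms) {
    counts += s;
    if (bin_steps > 0) bins.col(step / bin_steps) += s;
    if (record_raster) {
      for (arma::uword i = 0; i < s.n_elem; ++i) {
        if (s[i] > 0) {
          if ((int)ras_id.size() >= max_raster) { raster_truncated = true; return; }
          ras_id.push_back((double)(i + 1));
          ras_t.push_back(t_ms);
        }
      }
    }
  }

  void trace(int step, double t_ms, const arma::vec& f, const arma::vec& h,
             const arma::vec& vW, const arma::vec& vM, const arma::vec& vG,
             double a, double th, double phi0) {
    if (trace_every <= 0 || ((step + 1) % trace_every) != 0) return;
    if (irec >= (int)traces.n_rows) return;
    traces(irec, 0) = t_ms;
    traces(irec, 1) = arma::mean(arma::abs(f - phi_static(vW, a, th, phi0)));
    traces(irec, 2) = arma::mean(arma::abs(f - phi_static(vM, a, th, phi0)));
    traces(irec, 3) = arma::mean(arma::abs(f - phi_static(vG, a, th, phi0)));
    traces(irec, 4) = arma::mean(h);
    traces(irec, 5) = arma::mean(f);
    ++irec;
  }

  List raster() const {
    return List::create(_["neuron"] = wrap(ras_id), _["time_ms"] = wrap(ras_t),
                        _["truncated"] = raster_truncated);
  }
};

// [[Rcpp::export]]
List sim_ndl_cpp(arma::mat W, arma::mat M, arma::mat G, arma::vec x,
                 arma::vec y, arma::vec h, double t0, const arma::mat& prob,
                 const IntegerVector& program, List par, bool plastic_W,
                 bool plastic_M, bool plastic_G, bool fixed_h,
                 const arma::mat& w_mask, bool use_wmask, int bin_steps,
                 int trace_every, bool record_raster, int max_raster) {
  const double dt = par["dt"], tau = par["tau"], tau_h = par["tau_h"],
               tau_r = par["tau_r"],
               phi0 = par["phi0"], g = par["g"], beta0 = par["beta0"],
               theta0 = par["theta0"], eta = par["eta"],
               h_floor = par["h_floor"];
  const double a = g * beta0, th = g * theta0;
  const double decay = std::exp(-dt / tau), decay_h = std::exp(-dt / tau_h);
  const double rise_r = 1.0 - std::exp(-dt / tau_r);
  const double p_scale = dt / 1000.0;
  const int steps = program.size();
  const int N = W.n_rows;

  Recorder rec(N, steps, bin_steps, trace_every, record_raster, max_raster);
  arma::vec spikes(N), u(N), vW(N), vM(N), vG(N), f(N);
  long h_clamps = 0;

  for (int s = 0; s < steps; ++s) {
    draw_input(x, prob, program[s] - 1, decay);
    vW = W * x;
    vM = M * y;
    vG = G * y;
    u = vW + vM - vG;
    if (((s & 255) == 0) && !u.is_finite())
      stop("non-finite membrane potential at t = %f ms", t0 + s * dt);
    if (!fixed_h) h_clamps += update_h_vec(h, u, th, decay_h, rise_r, h_floor);
    f = phi0 / (1.0 + arma::exp(a * (th * h - u)));
    draw_spikes(spikes, f, p_scale);
    if (plastic_W) {
      arma::mat dW = (eta * err_term(f, vW, a, th, phi0)) * x.t();
      if (use_wmask) dW %= w_mask;
      W += dW;
    }
    if (plastic_M) M += (eta * err_term(f, vM, a, th, phi0)) * y.t();
    if (plastic_G) {
      G += (eta * err_term(f, vG, a, th, phi0)) * y.t();
      G.clamp(0.0, arma::datum::inf);
    }
    y = y * decay + spikes;
    rec.spikes(spikes, s, t0 + (s + 1) * dt);
    rec.trace(s, t0 + (s + 1) * dt, f, h, vW, vM, vG, a, th, phi0);
  }

  return List::create(
      _["W"] = W, _["M"] = M, _["G"] = G, _["x"] = x, _["y"] = y, _["h"] = h,
      _["t"] = t0 + steps * dt, _["counts"] = rec.counts, _["bins"] = rec.bins,
      _["traces"] = rec.traces, _["raster"] = rec.raster(),
      _["h_clamps"] = (double)h_clamps);
}

// [[Rcpp::export]]
List sim_signed_cpp(arma::mat W, arma::mat Me, arma::mat Mi, arma::mat G,
                    const arma::mat& mask_e, const arma::mat& mask_i,
                    const arma::mat& mask_g, arma::vec x, arma::vec y,
                    arma::vec h, double t0, const arma::mat& prob,
                    const IntegerVector& program, List par, bool plastic_W,
                    bool plastic_M, bool plastic_G, bool fixed_h,
                    int bin_steps, int trace_every, bool record_raster,
                    int max_raster) {
  const double dt = par["dt"], tau = par["tau"], tau_h = par["tau_h"],
               tau_r = par["tau_r"],
               phi0 = par["phi0"], g = par["g"], beta0 = par["beta0"],
               theta0 = par["theta0"], eta = par["eta"],
               h_floor = par["h_floor"];
  const double a = g * beta0, th = g * theta0;
  const double decay = std::exp(-dt / tau), decay_h = std::exp(-dt / tau_h);
  const double rise_r = 1.0 - std::exp(-dt / tau_r);
  const double p_scale = dt / 1000.0;
  const int steps = program.size();
  const int N = W.n_rows;

  Recorder rec(N, steps, bin_steps, trace_every, record_raster, max_raster);
  arma::vec spikes(N), u(N), vW(N), vJ(N), vG(N), f(N);
  long h_clamps = 0;

  for (int s = 0; s < steps; ++s) {
    draw_input(x, prob, program[s] - 1, decay);
    vW = W * x;
    vJ = Me * y - Mi * y;  // joint excitatory-inhibitory recurrent prediction
    vG = G * y;
    u = vW + vJ - vG;
    if (((s & 255) == 0) && !u.is_finite())
      stop("non-finite membrane potential at t = %f ms", t0 + s * dt);
    if (!fixed_h) h_clamps += update_h_vec(h, u, th, decay_h, rise_r, h_floor);
    f = phi0 / (1.0 + arma::exp(a * (th * h - u)));
    draw_spikes(spikes, f, p_scale);
    if (plastic_W) W += (eta * err_term(f, vW, a, th, phi0)) * x.t();
    if (plastic_M) {
      arma::mat dJ = (eta * err_term(f, vJ, a, th, phi0)) * y.t();
      Me += dJ % mask_e;
      Mi -= dJ % mask_i;
      Me.clamp(0.0, arma::datum::inf);
      Mi.clamp(0.0, arma::datum::inf);
    }
    if (plastic_G) {
      G += ((eta * err_term(f, vG, a, th, phi0)) * y.t()) % mask_g;
      G.clamp(0.0, arma::datum::inf);
    }
    y = y * decay + spikes;
    rec.spikes(spikes, s, t0 + (s + 1) * dt);
    rec.trace(s, t0 + (s + 1) * dt, f, h, vW, vJ, vG, a, th, phi0);
  }

  return List::create(
      _["W"] = W, _["M_exc"] = Me, _["M_inh"] = Mi, _["G"] = G, _["x"] = x,
      _["y"] = y, _["h"] = h, _["t"] = t0 + steps * dt,
      _["counts"] = rec.counts, _["bins"] = rec.bins,
      _["traces"] = rec.traces, _["raster"] = rec.raster(),
      _["h_clamps"] = (double)h_clamps);
}

// Dale's-law model: populations X in {E, I}; per population the weights are
// W_X (signed afferent), M_XE (from E), G1_XI / G2_XI (the two inhibitory
// paths from I). Path 2 predicts jointly with excitation, path 1 alone.
// [[Rcpp::export]]
List sim_dl_cpp(arma::mat WE, arma::mat WI, arma::mat MEE, arma::mat MIE,
                arma::mat G1E, arma::mat G2E, arma::mat G1I, arma::mat G2I,
                arma::vec x, arma::vec yE, arma::vec yI, arma::vec hE,
                arma::vec hI, double t0, const arma::mat& prob,
                const IntegerVector& program, List par, bool plastic_W,
                bool plastic_M, bool plastic_G, bool fixed_h, int bin_steps,
                int trace_every, bool record_raster, int max_raster) {
  const double dt = par["dt"], tau = par["tau"], tau_h = par["tau_h"],
               tau_r = par["tau_r"],
               phi0 = par["phi0"], g = par["g"], beta0 = par["beta0"],
               theta0 = par["theta0"], eta = par["eta"],
               h_floor = par["h_floor"];
  const double a = g * beta0, th = g * theta0;
  const double decay = std::exp(-dt / tau), decay_h = std::exp(-dt / tau_h);
  const double rise_r = 1.0 - std::exp(-dt / tau_r);
  const double p_scale = dt / 1000.0;
  const int steps = program.size();
  const int NE = WE.n_rows, NI = WI.n_rows;

  Recorder recE(NE, steps, bin_steps, trace_every, record_raster, max_raster);
  Recorder recI(NI, steps, bin_steps, 0, record_raster, max_raster);
  arma::vec sE(NE), sI(NI);
  long h_clamps = 0;

  for (int s = 0; s < steps; ++s) {
    draw_input(x, prob, program[s] - 1, decay);

    arma::vec vWE = WE * x, vWI = WI * x;
    arma::vec v2E = MEE * yE - G2E * yI, v2I = MIE * yE - G2I * yI;
    arma::vec v1E = G1E * yI, v1I = G1I * yI;
    arma::vec uE = vWE + v2E - v1E, uI = vWI + v2I - v1I;
    if (((s & 255) == 0) && (!uE.is_finite() || !uI.is_finite()))
      stop("non-finite membrane potential at t = %f ms", t0 + s * dt);
    if (!fixed_h) {
      h_clamps += update_h_vec(hE, uE, th, decay_h, rise_r, h_floor);
      h_clamps += update_h_vec(hI, uI, th, decay_h, rise_r, h_floor);
    }
    arma::vec fE = phi0 / (1.0 + arma::exp(a * (th * hE - uE)));
    arma::vec fI = phi0 / (1.0 + arma::exp(a * (th * hI - uI)));
    draw_spikes(sE, fE, p_scale);
    draw_spikes(sI, fI, p_scale);

    if (plastic_W) {
      WE += (eta * err_term(fE, vWE, a, th, phi0)) * x.t();
      WI += (eta * err_term(fI, vWI, a, th, phi0)) * x.t();
    }
    if (plastic_M) {  // path-2 joint prediction drives M_XE and G2_XI
      arma::vec e2E = eta * err_term(fE, v2E, a, th, phi0);
      arma::vec e2I = eta * err_term(fI, v2I, a, th, phi0);
      MEE += e2E * yE.t();
      MIE += e2I * yE.t();
      G2E -= e2E * yI.t();
      G2I -= e2I * yI.t();
      MEE.clamp(0.0, arma::datum::inf);
      MIE.clamp(0.0, arma::datum::inf);
      G2E.clamp(0.0, arma::datum::inf);
      G2I.clamp(0.0, arma::datum::inf);
    }
    if (plastic_G) {  // path-1 prediction trains G1_XI alone
      G1E += (eta * err_term(fE, v1E, a, th, phi0)) * yI.t();
      G1I += (eta * err_term(fI, v1I, a, th, phi0)) * yI.t();
      G1E.clamp(0.0, arma::datum::inf);
      G1I.clamp(0.0, arma::datum::inf);
    }

    yE = yE * decay + sE;
    yI = yI * decay + sI;
    recE.spikes(sE, s, t0 + (s + 1) * dt);
    recI.spikes(sI, s, t0 + (s + 1) * dt);
    recE.trace(s, t0 + (s + 1) * dt, fE, hE, vWE, v2E, v1E, a, th, phi0);
  }

  return List::create(
      _["W_E"] = WE, _["W_I"] = WI, _["M_EE"] = MEE, _["M_IE"] = MIE,
      _["G1_EI"] = G1E, _["G2_EI"] = G2E, _["G1_II"] = G1I, _["G2_II"] = G2I,
      _["x"] = x, _["y_E"] = yE, _["y_I"] = yI, _["h_E"] = hE, _["h_I"] = hI,
      _["t"] = t0 + steps * dt, _["counts_E"] = recE.counts,
      _["counts_I"] = recI.counts, _["bins_E"] = recE.bins,
      _["bins_I"] = recI.bins, _["traces"] = recE.traces,
      _["raster_E"] = recE.raster(), _["raster_I"] = recI.raster(),
      _["h_clamps"] = (double)h_clamps);
}
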