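// Dynamic mean-field whole-brain simulator: reduced excitatory-inhibitory
// neural masses coupled by a connectome, with a Balloon-Windkessel
// haemodynamic observation model. Euler-Maruyama integration at sub-ms
// resolution; deterministic given the seed (internal 64-bit Mersenne
// twister, independent of R's RNG stream).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double phi_rate(double I, double a, double b, double d) {
  double x = a * I - b;
  if (std::abs(x) < 1e-9) return 1.0 / d;  // limit of x / (1 - exp(-d x))
  return x / (1.0 - std::exp(-d * x));
}

// [[Rcpp::export]]
List dmf_simulate_cpp(const arma::mat& C, double G, const arma::vec& J,
                      const arma::vec& ext_scale, double duration_s,
                      double tr_s, double dt_ms, double burn_s,
                      unsigned int seed, List consts) {
  const int N = C.n_rows;
  // reduced Wong-Wang constants (overridable)
  const double tauE  = as<double>(consts["tau_e_ms"]);    // 100 ms
  const double tauI  = as<double>(consts["tau_i_ms"]);    // 10 ms
  const double gam   = as<double>(consts["gamma"]);       // 0.641
  const double JN    = as<double>(consts["j_nmda"]);      // 0.15 nA
  const double I0    = as<double>(consts["i0"]);          // 0.382 nA
  const double WE    = as<double>(consts["w_e"]);         // 1.0
  const double WI    = as<double>(consts["w_i"]);         // 0.7
  const double wplus = as<double>(consts["w_plus"]);      // 1.4
  const double aE = as<double>(consts["a_e"]), bE = as<double>(consts["b_e"]),
               dE = as<double>(consts["d_e"]);
  const double aI = as<double>(consts["a_i"]), bI = as<double>(consts["b_i"]),
               dI = as<double>(consts["d_i"]);
  const double sigma = as<double>(consts["sigma"]);       // 0.01 nA

  // Balloon-Windkessel constants (time in seconds)
  const double kappa = as<double>(consts["bw_kappa"]);    // 0.65
  const double gam_h = as<double>(consts["bw_gamma"]);    // 0.41
  const double tau_h = as<double>(consts["bw_tau"]);      // 0.98
  const double alpha = as<double>(consts["bw_alpha"]);    // 0.32
  const double rho   = as<double>(consts["bw_rho"]);      // 0.34
  const double V0 = 0.02, k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;

  const double dt_s = dt_ms / 1000.0;
  const long n_steps = (long)std::llround((burn_s + duration_s) * 1000.0 / dt_ms);
  const long burn_steps = (long)std::llround(burn_s * 1000.0 / dt_ms);
  const long tr_steps = (long)std::llround(tr_s * 1000.0 / dt_ms);
  const int n_frames = (int)((n_steps - burn_steps) / tr_steps);
  if (n_frames < 2) stop("duration too short for the requested tr");

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);

  arma::vec SE(N, arma::fill::value(0.1)), SI(N, arma::fill::value(0.1));
  arma::vec hs(N, arma::fill::zeros), hf(N, arma::fill::ones),
            hv(N, arma::fill::ones), hq(N, arma::fill::ones);
  arma::vec rE(N), rI(N), IE(N), II(N);
  arma::vec rE_sum(N, arma::fill::zeros);
  long rE_count = 0;

  arma::mat bold(n_frames, N);
  int frame = 0;
  const double sqdt = std::sqrt(dt_ms) * sigma;
  const double inv_alpha = 1.0 / alpha;

  for (long step = 0; step < n_steps; ++step) {
    arma::vec coupling = C * SE;
    for (int i = 0; i < N; ++i) {
      IE(i) = WE * I0 * ext_scale(i) + wplus * JN * SE(i)
            + G * JN * coupling(i) - J(i) * SI(i);
      II(i) = WI * I0 + JN * SE(i) - SI(i);
      rE(i) = phi_rate(IE(i), aE, bE, dE);
      rI(i) = phi_rate(II(i), aI, bI, dI);
      SE(i) += dt_ms * (-SE(i) / tauE + (1.0 - SE(i)) * gam * rE(i) / 1000.0)
             + sqdt * gauss(rng);
      SI(i) += dt_ms * (-SI(i) / tauI + rI(i) / 1000.0)
             + sqdt * gauss(rng);
      if (SE(i) < 0.0) SE(i) = 0.0; else if (SE(i) > 1.0) SE(i) = 1.0;
      if (SI(i) < 0.0) SI(i) = 0.0; else if (SI(i) > 1.0) SI(i) = 1.0;

      // haemodynamics driven by the excitatory synaptic gating
      double z = SE(i);
      double f = hf(i), v = hv(i), q = hq(i);
      double v_a = std::pow(v, inv_alpha);
      double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f);
      hs(i) += dt_s * (z - kappa * hs(i) - gam_h * (f - 1.0));
      hf(i) += dt_s * hs(i);
      hv(i) += dt_s * (f - v_a) / tau_h;
      hq(i) += dt_s * (f * Ef / rho - q * v_a / v) / tau_h;
      if (hf(i) < 0.01) hf(i) = 0.01;
      if (hv(i) < 0.01) hv(i) = 0.01;
      if (hq(i) < 0.01) hq(i) = 0.01;
    }
    if (step >= burn_steps) { rE_sum += rE; rE_count++; }
    if (!SE.is_finite() || !hv.is_finite()) {
      stop("numerical blow-up (non-finite state) at step %ld", step);
    }
    if ((step + 1) > burn_steps && ((step + 1 - burn_steps) % tr_steps == 0)
        && frame < n_frames) {
      for (int i = 0; i < N; ++i) {
        bold(frame, i) = 100.0 * V0 *
          (k1 * (1.0 - hq(i)) + k2 * (1.0 - hq(i) / hv(i)) + k3 * (1.0 - hv(i)));
      }
      frame++;
    }
  }

  return List::create(_["bold"] = bold.rows(0, frame - 1),
                      _["mean_rate_e"] = rE_sum / std::max(rE_count, 1L),
                      _["n_frames"] = frame);
}
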