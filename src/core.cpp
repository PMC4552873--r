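// Compiled numerical cores: Euler-Maruyama integration of the dynamic
// mean-field network, Balloon-Windkessel hemodynamic integration, and
// brute-force k-nearest-neighbour distances for the nonparametric entropy
// estimator. All stochastic draws use R's RNG so set.seed() governs them.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sigmoidal f-I curve x/(1 - exp(-d x)) with x = a*u - b.
// Near x = 0 the removable singularity is evaluated by its series.
static inline double phi_rate(double u, double a, double b, double d) {
  double x = a * u - b;
  if (std::fabs(x) < 1e-4) {
    return 1.0 / d + x / 2.0 + d * x * x / 12.0;
  }
  return x / (1.0 - std::exp(-d * x));
}

static void fill_rnorm(arma::vec& v) {
  for (arma::uword i = 0; i < v.n_elem; ++i) v[i] = norm_rand();
}

// Integrate the stochastic gating equations for a trial ensemble.
// GC: premultiplied long-range matrix (G * w_net * C), N x N.
// S0: 2N x n_trials initial states (E block then I block).
// The stimulus Iext (nA, per node, E populations) is on for recorded steps
// s in [onset_step, offset_step). Recording happens every `subsample` steps,
// either of synaptic currents u (including Iext) or of gating variables.
// Returns a cube n_rec x 2N x n_trials.
// [[Rcpp::export]]
arma::cube sim_dmf_cpp(const arma::mat& GC, const arma::vec& wEI,
                       const List par, const arma::vec& Iext,
                       const int burn_steps, const int n_steps,
                       const int onset_step, const int offset_step,
                       const int subsample, const int n_trials,
                       const arma::mat& S0, const bool record_current) {
  const int N = GC.n_rows;
  const double aE = par["a_E"], bE = par["b_E"], dE = par["d_E"];
  const double aI = par["a_I"], bI = par["b_I"], dI = par["d_I"];
  const double tauE = par["tau_E"], tauI = par["tau_I"];
  const double gamma = par["gamma"];
  const double I0E = par["I0_E"], I0I = par["I0_I"];
  const double wEE = par["w_EE"], wIE = par["w_IE"], wII = par["w_II"];
  const double beta = par["beta"], dt = par["dt"];
  const double sq = beta * std::sqrt(dt);

  const int n_rec = (n_steps + subsample - 1) / subsample;
  arma::cube out(n_rec, 2 * N, n_trials);

  arma::vec SE(N), SI(N), uE(N), uI(N), nE(N), nI(N);
  for (int tr = 0; tr < n_trials; ++tr) {
    SE = S0.col(tr).rows(0, N - 1);
    SI = S0.col(tr).rows(N, 2 * N - 1);
    int irec = 0;
    for (int s = -burn_steps; s < n_steps; ++s) {
      const bool stim_on = (s >= onset_step && s < offset_step);
      uE = I0E + wEE * SE + GC * SE - wEI % SI;
      if (stim_on) uE += Iext;
      uI = I0I + wIE * SE - wII * SI;
      if (s >= 0 && s % subsample == 0) {
        if (record_current) {
          for (int i = 0; i < N; ++i) {
            out(irec, i, tr) = uE[i];
            out(irec, N + i, tr) = uI[i];
          }
        } else {
          for (int i = 0; i < N; ++i) {
            out(irec, i, tr) = SE[i];
            out(irec, N + i, tr) = SI[i];
          }
        }
        ++irec;
      }
      fill_rnorm(nE);
      fill_rnorm(nI);
      for (int i = 0; i < N; ++i) {
        const double rE = phi_rate(uE[i], aE, bE, dE);
        const double rI = phi_rate(uI[i], aI, bI, dI);
        double se = SE[i] + dt * (-SE[i] / tauE + (1.0 - SE[i]) * gamma * rE) +
                    sq * nE[i];
        double si = SI[i] + dt * (-SI[i] / tauI + rI) + sq * nI[i];
        if (se < 0.0) se = 0.0; else if (se > 1.0) se = 1.0;
        if (si < 0.0) si = 0.0; else if (si > 1.0) si = 1.0;
        SE[i] = se;
        SI[i] = si;
      }
      if (!SE.is_finite() || !SI.is_finite()) {
        stop("simulation diverged (non-finite state) at step %d of trial %d",
             s, tr + 1);
      }
    }
  }
  return out;
}

// Balloon-Windkessel hemodynamics: vasodilatory signal s, inflow f,
// volume v, deoxyhemoglobin q, driven by neural signal z (nodes x time).
// Deterministic Euler integration at step dt from the resting state.
// Returns the BOLD percent-change series, nodes x time.
// [[Rcpp::export]]
arma::mat balloon_cpp(const arma::mat& drive, const double dt,
                      const double kappa, const double gam,
                      const double tau, const double alpha,
                      const double rho, const double V0) {
  const int N = drive.n_rows, T = drive.n_cols;
  const double k1 = 7.0 * rho, k2 = 2.0, k3 = 2.0 * rho - 0.2;
  const double ialpha = 1.0 / alpha;
  arma::vec s(N, arma::fill::zeros), f(N, arma::fill::ones),
      v(N, arma::fill::ones), q(N, arma::fill::ones);
  arma::mat bold(N, T);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      bold(i, t) =
          100.0 * V0 * (k1 * (1.0 - q[i]) + k2 * (1.0 - q[i] / v[i]) +
                        k3 * (1.0 - v[i]));
      const double vout = std::pow(v[i], ialpha);
      const double Ef = 1.0 - std::pow(1.0 - rho, 1.0 / f[i]);
      const double ds = drive(i, t) - kappa * s[i] - gam * (f[i] - 1.0);
      const double dfl = s[i];
      const double dv = (f[i] - vout) / tau;
      const double dq = (f[i] * Ef / rho - vout * q[i] / v[i]) / tau;
      s[i] += dt * ds;
      f[i] += dt * dfl;
      v[i] += dt * dv;
      q[i] += dt * dq;
      if (v[i] < 1e-6 || q[i] < 1e-6 || !std::isfinite(q[i])) {
        stop("hemodynamic state left its physical range at node %d", i + 1);
      }
    }
  }
  return bold;
}

// Distance to the k-th nearest neighbour of each row of X (excluding the
// point itself). Brute force, O(n^2 d); adequate for the sample sizes used
// by the entropy estimator.
// [[Rcpp::export]]
arma::vec knn_kth_dist_cpp(const arma::mat& X, const int k) {
  const int n = X.n_rows;
  if (k >= n) stop("need more samples than neighbours");
  arma::vec out(n);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    const arma::rowvec xi = X.row(i);
    for (int j = 0; j < n; ++j) {
      const arma::rowvec dv = X.row(j) - xi;
      d2[j] = arma::dot(dv, dv);
    }
    d2[i] = std::numeric_limits<double>::infinity();
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    out[i] = std::sqrt(d2[k - 1]);
  }
  return out;
}
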