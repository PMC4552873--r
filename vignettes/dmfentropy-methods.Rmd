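---
title: "Modeling stimulus-driven contraction of cortical activity space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stimulus-driven contraction of cortical activity space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfentropy)
```

## The model

`dmfentropy` implements a whole-cortex dynamic mean-field model: `N` brain
regions, each a pair of excitatory (E) and inhibitory (I) neural
populations, coupled through a structural connectome `C` (DSI/tractography
fiber densities, zero diagonal). The state of region `i` is the pair of
synaptic gating fractions `S_E[i], S_I[i]` (fraction of open channels, in
`[0, 1]`). Input currents are

    u_E[i] = I0_E + w_EE S_E[i] + G w_net sum_j C[i,j] S_E[j]
             - w_EI[i] S_I[i] + I_ext[i]
    u_I[i] = I0_I + w_IE S_E[i] - w_II S_I[i]

and population rates follow the soft-rectifying sigmoid
`r = (a u - b) / (1 - exp(-d (a u - b)))`. The gating dynamics are

    dS_E/dt = -S_E/tau_E + (1 - S_E) gamma r_E + beta eta_E(t)
    dS_I/dt = -S_I/tau_I + r_I + beta eta_I(t)

with independent unit white noises per population and node. A "task" is a
set of regions whose excitatory populations receive a constant extra
current `I_ext` (default 0.02 nA to 8 regions); the spontaneous (rest)
condition is `I_ext = 0`.

Parameter defaults (`dmf_params()`) are the canonical reduced Wong-Wang
constants: `a_E = 310` nC^-1, `b_E = 125` Hz, `d_E = 0.16` s, `a_I = 615`
nC^-1, `b_I = 177` Hz, `d_I = 0.087` s, `tau_E = 0.1` s (NMDA),
`tau_I = 0.01` s (GABA), `gamma = 0.641`, `I0_E = 0.3438` nA,
`I0_I = 0.2674` nA, `w_EE = 0.21`, `w_IE = 0.15`, `w_II = 1`,
`beta = 0.01`, `dt = 1e-4` s. The long-range efficacy `w_net = 0.15` nA is
the same NMDA conductance that appears inside the local weights
(`w_EE = 1.4 * w_net`, `w_IE = w_net`); the dimensionless global coupling
`G` scales it. Every constant is a plain list entry and can be overridden.

## Feedback inhibition control

`calibrate_fic()` sets the per-node inhibitory-to-excitatory weight
`w_EI[i]` so the stationary excitatory rate of every node equals the
target (3 Hz), connected or not. Because the target pins every `S_E` to
the same value, the calibration is algebraic rather than iterative: the
required E current is the inverse transfer function at the target rate,
the I population solves a scalar fixed-point equation independent of
`w_EI`, and each node's weight balances its current budget, which grows
linearly with its in-strength `sum_j C[i,j]`. The result is verified by a
damped-Newton solve of the full network drift (machine-precision residual)
and a Hurwitz check of the analytic Jacobian. The procedure is exact,
deterministic and runs in milliseconds at `N = 66`; an iterative
controller would converge to the same weights, since the stationary rate
of a node is strictly decreasing in its own `w_EI` (a tested property).

## Linear noise approximation

For weak noise the fluctuations around the deterministic fixed point `mu`
are Gaussian with covariance `P` solving `A P + P A' + Qn = 0`, where `A`
is the analytic Jacobian at `mu` and `Qn = beta^2 I` (continuous-time
intensity; `generate_correlated_noise_covariance()` provides non-diagonal
variants modeling shared background noise). Everything else follows from
`(mu, A, P)`:

* synaptic-current covariance `Cv = W P W'` with the block coupling map
  `W` (`coupling_matrix()`);
* stationary autocovariance `F_u(tau) = W e^{tau A} P W'`, per-node
  autocorrelation `ACF(tau)`, and the decay timescale T95 — the lag at
  which the node-averaged ACF of a population first reaches 0.05,
  linearly interpolated between grid points;
* cross-spectra `Pi_u(w) = W (A + iw)^{-1} Qn (A' - iw)^{-1} W^H`, PSD =
  real diagonal;
* condition contrasts: `Dm`, `Dsigma2`, `DPSD` (percent change task vs
  spontaneous), the across-node `Dm`-`Dsigma2` correlation, functional
  connectivity similarity, and pairwise covariance/correlation changes;
* Gaussian differential entropy of the E- and I-block current covariances
  (bits) and the Kullback-Leibler divergence of each block from the
  corresponding intrinsic-noise block — the uncertainty the network
  dynamics add to their noise input.

`beta` cancels from every relative quantity (`Dsigma2`, `DPSD`, ACF, T95,
FC similarity, entropy differences, KLD): rescaling `Qn -> c Qn` is a
tested invariance.

### Numerical choices

* The Lyapunov equation is solved through the eigendecomposition of `A`
  (`X[i,j] = -Qt[i,j]/(l_i + l_j)` in the eigenbasis); the relative
  residual must be below `1e-8` or the solve aborts. No explicit matrix
  inverses are formed elsewhere either: spectra use complex linear solves,
  entropies use Cholesky log-determinants.
* `e^{dtau A}` is built once from the same eigendecomposition and reused
  along the uniform lag grid.
* The transfer function's removable singularity at `a u = b` is evaluated
  by its series within `|a u - b| < 1e-4`, keeping the function and its
  derivative smooth there (the Jacobian needs the derivative).
* Fixed points are found by damped Newton iteration with backtracking;
  stimulated states use continuation in the input amplitude (the evoked
  branch can fold for strong inputs), with a relaxation fallback that
  integrates the deterministic flow before polishing. Tolerance `1e-12`
  on the max drift component.
* Spectra use the two-sided angular-frequency convention,
  `var = (1/2pi) integral S(w) dw`, reported on a Hz axis; Parseval
  recovery of the variance within 1% is a tested contract. Spectral-change
  minima are localized by parabolic interpolation in log-frequency on a
  400-point logarithmic grid (0.01-200 Hz).
* The stochastic simulator is plain Euler-Maruyama (`beta sqrt(dt) N(0,1)`
  per step) in compiled code, `dt = 0.1` ms, with gating clamped to
  `[0, 1]` after each step; trials start from the fixed point and discard
  a 2 s burn-in so recording begins in the stationary distribution. The
  simulator is cross-checked against the Lyapunov covariance and the
  matrix-exponential ACF at 1000-1500 trials.
* The Balloon-Windkessel stage uses the standard constants
  (`kappa = 0.65` s^-1, `gamma = 0.41` s^-1, `tau = 0.98` s,
  `alpha = 0.32`, `rho = 0.34`, `V0 = 0.02`), integrating at `<= 1` ms
  with sample-and-hold sub-stepping. Its neural drive is the summed E+I
  current per node, z-scored against the pre-onset baseline and scaled by
  `drive_scale = 0.2` to stay in the filter's physiological linear range;
  all reported BOLD statistics are relative changes, so the scale cancels
  at first order.

## Operating regime

The calibrated model has a single low-rate fixed point whose stability
depends on the product of the global coupling and the connectome's
spectral radius. Two facts about this parameter set are worth stating
plainly, because they shape every default in the package:

1. The inhibitory-to-excitatory feedback gain available to stabilize the
   network is bounded: per unit of feedback weight it can never exceed
   `w_IE/w_II` times the excitatory gain, and the FIC balance ties the
   weight itself to the node's long-range input. Summing the two effects,
   feedback compensates only about a third of the long-range excitation
   at this operating point.
2. Consequently, for connectomes whose spectral radius is comparable to
   their mean row sum — which includes every near-balanced random graph
   and any matrix with approximately symmetric support — the fixed point
   loses stability once `G * w_net * (mean row sum)` exceeds a few
   hundredths of a nA. For a 66-node matrix with mean weight 0.025 that
   bifurcation sits near `G ~ 0.25`; strongly-coupled operating points
   on such matrices are therefore outside the regime where a stationary
   covariance exists, and `solve_moments()` reports this as an explicit
   stability error rather than returning a divergent answer.

The package's whole-network examples and experiments therefore run on
binary modular graphs whose links carry weight `m = 0.025` each (matrix
mean `q * m`), at `G = 1` — safely inside the stable regime, with the
bifurcation reached near `G ~ 1.9` and highly clustered graphs
(`p = 0.9`) losing their regulable state already at `G = 1.2`, which is
how `run_modularity_sweep()` exhibits the breakdown of the mean-variance
relation under excessive clustering. In this regime the stimulus-driven
phenomenology is robust: every node's trial-by-trial variance is quenched,
the mean change and variance change are strongly negatively correlated
across nodes, functional connectivity is nearly unchanged while
covariances change substantially, temporal memory (T95) shortens under
stimulation, and the differential entropy and relative entropy of the
evoked activity are below their spontaneous values. The quantitative
magnitudes (timescales in seconds rather than hundreds of milliseconds,
spectral suppression maximal at low frequency, entropy reductions of tens
of bits) are properties of this stable regime and scale with the distance
to the bifurcation.

## Synthetic data

Two generators make every analysis runnable without external files.

`generate_modular_connectome()` draws directed binary graphs from a
two-parameter family: overall link density `q` and within-module link
proportion `p` across five contiguous modules, with
`round(q N (N-1))` links placed by quota without replacement. Weights are
uniform per link (`scale`), or calibrated so the full-matrix mean hits a
target (`mean_weight`); `synthetic_connectome_66()` is the documented
66-region stand-in for a DSI-derived cortical matrix (`q = 0.14`,
`p = 0.5`, matrix mean 0.025, non-symmetric). What these graphs do not
emulate: heavy-tailed weight distributions, hemispheric organization,
distance-dependent wiring, and the in/out-strength correlations of real
tractography — so tests passing on them certify the machinery, not
anatomical realism.

`generate_surrogate_fmri()` and `surrogate_rest_task()` emulate a
rest-versus-task BOLD ROI study: 17 subjects x 4 runs x 194 frames x 33
ROIs at TR 2.16 s. Frames are i.i.d. multivariate normal — a deliberate
simplification justified for entropy estimation because the estimators
under test are themselves covariance-based or neighbor-based on frames;
temporal autocorrelation of real BOLD is not reproduced. The population
covariance has a five-network block structure plus three subcortical
regions, is projected to rank 29 (emulating the removal of four nuisance
regressors upstream), and per-subject covariances are Wishart draws around
it (df = 100, a moderate inter-subject variability chosen once). Task
runs carry stimulus onsets at inter-stimulus intervals uniform in
17.3-30.2 s, a sustained variance factor 0.9 and a transient peristimulus
variance dip (depth 0.3 over 8 s, raised-sine profile) — magnitudes chosen
to produce an entropy reduction of a few bits over 33 ROIs, the scale the
model side predicts. Rest "equivalent periods" in the time-resolved
analysis reuse the paired task run's onsets on the same-index rest run.

## Entropy estimation

Three estimators, with distinct roles:

* `gaussian_entropy()` — exact Gaussian entropy from a full-rank
  covariance via Cholesky, used on model covariances.
* `svd_entropy()` — Gaussian entropy of data whose sample covariance may
  be rank-deficient (rank-29 ROI data; 5-frame sliding windows of 33 ROIs
  have rank at most 4): the determinant is the product of singular values
  above `max(lambda) * n * eps * 1e6`, and the retained rank `k` is
  reported alongside.
* `knn_entropy()` — the nearest-neighbor (Kozachenko-Leonenko)
  nonparametric estimator, `psi(N) - psi(k) + ln V_d + (d/N) sum ln eps_i`
  in bits, default `k = 1`, brute-force distances in compiled code. It
  assumes no normality; on rank-deficient data it is negatively biased,
  but per-subject values track the parametric estimator closely
  (correlation ~0.95 on the surrogate study), which is the property the
  pipeline relies on.

The sliding-window analysis uses 5-frame windows stepped by 1 frame,
peristimulus spans of +/- 17.3 s, excludes presentations whose span
crosses a run boundary, references all curves to the rest average `H0`,
and tests task-vs-rest per window with a paired t-test across subjects,
uncorrected by default (a Bonferroni option exists).

## Problem sizes

The test-suite and the acceptance script are sized to run on one CPU in
minutes: simulator cross-checks use an 8-node two-module network at
1000-1500 trials; whole-network experiments use `N = 66` with stationary
solves (seconds each); the random-stimulation entropy experiment runs 500
patterns (~0.3 s per stationary solve); BOLD trial statistics use 16-24
trials of 28 s; surrogate fMRI analyses use the full 17 x 4 x 194 x 33
layout. All randomness flows through explicit seeds.

## Known limitations

* Transmission delays between regions are not modeled.
* The connectome generators do not reproduce weighted, heavy-tailed
  empirical fiber-density matrices; dataset-level checks on the 66-node
  stand-in certify summary statistics (density, mean), not anatomy.
* The strongly-coupled operating regime (`G ~ 2` on a mean-0.025 matrix)
  is beyond the model's bifurcation under this parameter set (see
  "Operating regime"); quantitative targets tied to that regime —
  sub-second T95 values in the low hundreds of milliseconds, a ~9.5 Hz
  spectral-suppression peak, entropy drops of only 1-3 bits — are not
  attainable in the stable regime and are reported as measured.
* Surrogate BOLD frames are temporally white; analyses that depend on
  BOLD autocorrelation should not be validated against them.
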