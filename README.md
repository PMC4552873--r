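# dmfentropy

Whole-brain dynamic mean-field modeling and entropy analysis of
spontaneous versus stimulus-driven cortical activity.

A robust hallmark of task-driven brain dynamics is that variability goes
*down* when a stimulus arrives: trial-to-trial variance, temporal
autocorrelation, and — putting the pieces together — the differential
entropy of the multidimensional activity distribution all shrink relative
to rest. `dmfentropy` is for computational neuroscientists who want to
study this mechanistically: it implements a cortex-wide network of
excitatory–inhibitory (E–I) neural-mass nodes coupled through a structural
connectome, analytic machinery to compute the second-order statistics of
that network with and without external input, and the matching empirical
pipeline for rest-versus-task ROI fMRI time series.

## The model and the statistics

Each region `i` carries synaptic gating variables `S_E, S_I` with

    dS_E/dt = -S_E/tau_E + (1 - S_E) * gamma * r_E + beta * eta(t)
    dS_I/dt = -S_I/tau_I + r_I + beta * eta(t)

where rates `r = (a u - b)/(1 - exp(-d (a u - b)))` respond to currents
`u_E = I0_E + w_EE S_E + G w_net C S_E - w_EI S_I + I_ext` and
`u_I = I0_I + w_IE S_E - w_II S_I`. Feedback inhibition control (FIC)
calibrates each node's `w_EI` so every excitatory population rests at
3 Hz (`calibrate_fic()`). For weak noise, fluctuations around the fixed
point are Gaussian with covariance `P` solving the Lyapunov equation
`A P + P A' + Qn = 0` (`solve_moments()`), from which the package derives
synaptic-current covariances (`Cv = W P W'`), autocovariances and decay
timescales T95 (`lna_autocovariance()`), cross-spectra and PSDs
(`cross_spectrum()`), stimulus-response contrasts Δm, Δσ², ΔPSD
(`response_metrics()`), differential entropy `H = ½ log2((2πe)^n det Σ)`
and the Kullback–Leibler divergence of activity from intrinsic noise
(`gaussian_entropy()`, `kld_gaussian()`). A stochastic Euler–Maruyama
simulator (`simulate_ensemble()`, compiled core) validates the analytics,
and a Balloon–Windkessel stage (`bold_transform()`,
`bold_trial_experiment()`) forwards synaptic activity to BOLD.

The empirical side (`subject_entropy()`, `time_resolved_entropy()`,
`fc_comparison()`, `run_fmri_entropy_pipeline()`) estimates per-subject
and peristimulus entropy of ROI time series with a rank-truncated
Gaussian estimator (`svd_entropy()`) and a nearest-neighbour
nonparametric estimator (`knn_entropy()`). Synthetic generators
(`generate_modular_connectome()`, `surrogate_rest_task()`) produce
modular connectomes and paired rest/task surrogate fMRI studies so the
entire pipeline runs without any external data.

## Worked example

Stimulate eight regions of a 66-node modular connectome (link density
0.14, per-link weight 0.025) with 0.02 nA at global coupling G = 1:

```r
library(dmfentropy)
spec <- modular_graph_spec(66, 5, q = 0.14, p = 0.5, scale = 0.025, seed = 1)
conn <- generate_modular_connectome(spec)
ex <- run_stimulation_experiment(conn, G = 1, tau_max = 8)
ex
#> stimulation experiment (G = 1, 8 targets at 0.02 nA)
#>   T95 excitatory: 1465 ms (spont) vs 283 ms (task)
#>   T95 inhibitory: 786 ms (spont) vs 17 ms (task)
#>   max ratio-of-PSD reduction at 0.01 Hz (direct E) / 0.01 Hz (indirect E)
#>   cor(Dm, Dsigma2) E: -0.972;  FC similarity: 0.950

head(ex$report[, c("node", "direct", "delta_m_E", "delta_sigma2_E", "w_EI")], 4)
#>      node direct delta_m_E delta_sigma2_E      w_EI
#> R001    1  FALSE  23.58862      -72.50847 0.1069035
#> R002    2  FALSE  26.18201      -78.29956 0.1690654
#> R003    3  FALSE  24.16852      -74.15398 0.1224439
#> R004    4  FALSE  29.22029      -81.87408 0.2623084
```

Reading the output: the stimulus raises the mean synaptic activity of
every node (`delta_m_E > 0`, percent) while quenching its trial-by-trial
variance (`delta_sigma2_E < 0`) — including nodes that receive the input
only indirectly through the connectome — with a strong negative relation
between the two across nodes (r = −0.97). Temporal memory shortens
(excitatory T95 drops from 1.47 s to 0.28 s), yet functional connectivity
(the correlation structure) stays almost unchanged (similarity 0.95).
`run_entropy_experiment()` extends this to many random stimulation
patterns and reports the entropy reduction of the evoked activity
distribution; `run_fmri_entropy_pipeline()` runs the corresponding
rest-versus-task analysis on (surrogate or user-supplied) BOLD data.

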