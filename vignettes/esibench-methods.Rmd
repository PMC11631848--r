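---
title: "Models and methods behind esibench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind esibench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`esibench` is a self-contained benchmark for spatio-temporal EEG source
imaging (ESI): given scalp potentials `Y` (Ne electrodes x T samples), it
estimates the regional cortical current distribution `X` (Nr regions x T)
under the linear forward model

    Y = L X + eps,

where `L` is the leadfield and `eps` sensor noise. The package contains
every ingredient needed to study this problem without any external data:
an analytic head model, two independent simulators, classical linear
inverses, three trainable inverse operators, and a five-metric evaluation
suite with ANOVA/Tukey method comparison. This vignette explains the
science of each part, the tunable parameters, and the design choices made
where the design was genuinely open.

## The spherical head model

Realistic ESI pipelines compute `L` from a segmented MRI with a BEM/FEM
solver. To keep the benchmark fully reproducible and download-free,
`build_spherical_head()` instead uses the classical three-shell concentric
spherical conductor (brain/skull/scalp, default radii 79/82/87 mm,
conductivities 0.3/0.006/0.3 S/m), for which Poisson's equation has an
analytic series solution. Per harmonic degree the potential in each shell
is `a r^n + b r^-(n+1)`; coefficients follow from continuity of potential
and radial current density at the interfaces and an insulating scalp
boundary. The series is truncated when the relative increment drops below
1e-10 (cap 200 terms). As an independent oracle the package also ships the
closed-form surface potential of a dipole in a *homogeneous* sphere
(`homogeneous_sphere_dipole()`); with equal conductivities the multilayer
series must agree with it, and the test suite holds that to 1e-6 relative.

Sources are quasi-uniform (Fibonacci lattice) on a sphere at 0.85 x the
brain radius with radial orientations, mimicking pyramidal-cell dipoles
perpendicular to the cortical surface. The cortical parcellation is
synthetic: farthest-point seeding plus nearest-centroid assignment
produces `Nr` connected, Voronoi-like regions, and regions are adjacent
when their member sources are neighbours in a k-nearest-neighbour source
graph. The regional leadfield sums member-source columns (all sources in a
region are assumed equally active; no size normalization). All leadfields
and all simulated EEG are average-referenced. Units are mm, A.m, S/m and
V throughout. A precomputed leadfield from a realistic head model can be
substituted via `head_from_arrays()`.

The region-size distribution of this synthetic parcellation is not
calibrated against any anatomical atlas; with the desk-scale default of
50 regions on a sphere each region has roughly 5-13 sources and ~5-6
neighbours.

## Event-related simulator

`simulate_sample_sereega()` draws, per sample, two seed regions and a
growth order in 1-3; an extended source is the graph ball of that order
around the seed (`grow_region()`). All members share one Gaussian
waveform

    f(t) = a exp(-1/2 (6 (t - c) / w)^2),

with amplitude `a` uniform in 0.5-1.5 nA.m divided by the mean region
source count, center `c` in 49-51 ms and width `w` in 125-375 ms; member
amplitudes decay with centroid distance `d` from the seed as
`exp(-d^2 / (2 sigma_d^2))`. The decay scale `sigma_d` is not dictated by
the physics; its default is the mean centroid spacing of adjacent regions,
which attenuates first neighbours by about `e^-1/2`. Overlapping extended
sources add, by linearity of the source model. The clean EEG is `L X`;
white Gaussian sensor noise is rescaled so the realized Frobenius power
ratio `10 log10(||Y_clean||_F^2 / ||eps||_F^2)` equals the requested SNR
(default 5 dB) *exactly*, which makes the noise contract testable to
1e-9 dB. Note the default center range places the waveform peak early in
the 1 s epoch, so most of the epoch carries almost no source signal; a
late-peak configuration (e.g. 490-510 ms) is one config change away.

## Neural-mass simulator

The second generator grounds the source dynamics in biophysics. Each
region is an independent Jansen-Rit column: six states describing a
pyramidal population with excitatory and inhibitory interneuron feedback,
integrated by Euler-Maruyama at 2000 Hz (time unit ms; standard constants
B = 22 mV, a = 0.1/ms, b = 0.05/ms, C = 135 with the usual 1/0.8/0.25/0.25
split, v0 = 6 mV, e0 = 0.0025/ms, r = 0.56/mV). The stochastic drive is
drawn per step as `N(mu, sigma^2)`.

Two drive regimes matter, and they are deliberately distinct:

* `jansen_rit_params()` defaults to the canonical drive `mu = 0.22/ms`,
  where the model sits on its alpha limit cycle: the spectral peak is
  ~10.5 Hz across seeds (the test suite checks 7-13 Hz on 20 seeds).
* Spike generation runs at low drive `mu = 0.087/ms`, just below the
  oscillation onset. There the background gain `A = 3.25` mV gives
  spike-free subthreshold activity, while raising the excitatory gain to
  `A = 3.6` mV puts the column inside the noise-triggered spiking regime:
  sparse interictal-like transients, a few per 10 s.

The per-step drive noise sd defaults to 0.065/ms. This value was fixed
once, from a bifurcation/eigenvalue analysis of the deterministic system
plus a seed sweep, as the scale at which the active regime produces 3-9
detectable spikes per 10 s on essentially every seed while the background
regime produces none. A single drive mean cannot produce both a dominant
alpha peak and sparse detectable spikes in this model — the alpha branch
requires roughly `mu > 0.17/ms` whereas noise-triggered spiking at
`A = 3.6` requires roughly `mu < 0.11/ms` — which is why the background
regime used *inside* the spike generator runs at the low drive, and the
alpha regime is the model default.

Spike extraction mirrors clinical practice: `detect_spikes()` flags local
maxima above `median + 6 MAD` with a 250 ms refractory gap (both
configurable; the criterion is a package choice, not a published one).
`build_spike_bank()` treats each region in turn as the active one,
simulates 6 portions of 10 s, decimates 2000 -> 500 Hz with an 8th-order
low-pass anti-alias filter, and keeps 1 s windows centered on detected
spikes (event inside the middle 50% of the window) during which no other
region shows an event. `simulate_sample_nmm()` then grows two order-3
extended regions, assigns each a randomly drawn spike window of its seed
with the same Gaussian distance decay, scales the spike field against
resting background traces to a 15 dB Frobenius power ratio, projects
spike + background through `L`, and adds sensor noise at an SNR drawn per
sample from {5, 10, 15, 20} dB (a fixed-SNR mode exists). The stored
ground truth contains only the spike rows — the training target is the
denoised source field — so for this generator `Y` deliberately differs
from `L X`. Source amplitudes are rescaled so the spike field peaks at
1 nA.m; the neural-mass potentials are in arbitrary mV-like units and
only their pattern matters, since both training and evaluation are
amplitude-normalized.

## Linear inverses

`mne_solve()` is Tikhonov-regularized least squares with an l2 penalty,
computed in the dual form `X_hat = L'(LL' + lambda_s I)^-1 Y`. The
user-facing `lambda` is unitless: it is multiplied by the mean sensor
eigenvalue `trace(LL')/Ne`, so values transfer across head models. The
`"auto"` rule uses the standard heuristic `lambda = 1/SNR_linear` with the
generator's sensor SNR; every solution records the lambda used. The noise
covariance is assumed white, consistent with the simulators; no depth
weighting is applied. `sloreta_solve()` standardizes the minimum-norm
estimate by the square root of the diagonal of its resolution operator
`S = KL`. Because `S` is a Gram matrix in the metric `(LL' + lambda_s I)^-1`,
the Cauchy-Schwarz inequality makes the standardized estimate peak at the
true source for any noiseless single-source input and any lambda > 0 —
the defining zero-localization-error property, asserted for every region
in the test suite.

## Learned inverses

Three trainable operators map `Ne x T` to `Nr x T`. No deep-learning
framework is involved: the layers, backpropagation and the Adam optimizer
are implemented in the package on top of BLAS matrix products, and every
architecture's analytic gradient is checked against finite differences in
the tests.

* **1D-CNN** — one wide temporal convolution (default 2048 filters,
  kernel Ne x 5, same-padding in time, implemented exactly as a dense
  layer on a 5-lag time embedding), ReLU, then a dense map to Nr applied
  per time step.
* **bi-LSTM** — two bidirectional LSTM layers (hidden 85 per direction,
  dropout 0.2 between layers), ReLU, then a per-time-step dense map from
  the 170-dim concatenated state to Nr.
* **deepSIF-style** — a per-time-step spatial module of two residual
  blocks with ELU activations (the second lifts Ne to a 500-dim feature
  space, with a dense skip path) and a dense 500 -> 500, followed by a
  temporal module of three stacked LSTM layers whose hidden state has
  dimension Nr; the last hidden sequence is the estimate.

Where the published block diagrams are ambiguous (exact dense fan-ins,
whether maps act per time step), the readings adopted here are the only
ones that produce `Nr x T` outputs for arbitrary T. Published parameter
counts for these architectures could not be reconciled with any
straightforward reading of the diagrams; `build_model()` logs its own
count instead.

Training minimizes the cosine-similarity loss

    L(X, X_hat) = -(1/T) sum_t cos(X[, t], X_hat[, t])

on pairs normalized by `alpha = max(|Y|)` (which preserves the linear
relation). The loss is invariant to per-column positive rescaling, so
amplitudes are restored afterwards by global-field-power rescaling:
each column of the estimate is scaled by `std(Y[, t]) / std((L X_hat)[, t])`
over electrodes. Zero-norm loss columns contribute 0 (counted), and
zero-variance re-projection columns keep scale 1 (flagged). Optimization
is Adam (lr 1e-3 default, batch size 8) with early stopping after 20
epochs without validation improvement and gradient-norm clipping for the
LSTM. All shuffling and dropout derive from one seed; training is exactly
reproducible.

## Evaluation

Five complementary metrics, computed at `t0`, the instant of maximum
absolute seed activity (first index on ties):

* **LE** (mm): distance between true and estimated amplitude maxima. For
  two-source samples each true seed is greedily matched (strongest seed
  first) to one of the *n-strongest* estimated graph-local maxima, each
  claimed once, and the distances are averaged. Matching each seed to its
  nearest local maximum of any size was tried and rejected: a diffuse
  minimum-norm map has many minor maxima, so some peak is always close by,
  and the rule systematically rewarded spread over focality. The strict
  single-global-maximum definition remains available
  (`le_mode = "global"`).
* **extent AUC** (%): area under the ROC of max-normalized absolute
  amplitudes against active-region membership (union of both extended
  regions), swept over all unique thresholds — identical to the
  rank/Mann-Whitney statistic, which the tests exploit as an oracle. The
  true-positive rate is the standard `TP/(TP+FN)`.
* **nMSE**: mean squared difference of the two columns after each matrix
  is scaled by its own global maximum (the `1/Ns` single-column variant).
* **PSNR** (dB): over the whole epoch, on max-normalized matrices, capped
  at 300 dB for exact reconstructions.
* **time error** (ms): difference between the instants of maximum summed
  absolute amplitude.

`compare_methods()` runs a one-way ANOVA per metric across methods and a
Tukey HSD post hoc for pairwise adjusted p-values.

## Pipeline, seeding and problem sizes

`run_in_domain()` chains head building, simulation, training, inversion,
evaluation and report rendering; `run_out_of_domain()` re-scores the same
fitted models on a dataset from the other generator — the cross-simulator
generalization protocol. Every random stage derives its seed from the
master seed through a counter-based mix (`derive_seed()`), so adding a
method never perturbs data generation, and all outputs are stamped with a
configuration hash, the master seed and a git-describe string.

The shipped test configurations run at desk scale, chosen so the whole
suite completes comfortably on one CPU: a 32-electrode / 400-source /
50-region head with 2,000 event-related samples and a 128-filter CNN for
the method-ordering check, a 16/120/24 head for the network and
neural-mass chains, and short training budgets (the cosine loss on this
problem is far from converged at those budgets, which is why absolute
metric values are poorer than a full-scale run would give — the asserted
claim is the *ordering* of learned versus linear methods, not magnitudes).
The published-scale configuration (90 electrodes, 994 regions, 10,000
samples, 500-epoch budget) is reachable through the same configs.

## What the simulations do and do not show

Both generators share the head model and the extended-source geometry but
differ in waveforms and noise structure, which is exactly what makes the
cross-simulator protocol informative. Neither captures real-EEG
complexities: no inter-regional connectivity (columns are uncoupled), no
physiological artifacts or line noise, no electrode co-registration
error, a spherical rather than realistic conductor, and a parcellation
with no anatomical meaning. Passing tests therefore demonstrate the
correctness of the machinery and the qualitative method ordering under
these generative assumptions, not clinical performance. Small
parcellations add a further caveat: an order-3 graph ball can cover most
of a 50-region head, so extent AUC is computed only over samples that
retain both active and inactive regions, and absolute AUC values at desk
scale sit far below what a 994-region head yields.

## Degenerate inputs and numerical choices

All-zero EEG yields a guarded all-zero solution; all-zero estimates are
flagged and scored conservatively (AUC 50%, time error = epoch length).
Ties in any argmax resolve to the first index. The multilayer-series
linear systems are column-equilibrated, and harmonic degrees beyond
usable double precision are dropped (their contribution is below the
truncation tolerance). sLORETA excludes sources with a null leadfield
column. The Jansen-Rit integrator aborts with the offending step index if
a state becomes non-finite (step-size instability).
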