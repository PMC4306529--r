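---
title: "Tracking slow synaptic gain changes with windowed DCM for cross-spectral density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking slow synaptic gain changes with windowed DCM for cross-spectral density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrack)
```

## The problem

Transitions between brain states — the onset of an epileptic seizure being
the starkest example — unfold over seconds, while the neuronal dynamics
that express them unfold over milliseconds. This separation of timescales
licenses a *locally stationary* treatment: short, overlapping windows of a
multichannel electrophysiological recording are each summarised by their
complex cross-spectral density (CSD), and a biophysical model of coupled
neuronal populations is asked to explain the whole *sequence* of spectra
with parameters that are constant within a window but drift slowly across
windows. The estimated drift is a trajectory through synaptic parameter
space: which couplings changed, by how much, and on what timescale.

`synaptrack` implements this programme for a two-source network, with a
synthetic face-validation surface as its primary test bed: datasets are
generated from known parameter trajectories, and the package's own
estimator has to recover them.

## The neural mass model

Each source is a canonical microcircuit (CMC) of four populations — input
cells (granular, `ss`), superficial pyramidal cells (`sp`), inhibitory
interneurons (`ii`) and deep pyramidal cells (`dp`). Each population obeys
a second-order synaptic convolution kernel driven by the sigmoid-transformed,
conduction-delayed depolarisation of its afferents:

$$\dot v_p = z_p, \qquad
  \dot z_p = \kappa_p \Big( \textstyle\sum_e w_e\,\sigma\!\big(v_{\mathrm{src}(e)}(t-\tau_e)\big) + u_p(t) \Big)
  - 2\kappa_p z_p - \kappa_p^2 v_p,$$

with $\kappa_p$ the synaptic rate constant, $w_e$ signed connection
strengths (Hz) and $\sigma(v) = 1/(1+e^{-\gamma v}) - 1/2$ a *centered*
sigmoid, so the origin is an exact fixed point of the unforced system and
$\sigma'(0)=\gamma/4$ is the resting gain. Intrinsic (within-source) edges
follow the laminar CMC graph; interneuron projections and the recurrent
(self) connections are inhibitory. The recurrent self-inhibition of the
superficial pyramidal cells is the tracked "intrinsic gain": several
interneuron populations are absorbed into this one negative coupling, which
keeps the parameter count at a level the data can support. Between sources,
forward connections originate in `sp` and target `ss` (and, more weakly,
`dp`); backward connections originate in `dp` and target `sp` (inhibitory)
and `ii`. Intrinsic conduction delays are about 1 ms, extrinsic delays
about 8 ms, making these *delay* differential equations. Endogenous
fluctuations with a power-law spectrum drive the input cells; the
observation is the depolarisation of the superficial pyramidal cells scaled
by an electrode gain.

Every parameter is expressed as a positive prior mean times
$\exp(\theta)$, with a Gaussian prior on the dimensionless log-scaling
$\theta$; a prior variance of zero fixes a parameter. `default_priors()`
lists the full table.

```{r priors, eval = FALSE}
default_priors()
```

### Structural magnitudes

The wiring magnitudes live in configuration (`cmc_config()`), not code.
Defaults and their rationale:

* **Intrinsic rates** $200\times(8,4,8,4,4,2,4,4,2,1)$ Hz — the
  conventional CMC values; weaker settings (e.g. halved) leave the
  linearized loop gains too low to produce the resonant, band-limited
  spectra that make spectral inversion informative.
* **Extrinsic rates** 1600 Hz prior mean per direction (scaled 1 / 0.5
  over each direction's laminar sub-targets) — between-source drive
  comparable to within-source recurrent drive. This describes a strongly
  coupled pair, with inter-channel coherence up to ~0.5 at prior means, as
  seen between neighbouring bipolar derivations inside an epileptogenic
  network. Much weaker coupling renders the questions the model space asks
  (does the forward or the backward connection change?) undecidable in
  principle, because the data then carry almost no information about the
  extrinsic parameters.
* **Rate constants** $\kappa = 1000/2, 1000/2, 1000/16, 1000/28$ Hz;
  sigmoid slope $2/3$; delays 1 ms / 8 ms.
* **Scales.** The amplitude parameters for the endogenous input and the
  measurement noise (prior means 1) are dimensionless; two structural constants
  (`input_scale`, `noise_scale`) convert them to spectral densities in
  measurement units. `noise_scale = 1e-8` puts the measurement-noise floor
  about a factor 5 below the in-band neuronal spectrum at prior means — a
  realistic regime for intracranial EEG, where neuronal signal dominates
  the amplifier floor.

At the default priors the linearization is stable (all zero-delay system
eigenvalues in the left half-plane, asserted in the tests), and the time-domain
integrator (`cmc_integrate()`, fixed-step RK4 with a linear-interpolation
history buffer for the delayed states) reproduces the spectral forward
model's auto-spectra within sampling error — that equivalence is asserted
in the test suite at 10% over 8–48 Hz.

## The spectral forward model

Linearizing about the fixed point gives a delay state-space model whose
transfer functions are evaluated exactly in the frequency domain, the
delays entering as phase factors $e^{-i\omega\tau}$ on the delayed
couplings (no Taylor approximation — exactness is cheap here and testable
against simulation). The predicted CSD over channels is

$$G_y(f) = T(f)\, G_u(f)\, T(f)^{\mathsf H} + G_n(f),$$

with $G_u$ the (independent, per-source) power-law input spectra and $G_n$
a channel-specific plus common-mode power-law noise floor. Because the
second-order structure pairs every depolarisation with its derivative, the
resolvent reduces by Schur complement to an 8-dimensional complex solve
per frequency; the test suite checks this fast path against a plain
full-matrix resolvent. Predictions are Hermitian with real non-negative
diagonals by construction, and differentiable in every log-scaling — the
property the inversion relies on.

Frequencies are modelled on a 1-Hz grid over 8–48 Hz by default: slow
(theta-range) fluctuations are removed, and the band covers the beta/low-
gamma activity where seizure-related spectral changes concentrate.

## Windowed data features and estimation from recordings

Recordings (EDF or delimited text) are re-referenced to bipolar
derivations, band-pass filtered 0.5–48 Hz with a 4th-order Butterworth
applied forward–backward (zero phase, so cross-spectral phase relations
survive), and partitioned into 2-s windows with 50% overlap: ten seconds
on each side of the onset gives 9 + 9 = 18 windows. Per-window CSDs come
from either a vector-autoregressive estimator (default, order 8 — smooth
and well-behaved on 2-s windows) or a sine-taper multitaper
cross-periodogram (nonparametric cross-check); the estimator and its
settings are recorded in the container metadata. All spectra are one-sided
densities in (units)²/Hz.

## Inversion: variational Laplace

The windowed CSDs are embedded losslessly in a real feature vector (real
upper triangle plus imaginary strict upper triangle, per window and
frequency; $18 \times 41 \times 4 = 2952$ features for two channels). A
Gaussian posterior over all free log-scalings is estimated by Gauss–Newton
ascent on the variational free energy

$$F = \mathbb E_q\big[\log p(y\,|\,\theta)\big]
      - \mathrm{KL}\big(q(\theta)\,\|\,p(\theta)\big)
      - \mathrm{KL}\big(q(\lambda)\,\|\,p(\lambda)\big),$$

which is exact for linear models — the engine reproduces conjugate
linear-Gaussian posteriors and log evidence to $10^{-6}$ in the tests —
and serves as the log-evidence approximation for model comparison.
Gradients are central finite differences (step $10^{-3}$ in log-scaling
space), noise log-precisions $\lambda$ are updated in closed form between
parameter steps, and steps that lower $F$ are rejected under Levenberg
regularization. Inversions start deterministically at the prior means.
Convergence is declared after 8 consecutive proposals that fail to improve
$F$ by more than $10^{-2}$ nats (at most 64 iterations); inversions still
improving at the cap are flagged non-convergent and excluded from model
comparison rather than patched.

### The noise model for CSD features

Sampling error of a windowed spectral estimate is not white: it is (a)
proportional to the local spectral amplitude and (b) correlated across
neighbouring frequency bins over the estimator's smoothing bandwidth. The
likelihood therefore divides each feature by a segment-averaged empirical
amplitude profile $\sqrt{|G_{ii}||G_{jj}|}$ (variance stabilization;
segment averaging keeps the weights essentially independent of any single
window's noise) and whitens each (window, component) frequency series with
an AR(1) inverse square root (`noise_rho = 0.6`, matching a ~2-bin
smoothing bandwidth at 1-Hz spacing). With an independent-and-identical
noise assumption instead, smooth noise masquerades as signal: credible
intervals become overconfident and trajectory estimates noisier. The
whitened likelihood is the package default; `noise_rho = 0` switches it
off.

## The model space and slow trajectories

A candidate model is an extrinsic architecture (forward connection
originating in the primary or the secondary source) plus four binary flags
for which couplings may change across windows: the superficial-pyramidal
self-inhibition in each source, and the forward and backward extrinsic
strengths — 16 flag combinations in all. Flagged parameters acquire
per-window deviations through an orthonormal polynomial basis (order 3 per
segment, independent pre- and post-onset blocks, so the trajectory may
jump at the transition); all other parameters are held constant across
windows. The per-segment constant columns carry the level of a flagged
parameter, so its shared log-scaling is dropped — one parameterization,
no redundancy.

Trajectory coefficients get a mean-zero Gaussian prior whose variance
starts at 2 for the constant columns and halves with each polynomial
order. This is a smoothness prior and nothing more: the premise of the
method is that the modulations being tracked are *slow*, so high-order
wiggle within a 9-window segment is a priori less plausible than drift.

Model comparison is fixed-effects: pooled log evidence is the sum of
per-session free energies, and posterior model probabilities are its
softmax. A pooled log-evidence difference of 3 corresponds to odds of
about 20:1. Across sessions, `bayesian_update()` carries posterior means
and covariances of the shared parameters forward as the next session's
priors, while session-specific parameters — by default the electrode
gains, which have no reason to be stable across recordings — are reset to
their original priors. Trajectory coefficients are treated as
session-specific (each transition gets its own trajectory). On
linear-Gaussian toys, carrying the full covariance makes sequential
updating exactly equal to joint inversion, which the tests assert at
$10^{-6}$.

## The synthetic face-validation surface

`true_trajectories()` encodes the validation design: 9 pre-onset windows
at the prior expectation, then mono-exponential decay back towards it —
intrinsic excursions of +2 log units (both sources) with an 8-s time
constant, a forward excursion of +1 log unit with a 2-s time constant, and
no backward change. The +2 intrinsic amplitude mirrors the magnitude of
empirically reported seizure-onset changes in log scaling (about two, an
eightfold change); the forward amplitude of +1 is a deliberate weaker
contrast.

`generate_dataset()` computes the noiseless CSD for each window from the
spectral forward model along those trajectories and adds Hermitian noise
with AR(1) smoothness across frequency ($\rho = 0.6$), drawn as a pool of
window-sized realizations assigned to windows by a random permutation,
shaped by the local spectral amplitude (sampling error of a spectral
estimate is proportional to the spectrum), and normalized so the RMS
amplitude ratio of signal to noise is exactly the requested SNR (4) per
channel and window. Identical seed and configuration reproduce a dataset
bit-exactly.

What the generator does *not* emulate: real ictal recordings contain
artifacts, nonstationarity within windows, line noise, genuinely
non-Gaussian residuals, and model mismatch — the data-generating circuit
is the same CMC the estimator assumes. Passing face validation therefore
establishes *identifiability under the model's own assumptions* (can the
estimator recover what the model itself generated, at realistic noise?),
not clinical validity on patient data.

## Numerical choices

* Integrator: fixed-step RK4, default step $1000/2048$ ms (the step must
  not exceed the 1-ms intrinsic delay); delayed states interpolated
  linearly on the step grid; halving the step changes 8-s output spectra
  by well under 1%.
* Fixed points by damped Newton iteration on the zero-delay equations;
  residual tolerance $10^{-10}$.
* Stability guard: a parameter set whose zero-delay system matrix has a
  non-negative real eigenvalue signals a condition; the optimizer rejects
  such steps. The guard is skipped inside finite-difference perturbations
  ($10^{-3}$ nudges from a guarded point).
* Noise log-precisions are clamped to $\pm 32$ of their hyperprior mean:
  residual variances below $e^{-32}$ of the data scale are numerically
  noiseless (this matters only for exactly noise-free inputs).
* Near-singular precision matrices (noiseless data, strongly determined
  parameters) are inverted with an eigenvalue floor at $10^{-12}$ of the
  largest eigenvalue.
* Ties and degeneracies: models missing any session's evidence are
  excluded from comparison (with the reason recorded) rather than imputed.

## Problem sizes in the tests

The test suite exercises the full study conditions — 18 windows of 41
frequency bins at SNR 4 — for the face-validation recovery (5 seeds) and
the 16-model recovery; module tests use a coarse 11-bin grid where only
plumbing is at stake. Simulation-versus-prediction oracles use 60-s
integrations. These sizes were chosen as the smallest at which the
estimators' sampling behaviour is representative.

## Known limitations

* Two sources, mapped one-to-one onto two bipolar channels with a diagonal
  gain; no lead-field mixing.
* The stability guard tests the zero-delay eigenvalues; delays can in
  principle destabilize a system that passes it (at these delay magnitudes
  and frequencies we have not observed this).
* Finite-difference gradients cost ~2p forward-model evaluations per
  iteration; analytic gradients would be the natural next optimization.
* The AR(1) feature-noise model is itself an approximation to the true
  dependence structure of windowed spectral estimates; `noise_rho` is a
  fixed structural constant, not estimated.
* Fixed-effects pooling across sessions is appropriate for repeated
  sessions in one subject; between-subject comparison would need
  random-effects machinery that is out of scope.
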