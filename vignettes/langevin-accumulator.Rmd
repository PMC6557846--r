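---
title: "Reconstructing Langevin accumulator models from epoched neural data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing Langevin accumulator models from epoched neural data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accubound)
```

## The model

`accubound` treats a single-channel, trial-epoched neural time series as
realizations of a one-dimensional, time-homogeneous Markov (Langevin)
process

$$\frac{dz}{dt} = P_G(z) + P_H(z)\,\Gamma(t),$$

with polynomial drift $P_G$ (degree $G$) and noise amplitude $P_H$ (degree
$H$), and $\Gamma$ Gaussian white noise with
$\langle\Gamma(t)\Gamma(t')\rangle = \delta(t-t')$ (Itô convention). Drift
and diffusion equal the Fokker–Planck coefficients: $P_G = D^{(1)}$,
$P_H^2 = D^{(2)}$. Two degree sets matter in practice: $G=1, H=0$ is the
leaky stochastic accumulator (an Ornstein–Uhlenbeck process, spectrally
locked to $1/f^2$ above its relaxation knee), and $G=3, H=2$ is the minimal
polynomial generalization whose state-dependent noise admits variable
$1/f^\alpha$ autocorrelation structure while keeping drift odd-symmetric
and noise even-symmetric to leading order.

The assumptions the estimator inherits: Markovianity (no memory beyond the
current state), stationarity of the coefficient functions over the analysis
window (no explicit time dependence), and white — not merely uncorrelated —
driving noise. None of these are tested by the package; they are the
modeling frame.

## Conditional-moment estimation

`estimate_km_field()` implements binned Kramers–Moyal estimation:

1. the observed state range is split into `n_bins = 100` equal bins;
2. for lags $\tau = 1/f_s, \dots, 10/f_s$ (10 values at $f_s = 250$ Hz),
   the conditional moments $A_1(x,\tau) = \langle x(t+\tau)-x(t)\rangle$
   and $A_2(x,\tau) = \langle (x(t+\tau)-x(t))^2\rangle$ are accumulated
   per bin of $x(t)$;
3. the final `max(lag)` samples of each trial contribute no pairs (the
   "right boundary"), and no pair ever spans a trial boundary;
4. per bin, $D^{(1)}$ and $D^{(2)}$ are the $\tau \to 0$ limits of
   $A_1, A_2$, obtained by a zero-intercept quadratic-in-$\tau$ least
   squares fit whose linear coefficient is the limit
   (`extrapolate_moment()`).

Numerical choices, and why:

* **Zero-intercept extrapolation.** $A(0) = 0$ holds identically, so the
  intercept is not estimated; the quadratic term absorbs the leading
  finite-lag bias (for an Ornstein–Uhlenbeck drift the relative bias of the
  naive single-lag estimate is $O(a\tau)$, a few percent at these lags).
* **Bin validity.** A bin is valid only with at least `min_count = 10`
  pairs at every lag. Low-occupancy bins sit at the range extremes, where
  conditioning interacts with the observed extrema of the series and the
  moment estimates are both noisy and selection-biased.
* **Negative diffusion.** A negative extrapolated $D^{(2)}$ is
  finite-sample noise in a nonnegative quantity: it is clamped to zero and
  the bin is masked from the noise fit.
* **Weighting.** Field-level polynomial fits (`fit_langevin_model()`)
  weight bins by pair counts. This keeps the sparsely sampled edge bins —
  the ones carrying extreme-value selection bias — from steering the fit.

## Reconstruction modes

`reconstruct()` exposes three estimation modes:

* **concatenated** — one field from all trials jointly (boundaries
  respected), one model. Maximal data, one set of coefficients per channel.
* **single_trial** — one field and model per epoch. Captures
  trial-to-trial variation; with 750-sample epochs the per-trial fits are
  noisy and only the well-occupied central bins survive the validity mask.
* **pooled** — one field per epoch, then all valid per-trial
  $(x, D^{(1)})$ and $(x, \sqrt{D^{(2)}})$ points enter a single
  polynomial fit. This is the mode used to build behavioral models: one
  equation per channel, estimated from every trial.

Pooled mode departs from the field-level fits in two deliberate ways.
First, all trials of a channel share one binning grid (the range over all
trials), so bin placement does not depend on each short trial's own
extremes. Second, the pooled points enter **unweighted**. In calibration
runs on synthetic ground truth, count-weighted pooling attenuated the
fitted drift slope severely: in 750-sample trials a bin's occupation count
is correlated with the very increments being averaged (a trial lingers
where its sampled increments happened to be small), and weighting by counts
systematically overweights low-increment evidence. Unweighted pooling of
validity-masked points removed most of that attenuation while the shared
grid removed the rest of the placement bias. For long concatenated series
the correlation is negligible and count weights help, so both conventions
coexist, each where it is the better estimator.

Windows and units: reconstruction accepts a crop window relative to the
event (`c(-2.5, 0.5)` for signal-level description; `c(-3, 0)` for
behavioral-model building, stopping at the movement because the dynamics
change at the field's culmination) and a `scale` factor applied before
estimation. Recordings in Tesla are rescaled by $10^{13}$ so the evidence
variable is order one — estimation is scale-covariant, but order-one state
values avoid degenerate numerics in binning, fitting and simulation. The
scale is recorded in model provenance and never silently applied twice.

## The synthetic-data generator

`synth_config()` + `generate_dataset()` produce trial-epoched datasets from
a known ground-truth model. Defaults encode the targeted recording
conditions: 250 Hz sampling, 3-s epochs of 750 samples with the
button-press event 2.5 s in, 60 trials per subject (datasets of 49–99
trials are typical in this paradigm), amplitude scale $10^{-13}$ T per
model unit so order-one dynamics land at ~100 fT, and the reference
leaky-accumulator coefficients (drift $-0.29 z + 1.43$, noise 1.78) as the
default ground truth. Integration is Euler–Maruyama at one step per sample
($\Delta t = 1/f_s$): the generator's job is to produce data with exactly
the assumed Markov structure at the recording resolution, not to be a
high-accuracy SDE solver. All channels of one (subject, trial) share a
single latent path scaled by per-channel gains — an idealized "one source,
many sensors" picture — with optional independent sensor noise and an
optional deterministic ramp-and-collapse event-related template (off by
default, so reconstruction tests see a pure Langevin process).

What the generator deliberately does not emulate: volume conduction and
realistic sensor geometry, ocular/cardiac artifacts, nonstationary
coefficient drift across the epoch, inter-trial dependence, and non-Markov
(long-memory) noise. Passing the recovery tests therefore shows the
estimator chain is correct *under its own assumptions*; it does not show
that real recordings satisfy those assumptions.

Reproducibility: every (subject, trial) uses an RNG substream derived
arithmetically from the master seed, so regeneration of any single epoch is
independent of iteration order, and identical configurations are
byte-identical.

## First-passage simulation and waiting-time fits

`simulate_wt_sample()` integrates a model from $z(0) = 0$ with
Euler–Maruyama at $\Delta t = 2^{-8}$ s and records, per run, the first
step satisfying the crossing criterion. Two criteria are exposed:

* `band` (default): first step with $|z - \beta| < 0.01$. This is the
  reproduction protocol. Note its interaction with the discretization: with
  noise amplitude ~1.7 the per-step increment has standard deviation ~0.11,
  five times the band width, so trajectories frequently jump the band and
  are detected only on a later pass — band waiting times are systematically
  longer and more dispersed than first upcrossing times at this $\Delta t$.
* `upcross`: first step with $z \ge \beta$; the criterion with a clean
  $\Delta t \to 0$ limit (Euler upcrossing still carries an
  $O(\sqrt{\Delta t})$ overshoot bias, which is why halving $\Delta t$
  shifts mean waiting times by a few percent rather than nothing).

Runs are capped at `t_max = 60` s; runs that never meet the criterion are
counted as censored and excluded from fitting. Each run has its own
substream keyed by (seed, run index), so enlarging `n_runs` never
reshuffles existing runs. A fitted noise polynomial can dip to zero inside
the state range; simulation floors the amplitude at $10^{-6}$ to keep the
SDE defined, and the model object flags when the floor is active.

Waiting times are fitted by the closed-form inverse-Gaussian maximum
likelihood estimates $\hat\mu = \bar w$,
$\hat\lambda = n / \sum(1/w_i - 1/\hat\mu)$ — exact, fast, and the natural
family for first-passage data. `optimize_threshold()` scans a $\beta$ grid
(default 2–8 in steps of 0.1), fits each simulated sample, and minimizes
the Euclidean distance $E(\beta)$ to the target $(M, L)$; grid points where
every run censors are excluded. By default each grid point simulates on an
independent substream; `share_noise = TRUE` reuses the same per-run streams
across the grid, which makes $\mu(\beta)$ monotone under upcrossing and is
useful for variance-reduced scans. Fitted-model comparison uses the L2
distance between the two fitted densities, integrated adaptively over
(0, 50] s (the densities involved are below $10^{-12}$ beyond 50 s);
distances are conventionally reported at 2 decimals.

A caution on reproducing reported optima: when the reported
$(\mu(\beta_0), \lambda(\beta_0))$ pair is itself the argmin of a scan over
noisy small-sample estimates (at $N_T = 100$ the shape estimate has a
standard error of roughly $\lambda\sqrt{2/N_T} \approx 3$), the selection
step biases the reported pair toward the target. Re-simulating at the fixed
reported $\beta$ — as the acceptance script does — estimates the
protocol's true parameters at that threshold and will generally land below
a selection-biased reported $\lambda$. The package reports what the
protocol actually produces.

## Channel selection and spectra

`select_channels()` scores each channel by a readiness weight $W$: the
trial-averaged field (ERF) is searched for its maximum within ±0.2 s of the
event (101 samples at 250 Hz), and $W$ is the ERF mean over ±0.1 s around
that maximum (51 samples), truncated at epoch edges. Ties take the first
index; the signed field is used by default (a readiness-type field is a
signed extremum near the event), with an `absolute` option for
polarity-ambiguous sensors. The top `k = 5` channels per subject are kept,
sorted by $W$ with ties broken by channel order.

`estimate_psd()` is a Welch estimator (256-sample segments, 50% overlap,
Hann taper, per-segment demeaning, one-sided density normalized so the PSD
integrates to the variance), and `fit_spectral_exponent()` fits
$\log_{10} S$ vs $\log_{10} f$ over 0.5–40 Hz by least squares,
reporting $\alpha = -$slope. These are conventional choices for
sensor-level spectra; trajectories shorter than one segment are rejected
rather than zero-padded.

## Decisions on open points

* Trial sets are treated as a single condition; no per-condition split.
* The crossing band is evaluated after every Euler step, not at
  sample-rate resolution.
* Threshold scans default to independent noise per grid point (sharing is
  opt-in).
* In the end-to-end pipeline, the threshold is optimized per candidate
  model and the globally best model is the one with the smallest
  $E(\beta_0)$ across subjects and channels, for each degree set
  separately.
* Epoch containers are delimited-text matrices (one per subject–channel,
  samples × trials) plus a JSON sidecar; models and scans serialize to
  JSON; waiting times to commented CSV.

## Problem sizes and test design

The test suite verifies estimators against independent oracles (exhaustive
pair enumeration for the conditional moments; numerical likelihood
maximization for the inverse-Gaussian MLE; closed-form laws for noiseless
drift, Ornstein–Uhlenbeck variance, driftless-Brownian first passage and
$1/f^2$ spectra) and recovery of known ground truth through the full
chain. Recovery tolerances were frozen from 20-replicate calibration runs
under the default study conditions (60 trials × 750 samples for pooled
linear recovery; ~$10^6$ samples for cubic-drift recovery); spectral and
spectral-limit checks use $10^5$-sample series; end-to-end model
comparison uses 20 seeded pipeline runs at 60 trials with a 0.25-wide
$\beta$ grid and $N_T = 200$. These sizes were chosen once as realistic
desk-scale instances of the estimators' intended operating range.

## Known limitations

* Polynomial drift and noise only; no non-integer or rational exponents.
* No Markovianity or stationarity diagnostics.
* The band-crossing waiting-time protocol is $\Delta t$-dependent by
  construction (see above); results quoted under it are tied to
  $\Delta t = 2^{-8}$ s.
* Single-subject, single-channel models; no hierarchical pooling across
  subjects.
* Censored runs are excluded from inverse-Gaussian fitting rather than
  handled by censored likelihood; with the default 60-s cap and the
  reference models this affects a fraction of a percent of runs.
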