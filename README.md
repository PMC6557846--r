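# accubound

Data-driven reconstruction of Langevin (drift–diffusion) equations from
trial-epoched neural time series, and integration-to-bound decision models
built on the reconstructed equations.

## The problem

Self-initiated movements are preceded by a slow buildup of neural activity
(the readiness potential / event-related field). A common account treats the
single-trial signal as a stochastic accumulation-to-bound process: an
evidence variable `z` integrates noisy input until it crosses a threshold
`β`, at which point the movement is triggered. The canonical model is the
leaky stochastic accumulator (LSA, an Ornstein–Uhlenbeck process),

    dz/dt = a z + b + A Γ(t),

with Gaussian white noise `Γ`. But constant-noise accumulators are
spectrally rigid — their output is Brownian, `S(f) ∝ 1/f²` — while real
neural recordings show `1/f^α` spectra with `α` varying between 0 and 2.
`accubound` implements the full workflow for fitting and testing a more
general polynomial Langevin model directly on data:

    dz/dt = P_G(z) + P_H(z) Γ(t),

where `P_G` (drift, degree `G`) and `P_H` (state-dependent noise amplitude,
degree `H`) are estimated nonparametrically from binned Kramers–Moyal
conditional moments,

    D1(x) = lim_{τ→0} ⟨x(t+τ) − x(t)⟩ / τ,
    D2(x) = lim_{τ→0} ⟨(x(t+τ) − x(t))²⟩ / τ,

with `P_G = D1` and `P_H = sqrt(D2)`, then fit by polynomial least squares.
First-passage waiting times of the fitted models are simulated with
Euler–Maruyama (`Δt = 2⁻⁸ s`), fitted to the inverse-Gaussian (Wald) family

    ρ(w; μ, λ) = sqrt(λ / 2πw³) · exp{ −λ(w−μ)² / 2μ²w },

and the threshold `β` is optimized so that the fitted `(μ(β), λ(β))` are as
close as possible to an empirical target `(M, L)` in Euclidean distance
`E(β)`; competing models are compared by the L2 distance
`D(ρ₁, ρ₂) = sqrt(∫ (ρ₁ − ρ₂)² dw)` between fitted densities.

Because the matching MEG recordings are not publicly distributable, the
package ships a synthetic-data module that generates MEG-like epoched
datasets (250 Hz, 750-sample epochs around a button-press event, fT-scale
amplitudes) from known ground-truth Langevin models, so every stage —
channel selection, reconstruction, simulation, optimization, spectral
analysis — is testable end to end.

## Worked example

Generate a synthetic dataset from a known nonlinear ground truth
(`P_G(z) = −0.03z³ + 0.17z² + 0.81`, `P_H(z) = 0.01z² − 0.01z + 1.72`),
then run the full pipeline: select the channel most resembling a readiness
field, reconstruct pooled LSA (G=1, H=0) and nonlinear (G=3, H=2) models,
optimize each model's threshold against the empirical waiting-time target
IG(μ = 5.95, λ = 21.96), and compare densities:

```r
library(accubound)

truth <- synth_config(
  drift_coeffs = c(-0.03, 0.17, 0, 0.81),
  noise_coeffs = c(0.01, -0.01, 1.72),
  n_trials = 60, n_channels = 3, channel_gains = c(0.6, 1, 0.8),
  epoch_duration = 3.5, event_latency = 3, seed = 2024
)
run <- run_pipeline(truth, k = 1, betas = seq(3, 8, by = 0.25),
                    config = sim_config(n_runs = 200), seed = 2024)
run
#> <accubound_run>
#>   1 selected channel(s); target (mu, lambda) = (5.95, 22)
#>   best lsa       S01/MEG002: beta0 = 6.25, mu = 10.3, lambda = 19, E = 5.27, D = 0.158
#>   best nonlinear S01/MEG002: beta0 = 6.25, mu = 8.87, lambda = 19.8, E = 3.66, D = 0.127
#>   mean spectral alpha over selected channels: 2.04

run$best$model[[which(run$best$model_type == "nonlinear")]]
#> <langevin_model> dz/dt = P_G(z) + P_H(z) Gamma(t)
#>   drift  P_G (degree 3 ): -0.01896 z^3 + 0.1164 z^2 + -0.1921 z + 0.7574
#>   noise  P_H (degree 2 ): 0.01145 z^2 + -0.02748 z + 1.677
#>   state range: [ -3.395 , 7.413 ] model units
#>   provenance: pooled
```

Reading the output: the gain-1 channel is correctly selected; the pooled
reconstruction recovers drift and noise polynomials close to the generating
ones (leading drift coefficient −0.019 vs −0.03, constant noise 1.68 vs
1.72); and the nonlinear model's optimized waiting-time density sits closer
to the empirical target than the LSA's (`D = 0.127 < 0.158`, `E = 3.66 <
5.27`) — the qualitative ordering the model comparison is about. Each stage
is also available separately (`generate_dataset()`, `select_channels()`,
`reconstruct()`, `simulate_wt_sample()`, `fit_inverse_gaussian()`,
`optimize_threshold()`, `l2_density_distance()`, `spectral_exponent()`),
returns tibbles or objects with `tidy()`/`glance()` methods, and has an
`autoplot()` where a picture helps.

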