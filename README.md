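# coralspectra

Desk-scale tools for automated coral-reef health monitoring. Coral health
degrades continuously — Healthy → Sub-healthy → Bleached → Dead — and the
imagery used to track it is corrupted by turbidity: wavelength-dependent
attenuation, a bluish-green veiling light, and high-frequency backscatter
from suspended particles. `coralspectra` implements, in plain R, the three
computational layers a dual-domain monitoring pipeline needs, together with
the synthetic generators required to exercise every one of them without any
field data:

1. **Spectral soft-gated filtering** (perception). A 2-level discrete
   wavelet transform (Daubechies db4, periodized, exactly orthonormal)
   splits a feature map `F` into sub-bands `F_LL, F_LH, F_HL, F_HH`.
   Learnable gates rescale each band elementwise,

   ```
   F'_LL = F_LL ⊙ (1 + α σ(W_LL * F_LL))     F'_LH = F_LH ⊙ (1 + γ σ(W_LH * F_LH))
   F'_HH = F_HH ⊙ (1 − β σ(W_HH * F_HH))     F'_HL = F_HL ⊙ (1 − δ σ(W_HL * F_HL))
   ```

   (σ = sigmoid, `W_*` are 1×1 channel-mixing blocks, α..δ ∈ [0,1], defaults
   α = 0.5, β = 0.7), and the inverse transform reconstructs a denoised map.
   Structure lives in the low bands; turbidity noise in the high bands.

2. **Prototype-contrastive classification** (understanding). Detections are
   embedded on the unit sphere; a supervised contrastive loss
   `-mean_i 1/|P(i)| Σ_{p∈P(i)} log[ exp(z_i·z_p/τ) / Σ_{a≠i} exp(z_i·z_a/τ) ]`
   (τ = 0.10) pulls same-state corals together, a momentum bank
   `μ_c ← (1−m) μ_c + m · mean(z: y = c)` maintains one prototype per health
   state, and classification is nearest-prototype with margin confidence
   `(d₂−d₁)/(d₂+d₁)`. Diagnostics: expected calibration error, silhouette
   score, centroid distances.

3. **State-space health forecasting** (prediction). Health trajectories
   `h(t) ∈ [0,1]` are encoded per step, run through a diagonal selective
   state-space scan `x_t = Ā_t x_{t−1} + B̄_t u_t`, `y_t = C x_t`, with
   input-dependent step size (zero-order-hold discretization, log-spaced
   timescales), and read out by ridge heads at 1-, 2- and 4-week horizons.
   A ConvLSTM baseline trains through the identical readout for
   comparison; Monte-Carlo dropout (30 passes, p = 0.1) yields 95%
   intervals `μ ± 1.96σ`.

A fourth module generates the synthetic world: turbid scenes via the
scattering model `I = J·t + A·(1−t)`, `t = exp(−c·NTU)` plus broadband
backscatter grain; four-class coral blob scenes with YOLO/COCO
annotations; and canonical health trajectories (stable at 0.95,
exponential decay 0.95 → 0.10 over four weeks, dip-to-0.30/recover-to-0.60,
and spatially heterogeneous decay). A harness adds detection AP, robustness
scores, deployment energy/endurance arithmetic, and an experiment runner.

## Worked example

```r
library(coralspectra)

# a synthetic reef scene, degraded at high turbidity (8 NTU)
sc     <- generate_scene(n_corals = 6, size = 96, seed = 42)
turbid <- simulate_turbidity(sc$image, ntu = 8, seed = 7)
gray_clean  <- apply(sc$image, c(1, 2), mean)
gray_turbid <- apply(turbid,   c(1, 2), mean)

sd(gray_clean); sd(gray_turbid)        # contrast: 0.0831 -> 0.0350
subband_energy_fraction(decompose(gray_turbid), "HH", 1)
                                       # finest HH fraction: 0 -> 0.00104

# suppressive gating (beta = delta = 1, saturating logits) de-noises
sat <- replicate(2, {I <- matrix(100, 1, 1); list(LL=I, LH=I, HL=I, HH=I)},
                 simplify = FALSE)
gp   <- gate_params(2, 1, alpha = 0, beta = 1, gamma = 0, delta = 1,
                    weights = sat)
filt <- wio_filter(gray_turbid, gp)$values[1, , ]
mean((gray_turbid - gray_clean)^2)     # 0.00439
mean((filt - gray_clean)^2)            # 0.00432  (closer to clean)

# a noisy bleaching trajectory, and recovery of its decay parameters
tr  <- generate_trajectory(scenario_spec("decay", noise_sd = 0.02, seed = 11),
                           steps_per_day = 2)
fit_decay(tr)[c("k", "p")]             # k = 0.00776 /h (true 0.00764),
                                       # plateau 0.099 (true 0.10)

# AUV deployment arithmetic (25 W, 15.6 ms, 30 FPS, 1.5 kWh, 200 W base)
auv_endurance(deployment_spec())
# 0.39 J/frame, 11.7 W compute, 211.7 W total, 7.09 h endurance
```

The contrast drop, the rise of finest-band HH energy with turbidity, and
the MSE improvement from suppressive gating are the three directional
signatures the test suite asserts across many seeds.

## Command line

```sh
Rscript -e 'coralspectra::cli_main()' -- simulate scene --seed 4 --size 128 --out out/
Rscript -e 'coralspectra::cli_main()' -- filter --in out/scene.png --out filtered.png \
    --basis db4 --levels 2 --alpha 0.5 --beta 0.7
Rscript -e 'coralspectra::cli_main()' -- forecast --history traj.csv \
    --horizons 1,2,4 --passes 30 --seed 7
```

See `vignettes/coral-monitoring-methods.Rmd` for the model assumptions,
parameter choices, and the limits of what the synthetic world can
establish.
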