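# popout

Simulation and decoding tools for degraded-speech "pop-out" experiments:
EEG speech-envelope reconstruction, band-limited spectral analysis with
cluster-based permutation statistics, and pupillometry, driven end to end
by a synthetic-data generator with injectable, known condition effects.

## The problem this package addresses

Hearing a heavily degraded sentence, reading its transcription, then
hearing the same degraded sentence again usually produces a dramatic
subjective improvement in clarity — *pop-out*. A standard way to study its
neural basis is a two-presentation design: participants hear sine-wave
(SWS) or noise-vocoded (NVS) sentences twice, with the interleaved text
being correct (P+), an incorrect near-match (P−), or uninformative (P0),
while EEG, pupil size, and 1–4 clarity ratings are recorded.

The central measurement is **backward stimulus reconstruction**: a linear
temporal-response-function (TRF) decoder is trained to map lagged
multichannel EEG onto the 2–8 Hz auditory envelope of clear speech,

```
ŝ(t) = Σ_c Σ_τ  w(c, τ) · EEG_c(t + τ) + b,     τ = 0 … 300 ms (10 ms steps)
```

with `w = (XᵀX + λI)⁻¹ Xᵀs` the ridge solution on the lagged design `X`.
Reconstruction quality is the Pearson correlation `r` between ŝ and the
stimulus envelope extracted by a gammatone (STEP) auditory model —
higher `r` means a more faithful cortical representation of the speech
envelope. Band power (delta/theta/alpha/beta), induced (non-phase-locked)
power profiles, and pupil dilation are analyzed alongside, with
nonparametric cluster-based permutation tests (summed-t cluster mass
against a max-mass sign-flip null).

Because the original human recordings cannot be regenerated, the package
ships a forward simulator that emulates the full study — stimuli, design,
EEG, pupil, ratings — with multiplicative condition effects you control,
so every stage of the analysis is validated by *parameter recovery*: inject
tracking_gain(P+) = 1.5, recover Δr(P+ − P0) > 0; inject nothing, reject
at the nominal rate. It is aimed at researchers developing or teaching
envelope-tracking analyses who need a ground-truthed testbed.

## Worked example

Simulate a small study with paper-like effects (correct priors boost
envelope tracking by 50% on the second presentation), decode every trial,
and summarize the condition cells:

```r
library(popout)
library(dplyr)

cfg <- run_config(
  n_participants = 6, n_pairs = 10, seed = 11,
  effects = paper_like_effects(),
  trials_per_cell = 2, presentations = 2, n_iterations = 1,
  training_duration = 15, lambda = 1e4,
  measures = c("reconstruction", "ratings")
)
bundle <- run_pipeline(cfg)
s <- summarize_conditions(bundle)
s$cell_means |>
  group_by(measure, prior) |>
  summarise(mean = mean(value), .groups = "drop")
#>          measure prior  mean
#> 1        clarity    P+ 3.458
#> 2        clarity    P- 2.167
#> 3        clarity    P0 1.833
#> 4 reconstruction    P+ 0.415
#> 5 reconstruction    P- 0.227
#> 6 reconstruction    P0 0.264
s$contrasts
#>          measure stimulus_type prior mean_diff p_value n
#> 1        clarity           NVS    P+    1.6667  0.0355 6
#> 2        clarity           NVS    P-    0.2500  0.3711 6
#> 3        clarity           SWS    P+    1.5833  0.0355 6
#> 4        clarity           SWS    P-    0.4167  0.2693 6
#> 5 reconstruction           NVS    P+    0.1661  0.1422 6
#> 6 reconstruction           NVS    P-   -0.0587  0.8339 6
#> 7 reconstruction           SWS    P+    0.1368  0.1422 6
#> 8 reconstruction           SWS    P-   -0.0154  0.6750 6
```

Reading the output: clarity ratings after the second presentation jump
for correct priors only (P+ 3.46 vs P0 1.83 on the 1–4 scale — the
behavioral pop-out), and reconstruction scores (Pearson r between the
decoded and true 2–8 Hz envelope over the first 3.5 s of presentation 2)
follow the same pattern: P+ 0.415 vs P0 0.264 with P− ≈ P0, exactly the
injected effect structure. `contrasts` gives per-stimulus-type paired
differences against P0 with descriptive Wilcoxon p-values; six
participants at two trials per cell are enough to see the effect sign but
not to reach significance on reconstruction — the packaged validation
(below) uses 19 participants.

The building blocks are exported individually and pipe together:

```r
pool  <- build_stimulus_pool(80, seed = 1)          # 160 paired sentences
design <- assign_conditions(pool, participant_index = 1, seed = 1)
clear <- synthesize_clear(pool[1, ])                # 10.5 s waveform
nvs   <- noise_vocode(clear, n_bands = 7)
env   <- extract_envelope(nvs)                      # 100 Hz, 2-8 Hz band
autoplot(env)

model <- train_decoder(training_eeg, training_env,  # ridge + CV
                       lambda_grid = 10^seq(-6, 6))
glance(model)                                       # lambda, training r
scores <- score_reconstruction(
  reconstruct_envelope(model, trial_eeg), env)

res <- cluster_permutation(power_Pplus, power_P0, build_neighbors(channel_layout()))
tidy(res)                                           # mass, sign, Monte Carlo p
```

`simulate_session()` generates a complete per-participant dataset (design,
ratings, training narrative and EEG, trial epochs, pupil traces), and
`write_session()`/`write_wav()` serialize everything as plain text/WAV.

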