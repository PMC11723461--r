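# eeggan

Removal of EMG, EOG, ECG and mixed physiological artifacts from
single-channel EEG segments with a dual-branch hybrid CNN–Transformer
generator trained adversarially against three least-squares discriminators
— implemented entirely in R (the forward and backward passes are
hand-written on BLAS matrix operations with small C++ kernels for the
attention hot path), so no external deep-learning framework is required.

**Who it is for:** researchers working with single-channel EEG (BCI,
sleep, wearables) who need a denoiser that can be trained, inspected and
evaluated end to end inside R, plus a reproducible semi-simulated
contamination benchmark and a six-metric scoring suite.

## Model

A contaminated segment is modelled as a linear mixture
`y = x + λ·n` of clean EEG `x` and an artifact `n`, with
`SNR = 10·log10(RMS(x)/RMS(λ·n))` controlled exactly by solving for λ.
The generator takes `y` and produces three outputs: a clean estimate `Y₁`
(branch 1 learns the clean-EEG distribution), a noise estimate `Y₂`
(branch 2 learns the artifact distribution), and the fused prediction

```
Ypre = m₁ ⊙ Y₁ + m₂ ⊙ (y − Y₂)
```

where `m₁, m₂ ∈ (−1,1)` are masks from two tanh-gating networks. Each
branch runs a preprocessing module (two convolutions + average pooling),
five encoding blocks as parallel CNN and local–global-Transformer streams
(local self-attention inside 8 partitions, then global self-attention),
a fusion convolution, and a decoder. Three discriminators score `Y₁`,
`Y₂` and `Ypre` against real clean/noise segments; the generator loss per
branch is `MSE + λ₁·feature-matching + λ₂·least-squares-adversarial`.

Denoising quality is scored per segment by time- and spectral-domain
relative RMSE, Pearson correlation (with p-value), percentage artifact
reduction η, a global 1-D SSIM, and histogram mutual information.

## Worked example

```r
library(eeggan)

# synthetic pools: 250 clean EEG and 250 EOG artifact segments (2 s @ 512 Hz)
eeg <- gen_eeg(250, seed = 101)
eog <- gen_eog(250, seed = 202)

# 80/10/10 split; train pairs mixed at one SNR each in -7..2 dB,
# val/test pairs mixed once at every integer level
sp <- build_splits(eeg, eog, split_spec(seed = 11))

# small validation subset for the per-epoch early-stopping metric
vs <- sp$val
keep <- which(vs$snr_db %in% c(-7, -3, 0, 2))[1:40]
val_small <- pair_set(vs$X[keep, ], vs$N[keep, ], vs$lam[keep],
                      vs$snr_db[keep], vs$artifact_type, vs$fs)

fit <- fit_denoiser(
  sp$train, val_small,
  generator_config(width_scale = 8),      # desk-scale network
  discriminator_config(width_scale = 8),
  train_config(batch_size = 40, max_epochs = 30,
               lr_gen = 1e-3, lr_disc = 1e-3, seed = 11)
)

ts <- sp$test                                       # 100 held-out examples
tk <- which(ts$snr_db %in% -7:2)[1:100]
test_small <- pair_set(ts$X[tk, ], ts$N[tk, ], ts$lam[tk],
                       ts$snr_db[tk], ts$artifact_type, ts$fs)
ev <- evaluate_pairs(test_small, fit)                  # trained denoiser
bl <- evaluate_pairs(test_small, denoiser = identity)  # untouched mixtures
ev$report
```

On the held-out pairs of this configuration the scaled-down model reaches
(grand means over all ten SNR levels; your exact numbers depend only on
the seeds shown):

```
denoised:     rrmse_t = 0.77   cc = 0.72   eta = 40.3%   rrmse_t at 0 dB = 0.61
contaminated: rrmse_t = 2.19   cc = 0.49
```

i.e. the network removes most of the artifact energy (the contaminated
baseline's time-domain error is the analytic `10^(-SNR/10)`, exactly 1.0
at 0 dB) while keeping correlation with the clean signal above the
contaminated baseline. Full-width training on real data is a GPU-scale
undertaking and out of scope for the bundled studies.

`autoplot(ev$report)` draws the per-SNR metric curves, `tidy(fit)` returns
the per-epoch training log, `glance(fit)` a one-row summary, and
`save_checkpoint()` / `load_checkpoint()` round-trip trained models.
A thin command-line front end over these functions ships in
`inst/cli/eeggan.R` (subcommands `simulate`, `mix`, `train`, `denoise`,
`evaluate`).

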