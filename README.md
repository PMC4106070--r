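# rsae — robust stacked autoencoders for EEG seizure detection

`rsae` detects epileptic seizures in multichannel EEG at the level of
5-second segments. It is aimed at researchers in EEG analysis / neural
engineering who need a fully reproducible, artifact-robust detection
pipeline and a way to study *why* it is robust.

Scalp EEG is contaminated by short, high-amplitude EMG bursts that leave
extreme outliers in quadratic features and routinely trigger false
alarms. The package's core idea is to make the *feature learner* itself
robust: a stacked sparse autoencoder whose reconstruction loss is the
maximum correntropy criterion (MCC) instead of the mean square error,

    J_MCC = (1/n) Σᵢ Σⱼ κ_σ(x_ij − y_ij),     κ_σ(u) = exp(−u²/2σ²) / (√(2π) σ),

trained by minimising `−J_MCC + J_weight + J_sparse`. Each residual
contributes at most `κ_σ(0)/n` no matter how large it is (bounded
influence), so artifact-driven outliers cannot dominate the fit, while
for residuals ≪ σ the criterion behaves like MSE. The classical
MSE-based model (S-SAE) is included as the paired baseline.

The full pipeline: cross-power spectral matrices `a_ij = ∫ |P_ij(ω)| dω`
per segment → per-subject frequency-band choice (theta/alpha/beta) by
Fisher's discriminant ratio on the training split → log1p + min–max
scaling → layer-wise pretraining → joint fine-tuning with a softmax
classifier → held-out sensitivity/specificity over repeated trials.
A synthetic EEG generator (pink-noise background, coherent band-limited
ictal oscillations, label-independent EMG-like bursts) makes every stage
testable without patient data. Recording I/O covers a delimited text
dialect and 16-bit EDF.

## Worked example

Everything is driven by one experiment configuration. Under the default
synthetic conditions (8 channels, clear alpha-band seizures, EMG bursts
in both classes) the detector is essentially perfect, mirroring the
regime the method was designed for. A deliberately degraded regime shows
the moving parts better:

```r
library(rsae)

cfg <- experiment_config(
  synth = synth_config(n_channels = 4, seizure_amp = 3,   # weak rhythm,
                       coupled_fraction = 0.5,            # half the channels
                       seed = 2024),
  n_seizure = 60, n_nonseizure = 240,
  n_train_per_class = 40,
  layer_sizes = c(16, 12, 4),
  ae = ae_config("MCC"),        # "MSE" gives the S-SAE baseline
  n_trials = 3, seed = 2024)

res <- run_experiment(cfg)
print(res)
#> <detection_metrics> 3 trial(s), band alpha (8-13 Hz)
#>   sensitivity: 0.78 ± 2.9e-02  (before fine-tuning 0.82 ± 5.8e-02)
#>   specificity: 0.91 ± 2.9e-03  (before fine-tuning 0.84 ± 4.6e-02)
```

Reading the output: the band selector recovered alpha (where the
synthetic seizure rhythm was placed) from the training split alone;
each trial re-initialises the network on the same fixed train/test
split; sensitivity is the fraction of seizure segments detected and
specificity the fraction of nonseizure segments correctly classified on
the held-out set; joint fine-tuning trades a little sensitivity for a
substantially better false-alarm rate in this weak-signal regime. With
the default `synth_config()` all four numbers are 1.00.

`sweep_parameter(cfg, "q", c(20, 10, 3))` and
`sweep_parameter(cfg, "sigma", c(0.01, 0.05, 0.2))` reproduce the model
analyses (feature dimension and kernel size); `run_trial()` exposes a
single trial with its trained network, selected band, scaler and
before/after-fine-tuning metrics; `save_model()`/`load_model()`
round-trip the whole detector as JSON.

A command-line front end with `synth`, `features`, `select-band`,
`train`, `evaluate`, `sweep` and `run-all` subcommands lives at
`inst/cli/rsae.R`:

```sh
Rscript inst/cli/rsae.R synth --seed 3 --out /tmp/demo
Rscript inst/cli/rsae.R train --recording /tmp/demo/recording.txt \
    --fs 256 --intervals /tmp/demo/intervals.txt --loss mcc --out /tmp/demo
```

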