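# dysvoice

Voice-based screening of hypokinetic dysarthria (the Parkinsonian speech
syndrome) from sustained-vowel recordings, for speech scientists and
clinical-ML researchers who need a fully reproducible, testable pipeline
without access to clinical audio.

Parkinsonian phonation differs from healthy phonation in a handful of
well-established acoustic quantities measured on the sustained vowel /a/:

- **Jitter** — cycle-to-cycle period instability,
  `Jitter = (1/(N−1)) Σ |Tᵢ − Tᵢ₊₁| / T̄` (healthy ≤ 0.5 %, pathological 3–5 %);
- **Shimmer** — cycle-to-cycle amplitude instability, the amplitude analogue
  (reported in % and dB);
- **Harmonics-to-noise ratio** — `HNR = 10 log₁₀(P_harmonic / P_noise)`
  (healthy ≥ 10 dB, pathological ≤ 7 dB, a breathy voice);
- reduced F0 variability (monotone pitch), blurred LPC formants, and shifted
  spectral-shape descriptors (centroid, bandwidth, flatness, sub-band
  contrast, zero crossing rate);
- MFCCs with delta/delta-delta dynamics, and 40 × 128 log-mel spectrogram
  grids as classifier input.

The package provides the whole chain as composable functions:

| stage | functions |
|---|---|
| audio I/O & segmentation | `load_wav()`, `write_wav()`, `normalize()`, `segment_fixed()` |
| spectral-gating denoiser | `stft()`, `estimate_noise_psd()`, `spectral_gate()`, `denoise()` |
| voice-quality features | `track_f0()`, `extract_cycles()`, `jitter_percent()`, `shimmer_percent()`, `hnr_db()`, `formants_lpc()`, `mfcc_stack()`, `mel_spectrogram()`, `featurize()` |
| dysphonic-vowel synthesis | `voice_profile()`, `preset_profiles()`, `synth_vowel()`, `make_corpus()` |
| feature selection | `mutual_information_rank()`, `rfe_select()` |
| classifiers | `build_model()` (BiLSTM / CNN-LSTM / CNN-GRU / DNN), `train_model()`, `fit_classical()` (SVM / XGBoost / logistic) |
| evaluation | `confusion()`, `metrics()`, `roc_auc()`, `kfold_cv()`, `run_pipeline()` |

A built-in source–filter synthesizer generates sustained vowels with
controllable F0, jitter, shimmer, HNR and formants, so every estimator is
tested against known ground truth and the full pipeline runs end-to-end
with no external data. The deep classifiers (convolutional-recurrent
stacks trained with Adam and binary cross-entropy) are implemented as a
compact, gradient-checked neural-network engine in R.

## Worked example

```r
library(dysvoice)

profiles <- preset_profiles()
hc <- synth_vowel(profiles$hc, rate = 8000, seed = 7)   # healthy vowel
pd <- synth_vowel(profiles$pd, rate = 8000, seed = 7)   # pathological vowel
f <- rbind(featurize(hc), featurize(pd))
round(f[, c("jitter_pct", "shimmer_pct", "hnr_db",
            "f0_mean_hz", "f1_hz", "f2_hz")], 2)
#>   jitter_pct shimmer_pct hnr_db f0_mean_hz  f1_hz   f2_hz
#> 1       0.04        6.77  15.21     201.51 675.24 1211.21
#> 2       4.03       22.65   6.07     179.11 704.91 1203.54
```

Row 1 is the healthy voice: jitter far below the 0.5 % clinical bound, HNR
above 10 dB, and formants near the /a/ targets (700, 1200 Hz). Row 2 is the
pathological voice: jitter recovered at its 4 % synthesis target, HNR below
the 7 dB bound. (Shimmer readings include a noise-dependent measurement
floor — see the methods vignette.)

The end-to-end pipeline — synthesize, extract, train, evaluate — is one
call:

```r
report <- run_pipeline(pipeline_config(n_pd = 20, n_hc = 20, seed = 7,
                                       model = "DNN", epochs = 8))
#> [data] synthetic corpus: 20 PD / 20 HC, seed 7
#> [features] 40 log-mel grids (40 x 128)
#> [train] DNN, protocol split
#> [evaluate] accuracy 1.000, AUC 1.000
```

The report carries accuracy, precision, recall, specificity, F1, the
Matthews correlation coefficient and ROC/AUC for the held-out stratified
20 % split (here the synthetic classes are fully separated, so the
held-out metrics reach 1.0).

A thin command-line front-end over the same functions lives at
`inst/cli/dysvoice.R`:

```sh
Rscript inst/cli/dysvoice.R synth --n-pd 40 --n-hc 41 --seed 7 --out corpus/
Rscript inst/cli/dysvoice.R denoise --k 1.5 --alpha 0.1 in.wav out.wav
Rscript inst/cli/dysvoice.R pipeline --model BiLSTM --seed 7 --out run/
```

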