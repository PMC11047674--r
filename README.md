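# mwppg — multi-wavelength PPG fusion for cuffless blood pressure

`mwppg` estimates systolic and diastolic blood pressure (SBP/DBP, mmHg)
from four-wavelength fingertip photoplethysmography (PPG). Light at
660/730/850/940 nm probes different tissue depths, so the four channels
carry depth-distinct views of the same pulse; fusing them recovers
information no single wavelength can see. The package is aimed at
researchers prototyping image-based cuffless BP methods and at anyone who
needs the device-validation statistics (AAMI, BHS, Bland–Altman) as
reusable, tested code.

The pipeline, end to end:

1. **Preprocess** — zero-phase second-order Butterworth band-pass
   (0.5–8 Hz), per-record z-scoring, simultaneous 5 s / 1 s sliding
   windows across the four channels, rule-based abnormal-segment
   rejection.
2. **Scalogram fusion** — each window of each wavelength becomes a
   continuous wavelet transform scalogram (first-order complex Gaussian
   wavelet, `WT(a,b) = |a|^{-1/2} ∫ x(t) ψ*((t−b)/a) dt`, magnitudes),
   rendered as an RGB image; the four RGB images are stacked depth-wise
   into one H×W×12 tensor.
3. **Regression** — a compact attention CNN (conv → batch-norm → SELU →
   squeeze-and-excitation channel attention → pool, ×3) feeds a two-layer
   bidirectional LSTM and two dense layers that emit (SBP, DBP). Three
   input variants reproduce the classic comparison: one wavelength
   (`single`), four parallel conv branches (`four_branch`), and the fused
   12-channel tensor (`fused12`).
4. **Evaluation** — ME, SD (population form, so RMSE² = ME² + SD²
   exactly), MAE, RMSE, R², the AAMI verdict (|ME| < 5 and SD < 8 mmHg),
   BHS cumulative-error grading (A = 60/85/95 % within 5/10/15 mmHg), and
   Bland–Altman limits of agreement ME ± 1.96·SD.

A synthetic cohort generator (`simConfig()`/`simulateCohort()`) emulates
the acquisition protocol — 200 Hz, 60 s, four channels with a monotone
dicrotic-prominence gradient across wavelengths — with BP labels linked
affinely to beat morphology, so the whole pipeline runs and is tested at
desk scale without any data download. See the methods vignette
(`vignettes/mwppg-methods.Rmd`) for the model, conventions and design
decisions.

## Worked example

```r
library(mwppg)

# a 12-subject synthetic cohort: 200 Hz, 60 s, 4 wavelengths each
cohort <- simulateCohort(simConfig(n_subjects = 12, seed = 7))
cohort$labels[1:3, ]
#>   subject_id sbp dbp hypertensive
#> 1       S001 148  89         TRUE
#> 2       S002 150  89         TRUE
#> 3       S003 109  77        FALSE

# preprocess one record: 56 aligned windows of 1000 samples
ws <- preprocessRecord(cohort$records[[1]], win = 5, stride = 1)
ws
#> WindowSet 'S001': 56 aligned windows x 4 channels, 1000 samples each @ 200 Hz

# scalogram of one window, fused across the four wavelengths
imgs <- lapply(1:4, function(k)
  scalogramToRGB(cwtScalogram(ppgSamples(ws)[, 1, k], 200),
                 size = c(64, 64)))
fuseChannels(imgs)
#> FusedTensor: 64 x 64 x 12 (four RGB blocks, Ch1..Ch4)

# evaluation harness on its own: published-style metrics from predictions
report <- computeMetrics(yTrue = c(120, 135, 110, 128, 142, 118),
                         yPred = c(122, 131, 113, 126, 139, 121))
report
#> EvalReport (n = 6)
#>   ME -0.17  SD 2.91  MAE 2.83  RMSE 2.92 mmHg   R^2 0.927
#>   AAMI (|ME| < 5, SD < 8): pass
#>   BHS: 100% <=5, 100% <=10, 100% <=15 mmHg -> grade A
#>   Bland-Altman: -0.167 [-5.872, 5.538] mmHg
```

A full fused-tensor training run on the packaged synthetic study
(60 subjects, 5 s windows sliding by 3 s, 32×32 images) takes a few
minutes on one CPU core:

```r
cohort <- simulateCohort(simConfig(n_subjects = 60, label_noise_sd = 0,
                                   seed = 11))
dataset <- buildTrialDataset(cohort)
res <- runTrial(3, cohort, dataset = dataset, tcfg = trainConfig(seed = 1))
res$report$sbp@mae
#> [1] 10.549
meanPredictorBaseline(dataset$meta$sbp[res$splits$train],
                      dataset$meta$sbp[res$splits$test])
#> [1] 25.355
```

On this cohort the fused model reaches a held-out SBP MAE below half the
mean-predictor baseline and below the best single-wavelength model
(channel 1: 11.08, channel 4: 11.56 mmHg at the same seed) — the
synthetic labels depend on a cross-channel dicrotic contrast that no
single wavelength can observe, so fusion must win if (and only if) the
pipeline is wired correctly.

## Command line

A thin CLI over the package functions lives in
`inst/scripts/mwppg-cli.R`:

```sh
Rscript inst/scripts/mwppg-cli.R simulate --n 10 --seed 1 --out-dir data/
Rscript inst/scripts/mwppg-cli.R inspect data/S001.txt
Rscript inst/scripts/mwppg-cli.R train --trial 3 --n 60 --seed 1 --out-dir run/
Rscript inst/scripts/mwppg-cli.R evaluate --pred preds.csv --truth labels.csv --out report/
```

## On-disk formats

Signal files are plain text, one row per sample, four numeric columns in
channel order 660/730/850/940 nm, `#` comments allowed; labels are a CSV
`subject_id,sbp,dbp` (the hypertension flag, SBP ≥ 130 or DBP ≥ 90 mmHg,
is derived on read). `readRecord()`/`writeRecord()` round-trip to six
decimal places.
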