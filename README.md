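# snorevol

Calibration-free estimation of **qualitative tidal volume levels**
(high / medium / low) from sleep respiratory sounds.

## Who this is for

Acoustic flow estimation from tracheal sound classically fits a
flow–sound power law (`log F = C1 log E + C2`) whose coefficients must be
calibrated per subject — impractical at home, and invalid during snoring,
when sound gets louder while airflow drops. `snorevol` implements an
alternative for sleep-respiratory research: an unsupervised pipeline that
never needs calibration and outputs a coarse tidal volume level per
one-minute clip, validated against the minute's lowest oxygen saturation
(LoO₂) from a 1 Hz SpO₂ channel.

## Method at a glance

For a mono tracheal recording `x(t)`:

1. 50–2450 Hz zero-phase Butterworth bandpass, downsample to 5 kHz,
   segment into 60 s clips.
2. Per clip: MFCC matrix (40 mel filters, 1 s / 0.5 s STFT frames,
   DCT-II, 13 coefficients) averaged over frames into one feature point;
   pairwise Euclidean distances
   `d(p,q) = sqrt(Σᵢ (pᵢ − qᵢ)²)`.
3. Average-linkage agglomerative clustering, dendrogram cut at k = 3,
   clusters labelled **snoring / normal / uncertain** by mean clip RMS.
4. Snoring clips: snore episodes from an RMS envelope; per-episode F1 by
   14th-order LPC (Yule–Walker / Levinson–Durbin, 20 ms Hamming frames,
   50 % overlap); the feature (SD of F1, SD of F1 interval) is split by
   K-means (k = 2) into **simple** vs **apneic** snoring.
5. Rule table: apneic with maximum breathing pause interval
   MBPI > 10 s → **low**, else **medium**; simple snoring sustained
   ≥ 4 min → **medium**, else **high**; normal → **high**.
6. Evaluation: LoO₂ per minute graded >95 % high / 90–95 % medium /
   <90 % low; `accuracy = correct / (total − uncertain)`.

## Worked example

```r
library(snorevol)

# a 20-minute synthetic night: normal breathing, simple and apneic
# snoring (with inserted breathing pauses), and near-silent minutes
plan <- random_plan(n_normal = 4, n_ss = 8, n_as = 5, n_unc = 2, seed = 3)
sc <- gen_scenario(plan)

report <- run_pipeline(sc$audio, sc$spo2, out_dir = "out")
#> [preprocess] bandpass 50-2450 Hz at 5000 Hz
#> [preprocess] 19 clips of 60 s
#> [mfcc] 40 mel filters, 13 coefficients, 1000/500 ms frames
#> [ahc] average linkage, cut at k = 3
#> [formants] LPC order 14 on 13 snoring clips
#> [rules] MBPI threshold 10 s, elapsed threshold 4 min
#> [evaluation] LoO2 per clip window
#> [evaluation] accuracy 0.941 (16/17, 2 uncertain excluded)

print(report)
#> <snorevol_report> 19 clips (2 uncertain)
#>   labels:  apneic_snoring=4, normal=4, simple_snoring=9, uncertain=2
#>   accuracy (uncertain excluded): 0.941 (16/17)

head(report$results, 4)
#>   clip_index          label mbpi_s elapsed_min pred_level loo2 ref_level
#> 1          0      uncertain     NA          NA  uncertain   97      high
#> 2          1      uncertain     NA          NA  uncertain   97      high
#> 3          2 simple_snoring     NA           1       high   97      high
#> 4          3 simple_snoring     NA           2       high   97      high
```

Reading the output: each row is one minute. Near-silent minutes are
flagged uncertain and excluded from scoring. Early simple-snoring minutes
of a run keep a high tidal level; from the 4th consecutive snoring minute
the predicted level (and the reference LoO₂ level) drops to medium.
Apneic minutes carry the measured MBPI instead, and an MBPI above 10 s
marks a low level (hypoxemia-range LoO₂). `out/` receives `results.csv`,
`summary.json` and a four-panel summary plot.

A command-line interface wraps the same steps
(`inst/cli/snorevol run|synth|eval`), e.g.
`... synth --plan plan.csv --seed 0 --out d/` writes `audio.wav`,
`spo2.csv`, `truth.csv`.

## Scope

The package consumes WAV + CSV (EDF extraction from polysomnography
exports is a documented user preprocessing step), and its quantitative
claims are about the synthetic testbed; clinical accuracy must be
established on real recordings. See `vignettes/tidal-volume-levels.Rmd`
for the model, the design decisions and the generator's limitations.
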