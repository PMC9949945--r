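---
title: "Estimating tidal volume levels from sleep respiratory sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tidal volume levels from sleep respiratory sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tidal volume — the air moved per breath, roughly 500 mL in a healthy adult —
collapses when the upper airway narrows or closes during sleep. Quantitative
acoustic flow estimation needs a per-subject calibration of the flow–sound
relationship, which is impractical at home and breaks down during snoring,
when sound gets louder while airflow drops. `snorevol` instead estimates a
*qualitative* tidal volume level (high / medium / low) for every one-minute
clip of a tracheal sound recording, with no calibration at all, and
evaluates the result against the per-minute lowest oxygen saturation
(LoO~2~) from a synchronized 1 Hz SpO~2~ channel.

## The pipeline

1. **Preprocess.** A 50–2450 Hz Butterworth bandpass (order 4, applied
   forward–backward so it is zero-phase), downsampling to 5000 Hz, and
   segmentation into 60 s clips. Zero phase matters because the pause
   analysis below measures event timing; a causal filter would shift
   onsets by a frequency-dependent delay.
2. **Clip features.** Per clip, a Hann-windowed power STFT (1000 ms
   windows, 500 ms hop), a 40-filter triangular mel filterbank, a log with
   a 1e-10 floor, and an orthonormal DCT-II; the first 13 cepstral
   coefficients (including the 0th) are averaged across the 119 frames
   into one 13-dimensional point per clip.
3. **Three-way clustering.** Pairwise Euclidean distances between clip
   features feed average-linkage agglomerative clustering; the dendrogram
   is cut at k = 3 and the clusters are labelled by mean clip RMS:
   quietest → *uncertain* (signal too weak to analyse), loudest of the
   rest → *snoring*, remainder → *normal breathing*.
4. **Snore typing.** For each snoring clip, snore episodes are segmented
   on a short-time RMS envelope and each episode's first formant F1 is
   estimated by 14th-order LPC (Yule–Walker via Levinson–Durbin, 20 ms
   Hamming frames, 50 % overlap). The 2-D feature
   (population SD of episode F1, population SD of onset-to-onset
   intervals) is z-scored and split by K-means (k = 2): apneic snoring has
   the larger, more irregular breath spacing and the more variable F1.
5. **Rule table.** Apneic clips: maximum breathing pause interval (MBPI)
   ≤ 10 s → medium, > 10 s → low. Simple-snoring clips: less than 4
   consecutive minutes of snoring → high, ≥ 4 → medium. Normal → high;
   uncertain stays uncertain.
6. **Evaluation.** Per clip, the LoO~2~ of its minute is graded
   > 95 % high, 90–95 % medium, < 90 % low, and accuracy is
   `correct / (total − uncertain)` — uncertain clips are excluded from
   both numerator and denominator.

## Parameters that matter

| key | default | meaning |
|---|---|---|
| `band_low_hz`, `band_high_hz` | 50, 2450 Hz | respiratory energy band; the upper edge sits 50 Hz under the post-downsampling Nyquist so the design never degenerates |
| `target_rate_hz` | 5000 Hz | analysis rate after downsampling |
| `clip_len_s` | 60 s | clip length: 10–20 breath cycles, longer than a severe apnea |
| `n_mels`, `n_mfcc` | 40, 13 | mel filters and retained cepstra |
| `stft_win_ms`, `stft_hop_ms` | 1000, 500 ms | STFT framing of the mel spectrum |
| `linkage` | average | AHC linkage (single/complete/ward selectable) |
| `lpc_order`, `lpc_win_ms` | 14, 20 ms | formant analysis model order and frame |
| `episode_min_ms`, `event_min_ms` | 300, 200 ms | minimum snore-episode and breath-event durations |
| `mbpi_threshold_s` | 10 s | apnea definition: pause longer than this ⇒ low |
| `ss_elapsed_threshold_min` | 4 min | sustained simple snoring before SpO~2~ is expected to drop |
| `kmeans_seed` | 0 | restart seed for the snore-typing K-means |

## Design choices where the design was open

- **Filter order and phase.** Only the band is prescribed by the method;
  order 4 forward–backward is the conventional least-surprise choice that
  keeps MBPI timing exact.
- **2450 Hz upper edge.** A 2500 Hz edge equals the 5000 Hz Nyquist and
  produces a degenerate design; the edge is pulled in by 50 Hz, which also
  guarantees anti-aliased downsampling.
- **13 cepstra, 0th included.** The coefficient count is unstated in the
  method; 13 is the conventional envelope summary, and the 0th (overall
  log energy) is deliberately kept because loudness is exactly what
  separates snoring / normal / near-silent clips.
- **Average linkage, no feature standardization.** The linkage criterion
  is unstated; average linkage on the raw cepstral means is the
  least-assumption default and is config-exposed.
- **Semantic labels by RMS ordering.** The original assignment was by
  visual inspection of cluster spectra. Loudness ordering automates it
  (snoring clips are the loudest, unusable clips the quietest); a
  `label_map` override restores fully manual assignment. Ties break by
  cluster id, so the assignment is always a bijection.
- **"F1 interval" = episode onset-to-onset time.** The feature is
  described as the spacing between snores (it tracks airflow-reduction
  time), so intervals are measured between successive episode onsets, not
  between LPC frames. Population (not sample) SDs keep small-n features
  deterministic.
- **Pre-emphasis 0.5 inside the F1 tracker.** With strongly harmonic
  excitation, raw 20 ms LPC frames occasionally park a pole on a pitch
  harmonic below the true resonance. A mild 1 − 0.5 z⁻¹ pre-emphasis
  removes that bias across the 200–2400 Hz range; the heavier speech
  default (0.97) overcorrects and was measurably worse.
- **Envelope event detector.** Shared by snore-episode and breath-event
  detection: 100 ms RMS envelope, threshold `median + 0.5·(p95 − median)`
  (gain-invariant), minimum durations 300 ms / 200 ms. Two guards: a flat
  but nonzero envelope (continuous tone) is one full-length event, and a
  low-contrast envelope (p95 < 2 × median, i.e. steady texture with no
  distinct bursts) yields no events rather than spurious ones. The
  detector therefore needs events to occupy roughly ≥ 5 % of the clip to
  register — a single isolated burst in an otherwise noisy minute can be
  missed.
- **MBPI boundary gaps count.** A pause that spans a clip edge still
  suppresses breathing, so the gaps before the first and after the last
  event are included; an event-free clip has MBPI equal to the clip
  length. MBPI exactly 10 s maps to medium; elapsed exactly 4 min maps to
  medium; LoO~2~ exactly 95 or 90 maps to medium (closed boundaries).
- **K-means restarts instead of k-means++.** `stats::kmeans` with 10
  random restarts under a fixed seed; on z-scored 2-D features the
  initialization scheme is immaterial, and with exactly two snoring clips
  (k = n) the split is decided directly by the feature ordering.

## What the synthetic generator states — and what it does not

The generator is the package's testbed world:

- *Normal breathing*: broadband 50–2000 Hz noise bursts shaped by
  inspiration/expiration envelopes, period uniform in 3–6 s (so 10–20
  cycles per minute), over a 0.002 RMS sensor floor.
- *Simple snoring*: harmonic bursts (100 Hz impulse-train source through
  an 80 Hz-bandwidth resonator at F1 = 400 Hz, per-episode jitter
  σ = 15 Hz) every 4 s with σ = 0.2 s onset jitter.
- *Apneic snoring*: the same source–filter model at F1 = 600 Hz with
  σ = 100 Hz jitter, irregular spacing (nominal σ = 3 s, truncated to
  1.5–5 s), and exactly one inserted silent pause. The truncation plus a
  final burst anchored near the clip end make the inserted pause the
  maximum gap *by construction* — without it a 5 s pause would be
  indistinguishable from the natural spacing tail, and pause recovery
  would be ill-posed.
- *Uncertain*: broadband noise at under 1 % of the normal-minute RMS.
- *SpO~2~*: baseline 97 %, with dips to 92 % (apneic pause ≤ 10 s), 88 %
  (pause > 10 s) or 93 % (≥ 4th consecutive simple-snoring minute), each a
  trapezoid contained in its own minute with 15 s linear transitions. The
  dip values sit strictly inside the level bands, so ground truth is
  unambiguous and a perfect predictor scores accuracy 1.

A green end-to-end test therefore establishes that the pipeline recovers
the stated acoustic classes and rule outcomes under controlled conditions.
It does **not** establish clinical performance: real tracheal audio has
ambient noise, body movement, position changes, cardiac sounds, mixed and
transitional minutes, and desaturation lags that the generator does not
model, and the published accuracies on clinical recordings (83–88 %) are
not reproducible from synthetic data.

## Numerical notes

- Mel power is floored at 1e-10 before the log, so silent frames stay
  finite; the DCT of such a frame is a constant 0th coefficient and zeros
  elsewhere.
- The bandpass is applied as a cascade of biquads (second-order sections):
  the 8th-order transfer function form is numerically ill-conditioned for
  a 50 Hz edge at 48 kHz.
- Downsampling is linear interpolation; content is already limited to
  2450 Hz by the bandpass at ≥ 10× oversampling, where interpolation error
  is far below the 16-bit container floor.
- A zero-energy LPC frame is flagged unvoiced rather than raising an
  error; episodes whose frames yield no qualifying pole get `NA` F1 and
  are excluded from the episode-F1 statistics.
- Clips with fewer than three snore episodes get the feature (0, 0) and a
  `low_evidence` flag instead of unstable statistics.

## Known limitations

- Minutes containing a class transition are forced into a single label.
- The RMS-based semantic assignment assumes snoring is louder than normal
  breathing on average; gain riding or compression in the recorder would
  break that ordering (use `label_map`).
- No desaturation-lag correction is applied beyond the 4-minute
  simple-snoring rule.
- Accuracy counts exclude uncertain clips entirely, mirroring the
  evaluation formula; a pipeline that labels everything uncertain is
  undefined, not perfect, and is reported as such with a warning.
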