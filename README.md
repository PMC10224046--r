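# scgbeat

ECG-free heartbeat detection in seismocardiography (SCG) signals by
template matching.

## The problem

Seismocardiography records the small chest-wall accelerations produced by
the beating heart with an accelerometer placed on the sternum. Each
heartbeat appears in the dorso-ventral (z-axis) channel as a short
oscillatory *systolic complex*, often followed by a weaker *diastolic
complex*. Locating heartbeats in SCG is usually done with the help of a
simultaneous ECG; `scgbeat` implements a standalone (ECG-free) detector
for users — physiologists, biomedical engineers, wearable-device
developers — who need beat-by-beat heart rate and inter-beat intervals
(IBIs) from the accelerometer alone, plus the full scoring machinery to
validate such a detector against a reference ECG.

## The method

A single heartbeat snippet `t` (the **template**) is selected from the
band-passed SCG signal `s` — either spanning both complexes (*case 1*) or
only the systolic complex (*case 2*, for records without a clear
diastolic complex). The normalized cross-correlation at lag `k`,

```
            Σₙ (s[n] − μ_s(k)) (t[n−k] − μ_t)
NCC(k) = ─────────────────────────────────────────────
         √( Σₙ (s[n] − μ_s(k))² · Σₙ (t[n] − μ_t)² )
```

is the zero-mean cosine similarity between the template and the signal
window at that lag, bounded in [−1, 1]. Its local maxima with topographic
prominence ≥ 0.5 (0.3–0.7 admissible for case 2) and pairwise distance
≥ 500 ms mark heartbeats.

Supporting stages mirror standard practice: both channels are oversampled
to 1 kHz by linear interpolation; the SCG is band-passed 7–30 Hz and the
ECG 0.5–40 Hz (4th-order zero-phase Butterworth) with a 50 Hz powerline
notch; reference R-peaks come from a Pan–Tompkins detector. Detections
are scored per cardiac cycle `[Rᵢ, Rᵢ₊₁)` as TP / FP (extra peak in a
cycle) / FN (empty cycle) / DE (sole peak at an implausible latency,
counted against both metrics):

```
Sensitivity = 100 · TP / (TP + FN + DE)
PPV         = 100 · TP / (TP + FP + DE)
```

Matched IBIs (ECG: consecutive R-peaks; SCG: consecutive NCC peaks) are
compared by least-squares regression, Pearson correlation, and
Bland–Altman analysis (bias ± 1.96·SD limits of agreement).

A synthetic two-channel generator (`generate_record()`) with known beat
times — quasi-periodic RR series with respiratory sinus arrhythmia,
damped-oscillation SCG complexes, respiratory amplitude modulation,
configurable SNR — makes every stage testable without any recording.

## Worked example

```r
library(scgbeat)

synth <- generate_record(synth_config(duration_s = 60, mean_hr_bpm = 70,
                                      snr_db = 20, seed = 42))
synth
#> <scg_synth_record: 69 beats, 60 s @ 256 Hz, SNR 20 dB, seed 42>

res <- run_pipeline(list(record = synth$record, out_dir = tempdir()))
res$template
#> <scg_template case 1: 737 samples (737 ms) @ 1000 Hz, systolic peak at +44 ms>
res$report
#> <scg_report: 68 cycles | TP 68  FP 0  FN 0  DE 0 | Se 100.0%  PPV 100.0%>

rep   <- classify_detections(synth$truth_r, res$beats)
pairs <- extract_ibi_pairs(rep)
bland_altman(pairs)
#> <scg_agreement: n=67 | slope 0.999, intercept 0.85 ms, R^2 0.9999 | bias +0.00 ms (p=0.966), LoA +/- 0.8 ms>
```

Reading: all 68 scored cardiac cycles of a 60 s record at 20 dB SNR were
detected from the SCG alone (sensitivity and PPV 100%); the 67 chained
inter-beat intervals agree with the ECG-derived truth with sub-millisecond
bias and ±0.8 ms limits of agreement — the detector's timing error is far
below physiological RR variability.

On the published 77-patient valvular-heart-disease cohort this method
reports sensitivity/PPV of 96%/97% with full (case 1) templates and
79%/82% with systolic-only (case 2) templates; those count totals
reproduce exactly through `detection_report()` + `sensitivity()` /
`ppv()` (see `tests/testthat/test-acceptance.R`).

## Command line

```sh
scgbeat simulate --config synth.json --out rec.csv --truth truth.csv
scgbeat rpeaks rec.csv --out rpeaks.csv
scgbeat detect rec.csv --template 10.2,10.95 --case 1 --out beats.csv --out-dir out/
scgbeat evaluate --ref rpeaks.csv --det beats.csv --out report.json
scgbeat agree --pairs pairs.csv --out agreement.json
scgbeat run rec.csv --out-dir out/        # full pipeline
```

(wrapper script: `system.file("exec", "scgbeat", package = "scgbeat")`)

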