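---
title: "Methods: template-matching heartbeat detection in SCG signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-matching heartbeat detection in SCG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgbeat)
```

## The model

Seismocardiography (SCG) measures precordial acceleration; in the
dorso-ventral axis each heartbeat produces a short oscillatory systolic
complex and, in many subjects, a weaker diastolic complex. The detector
implemented here makes a single structural assumption: *within one
recording, heartbeats share a repeating morphology*. It therefore selects
one heartbeat snippet as a template and computes the normalized
cross-correlation (NCC) of that template against every fully overlapping
signal window,

$$\mathrm{NCC}(k) \;=\;
\frac{\sum_n (s_n - \mu_s(k))\,(t_{n-k} - \mu_t)}
{\sqrt{\sum_n (s_n - \mu_s(k))^2 \;\sum_n (t_n - \mu_t)^2}},$$

where $\mu_t$ is the template mean and $\mu_s(k)$ the signal mean over
the shifted template support. Subtracting the window mean and dividing by
both norms makes the statistic invariant to local offset and positive
scaling — exactly the invariances needed against respiratory amplitude
modulation and slow baseline drift. NCC local maxima passing a
topographic-prominence threshold and a minimum mutual distance are
heartbeats. No fiducial-point model of the SCG waveform is assumed, which
is what lets the method absorb inter-subject morphology variability.

Two template classes are distinguished. A *case 1* template spans both
complexes (recommended: start 2–3 oscillations before the systolic peak,
end just after the last diastolic oscillation); it encodes the
within-beat systole–diastole pattern and is the more specific matcher. A
*case 2* template covers only the systolic complex (about 1–2
oscillations either side of the systolic peak) and is the fallback when
diastolic complexes are absent or unstable; single complexes are less
peculiar, so case 2 is measurably more error-prone.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| SCG band | 7–30 | Hz | isolates the oscillatory heartbeat component |
| ECG band | 0.5–40 | Hz | QRS-preserving diagnostic band |
| filter order | 4 | — | design order; applied forward–backward |
| powerline notch | 50, Q = 30 | Hz | narrowband interference removal |
| target rate | 1000 | Hz | oversampling grid for ms-level peak timing |
| NCC prominence | 0.5 | — | operating point; 0.3–0.7 legitimate for case 2 |
| min peak distance | 0.5 | s | floor below any plausible RR interval |
| scoring tolerance | 0.150 | s | DE discrimination window (see below) |

The scoring tolerance deserves emphasis: the published scheme labels a
cycle's sole, badly-timed peak a *detection error* (DE) without
quantifying "badly timed". `classify_detections()` estimates the
expected systolic latency as the median first-peak offset across cycles
and accepts the candidate within ±150 ms of it (half the minimum-peak-
distance floor). This is the scoring scheme's main reproducibility knob
and is configurable; counts, not waveforms, depend on it.

## Scoring and agreement

Cycles are half-open intervals $[R_i, R_{i+1})$, so every detection
belongs to exactly one cycle; detections before the first or after the
last R-peak are ignored, and cycles overlapping a motion-artifact
interval are excluded with their peaks before counting. Per cycle: the
peak nearest the expected latency is TP (within tolerance) or DE
(outside); remaining peaks are FP; an empty cycle is FN. A DE counts
against both sensitivity ($100\,\mathrm{TP}/(\mathrm{TP+FN+DE})$) and PPV
($100\,\mathrm{TP}/(\mathrm{TP+FP+DE})$) because it simultaneously asserts
a false beat and misses the true one. Two conservation identities are
enforced by the report type and by property tests: TP+FN+DE equals the
scored cycle count, and TP+FP+DE equals the number of detections falling
in scored cycles.

Inter-beat intervals are chained only across consecutive TP cycles
(intervals touching FN/DE/excluded cycles are dropped), then compared by
ordinary least squares, squared Pearson correlation, and Bland–Altman
analysis with differences oriented SCG − ECG and limits of agreement at
bias ± 1.96·SD (sample SD, $n-1$). The bias test is a two-sided
one-sample t-test — the convention of the standard Bland–Altman tooling;
the multiplier 1.96 is likewise fixed by convention. Pooled analysis
across records is used; per-record grouping can be performed by calling
the functions per record.

## The synthetic world

`generate_record()` emulates exactly the statistical structure the
detector exploits:

* RR series $RR_i = 60000/\mathrm{hr} + \mathrm{rsa}\cdot\sin(2\pi
  f_\mathrm{resp} t_i) + \varepsilon_i$, $\varepsilon_i \sim
  N(0, \sigma_{RR})$ — quasi-periodicity with respiratory sinus
  arrhythmia;
* ECG as beat-locked Gaussians (P, Q, R, S, T) with a narrow dominant R;
* SCG beats as a damped sinusoid $e^{-u/\tau}\sin(2\pi f_\mathrm{sys} u)$
  starting 30 ms after R ($f_\mathrm{sys}=18$ Hz, $\tau=40$ ms), plus an
  optional diastolic copy at 380 ms scaled by `dia_amp_ratio`
  (0 produces systolic-only records that force a case 2 template);
* respiratory amplitude modulation of both channels and additive white
  (optionally 7–30 Hz band-limited) Gaussian noise at a set SNR.

Defaults (256 Hz, 70 bpm, 25 ms jitter, 30 ms RSA at 0.25 Hz, ratio 0.5,
20% AM, 20 dB SNR) were chosen once as a plausible resting adult at the
source database's acquisition rate and are not tuned per test. Records
start 0.1 s before the first beat and extend 0.9 cardiac cycles past the
last one so that the final beat's waveform — and a full-beat template
aligned to it — lies wholly inside the record; since the NCC is computed
over fully overlapping windows only, a shorter tail would make the final
beat undetectable in principle and let cross-matches in the last cycle
escape the minimum-distance competition.

What a green synthetic test does **not** establish: robustness to real
morphological instability (valvular disease alters complexes in ways two
damped sinusoids cannot express), to motion artifacts (the mask machinery
is exercised, artifact *detection* is out of scope), to electrode or
sensor artifacts, or to pathological rhythms. The synthetic results bound
the method's numerical behaviour, not its clinical performance.

## Numerical choices

* **Filters.** No R signal-processing package is assumed: Butterworth
  designs are derived from the analog prototype, frequency-transformed,
  bilinear-mapped with pre-warping and emitted as second-order sections
  (validated against an independent analytic magnitude formula in the
  tests). "4th order zero-lag" is read as a 4th-order *design* applied
  forward–backward, i.e. the effective magnitude is the squared design
  response — the common reading of the cited tooling.
* **Edge handling.** Forward–backward filtering uses odd-reflection
  padding with steady-state per-section initial conditions. A fixed
  padding of 3× the filter length proved insufficient: the 7–30 Hz band
  at 1 kHz has a slowest-pole transient needing ~2 s to decay below
  1e-9, which broke the time-reversal symmetry property. The padding
  length is therefore derived from the slowest pole radius (decay below
  1e-12), clipped to the signal length.
* **Degenerate NCC windows.** A zero-variance window would divide by
  zero; its NCC is defined as 0 (no similarity evidence), never NaN.
* **Peak semantics.** Local maxima collapse plateaus to their middle
  sample; prominence is standard topographic prominence (height above
  the higher of the two minima toward higher ground or the edges). Note
  that on a series bounded in [−1, 1] prominence is bounded by 2, not 1.
  Minimum distance is enforced greedily by descending peak value with
  earlier-lag tie-breaking — deterministic and matching common tooling.
* **Pan–Tompkins.** Published constants are adopted wholesale (5–15 Hz
  band, five-point derivative, squaring, 150 ms integration, dual
  adaptive thresholds with 0.125/0.875 updates, search-back at 1.66×RR,
  200 ms refractory, T-wave rejection under 360 ms, 2 s learning phase).
  Because this implementation is offline and zero-phase, the derivative
  and integration window are *centered*, so the integrator fiducial falls
  on the QRS and the final refinement to the ECG maximum needs only a
  ±40 ms window.
* **Timestamps.** Sample $i$ (0-based) is at $i/f_s$ seconds everywhere.
  Detected beat times carry the template's systolic-peak offset so they
  align with beats visually; IBIs are invariant to that constant shift.

## Open design points, resolved

* *Cycle assignment*: the source scheme does not state whether peaks are
  assigned by R-to-R window or nearest R; half-open R-to-R cycles were
  chosen so each peak belongs to exactly one cycle, and the conservation
  identities then hold by construction.
* *Sensitivity denominator*: TP+FN+DE and the reference-beat count
  coincide under the conservation invariant, so the ambiguity between
  the two published phrasings is immaterial here — the invariant is
  enforced.
* *Automatic template choice*: the source method selects templates
  manually. `suggest_template()` is a documented extension: candidate
  beats are scored by the median height of the NCC peaks they detect,
  excluding each candidate's self-match at its own source lag (a
  self-match is always 1 and would mask a record with no repeating
  morphology); medians below 0.5 set a low-confidence flag.
* *Notch harmonics*: after a 40 Hz low-pass edge the 100 Hz harmonic is
  already suppressed, so the default notches only the fundamental;
  harmonics are configurable and skipped above Nyquist with a message.

## Known limitations

Manual template bounds remain the primary mode, mirroring the method's
operator dependence; `suggest_template()` needs ≥ 10 reference beats and
a working R-peak detector, so it cannot bootstrap a truly ECG-free cold
start (it exists to automate validation studies). WFDB support covers the
common single-file format-16 layout only. Downsampling, artifact
*detection*, multi-axis fusion and adaptive/multi-template tracking are
out of scope. Sensitivity of the published scheme to the 150 ms DE
tolerance is real: report counts should always be read together with the
tolerance that produced them.
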