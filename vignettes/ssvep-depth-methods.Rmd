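---
title: "Methods: simulating and decoding SSVEPs across virtual depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding SSVEPs across virtual depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepDepth)
```

## The problem

A steady-state visual evoked potential (SSVEP) is the periodic occipital
EEG response that phase-locks to a flickering stimulus at its fundamental
frequency $F_0$ and harmonics. SSVEP-driven brain-computer interfaces in
head-mounted displays face a specific confound: the
vergence-accommodation conflict (VAC). The eyes accommodate to the fixed
display plane while they converge on the virtual depth of the stimulus,
and the mismatch grows with the discrepancy between the two. Mixed-reality
(MR) rendering, which overlays stimuli on the real scene, preserves more
natural depth cues than fully virtual (VR) rendering, so SSVEP quality is
expected to degrade with stimulus depth and to be poorer in VR than MR.

This package provides the full computational chain needed to study that
question — stimulus design, trial scheduling, a calibrated synthetic EEG
generator, preprocessing, three decoders, and evaluation statistics — so
that every stage is testable without access to human recordings.

## Stimulus design

**Geometry.** All stimuli subtend a constant visual angle
$\theta = 2.07^\circ$, which equalises the retinal image size across
depths. The rendered disc diameter is

$$d = 2 D \tan(\theta / 2),$$

so at depths $D = 0.4, 1.0, 1.8$ m the discs are 1.45, 3.61 and 6.50 cm
wide. `visualAngleToDiameter()` implements this literally and is linear in
depth at fixed angle.

**Frame-locked flicker.** On a display refreshing at 90 Hz a flicker
period must span a whole number of frames, so admissible frequencies are
$f = 90 / n$ for integer $n$: 18 Hz ($n = 5$), 11.25 Hz ($n = 8$) and
7.5 Hz ($n = 12$) are the three used throughout. The luminance follows a
square wave $S(t) = I_{\max}$ for $(t \bmod T) < \alpha T$ and $0$
otherwise, with period $T = 1/f$ and duty cycle $\alpha = 0.5$; at
$n = 8$ this is four frames on, four frames off. `squareWave()` refuses
duty cycles that do not correspond to a whole number of on-frames —
fractional frames cannot be rendered and would distort the waveform — and
its sampled output has mean exactly $\alpha$ over whole cycles.

**Trial schedule.** A session presents each (depth, frequency) cell ten
times: a 1-s fixation cross, a 5-s flicker, a 3-s rest, blocked by depth
and then by frequency in sub-blocks of ten consecutive flashes
(`ordering = "random"` interleaves instead). Three depths × three
frequencies × ten repetitions gives 90 trials in 810 s (13.5 min) per
environment. Rounds are carried as a column but pooled in analysis.

## The synthetic EEG generator

`simulateSession()` produces continuous 9-channel recordings (Oz, O1, O2,
PO3–PO6, POz, Pz at 1000 Hz) whose statistical structure carries exactly
the features the analysis chain assumes:

* **Background.** A $1/f$ ("pink") process above 0.1 Hz with 10 µV RMS,
  split into a spatially shared component (90% of the pink power, added
  coherently to every channel) and an independent per-channel residual,
  plus 2 µV independent white sensor noise. Scalp potentials over a
  compact posterior montage are strongly correlated by volume conduction;
  the shared fraction is the single parameter that controls how much of
  the background a spatial decoder can cancel, and 0.9 was chosen so that
  the default sessions reproduce a realistic *joint* operating point:
  narrow-band SNR near +1 dB *and* broadband-CCA accuracy near 60% over
  5-s windows. With fully independent channel noise the same narrow-band
  SNR yields near-chance decoding, which no real scalp recording shows.
* **Alpha.** One shared narrow-band oscillator (Gaussian spectral bump,
  SD 1 Hz) centred at 10 Hz with 4 µV RMS — deliberately adjacent to the
  11.25 Hz stimulus to stress the decoders. It is a single coherent
  source, as posterior alpha is; making it independent per channel would
  hand a multichannel decoder nine spurious narrow-band dimensions to
  overfit.
* **Evoked component.** During each stimulus window, starting 140 ms
  after flicker onset, every channel receives
  $a\,g_c [\sin(2\pi F_0 t + \phi_1) + r \sin(4\pi F_0 t + \phi_2)]$ with
  harmonic ratio $r = 0.5$ and an occipitally weighted topography $g$
  (Oz/POz 1.0, O1/O2 0.9, PO3–PO6 0.7, Pz 0.5). Phases are
  stimulus-locked: each class draws base phases once per session and
  individual trials jitter around them with SD 0.2 rad. Phase locking is
  not optional — it is the physical premise of task-related component
  analysis, whose objective (inter-trial covariance) is identically zero
  under trial-independent uniform phases.
* **Condition map.** The evoked amplitude is calibrated per condition so
  the expected narrow-band SNR (measured by `snrDb()` after the standard
  preprocessing) matches a target table: MR = 1.8, 1.4, 1.0 dB at 0.4,
  1.0, 1.8 m and VR = MR − 0.85 dB. Depth and environment influence the
  simulation *only* through these targets.

**Calibration.** `calibrateAmplitude()` estimates the preprocessed noise
spectrum from 384 noise-only Monte-Carlo trials under a fixed calibration
seed (memoised, so the cost is paid once per noise model), keeps the
complex spectral amplitudes at $F_0$ and $2F_0$ so the signal–noise cross
term is modelled rather than ignored, applies the deterministic filter
gains at both frequencies (the 36 Hz harmonic of the 18 Hz class loses
about half its power at the 40 Hz band edge) and the latency duty factor,
and solves for the amplitude by bisection. Closed-loop checks in the test
suite recover a +3 dB target within the ±0.8 dB Monte-Carlo band, and
doubling the amplitude adds 6 dB on the signal-dominated asymptote.

**What the generator does not model.** Eye-blink and movement artifacts
(the rejection stage is exercised with synthetic amplitude bursts
instead), non-stationarity and fatigue drift within a session,
inter-subject variability, electrode impedance drift, and line noise.
Passing the recovery suite therefore shows that the *chain* is correct
under the stated signal model, not that real recordings would give the
same absolute numbers.

## Preprocessing

The chain is band-pass → epoch → decimate → reject, in that order:

1. **Band-pass 0.1–40 Hz**, order-4 Butterworth, zero phase. The
   zero-phase response is applied spectrally: the bilinear-warped
   squared magnitude $|H_1(f)|^2$ (i.e. two passes) multiplies the FFT of
   the reflection-padded signal. A recursive forward–backward
   implementation of the same filter is numerically explosive here — the
   0.1 Hz edge at 1 kHz puts poles at $|z| \approx 0.9997$ and the
   order-8 polynomial diverges on session-length records — while the
   spectral application is exact and matches the textbook frequency
   response to within test tolerances.
2. **Epoching** cuts the half-open window $[-1, 5)$ s around each
   stimulus-onset marker: a 1-s pre-stimulus baseline plus the 5-s
   flicker. Sample counts are exact by construction
   (`(end - start) * rate`).
3. **Decimation** to 250 Hz with a zero-phase anti-alias low-pass at 80%
   of the new Nyquist (the signal is already limited to 40 Hz, so
   in-band amplitudes are preserved within 2%).
4. **Rejection** clears the kept-mask of any epoch whose peak-to-peak
   amplitude on any channel exceeds 200 µV — a conventional scalp-EEG
   bound, configurable.

Decoding and SNR estimation use only the $[0, 5)$ s stimulus window; the
baseline second is carried for baseline checks.

## Decoders

**CCA.** For each candidate frequency a reference matrix stacks unit
sine/cosine rows at $h f$, $h = 1, 2$ (two harmonics match the SNR
definition and fit inside the 0.1–40 Hz band). `ccaCorrelation()` solves
the canonical correlation by the whitened cross-covariance SVD with a
relative ridge of $10^{-9}$ on the auto-covariances; the decision is the
frequency with the largest correlation, ties broken toward the lowest
frequency. The estimate is invariant to invertible channel mixing and is
verified against a direct numerical optimiser over the weight vectors.

**Filter-bank CCA.** The epoch is decomposed into four subbands
(0.1–10, 10–20, 20–30, 30–40 Hz; order-4 zero-phase Butterworth), CCA is
run per subband against each full reference, and the features fuse as

$$\tilde\rho_k = \sum_{n=1}^{N} w(n)\, (\rho_k^n)^2, \qquad
  w(n) = n^{-1.25} + 0.25,$$

with $w = (1.25, 0.670, 0.503, 0.427)$ for $N = 4$ — strictly positive
and strictly decreasing. A single full-range band reduces FBCCA to plain
CCA decisions, which the tests assert.

**TRCA.** For $K$ trials of one class, task-related component analysis
maximises inter-trial consistency through the generalized eigenproblem
$S^{(t)} w = \lambda S^{(n)} w$, where $S^{(t)}$ sums the cross-trial
covariances over ordered pairs $j \neq k$ (computed via the
covariance-of-sums identity and symmetrised) and $S^{(n)}$ is the total
covariance summed over trials (the identity matrix is available by
option). The solve is Cholesky-whitened symmetric eigendecomposition;
filters come back sorted by eigenvalue and normalised to
$w^\top S^{(n)} w = 1$, a near-singular $S^{(n)}$ is ridge-regularised
with a warning, and the returned eigenpairs satisfy the defining relation
to $10^{-8}$ relative residual. TRCA is used primarily as an
SNR-enhancing spatial filter: models are trained per class on the
training split of each validation repetition and held-out trials are
projected onto their own class's leading component.
`trcaDecode()` additionally offers template-correlation classification,
which goes beyond the filter's SNR-enhancement role and is flagged as
such in its documentation.

## Evaluation

**Narrow-band SNR.** For a trial with target $F_0$,

$$\mathrm{SNR(dB)} = 10 \log_{10}
  \frac{P_{F_0} + P_{2F_0}}{P_{\mathrm{noise}}},$$

with powers from the rectangular-window periodogram of the 5-s stimulus
window, evaluated *at the exact target frequencies* (none of 7.5, 11.25
or 18 Hz sits on the 0.2 Hz DFT grid of a 5-s window). The background is
sampled at offsets $k/T$ ($k = 1 \dots 5$, i.e. out to ±1 Hz, excluding
±0.1 Hz) around each peak; these offsets are the Dirichlet-kernel nulls
of a $T$-long sinusoid at the peak, so the evoked component leaks nothing
into the background estimate. $P_{\mathrm{noise}}$ is the sum of the two
per-neighbourhood background means — one per spectral component, matching
the two-component numerator — which makes noise-only data sit at 0 dB in
expectation (a pooled single mean would impose a +3 dB floor and make
sub-3 dB conditions unrepresentable). Powers are averaged across channels
before the ratio, so the reported identity holds exactly per trial;
per-channel dB values are also returned. After TRCA filtering the SNR is
computed on the first component.

**Validation scheme.** `makeCvSplits()` makes ten seeded repetitions of
random 70/30 partitions stratified by the nine (depth × frequency) cells:
each cell of ten contributes exactly 7 training and 3 test trials, so a
90-trial session always splits 63/27 with disjoint sets. (Repeated
Monte-Carlo splitting at fixed 63/27 counts is used rather than literal
10-fold partitioning, whose fold sizes could not match those counts.)

**Accuracy** is $N_{\mathrm{correct}} / N_{\mathrm{total}} \times 100\%$
per cell and pooled, with mean ± SD across repetitions when decisions
carry a repetition column; empty cells report NA, not zero.

**Wilcoxon signed-rank** (`wilcoxonSignedRank()`) follows the
SPSS-compatible normal approximation: zero differences dropped, tied
absolute differences mid-ranked, tie-corrected variance
$\sigma^2 = n(n+1)(2n+1)/24 - \sum(t^3 - t)/48$, no continuity
correction, $Z = (T_{-} - \mu)/\sigma$ so that second-sample excess
(VR > MR when called as `wilcoxonSignedRank(mr, vr)`) yields a negative
$Z$. Five positive unit differences with one tie-group of four give
$Z = -2.121$, two-sided $p = 0.034$; Bonferroni over ten comparisons sets
the significance level at $\alpha = 0.005$. The approximation's p-values
are order-consistent with an exact sign-flip enumeration for $n \le 10$.

**Linear fits** (`linearFit()`) return least-squares slope/intercept and
Pearson $r$, used to relate decoder features (CCA correlations, fused
FBCCA features) to per-trial SNR.

## Numerical choices and degenerate inputs

* Ties in every argmax decision go to the lowest candidate frequency.
* CCA ridge $10^{-9}$ (relative to the mean diagonal); rank-deficient
  inputs are solved with a warning rather than an error.
* TRCA ridge $10^{-8}$ on a near-singular $S^{(n)}$, also with a warning.
* The calibration uses a fixed seed (20260117) so a given noise model maps
  deterministically to amplitudes; session randomness comes only from the
  session seed, and identical configuration + seed gives bit-identical
  recordings and byte-identical pipeline reports (provenance blocks
  deliberately carry no wall-clock time).
* Zero-duration waveforms, empty marker lists and zero-trial epoch sets
  flow through without error; out-of-bounds epochs name the offending
  trials; a missing condition in the SNR target table is a configuration
  error.

## What the recovery suite shows

The acceptance tests simulate complete sessions and re-measure everything
end to end. At a planted +15 dB all three decoders classify perfectly; at
zero evoked amplitude all three sit inside the 95% binomial band of 1/3.
Over ten seeds per environment at the default condition map, the mean
measured SNR decreases strictly over 0.4 → 1.0 → 1.8 m, MR exceeds VR at
every depth, mean accuracy decreases strictly with depth for both
training-free decoders, and per-class TRCA filtering raises the mean SNR
in every condition (by roughly +1 to +3 dB).

One documented exception: at the weak default operating point
(~0.2–1.8 dB) filter-bank CCA averages about 9 percentage points *below*
broadband CCA, and the corresponding assertion in the acceptance suite
fails by design rather than being weakened. The band partition
concentrates each class's evidence in one or two subbands while the
heavily weighted ($w_1 = 1.25$) pink-noise-dominated 0.1–10 Hz band
contributes band-limited overfitting noise — thirteen free CCA weights
against a few dozen effective degrees of freedom — to every class's fused
feature. The ordering reverses as signal strength grows: FBCCA overtakes
CCA from about +9 dB planted SNR (92% vs 86% at +9 dB, 100% vs 97% at
+12 dB), where its dedicated harmonic bands pay off. So the subband
fusion's advantage is a strong-signal phenomenon under this noise model,
not a uniform one.

## Problem sizes

The shipped tests run full 90-trial sessions (9 channels, 1000 Hz
acquisition, 250 Hz working rate): ten seeds × two environments for the
ordering checks, three stratified 70/30 repetitions per session for TRCA,
and 384 memoised calibration trials per noise model. The complete suite
finishes in minutes on one CPU.

## Limitations

Absolute accuracies and SNRs depend on the generator's noise model; only
orderings and invariances should be read as predictions about real
recordings. The generator's depth/environment effects enter purely
through the SNR target map, so mechanisms that affect real VAC data in
other ways (binocular instability, fixation loss, artifact rates) are out
of scope. EDF+ interchange is not provided; recordings move through the
package's plain-text container (`writeRecording()`/`readRecording()`).
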