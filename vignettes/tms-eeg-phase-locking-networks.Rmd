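---
title: "Trial-wise phase-locking networks for TMS-EEG: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-wise phase-locking networks for TMS-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

A single suprathreshold TMS pulse over cortex evokes EEG activity that is
phase-locked to the pulse across repeated trials. If the pulse transiently
reorganises functional coupling between regions, that reorganisation should be
visible as a change in *cross-trial* phase locking between channel pairs, and,
at the network level, as a shift of weighted graph parameters between a
prestimulus baseline window and a poststimulus response window: connectivity
strength (CS) and clustering (ClC) up, characteristic path length (PL) down —
the signature of a more integrated, small-world-like regime.

`plvnet` implements that full analysis: epoched multi-trial EEG in, per-band
connectivity matrices and graph metrics out, with paired pre/post statistics;
plus a synthetic cohort generator that provides ground-truth coupling so every
stage can be validated without access to raw recordings.

# The estimators

## Trial-wise PLV

For channels $x, y$, wavelet scale $s$ and time $k$, with $\Delta\varphi_{xy}(k,s,n)$
the instantaneous phase difference on trial $n$:

$$\mathrm{PLV}_{xy}(k,s) = \left| \frac{1}{N_t} \sum_{n=1}^{N_t}
e^{i\,\Delta\varphi_{xy}(k,s,n)} \right|$$

i.e. the modulus of the trial-averaged unit phasor (the mean resultant
length). It is 1 for perfect cross-trial locking and has chance level
$\approx \sqrt{\pi/(4N_t)}$ for uniform phases ($\approx 0.114$ at
$N_t = 60$) — a floor that depends only on the trial count, which is why the
pre/post comparison is paired within subject.

## Corrected imaginary PLV

$$\mathrm{ciPLV}_{xy}(k,s) = \frac{\Im\, \bar z}{\sqrt{1 - (\Re\, \bar z)^2}},
\qquad \bar z = \frac{1}{N_t}\sum_n e^{i\,\Delta\varphi(k,s,n)}$$

Zero-lag (volume-conducted or common-reference) coupling produces purely real
$\bar z$ and is discounted; a quarter-cycle lag gives $|\mathrm{ciPLV}| = 1$.
At the degenerate denominator $|\Re\,\bar z| = 1$ (perfect zero-lag locking)
the value is defined as 0: perfect instantaneous mixing carries no lagged
interaction. Cell-wise $|\mathrm{ciPLV}| \le \mathrm{PLV}$ holds
algebraically, so corrected weights can never exceed their PLV counterparts.

Two conventions were open:

* **Averaging ensemble.** The single-trial (time-averaged) form exists in the
  literature; the pipeline averages across *trials* so that PLV and ciPLV are
  estimated on the same ensemble. Both modes are implemented
  (`ciplv(..., over = "time")`).
* **Stored weight.** The matrix entry is the *absolute value of the
  cell-averaged signed ciPLV*. Averaging magnitudes instead would impose a
  chance floor of $\sqrt{2/(\pi N_t)} \approx 0.10$ at 60 trials, which would
  swamp the zero-lag suppression the estimator exists for; the signed mean has
  chance level $\sim 0.02$ and keeps weights in $[0, 1]$.

# Wavelet decomposition and the cone of influence

The mother wavelet is the L1-normalised analytic Morlet
$\psi(t) = (\pi f_b)^{-1/2} e^{2\pi i f_c t} e^{-t^2/f_b}$ with bandwidth
$f_b = 1$ and centre frequency $f_c = 1$ (a balanced time-frequency
trade-off; both are configurable). A unit cosine at a scale's centre
frequency yields coefficients of modulus $1/2$ (the analytic half).

* **Temporal Heisenberg box.** The Gaussian envelope's standard deviation at
  analysis frequency $f$ is $\sigma_t = \sqrt{f_b/2}/f$. A coefficient is
  COI-valid iff its box $[t - \sigma_t,\, t + \sigma_t]$ lies entirely inside
  the analysis window. At 4 Hz the box spans $\sqrt{2}/4 \approx 354$ ms,
  which does not fit the 300 ms response window — the delta band is therefore
  structurally unmeasurable there and requesting it raises a classed error
  rather than returning silently biased values. At 8 Hz the box is half that,
  and a central valid run remains.
* **Analysis windows.** Prestimulus $-1000..0$ ms; poststimulus $15..315$ ms
  (the span of pulse-locked evoked potentials), exactly 300 ms.
* **Scale grid.** Centre frequencies are log-spaced at 6 voices per octave
  over 4–70 Hz. With $f_b = 1$ the Morlet spectral width is
  $\sigma_f \approx 0.225 f$, so a $2^{1/6}$ grid ($\Delta f/f \approx 12\%$)
  places about two scales per wavelet bandwidth: the spectrum is covered
  without gaps, while denser grids only add strongly correlated near-duplicate
  scales.
* **Band membership** is by scale centre frequency, half-open $[low, high)$
  with the 70 Hz ceiling closed; "global" is 4–70 Hz.

## Numerical realisation

The transform is computed by frequency-domain filtering of the zero-padded
window segment (power-of-two FFT with a $5\sigma_t$ guard band, so circular
wrap-around is below $4\times10^{-6}$ relative amplitude, and far below that
at any COI-valid cell). The production path additionally:

* samples each scale's time axis at a power-of-two stride of one-to-two
  $\sigma_t$ — coefficients closer than $\sigma_t$ are strongly correlated, so
  the subsample estimates the same band mean with negligible information loss;
  the stride is capped so that any nonempty COI run receives at least one
  cell, and `stride = 1` reproduces the full-grid mean exactly (tested to
  $10^{-10}$ against an independent slow path);
* evaluates the decimated inverse transform through spectral alias-folding,
  which is an exact identity, not an approximation.

`band_window_average()` is the spec of record for the reduction: an
unweighted mean over COI-valid cells whose scale lies in the band (equal to
a cell-count-weighted mean of per-scale averages).

# Graph metrics

All graphs are dense, weighted, undirected, zero-diagonal; no thresholding or
binarisation is applied.

* **CS** is the mean off-diagonal weight.
* **ClC** uses geometric-mean triangle intensity
  $t_i = \tfrac12 \sum_{j \ne i}\sum_{h \ne i,j} (w_{ij} w_{ih} w_{jh})^{1/3}$.
  Two normalisations exist: by node *strength*, $2t_i/(s_i(s_i-1))$, a
  transcription that circulates in the applied literature, and by *degree*,
  $2t_i/(k_i(k_i-1))$ with $k_i = N-1$ (the Onnela weighted clustering of the
  Rubinov–Sporns framework). On a uniform complete graph the degree form
  equals the edge weight itself, while the strength form gives
  $(N-2)w/((N-1)w-1)$ — about 1.03 at $w = 0.35$, $N = 62$, and *decreasing*
  in $w$. Reported ClC magnitudes for dense sensor graphs sit just below the
  corresponding CS values and rise with coupling, which is only consistent
  with the degree form; the strength-denominator rendering is evidently a
  transcription of the degree-based formula. `clustering_coefficient()`
  defaults to the strength form (faithful to that transcription, with an
  explicit degenerate-strength guard at $s_i \le 1$), and the analysis
  pipeline uses `denominator = "degree"` to reproduce the published analysis.
  At desk scale the distinction is not cosmetic: with 16-channel graphs near
  the chance floor, the strength form *decreases* when coupling increases
  (its denominator grows faster than its triangle term), whereas the degree
  form moves with the coupling, as the published tables do.
* **PL** maps weights to lengths via $d_{ij} = 1/w_{ij}$ (configurable
  alternative $1 - w$), runs Dijkstra from every source over the dense
  distance matrix, and averages shortest-path distances over ordered pairs.
  A zero weight that disconnects the graph is an error, not a silent `Inf`.

# Statistics

One paired $t$ test per parameter $\times$ band on the per-subject
(pre, post) values, $t$ computed on pre $-$ post so that a poststimulus
increase prints as negative $t$. Tabulated $(t, p)$ pairs in this literature
are mutually consistent only one-tailed ($|t| = 2.76$, $df = 28 \to 0.005$),
so one-tailed
is the default; `compare_windows()` prespecifies the directions (CS$\uparrow$,
ClC$\uparrow$, PL$\downarrow$), which makes the null false-positive rate at
the corrected threshold exactly $\alpha/n$ — the observed-direction reading
$p = P(T \le -|t|)$ offered by `paired_t()` matches that tabulation but is
descriptive, not calibrated. Bonferroni uses the exact thresholds
($0.05/18$ active, $0.05/15$ sham — the sham layout drops alpha); the rounded
0.002/0.003 appear only as annotations. Cohen's $d$ defaults to the
pooled-SD convention; reported effect sizes in this literature are not
mutually consistent with any single convention, so the paired
(difference-SD) form is selectable but no further convention is guessed.

# The synthetic cohort generator

The generator emulates the study conditions after cleaning, at desk scale:
20 subjects, 16 channels, 60 retained trials (75 delivered pulses minus
rejections — the per-subject retained count is unreported, 60 is a plausible
assumption), 2 s epochs at 1000 Hz (analysis happens below 70 Hz, so the
25 kHz acquisition rate is irrelevant to the method), pink (1/f) background
noise band-limited to 1–100 Hz with unit SD, synthesised in the frequency
domain with independent positive- and negative-frequency Gaussian spectra
(so paired real/imaginary outputs are genuinely independent channels).

Coupling structure: each `coupling_spec` is a shared sinusoid at its band's
midpoint whose per-trial initial phase is uniform; the first member channel
receives it exactly, the second with a von Mises phase jitter of
concentration $\kappa_{pre}$ (prestimulus half) or $\kappa_{post}$
(poststimulus half) around the specified lag. Jittering one member (rather
than both) makes the pair's cross-trial phase difference *exactly*
von Mises with the stated concentration — jittering both would give a
different (less concentrated, non-vM) difference law. $\kappa = 0$ is
uniform (chance-level PLV); $\kappa > 10^5$ is treated as perfect locking.
The coupling change applies from pulse onset onward; selecting the 15–315 ms
analysis span is the connectivity stage's job. The default effect cohort
couples three pairs (theta, alpha, beta-2) with $\kappa: 0 \to 5$ and
oscillator amplitude 2 against unit noise; the null cohort is identical with
$\kappa_{post} = 0$. Optional ingredients: an instantaneous mixing matrix
(volume conduction; the confound ciPLV must reject) and a decaying
exponential pulse artifact (the contaminant preprocessing must remove).

What the generator does *not* emulate — and hence what green tests do not
certify about real data: realistic evoked-potential waveforms (N45…N100),
auditory sham responses, between-subject heterogeneity of coupling strength,
non-sinusoidal or cross-frequency structure, channel geometry (mixing is an
arbitrary matrix, not a head model), and real artifact taxonomies (ocular,
muscle, ICA-level structure).

# Preprocessing conventions

The chain reproduces standard single-pulse conditioning: excision of
$-1..10$ ms with a natural cubic spline fitted to 20 ms flanks (local fit,
no ringing from distant data; windows are closed intervals in ms), common
average re-reference, robust bad-channel/bad-trial handling (median/MAD
z-score of peak-to-peak amplitude, threshold 5; flagged channels are replaced
by the mean of the remaining channels — spherical splines are out of scope —
and flagged trials dropped), 800 ms baseline correction, optional polyphase
resampling, and a 4th-order Butterworth 0.5–70 Hz band-pass applied
forward–backward (zero-phase, preserving the phase structure PLV needs; no
filter family is prescribed by the method, Butterworth is standard EEG
practice). The chain closes with a re-reference + baseline re-centering pass:
both operations are idempotent, and the closing pass guarantees exactly
reference-zero, baseline-zero epochs — the 0.5 Hz high-pass has poles close
enough to the unit circle that per-channel rounding otherwise leaves
$\sim 10^{-5}$ residue. ICA-based artifact rejection is a manual expert
procedure and is out of scope.

# Problem sizes used in validation

The automated checks run the generator defaults (16 channels, 60 trials,
1000 Hz): 50 effect cohorts for direction recovery, 20 null cohorts for
false-positive calibration, 2000 uniform-phase replicates for chance-level
calibration, and 100 random 5–8-node graphs against brute-force oracles.
These sizes give binomial/Monte-Carlo resolution comfortably finer than the
margins being tested.

# Known limitations

* **ciPLV across unequal windows.** The stored ciPLV weight, the absolute
  value of a cell-averaged signed quantity, has a chance floor that scales
  like $1/\sqrt{K}$ with $K$ the number of effectively independent COI-valid
  cells. The baseline window (1000 ms) has many more cells than the response
  window (300 ms), so under the *null* the poststimulus ciPLV floor is
  systematically higher than the prestimulus one, and paired pre/post ciPLV
  comparisons are biased toward "increase" — the package's null cohorts make
  this visible (strongly significant ciPLV rows with no true coupling
  change). PLV is immune: its per-cell chance mean does not depend on the
  cell count, and null PLV comparisons are calibrated. Pre/post ciPLV tables
  are still produced, matching the published analysis design, but magnitude
  changes in them should be read against window-matched surrogates rather
  than at face value.
* Sensor-space only; no source model, no leakage correction beyond ciPLV.
* The chance floor ties PLV comparisons to equal trial counts; the pipeline
  does not equalise trial counts across conditions for real data.
* Theta-band estimates in the 300 ms response window rest on few COI-valid
  cells; they are unbiased but noisy (the same caution the method itself
  attaches to theta).
* The BrainVision reader covers multiplexed IEEE float/int16 recordings;
  other orientations and EDF are not implemented.
* Published Cohen's d values cannot be reproduced exactly under any single
  convention; d is reported under the documented pooled-SD default.
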