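---
title: "How preprocessing choices move the N30: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How preprocessing choices move the N30: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Median-nerve somatosensory evoked potentials (SEPs) are quantified by
averaging many stimulus-locked EEG epochs and reading off component
amplitudes — here the frontal N30, measured peak-to-peak between the most
positive sample in 15–25 ms and the most negative sample in 25–35 ms on
channel F3, contralateral to the stimulated wrist. The measured amplitude
is not a property of the brain alone: it depends on the filter class
(linear-phase windowed-sinc FIR vs Butterworth IIR), the passband
(0.5–1000, 3–1000 or 30–1000 Hz), and whether non-brain ICA components are
removed before averaging. `sepkit` implements that full factorial
comparison as a tested pipeline, and ships a synthetic EEG generator with
known ground truth so every stage — and the direction of every effect —
can be verified without any recorded data.

# Filtering

## Kaiser windowed-sinc FIR

The FIR path designs a windowed-sinc kernel: an ideal-lowpass impulse
response truncated to `order + 1` taps and tapered by a Kaiser window. Two
standard design formulas connect the user-facing quantities:

* ripple → window shape: with $A = -20\log_{10}\delta$,
  $\beta = 0.1102(A-8.7)$ for $A > 50$ (the 60 dB specification
  $\delta = 10^{-3}$ gives $\beta = 5.653$);
* transition width → order: $N \approx (A - 7.95) / (2.285\,\Delta\omega)$,
  rounded **up to the next even integer** so that the group delay $N/2$ is a
  whole number of samples. At 2048 Hz this puts 1.5 Hz and 1.0 Hz
  transitions at orders near 4950 and 7426; the realized (measured)
  transition widths of those designs are what the package reports, and they
  land within a few percent of the nominal widths.

Conventions worth stating because they are easy to get silently wrong:

* the magnitude at each cutoff is 0.5 (−6 dB), the windowed-sinc
  convention, not the half-power convention of Butterworth designs;
* highpass kernels are built by spectral inversion of the complementary
  lowpass, which makes the DC gain exactly zero and keeps the taps
  symmetric (linear phase);
* a bandpass is **not** one symmetric kernel but a highpass∘lowpass
  cascade with the stated order per stage, so each band edge keeps its own
  transition semantics — the arrangement recommended for EEG work, where
  the high-pass edge should be sharp and the low-pass edge shallow;
* the measured transition bandwidth is the span between the last frequency
  whose attenuation reaches $A$ and the first frequency whose magnitude is
  within $\delta$ of the passband, evaluated on a dense (≤ 0.01 Hz) grid.

## Butterworth IIR

The IIR path is a 2nd-order Butterworth per band edge (bilinear transform
with pre-warping, via `signal::butter`), half-power at each cutoff,
monotone magnitude. "2nd order" is interpreted *per edge* — a bandpass is
a 2nd-order highpass cascaded with a 2nd-order lowpass — matching the
common convention of single-edge design routines; the alternative reading
(one 4-pole bandpass section) is noted as unresolved upstream.

## Zero-phase application

FIR filtering is one pass with the group delay compensated by an integer
shift — exact for linear-phase kernels. IIR filtering is forward-backward
(filter, reverse, filter, reverse), which squares the magnitude response
and cancels the phase; the signal is extended by mirror reflection
(3 × the section order sum per end, configurable) before the passes. Both
paths verify the contract the same way: a passband sinusoid must come out
with its cross-correlation peak at lag zero and phase shift below half a
degree. All filtering is done in double precision on the continuous
recording, never on epochs.

# The standardization stage

The stage before filtering mirrors a conventional EEG standardization
pipeline but deliberately simplified so it is deterministic and fully
documented: truncation to 30 s around the stimulation block; bad-channel
flagging; line-noise removal; average reference. Two choices deserve
explanation:

* **Bad channels** are flagged when the robust z-score (median/MAD across
  channels) of their robust amplitude (1.4826 × MAD of the samples)
  exceeds 5, or when they are exactly constant. The per-channel statistic
  is the robust spread rather than the standard deviation because sparse
  high-amplitude transients — blinks, above all — dominate a frontal
  channel's SD without making the channel bad; full pipelines use a robust
  amplitude (0.7413 × IQR) for the same reason. Flagged channels are
  excluded from the reference and from artifact checks but kept,
  unmodified, in the data matrix until the ICA preparation drops them.
* **Line noise** is removed by least-squares regression of sine/cosine
  pairs at 50 Hz and two harmonics in consecutive 4 s windows — not by a
  notch filter, which rings badly around sharp spectral lines. The fit is
  subtracted only where the line actually sticks out: its fitted power
  must exceed 30× the power fitted at four probe frequencies ±2.7/±5.4 Hz
  away (pure background by construction). Without this gate, blindly
  subtracting six regressors per window removes a √(p/n) ≈ 3–5 % slice of
  broadband noise even from line-free data; with it, a clean recording
  passes through bit-identical almost everywhere (RMS change ≪ 1 %) while
  genuine line components are attenuated by ≥ 20 dB.

# Epochs, artifact rules, N30

Epochs span −100 to 150 ms around each stimulus, half-open in samples
(512 samples at 2048 Hz), baseline-corrected on the half-open pre-stimulus
window [−100, 0). Epochs whose window does not fit in the recording are
dropped with a warning, never zero-padded.

Five rules mark (never delete) artifact epochs, each evaluated on every
non-bad channel with the stimulus window −2..2 ms masked out of all
computations: absolute voltage > 100 µV; sliding-window (200 ms / 100 ms
step) peak-to-peak > 150 µV; sliding-window (200 ms / 50 ms step)
half-window mean difference > 100 µV (the step detector); sample-to-sample
difference > 50 µV between adjacent unmasked samples; absolute voltage
< 2 µV for more than 125 ms. Window grids anchor at the epoch start and
add one end-flush window so the tail is always covered. The flatline run
length counts consecutive *unmasked* samples, so the stimulus gap breaks a
run. Every optimized rule is tested for exact agreement with a literal
nested-loop oracle on hundreds of adversarial random epochs, and a
mark/unmark override log reproduces the manual verification pass (e.g.
keeping frontal step-like epochs that are eye blinks) while preserving the
automatic flags as provenance.

N30 is the absolute difference between the window extrema. The windows
share the 25 ms boundary (both closed); ties break toward the earlier
latency; peaks are extremal samples, with no interpolation. Manual peak
overrides re-read the amplitude at the supplied latency and are rejected
outside the windows.

# ICA as a contract

The decomposition algorithm is out of scope by design: the pipeline
consumes any components × channels unmixing matrix with per-component
labels (brain / muscle / eye / channel-noise / line-noise). Cleanup is
back-projection of the retained components,
`mixing[, keep] %*% unmixing[keep, ] %*% data`, on the modeled channel
subset only. With the generator's ground-truth (exactly invertible) mixing
this removal is exact, which is what the linear-algebra identity tests
exploit. One subtlety: the pipeline average-references the data *after*
the ground-truth mixing was defined, so the model is re-derived for the
referenced space (mixing ← R·mixing with R the average-reference
projector, unmixing ← its pseudo-inverse); the re-referenced mixing has
rank channels − 1, and removal operates within that subspace.

# The synthetic generator

`synth_config()` defaults encode the emulated acquisition: 62 channels at
2048 Hz, 1000 stimuli at 2.3 Hz, an SEP template with a +1.5 µV lobe at
20 ms and a −2.0 µV lobe at 30 ms (Gaussian lobes, 5 ms FWHM) maximal at
F3, 1/f background noise at 8 µV RMS, eye blinks (15/min, 350 µV,
frontopolar topography), muscle bursts (4/min, 30 µV RMS, 20–300 Hz,
temporal topography with a 0.4 loading on F3), a 5 µV 50 Hz line source, a
biphasic ±1 ms stimulus artifact, and one dead (exactly constant) channel.
The recording is `mixing %*% sources` with a square, invertible mixing
over the good channels, so the returned ICA model is the true inverse with
true labels and the ground truth (per-epoch artifact labels, flat
channels, true template peak-to-peak) is consistent by construction. Each
source type draws from its own RNG stream split from the master seed, so
disabling one artifact type does not perturb the others.

Two generator choices are the reason the paper-level *directions* are
reproducible rather than accidental:

* the SEP lobes are 5 ms-FWHM Gaussians, concentrating template energy
  below ~100 Hz with substantial energy below 30 Hz — so a 30 Hz high-pass
  necessarily removes template energy and the 30–1000 Hz band measures a
  smaller N30 than 0.5–1000 or 3–1000 Hz;
* the muscle source carries, besides random bursts, a small
  **stimulus-locked reflex** (biphasic, +lobe near 18 ms, −lobe near
  32 ms, 2 µV at full loading): stimulation-evoked scalp EMG that overlaps
  the SEP complex. Being phase-locked it survives averaging, and being a
  muscle-labeled source it is removed by ICA cleanup — which is the
  physiological mechanism by which removing non-brain components lowers
  the measured N30. Purely random (non-locked) artifacts average out as
  $n^{-1/2}$ and cannot reproduce that effect at realistic epoch counts.

What the generator does **not** emulate: biophysical head geometry,
realistic electrode covariance, latency jitter of the SEP, imperfect
(estimated) unmixing matrices, or subject-level structure beyond a scalar
log-normal random intercept on the SEP amplitude. Tests passing on this
generator therefore validate the pipeline's mechanics and the qualitative
directions, not clinical effect sizes.

# The statistical layer

Artifact counts are compared between filter classes with a dependent
t-test (df = n − 1 over paired datasets). The N30 amplitudes are modeled
as gamma with a log link:

$$\log \mu_{ij} = x_{ij}^\top\beta + z_i,\qquad
  y_{ij}\sim\Gamma(\text{shape},\,\mu_{ij}),\qquad
  z_i\sim N(0,\sigma^2),$$

with the 12-coefficient coding (reference cell FIR, 0.5–1000 Hz, no ICA;
indicators for IIR, ICA, the 3–1000 and 30–1000 bands, and all
interactions). The marginal likelihood integrates the scalar random
intercept by **adaptive Gauss–Hermite quadrature**: per subject the
integrand's mode is found by Newton iterations (the log-link Hessian is
globally negative, so this is safe), nodes are recentred and rescaled by
the curvature, and 21 nodes are used by default — enough that the
log-likelihood matches brute-force adaptive quadrature (`integrate`) to
below 1e−4 on small instances. $(\beta, \log\sigma, \log\text{shape})$ are
optimized jointly by `nlminb` from a gamma-GLM start; the identity link
(available for AICc link comparison) guards against non-positive means by
constraining the mode search and rejecting invalid parameter points.
Standard errors come from the numerical Hessian at the optimum. As
$\sigma \to 0$ the fit collapses to the independence gamma GLM
(coefficients within 1e−3), and simulation at the study's dimensions
(17 subjects × 2 datasets × 12 cells) recovers each coefficient with
|bias| < 0.02 on the log scale.

Cell means are reported on the µV scale (`exp(x'β)`, delta-method SE,
exponentiated normal CI). Contrast families — filter within band × ICA,
band pairs within filter × ICA, ICA within filter × band — are reported as
amplitude ratios with asymptotic z statistics. Multiplicity is controlled
per family by a single-step max-|z| procedure: the null distribution of
the most extreme statistic is evaluated by seeded Monte-Carlo sampling
(1e5 draws) of a multivariate normal with the contrasts' estimated
correlation, emulating the Tukey-style adjustment of `emmeans`; Holm is
available as a cheap fallback. The family-wise error of this procedure is
verified by simulation to sit at the nominal 5 % (≤ 6 % observed). Degrees
of freedom are asymptotic (z), not Kenward–Roger.

# Problem sizes and numerical choices

The simulation-based tests and analysis scripts run scaled-down instances
chosen once as realistic desk-scale sizes: 16 channels (spread across the
scalp so the average reference behaves like a full montage) and 60–500
stimuli per recording, cohorts of 2–6 subjects × 2 sessions, 10 seeds for
the direction-of-effect suite, and 50 replicates for parameter recovery.
The generator's defaults remain the full emulated acquisition. Other
numerical choices: FIR convolution via FFT with exact integer delay
compensation; reflective padding for the IIR passes; quadrature nodes
configurable; Monte-Carlo seeds are required arguments wherever an
adjustment is stochastic; all thresholds strict inequalities as stated in
the rule definitions.

One synthetic behaviour worth flagging: at the 30–1000 Hz band the two
filter classes measure *different* synthetic N30 amplitudes, because the
2nd-order Butterworth's shallow 30 Hz roll-off and the order-7420 FIR's
razor transition remove different slices of the template's low-frequency
energy. With the wide bands (0.5 and 3 Hz high-pass edges, far below the
template energy) the classes agree closely. This is a real property of
the filters, not a defect — but it means synthetic class-equality
comparisons are only meaningful in the wide bands.

# Known limitations

The ICA contract is exercised with ground-truth mixing only — no
decomposition estimator is shipped, so label-quality and estimation error
effects are out of reach. The band-effect and ICA-effect directions are
properties of the template and reflex design (deliberately so); their
magnitudes are not calibrated to any recorded dataset. EDF input is not
supported; recordings travel in a documented delimited-matrix dialect.
The repeated-measures ANOVA sometimes used as a robustness check for this
design is not implemented.
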