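---
title: "Models and methods behind fnirsVHDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fnirsVHDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsVHDR)
```

# The problem

Event-related fNIRS of the visual cortex measures, through a pair of
near-infrared wavelengths (760 and 850 nm here), the stimulus-locked
changes in oxygenated (OHb), deoxygenated (DHb) and total (THb = OHb +
DHb) hemoglobin over occipital channels. A patterned stimulus evokes an
OHb/THb rise and a DHb dip; a zero-contrast "mock" stimulus evokes
nothing and serves as the within-subject control. The readouts of
interest per subject are the peak amplitude and latency of the
block-averaged response (channel average and best channel), the
hemisphere-average OHb peaks, and the laterality index

$$\mathrm{LI} = \frac{\mathrm{peak}_{left} - \mathrm{peak}_{right}}
                     {\mathrm{peak}_{left} + \mathrm{peak}_{right}},$$

negative under this sign convention when the response is right-dominant.
Group questions — is the response reliable against mock, is its
amplitude reduced in one cohort, is lateralization lost, does LI track a
clinical score — are answered with paired and independent t tests, a
hemisphere-by-group split-plot ANOVA, Spearman correlations, and
Benjamini–Hochberg FDR control.

The package contains both the analysis chain and a forward simulator
with ground truth, so every stage is verifiable without any external
data.

# The generative model

## Acquisition geometry and design

`makeDefaultMontage()` builds a mirror-symmetric two-row occipital grid
of 8 sources and 7 detectors paired into 22 channels, 11 per hemisphere;
one detector sits on the midline but every channel midpoint is
lateralised. Positions are planar arbitrary units; the modified
Beer–Lambert conversion uses the nominal 3 cm source–detector
separation. The published study this design emulates reports only the
optode counts and channel total, not coordinates, so the geometry is the
package's own construction satisfying those counts.

`generateEventSchedule()` produces the event-related design: by default
20 stimulus and 20 mock trials of 5 s on / 10 s off, pseudorandomly
interleaved by a seeded uniform shuffle (no run-length constraint), i.e.
a 10-minute block of 40 trials at a 10.2 Hz sampling rate. Inter-trial
timing is fixed; no jitter is modelled. `simulateSubject()` places the
schedule 10 s into the recording (plus 1 s tail) so that every trial,
including the first and last, supports the full epoch window.

## Evoked response

The impulse response is a double gamma
(`canonicalResponseKernel()`): a main lobe peaking at 6 s minus an
undershoot lobe at 16 s scaled by 1/6, normalised to unit peak on a
fixed 1 ms grid. A single-trial response is this kernel convolved with
the 5 s stimulus boxcar, then tapered to zero with a raised cosine over
the last 2 s of a 12 s support, and renormalised to unit peak. The
compact support is deliberate: with a 15 s trial cycle, a response that
has fully returned to baseline before the next trial's −2..0 s baseline
window makes the configured amplitude exactly recoverable from
baseline-corrected epochs, and matches the within-cycle return to
baseline characteristic of short-stimulus designs. DHb is modelled as
−1/3 of the OHb amplitude, lagged by 1 s; THb is the exact sample-wise
sum. Mock trials evoke exactly zero response.

Subject-level variation: the OHb amplitude is drawn from a normal
distribution (default mean 20 µM, SD 5 µM, resampled if non-positive);
the right-hemisphere gain λ is multiplied by a mean-one log-normal
jitter. `tdSimulationConfig()` (typical development) uses amplitude
20 µM, λ = 1.5 (true LI = −0.2), jitter SD 0.15;
`asdSimulationConfig()` uses amplitude 12 µM (a 40% reduction), λ = 1
(no mean lateralization) and jitter SD 0.3 (high LI variability). These
encode, as generative effect sizes, the qualitative findings the
analysis is designed to detect: reduced amplitude, lost right-dominance,
and more variable lateralization in the ASD group.

## Noise and artifacts

Physiological noise is a sum of seeded-random-phase sinusoids — cardiac
1.1 Hz (1 µM), respiration 0.3 Hz (0.8 µM), Mayer waves 0.1 Hz (1 µM) —
plus a slow random-walk drift (step SD 0.02 µM per sample, generated at
coarse knots and interpolated) and white noise (SD 0.5 µM), independent
per channel; the DHb series receives the same components scaled by 1/3.
These amplitudes were chosen once so that single-trial responses are
clearly sub-threshold while the 20-trial block average is stable — i.e.
the band-pass filter and the averaging step both matter.

Motion artifacts (`injectMotionArtifacts()`) occur at homogeneous
Poisson times (default 1.2/min) and are applied coherently to all
channels, as a head movement would be: transient spikes of 1–3 samples
(±1.0 OD, jittered ±20%) or persistent baseline steps (±0.5 OD). The
injected event list is returned so the detector can be scored against
ground truth.

## Clinical scores

`simulateCohort()` generates a two-group cohort (defaults 13 TD, 12 ASD)
and a clinical table for the ASD group in the reference layout (ID, Age,
ADOS total and comparison scores, AQ total, non-verbal IQ, Vineland
total). AQ is a linear, monotone function of the subject's *true* LI
plus Gaussian noise; all other scores are independent draws in the range
of the reference table. The AQ slope (120 per LI unit) and noise SD (6)
come from a design-time power computation: with 12 subjects and
BH adjustment inside an 8-test correlation family, the smallest p value
must fall below roughly α/8, which requires a sample Spearman ρ of about
0.75; the chosen parameters put the population correlation near 0.95 so
the adjusted test retains >90% power. Weaker choices (e.g. population
ρ ≈ 0.88) lose a quarter of their power to the FDR step — an effect
worth remembering when planning small-cohort correlational analyses.

# Optics: the modified Beer–Lambert law

`mbllForward()` maps concentration changes to optical-density changes,
$\Delta OD(\lambda) = \left[\varepsilon_{OHb}(\lambda)\,\Delta OHb +
\varepsilon_{DHb}(\lambda)\,\Delta DHb\right] \cdot DPF(\lambda) \cdot d$,
with the built-in extinction table (`defaultExtinction()`, cm⁻¹ per
mol/L at 760/850 nm, from the standard whole-blood compilation used in
continuous-wave NIRS), DPF 6 at both wavelengths and d the per-channel
distance. `mbllInverse()` solves the 2×2 system per sample and sets THb
to the exact sum. The round trip is the identity to better than 1e−10
relative error, which the tests assert on random inputs.

# Preprocessing

Order of operations (a common convention in fNIRS processing chains,
adopted here as a design decision): motion detection → motion correction
on ΔOD → zero-phase band-pass → MBLL inversion.

**Detection** (`detectMotion()`): motion is effectively instantaneous on
a 10.2 Hz grid while the hemodynamic response moves only a small
fraction of an OD unit per sample, so the primary criterion is any
sample-to-sample change exceeding `amp_thresh` (default 0.25 OD) on
either wavelength. A secondary criterion flags windows (default 0.5 s)
whose local SD exceeds `std_thresh` (default 6) times the channel's
median-absolute-deviation SD; it is skipped on near-constant channels
where the MAD is uninformative. Flags are dilated by two samples and
merged; each interval is classified by the *net* supra-threshold jump
across it — spikes cancel, steps do not — with threshold
`amp_thresh / 2`.

**Correction** (`correctMotion()`): one whole-series regression per
channel, fitted on clean samples only, with an intercept, a
discrete-cosine drift basis (below ~0.01 Hz), sine/cosine pairs at the
nominal physiological frequencies (1.1, 0.3, 0.1 Hz), the canonical
stimulus-response regressors built from the recording's schedule (trial
shape and its 1 s-lagged copy, so the evoked signal cannot bias the
step estimates), and one step indicator per detected shift. Fitted step
heights are subtracted; masked samples are replaced by the model's
prediction. The estimator is linear in the data, which makes the
correction exactly idempotent under a fixed mask, and on noise-free data
the design spans the true signal, so a single known step is removed
essentially exactly. Local-window alternatives were rejected: the lagged
response regressors are nearly collinear inside a short window and the
step estimate inherits that instability.

**Band-pass** (`bandpass()`): zero-phase (forward–backward) Butterworth
filtering — order-2 high-pass at 0.01 Hz cascaded with order-4 low-pass
at 0.5 Hz — after demeaning and odd-reflection padding of about eight
filter time constants to suppress startup transients. Zero-phase
filtering is chosen so peak latencies are unbiased. Pass-band gain at
the block-design fundamental (~0.07 Hz) is within 5% of unity; cardiac
noise at 1.1 Hz is attenuated by more than 99%.

Channels that are exactly constant on both wavelengths are marked
unusable (`rowData()$usable`), logged, and excluded from all downstream
averages.

# Response metrics

Epochs span −2..+15 s around each onset with a −2..0 s baseline whose
mean is subtracted per trial and channel (the stimulus is 5 s and the
rest 10 s, so +15 s covers the full cycle; the windows are package
choices, configurable). Block averages are trial means with n−1 SEMs.
Peaks are searched in 0..15 s: maximum for OHb/THb, minimum for DHb
(whose amplitude is reported signed), ties broken by the earliest time.
The channel-average readout extracts the peak of the across-channel mean
trace; the best channel is the one maximising the OHb peak for the
condition (ties to the alphabetically lowest channel id), with all three
chromophores reported from that channel. Hemisphere peaks are read
literally as the *average of per-channel maxima* within each hemisphere
(not the maximum of the averaged trace); midline channels are excluded.
`lateralityIndex()` evaluates the LI formula exactly and treats a zero
denominator as an error rather than returning NaN; `subjectResponse()`
records NA for a condition with no measurable response (a noiseless mock
epoch set). Subjects contribute one value per metric and condition.

# Group statistics

`runFullStats()` executes the statistical plan on the tidy metric table:

1. *reliability*: per group and readout, paired t of stimulus vs mock
   amplitudes per chromophore;
2. *amplitude* and 3. *latency*: TD vs ASD comparisons per chromophore
   and readout, Welch's t by default (the default group sizes are
   unequal; Student's form is available by flag);
4. *lateralization*: the hemisphere × group split-plot ANOVA on the
   hemisphere OHb peaks plus a group t test on LI;
5. *correlations*: Spearman of the ASD group's LI and channel-average
   OHb amplitude against AQ, Vineland, ADOS total and non-verbal IQ,
   with pairwise deletion of missing scores ("n.a." cells) and per-test
   n reported.

BH-FDR adjustment is applied within each of these five families; the
family structure mirrors the results subsections the plan answers and is
itself a design decision. All tests are two-sided.

The mixed ANOVA is computed from the classical split-plot
sums-of-squares decomposition (documented formula by formula in
`?mixedAnova`) rather than through a model-fitting wrapper, so a
hand-computed small-sample oracle can check it exactly; the test suite
also cross-checks it against `aov()` with an `Error(subject)` stratum.
An effect with exactly zero sum of squares reports F = 0 even when the
error stratum is also degenerate. BH adjustment and the Spearman and t
statistics delegate to `p.adjust()`, `cor.test()` and `t.test()`; the
worked examples in the tests pin their values.

# Numerical and interface choices

- Concentrations are mol/L throughout; OD is dimensionless; time is
  seconds from recording start; channels are named `S<i>_D<j>`.
- THb − (OHb + DHb) is validated to 1e−12 absolute; MBLL round-trip to
  1e−10 relative.
- Recordings interchange as a long-format CSV dialect (`time_s`,
  `channel_id`, `wavelength_nm_or_chromophore`, `value`) with companion
  CSVs for metadata, montage geometry and schedule, so a written
  recording reads back equal; clinical tables round-trip missing cells
  as "n.a.". HDF5-based interchange is outside the current dependency
  footprint and therefore not provided.
- The pipeline (`runPipeline()`) is a pure function of (config, seed):
  subject seeds derive from the master seed, and re-running a config
  yields byte-identical CSVs. Configurations serialise to YAML.
- A thin command-line front end (`inst/scripts/vhdr.R`) exposes
  simulate / preprocess / analyze / stats / run over these functions.

# What the checks do and do not show

The verification suite runs at these problem sizes, chosen to balance
Monte-Carlo resolution against a laptop-scale run time: 100 simulated
subjects for LI recovery (bias and RMSE), 100 simulated cohorts for the
power of the group analyses, 1000 metric-level replicates for null
calibration of every test (the tests operate on subject-level metrics,
so the null draws are generated at that level), and 200 seeded
recordings for motion-artifact sensitivity and correction error
(measured on the band-passed signal, the form in which data enter the
analysis).

The simulator reproduces the statistical structure the analysis assumes
— stimulus-locked responses with between-subject variation, stationary
sinusoidal physiological noise, random-walk drift, coherent spike/step
artifacts — but not everything about real recordings: optode-coupling
differences between channels, non-stationary or broadband (1/f)
physiology, gaze-dependent response fluctuations, and motion that decays
gradually rather than instantaneously are all absent. In particular the
corrector's harmonic regressors sit at the simulator's exact noise
frequencies; on real data those bands are broader and the in-gap fill
would be correspondingly less accurate. Passing the suite therefore
demonstrates correctness of the implementation under its stated model,
not performance guarantees on arbitrary clinical data.

# Known limitations

- No wavelet-based artifact correction, short-separation regression, or
  scalp-coupling channel pruning; the artifact model is spike + step.
- No GLM-based HRF estimation or time-frequency analysis; the readouts
  are peak-based, as in the study design the package follows.
- Latency is measured from stimulus onset on the epoch grid; its
  resolution is one sample (~98 ms).
- The split-plot ANOVA handles unbalanced *groups* but requires both
  hemisphere measurements per subject (others are dropped with a
  warning).
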