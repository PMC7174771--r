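---
title: "Methods: decoding binary answers from fNIRS hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding binary answers from fNIRS hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsbci)
```

## The paradigm and what the package computes

`fnirsbci` analyzes a binary ("yes"/"no") communication paradigm for
functional near-infrared spectroscopy (fNIRS), aimed at users who cannot
communicate motorically (e.g. locked-in syndrome). Answers are encoded
spatiotemporally: the participant performs *mental drawing* (MD) inside
an auditorily cued "yes" time window to answer yes, or *spatial
navigation* (SN) imagery inside a later "no" window to answer no. A
session comprises ten runs in fixed order: two localizer runs (MD then
SN; 20 trials of 10 s task / 20 s rest each, 20 s lead-in, 620 s total),
six answer-encoding runs (five yes/no window pairs each; the first "yes"
window opens 20 s into the run), and two more localizers for additional
classifier training data.

The montage is sparse by design: 3 sources (FC3, C3, CP3) and 6
detectors (FC5, C5, CP5, FC1, C1, CP1) over left fronto-parietal cortex,
giving 18 source-detector channels; the four diagonal pairs whose
separation exceeds 60 mm in the largest cap (FC3-CP1, FC3-CP5, CP3-FC1,
CP3-FC5) are dropped, leaving 14 analyzed channels. Sampling is 12.5 Hz
at 760 and 850 nm.

Intra-run gaps that the paradigm description leaves schematic — the rest
between a pair's "yes" and "no" windows, and between pairs — default to
20 s, matching the localizer rest period and the 20-s lead-in; both are
arguments of `make_encoding_schedule()`.

## Signal model and preprocessing

Raw intensities are converted to optical-density changes,
`dOD = -log10(I / I_ref)`, then to HbO/HbR concentration changes by
inverting the 2x2 modified Beer-Lambert system per channel and sample:

`dOD_lambda = (eps_HbO,lambda dHbO + eps_HbR,lambda dHbR) * d * DPF_lambda`

Defaults (all configurable in `mbll_parameters()`): published extinction
coefficients at 760/850 nm (0.0586/0.1548 and 0.1058/0.0691 per mM per
mm for HbO/HbR), DPF 6.0 at both wavelengths, 30 mm separation. These
constants cancel out of every *decision* the pipeline makes (decisions
compare t-values, which are invariant to per-channel linear rescaling),
so their exact values only matter for reporting concentrations in
physical units.

*Referencing.* `I_ref` defaults to the whole-run temporal mean — the
conventional choice when true baseline optics are unknown. A recording
written by the simulator carries its exact baseline intensities, and
`intensity_to_od(reference = "stored")` uses them; this is what makes
the forward/inverse round trip exact to numerical precision, whereas
mean-referencing leaves a per-channel constant offset (harmless
downstream, as detrending and high-pass filtering remove constants).

*Filtering.* The band filter is deliberately a *moving-average* design:
the low-pass is a centered boxcar running mean of `round(fs / cutoff)`
samples applied `order` times (reflection padding, zero phase); the
high-pass subtracts the analogous running mean at its own cutoff.
Defaults: 0.3 Hz / order 2 (suppresses cardiac and respiratory bands)
and 0.01 Hz / order 1 (removes drifts). "Order" is interpreted as the
number of passes; acquisition-software conventions differ, so the
implemented gains are verified empirically in the test suite (a 1.1 Hz
tone is attenuated below 0.3 of its amplitude, a 0.05 Hz tone passes
above 0.7). Zero-phase centering avoids onset transients that would
bias early-trial GLM fits.

## GLM core

All decoding rests on ordinary least squares with the canonical
double-gamma hemodynamic response function (HRF). The kernel is the
difference of two gamma densities rescaled to unit peak; shapes are
parameterized as `1 + delay/dispersion` so that `peak_delay = 6` puts
the kernel mode at exactly 6 s (and the undershoot at 16 s, ratio 6,
32 s support). Event regressors are event boxcars convolved with this
kernel and renormalized to unit peak, so betas read directly as peak
response amplitude in the series' units (uM).

No prewhitening or autocorrelation correction is applied: decisions
compare t-values *within* a fit, where serial correlation inflates both
sides equally, and this matches the plain GLM of the original analysis
chain. Localizer GLMs use an intercept as the only confound; trial-wise
(multivariate) GLMs add a linear trend. Both choices are arguments.

The HbR response to activation is negative. Because "largest t-value"
is only meaningful on the expectation-aligned scale, all HbR contrasts
are sign-flipped (`chromophore_sign()`): the most responsive channel
then attains the largest t for both chromophores. Without this
convention, HbR channel selection would systematically pick noise.

## Quality control

Channel screening uses the coefficient of variation of the *unfiltered*
raw intensities, `CV% = 100 * sd/mean` (sample SD; at realistic run
lengths the n vs n-1 distinction is negligible, but it is pinned for
reproducibility). A channel is excluded when CV% exceeds 15 for any
wavelength in either block-1 localizer run — per-run values, strict
inequality, so CV exactly 15.0 survives. A control mode
(`cv_exclusion = FALSE`) skips the criterion entirely, reproducing the
original control analysis.

The fNIRS suitability questionnaire sums seven physical-feature ratings
(hair length/color/thickness/density/structure, skin color, head size)
to a maximum of 21; the published constraints fix the 0-4 scale and the
total, but not the per-feature maxima, so the default split
(3,4,3,3,2,3,3) is a documented reconstruction and fully configurable.
Its association with signal quality is a one-tailed Pearson correlation
against the count of CV-surviving channels (directional hypothesis:
higher score, fewer good channels).

## Univariate answer decoding

From the block-1 localizers, four GLM analyses (HbO/HbR x MD/SN) each
select the included channel with the highest task-vs-rest t — the four
*channels of interest* (COIs). Ties break by canonical (source-major)
channel order; the same channel may serve both tasks.

Decoding fits a GLM with one predictor per answer window type and reads
out the "yes" vs "no" comparison as: t of the *yes-window* predictor at
the MD COI versus t of the *no-window* predictor at the SN COI (each on
its chromophore's aligned sign). `t_MD > t_SN` decodes "yes", otherwise
"no". This per-predictor reading is the one consistent with the
physiology: a clean "no" run drives the no-window predictor at the SN
COI while leaving the MD COI silent, so the SN side must be credited
with *its own* predictor's evidence, not penalized by a signed
difference contrast (under which every clean "no" run would decode
"yes"). Exact ties decode "no" deterministically — reproducibility over
a coin flip; ties have measure zero on real data and arise here only in
degenerate all-zero inputs.

Multi-trial mode fits the whole run (five pairs jointly, 6 decisions
per participant); single-trial mode fits each pair on its own local
segment, from 5 s before the pair's "yes" onset to 15 s after its "no"
offset (configurable), making pairs effectively independent (30
decisions per participant). The exact temporal extent of a pair-local
fit is a reconstruction; the margins are arguments.

Significance uses the binomial empirical chance level: the smallest
count `c` with CDF(c; n, 1/2) >= 0.95. This inverse-CDF convention
yields 19/30 (63.33%) and 5/6 (83.33%). Note it is *not* identical to a
strict one-sided binomial test at alpha = 0.05 (which would demand
20/30); the convention is kept because it is the field's established
recipe for empirical chance levels and reproduces the published
thresholds. Per-class detection rates divide correct "yes" ("no")
decisions by the encoded "yes" ("no") counts.

## Multivariate pattern analysis

Per run, one GLM with a per-trial HRF predictor plus intercept and
linear trend yields each trial's t-value per channel and chromophore;
the concatenated HbO+HbR pattern over the 14 montage channels (28
features) is the trial's feature vector. The nominal per-trial window
is -2 to 20 s around onset (0-10 s being the trial interval); trials
whose window is cut by the run edge are dropped and counted. Whether
the original analysis used HbO-only, HbR-only or combined features is
not documented; combined is the default and `channels`/feature
subsetting allows either single-chromophore mode.

Classification is a linear soft-margin SVM (`e1071::svm`, cost 1 —
both unstated in the original work and therefore pinned, configurable).
Features are z-scored with *training-set* statistics only; the stored
center/scale are re-applied at test time (a leakage canary test asserts
this). Two regimes: SVM20-20 trains on the 20 MD1 + 20 SN1 localizer
trials; SVM40-40 adds the block-2 localizers (40 per task). Testing
uses the 30 active encoding trials (6 runs x 5); per-run answers arise
by majority vote over the run's five predicted tasks (MD votes "yes",
SN votes "no"; five voters, so no tie is possible).

Permutation significance retrains on label-shuffled training data (pure
reassignment, no stratification) and tests on the untouched test set,
2000 times by default. Two tail summaries are reported: the
*percentile* (proportion of permutations with accuracy <= observed, the
convention of the original analysis) and the add-one p-value
`(1 + #{perm >= obs}) / (1 + N)`. Because accuracy over 30 trials takes
only 31 values, the percentile is discrete and tie-inflated; when the
test suite checks null calibration it therefore applies the standard
randomized-PIT correction `(#{<} + U(#{=}+1)) / (N+1)`, which is
exactly uniform under exchangeability — the raw "<=" percentile cannot
be, by construction.

The CV% exclusion applies to the univariate path only; all 14 montage
channels enter MVPA regardless (an `mvpa_cv_exclusion` flag enables
exclusion-aware MVPA).

## The synthetic participant generator

No recordings were released with the original study, so the generator
is a first-class module emulating the statistical structure the
analysis assumes:

- **Responses**: per active event, boxcar x HRF (unit peak) scaled by
  `response_amplitude_hbo` on one mapped channel per task (default MD
  on C3-C5 over motor cortex, SN on CP3-CP5 over parietal cortex); HbR
  is `-1/3` of HbO (typical magnitude ratio; the published description
  fixes the signs, not the ratio).
- **Noise**, added per channel and chromophore with independent random
  phases: white Gaussian noise (SD 0.1 uM), cardiac 1.1 Hz (0.2 uM),
  respiratory 0.25 Hz (0.1 uM), Mayer waves 0.1 Hz (0.15 uM) —
  frequencies are typical physiological bands, as the study names the
  sources but not values — and a cumulative-sum random-walk drift
  rescaled to 0.3 uM, producing the low-frequency trends the 0.01 Hz
  high-pass targets.
- **Forward optics**: `I = I0 * 10^(-dOD)` with the same MBLL constants
  the preprocessing inverts; baseline intensities are stored with the
  recording.
- **Defaults**: peak amplitude 0.5 uM — a realistic single-channel
  imagery response, five times the white-noise floor, yielding a
  well-performing but not saturated participant. Answers default to
  three "yes" and three "no", as the question selection required.

One seed fixes everything; ground-truth hemodynamics depend only on the
schedule and amplitudes, never on the seed. What the generator does
*not* emulate — and what passing tests therefore cannot certify about
real recordings — includes motion artifacts, superficial/systemic
shared noise across channels (an optional term was considered and left
out: the study does not characterize inter-channel noise correlation),
spatially spread multi-channel activation, optode-coupling
nonstationarity, and between-run amplitude variability. Simulated
decoding accuracies are accordingly cleaner than the published group
means; the package treats those means as context, not as reproduction
targets.

## Problem sizes and numerical choices

The test suite exercises the full chain at the paradigm's true sizes
(620-s localizers, 320-s encoding runs, 12.5 Hz). Calibration suites
use 200 null participants for decision balance and 200 permutation
replicates of 200 permutations each for percentile uniformity — sizes
chosen to give standard errors well inside the asserted bands (the
binomial SE of the null-accuracy mean at 200 x 30 decisions is about
0.65 percentage points). Event-to-sample mapping floors `onset * fs`
with half-open intervals; designs are validated for full column rank;
a zero-variance contrast with zero effect reports t = 0 (and t = NA
when the effect is nonzero), with NA decisions counted as incorrect,
conservatively.

## Known limitations

- File I/O uses a documented CSV dialect plus BIDS-like events TSV;
  no HDF5/SNIRF container support.
- No short-channel regression, motion correction, or physiological
  noise regression — mirroring the original chain, which had none.
- Inference is within-participant; cohort summaries are descriptive
  (means, SDs, significance counts), with no group-level model.
- The univariate single-trial segment extent and the questionnaire's
  per-feature maxima are reconstructions, exposed as parameters.
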