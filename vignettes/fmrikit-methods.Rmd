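---
title: "Models and methods in fmrikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fmrikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmrikit)
```

fmrikit analyzes multisubject fMRI time series after preprocessing, in
matrix form: each subject is a `SubjectTimeSeries` with a T × V data
matrix (T timepoints at interval `trSeconds`, V voxels/parcels/units).
This vignette explains the statistical models behind each method
family, the tunable parameters and their defaults, the numerical
choices, and what the simulation-based tests do and do not establish.

## Conventions

All standardization uses the *population* (1/T) variance, so that for
z-scored series the Pearson correlation is exactly the inner product
divided by T; several exact identities in the test suite depend on
this. Missing values are represented as `NaN` and are never silently
dropped: zero-variance series propagate `NaN` into correlation maps
and are excluded from summaries with a warning that reports the count.
In-mask voxels are serialized x-fastest in ascending linear order
(column-major), recorded in every `VolumeGeometry` and provenance
sidecar, so volume round trips are bit-exact.

## Intersubject correlation

When subjects receive the same time-locked stimulus, the response at a
unit decomposes into a stimulus-driven component shared across
subjects and an idiosyncratic component (attention, physiology, scanner
noise). ISC estimates the shared part: `isc()` correlates each unit's
series either between all subject pairs (`pairwise`) or between each
subject and the average of the others (`loo`). Under the additive model
`x_i = s + σ n_i` with unit-variance signal and noise, pairwise ISC
converges to `1/(1 + σ²)` and leave-one-out ISC to
`1/sqrt((1 + σ²)(1 + σ²/(N − 1)))` — the closed forms the acceptance
suite checks at T = 2000.

Each subject is z-scored per unit before the leave-one-out average is
formed. This gives every subject equal weight and makes all ISC-family
results exactly invariant to positive affine rescaling of any
subject's units, which would otherwise bias the average toward
high-gain subjects.

`isfc()` generalizes to all unit pairs (stimulus-driven functional
connectivity); the diagonal of the symmetrized leave-one-out ISFC
matrix is identically the leave-one-out ISC, an exact identity rather
than an approximation. `spatialISC()` transposes the logic to spatial
patterns at single timepoints, with the T × T all-pairs variant
revealing recurring patterns; `slidingISC()` windows the time axis
(0-based half-open windows) and runs an independent ISC per window.

Across-subject summaries default to the mean of Fisher-z transformed
correlations, inverse-transformed (the variance-stabilized
convention); the median is offered. Applied to identical values the
Fisher-z mean returns them exactly.

### Nonparametric tests

`iscTest()` offers four null constructions: *phase randomization*
(every subject's series is given conjugate-symmetric random Fourier
phases — DC and Nyquist keep zero phase so surrogates are real — which
preserves each column's amplitude spectrum exactly; one phase draw is
shared across a subject's units to preserve spatial covariance),
*circular shift* (each subject's time axis rotated by an independent
nonzero uniform offset), *subject bootstrap* (resampling subjects with
replacement on Fisher-z leave-one-out values, null centered at the
observed mean), and *sign permutation* (random sign flips of the
per-subject Fisher-z values; note its resolution is limited by the
2^−N sign granularity at small N). p-values follow the add-one rule
`p = (1 + #{null ≥ obs})/(1 + B)`, so the smallest attainable value is
`1/(B + 1)` and p = 0 is impossible; two-sided tests double the
smaller tail, capped at 1. Across units, false discovery is controlled
by Benjamini–Hochberg adjustment (`stats::p.adjust`), the field
default for maps. The calibration test runs 200 independent-noise
datasets at B = 99 and verifies the 5% rejection rate within its
binomial confidence interval.

## Shared response model

Anatomical alignment does not align function: the same stimulus drives
differently arranged topographies in different brains. The SRM finds a
k-dimensional shared response `S` (k × T) and per-subject orthonormal
topographic transforms `W_i` (V_i × k) minimizing
`Σ_i ‖X_i − W_i S‖_F²`. `srmFit()` alternates the exact coordinate
updates: `W_i ← UV'` from the SVD of `X_i S'` (orthogonal Procrustes)
and `S ← (1/N) Σ W_i' X_i`; the objective after each full iteration is
recorded and is non-increasing by construction. The iteration count is
fixed (`nIter = 10` by default) rather than tolerance-based, so runs
are exactly reproducible.

Initialization is the one genuinely open design choice. We draw a
single seeded T × k Gaussian probe `P` and start each subject at the
polar factor of `X_i P`. Because `polar(Q A) = Q polar(A)` for
orthogonal `Q`, the whole fit is *equivariant to orthogonal rotations
of any subject's unit space* — the objective trace depends only on the
data geometry, a property a per-subject random start would not have.
The shared space itself is identifiable only up to a k × k rotation;
tests compare subspaces (principal angles) or Procrustes-align
solutions before comparing.

Per-unit z-scoring is applied before fitting by default. It is
optional (`zscore = FALSE`) because z-scoring is a diagonal rescaling
that takes exact noise-free `W S` constructions out of the
orthonormal-transform model class; the machine-precision recovery
checks therefore generate centered `W S` data and disable it, while
realistic pipelines keep the default.

`srmTransform()` projects (new) data into the shared space (`W_i' X`),
`srmReconstruct()` maps back (`W_i S`), and their composition is the
rank-k orthogonal projection onto the span of `W_i`.
`timeSegmentClassify()` implements the standard alignment benchmark:
non-overlapping segments of `segmentLenTr` TRs (≥ 2), each held-out
subject's flattened segment correlated against the other-subject
average of every candidate segment; neighbors of the true segment
cannot win on ties, and remaining ties resolve to the earliest index.
On SRM-structured simulations, classification in the estimated shared
space clearly exceeds a per-subject PCA baseline at the same
dimensionality — the package's realization of the qualitative claim
that functional alignment improves between-subject decoding.

## Event segmentation

The left-to-right HMM formalizes three assumptions: (1) at every TR a
region stays in its current event or advances to the next; (2) it
starts in event 1 and ends in event K; (3) each event k has a
characteristic spatial pattern `m_k`, observed with isotropic Gaussian
noise. Emissions use a single shared variance σ², re-estimated each
iteration; data are z-scored per TR across units, and event patterns
are re-z-scored after each update so emission distances stay
comparable across iterations.

Inference is exact constrained forward–backward in log space (safe for
T in the thousands): stay probability `1 − K/T` per TR (so the
expected number of advances across the scan is K), the final state
conditioned to be event K by the backward initialization, and event K
absorbing. On instances small enough to enumerate every monotone path
(T ≤ 12, K ≤ 4), posteriors agree with the brute-force sum over paths
to 10⁻¹⁰.

Fitting alternates the forward–backward E-step with
posterior-weighted pattern and variance updates. Plain alternation
from a single K-equal-blocks start, however, reliably locks into merge/
split local optima on roughly a quarter of planted configurations —
verified by comparing the likelihood of the stuck solution against the
truth. `eventSegFit()` therefore runs a *deterministic multi-start*: 5
phase-shifted block initializations, each explored under a slowly
decaying inflated emission variance (deterministic annealing,
`annealVar0 = 4`, decay 0.9 per iteration) that keeps posteriors soft
until patterns settle; the best final likelihood wins and is refined
by plain alternation, whose ascending log-likelihood trace is the one
reported. With this scheme, planted 10-event boundaries (patterns
drawn N(0,1), noise sd 0.1) are recovered within ±1 TR across every
configuration tested.

`eventSegApply()` runs a single pass with fixed patterns (e.g. from an
independent dataset); `eventSegFitShared()` fits one set of patterns
across datasets with aligned units but different durations, each with
its own `K/T_d` advance rate — the perception/recall use case.
`eventBoundaries()` extracts 0-based TRs where the MAP event index
increments (ties toward the lower index), and `boundaryMatchTest()`
tests agreement with annotations by counting annotations within
±`windowTr` of a model boundary against a null that re-places the same
number of boundaries uniformly without replacement.

Model order K must be prespecified; cross-validated log-likelihood on
an independent run peaks at the planted K in the test suite. The
multiple-chain and split–merge extensions are out of scope; the
fixed-pattern entry point (`eventSegApply`) is the hook a chain
extension would build on.

## Inverted encoding models

An encoding model predicts responses from stimulus features; an IEM
inverts it to read features back out. Channels tile the circular
feature space: channel c responds to feature θ with
`max(0, cos(π d / period))^p`, where `d` is the signed circular
distance from the channel's center — for orientation (period 180°)
this is the classic half-wave-rectified cosine on the doubled angle.
For even exponents this basis is a finite Fourier series, so two
algebraic facts follow: the channel sum is *exactly* constant whenever
`nChannels > p/2` (tiling), and the training design can reach full
rank only when `nChannels ≤ p + 1`. The default pairs 9 channels with
`p = 8` — the field's usual choice — satisfying both; `iemFit()`
refuses rank-deficient designs (for example, p = 6 with 9 channels, or
repeating a single stimulus) with an error naming the problem, and
reports the design's condition number.

Training solves `B = WC` by per-unit ordinary least squares;
inversion computes `C₂ = (W'W)⁻¹W'B₂` per trial (refusing condition
numbers above 10¹⁰) and reads out a point estimate as the circular
population vector of channel centers weighted by the rectified channel
responses. Because the basis is smooth in θ, reconstruction
interpolates: a noise-free trial at 142° is recovered exactly even
when 142° never appeared in training. Estimates are equivariant to
feature rotation and invariant to unit permutation or duplication.

`iemClassifierComparison()` realizes the claim that encoding structure
helps at small sample sizes: two-condition data are simulated with
per-trial feature jitter (sd 25°) around two prototypes, and held-out
trials are decoded by the IEM (smaller circular error to either
prototype) versus a linear SVM on raw responses, averaged over 20
simulations per training size. The jitter is the operative ingredient:
the IEM models the response as a function of the continuous feature,
while the SVM treats within-class stimulus variability as noise. A 2-D
spatial variant (`makeSpatialBasis()`, Gaussian bumps on a grid) uses
the identical algebra.

## The simulator

`generateNoise()` builds noise as a linear combination of components
with recognizable physical counterparts, each drawn from its own named
RNG stream derived from the user seed (adding a component never
perturbs another's draws; identical seeds give bit-identical volumes):

- baseline intensity (default 100) inside the mask;
- low-frequency drift: cosines below 1/128 Hz, scaled to `driftSdPct`
  (default 0.5% of baseline);
- AR(1) temporal noise per voxel plus white machine noise;
- physiological sinusoids (defaults 0.2 Hz respiratory, 1.17 Hz
  cardiac) evaluated at TR sample times — hence implicitly aliased —
  with voxel-specific random phase, since cardiac and respiratory
  cycles reach voxels with different delays;
- spatially smoothed Gaussian system noise (FWHM `spatialFwhmMm`,
  default 4 mm), white in time;
- out-of-mask background noise scaled so the middle-volume spatial SNR
  matches `snr`.

`measureNoise()` estimates SFNR (voxel mean over temporal sd after
quadratic detrending, averaged in-mask), spatial SNR (with a
high-frequency temporal proxy, flagged by a warning, when the mask
covers the whole grid), the lag-1 autocorrelation of the in-mask
average after removing both the quadratic trend and the low-frequency
drift model (so slow drift cannot masquerade as autocorrelation), and
the drift amplitude as percent of the mean.

The generator fits itself to the target profile: component amplitudes
are refined for up to 20 iterations until measured SFNR and AR(1) are
within 5% of the target. The refinement is damped and direction-aware
— overall amplitude tracks the SFNR error; the AR share of the
temporal block grows first; once it saturates, the *generating* AR
coefficient is pushed past the target (detrending and spatial dilution
bias the measurement downward) and the temporally-white competitors
shrink. Failure to converge is reported in a warning with the achieved
values, never silently. The acceptance check verifies the round trip —
`measureNoise(generateNoise(P))` within 10% SFNR and ±0.1 AR(1) on a
64-voxel, 200-TR fixture — which is also the limit of the fidelity
claim: the simulator matches its own measured profile; no claim is
made about matching any particular scanner's numerics.

`applySignal()` adds `scale/100 · baseline_v · Σ pattern_c[v] ·
timecourse_c[t]` to ROI voxels, i.e. signal in percent signal change
units, leaving non-ROI voxels untouched; `generateStimfunction()`
turns BIDS-style event tables into upsampled boxcars (half-open
intervals, amplitudes summing under overlap with a warning), and
`convolveHrf()` convolves with a double-gamma HRF (response shape 6,
dispersion 0.9 s; undershoot shape 12, dispersion 0.9 s, ratio 0.35;
peak-normalized). The response gamma's mode sits at (6−1)·0.9 = 4.5 s;
subtracting the undershoot moves the combined peak to ≈ 4.4 s, which
the tests assert within 0.15 s.

## Searchlight

`searchlight()` repeats an arbitrary multisubject statistic in a local
window around every in-mask voxel: cubic (default) or spherical
windows of integer radius, truncated at volume edges (physical
boundaries, no wrapping), evaluated only where at least `minUnits`
in-mask units remain, `NaN` elsewhere. Errors raised by the statistic
are re-thrown with the voxel coordinate attached. With a mean
statistic the engine reproduces an independently coded brute-force box
filter exactly, which is how it is tested.

## What the simulations do and do not show

Every test input is generated by the simulator or by explicit
construction, so the suite established: exact algebraic identities
(ISFC diagonal, projection identities, pseudoinverse round trips,
posterior oracle agreement), calibration of the permutation tests
under true nulls, and recovery of planted structure under the models'
own generative assumptions at realistic noise levels. What it cannot
establish is robustness to the ways real fMRI violates those
assumptions — hemodynamic nonlinearity, motion artifacts, non-Gaussian
and non-stationary noise, imperfect time-locking across subjects.
Problem sizes in the tests (tens of voxels, hundreds of TRs, ≤ 10
subjects) were chosen as the smallest at which the statistical
behavior of each method is visible and stable; all methods scale to
ROI-sized real data directly, and to whole-brain maps through the
searchlight.

## Command-line interface

The installed script `inst/cli/fmrikit` dispatches to `runCli()`:
subcommands `isc`, `isfc`, `srm`, `eventseg`, `iem`, `simulate`,
`searchlight`; inputs are plain TSV time-series matrices (T rows × V
columns, one file per subject), BIDS-style events TSVs, JSON noise
profiles and NIfTI volumes; a JSON config file can be merged under
explicit flags (flags win). Every run writes a `<out>.json` sidecar
with the resolved configuration, seed and package version; identical
configuration and seed give identical outputs. Exit status 2 marks
usage errors, 1 validation errors (with a message naming the offending
input), 0 success.
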