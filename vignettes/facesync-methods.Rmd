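---
title: "Models and methods behind facesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind facesync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facesync)
```

## The problem

When several people watch the same material, the degree to which their
facial behaviour co-varies is a usable index of shared processing of the
stimulus: viewers who attend to the same events, and respond to them
similarly, move similar parts of their faces at similar times. Webcam
landmark trackers make this measurable without storing video - each frame
is reduced to 68 (x, y) landmark positions plus seven emotion-classifier
scores - but the resulting recordings are awkward: sampling is irregular
(nominally ~5 Hz), frames go missing, and every analysis of synchrony
needs recordings matched in length and rate. `facesync` covers the path
from such raw CSV exports to two complementary synchrony statistics:

* **SUSY** (surrogate synchrony) for *single-channel* dyadic signals,
  such as per-second head movement or one emotion score;
* **CorrCA** (correlated component analysis) for the *multivariate*
  landmark signals, yielding spatial components of shared facial movement
  and an intersubject correlation (ISC) per component, per subject, and
  per time window.

## Preprocessing model

**Missingness.** A recording's missingness is
`1 - valid_frames / (duration x expected_rate)`, clamped to [0, 1], where
duration is the span between first and last timestamp and a frame is
valid when its landmark cell parses to exactly 68 pairs. Rows whose cell
is corrupt are *retained* as gaps - they count toward missingness but are
never silently dropped. Exclusion is strict: a recording is removed only
when its fraction exceeds the configured threshold (default 0.3).

**Resampling.** Each of the 136 coordinate channels (and each emotion
channel) is linearly interpolated onto a uniform grid at `target_rate`
(default 5 Hz). The grid is *phase-aligned* - sample times are integer
multiples of `1/rate` - so that independently resampled recordings share
grid points and group alignment reduces to trimming. No extrapolation is
performed: leading or trailing gaps shorten the usable span. Linear
interpolation reproduces affine signals exactly; this is asserted in the
tests rather than assumed.

**Alignment.** Two trimming policies: common overlap (all recordings of a
group trimmed to the intersection of their spans) and fixed duration
(every recording truncated to a stated length from its own start and
re-indexed to 0 s). Either way all recordings in a set end up with
identical sample counts, which is asserted.

**Head movement.** Per second, the summed frame-to-frame Euclidean
displacement of the nose tip (landmark 34, chosen because it is rigid
with respect to the face) is converted from pixels to centimetres with
the factor `6.3 / IOD_px`, where 6.3 cm is the average adult
inter-ocular distance and `IOD_px` is the per-recording median distance
between the eye-landmark centroids (37-42 vs 43-48). The displacement
between frames i and i+1 is credited to the second containing frame i,
so every bin aggregates `rate` displacements except the final one
(`rate - 1`); a mean-displacement variant is available via
`head_movement_stat = "mean"`. The measure is invariant to translation
of the face and to uniform zoom (the IOD scaling cancels it), both
tested.

**Scalarisation.** CorrCA needs one scalar series per landmark, not X/Y
pairs (separate horizontal and vertical features would produce
anatomically implausible axis-specific components). Two options:
`vector_norm` (default), the distance from the landmark's mean position
with the mean taken over the full recording; and `motion_amplitude`, the
displacement from the previous frame with the first sample defined as 0.
Both discard movement *direction*; two viewers raising versus furrowing
their brows look identical to these features. This is the main known
limitation of the feature set.

## SUSY

Each dyad's two series are cut into consecutive non-overlapping segments
of `segment_seconds` (default 5 s; trailing partial segments are
dropped). Within each segment, one member is shifted by every integer
lag up to `±L = round(maxlag_seconds x rate)` samples, and the Pearson
correlation of the overlapping portions (each mean-centred over the
overlap, no wraparound across segment borders) is Fisher-Z transformed,
`z = atanh(r)`. The lag axis therefore has `2L + 1` points. Correlations
are clipped to `|r| <= 1 - 1e-7` so z stays finite; a zero-variance
overlap yields z = 0 and is counted.

The null is built by *circular rotation*: the second series is rotated
by a random offset drawn uniformly from `[segment, T - segment]`
samples, which preserves its value multiset (mean, SD, marginal
distribution) exactly while destroying temporal alignment. With 100
replicates per dyad (default), the effect size is

```
ES = (mean aggregated real z - mean aggregated surrogate z) / SD of aggregated surrogate z
```

where aggregation is the signed mean over segments and lags (an
absolute-mean variant exists; signed is the default because opposite-sign
correlations should cancel in a measure of *shared* dynamics). At group
level all `choose(N, 2)` dyads are processed; for efficiency one
rotation per subject per replicate is drawn and shared across that
subject's dyads - pair (i, j) correlates unrotated i with rotated j -
which leaves each dyad's null distribution unchanged. The per-dyad
`circular_surrogates()` operation draws independent offsets.

Windowed hypothesis tests pool (real z, replicate-mean surrogate z)
pairs over dyads, lags, and all segments whose *closed* time span
intersects the closed query window, then apply a paired t-test. Closed
intervals matter: a 70-80 s window under 5-s segments touches three
segments (70-74, 75-79, 80-84), giving 435 x 3 pairs and df = 1304 for
30 subjects.

On independent white-noise dyads the ES distribution is centred at zero
with ~5% of seeds outside the 1.96 SD band; this calibration is part of
the test suite.

## CorrCA

With each subject's D-feature series mean-centred over time, pairwise
cross-covariances are `R_ij = X_i X_j' / (T - 1)`. The pooled
within-subject covariance is `R_w = sum_i R_ii`; the per-subject
between-covariance is the symmetrised sum of cross terms,
`R_b,i = sum_{j != i} (R_ij + R_ij')/2`, and `R_b = sum_i R_b,i`. These
definitions are verified against a naive double-loop oracle in the
tests.

Because facial data are high-dimensional relative to recording length,
the within covariance is shrunk toward an isotropic target before
inversion:

```
R_w(gamma) = (1 - gamma) R_w + gamma (trace(R_w) / D) I,   gamma in [0, 1]
```

with default `gamma = 0.1`; `gamma = 1` is the fully isotropic endpoint
(at which the decomposition reduces to a PCA of `R_b`). The components
solve the generalised eigenproblem `R_b W = R_w(gamma) W Lambda`,
computed by Cholesky whitening of `R_w(gamma)` followed by a symmetric
eigendecomposition (with an eigendecomposition fallback and a clear
error suggesting larger gamma when the shrunk covariance is singular).
Eigenvectors are sorted by descending eigenvalue (ties keep solver
order, which is arbitrary and documented as such), normalised so
`w' R_w(gamma) w = 1`, and sign-fixed so each component's
largest-magnitude forward-model loading is positive - the eigenproblem
determines eigenvectors only up to sign, so only the relative pattern of
loadings is interpretable.

Eigenvalues map to component ISC as `rho_k = lambda_k / (N - 1)`; for
identical subjects `rho_1 = 1`. Per-subject contributions use the pooled
denominator

```
ISC_ik = N (w_k' R_b,i w_k) / ((N - 1) w_k' R_w(gamma) w_k)
```

The factor N is forced by two requirements at once: the subject mean
must equal `rho_k` exactly (since `sum_i R_b,i = R_b` and the pooled
denominator aggregates N per-subject within covariances), and identical
subjects must each score 1. A per-subject-denominator variant
(`w_k' R_w,i w_k`, no factor N) is available via
`subject_isc_variant = "per-subject"`.

**Windowed ISC.** Covariances are re-estimated inside a sliding window
(default 3 s long, 1 s step) and projected through the *global* W -
never refit per window, which would break component identity over time.
Windows lie on a full-window grid (starts at 0, step, 2 x step, ... with
start + window <= duration), giving `floor((T - w)/s) + 1` estimates;
data are mean-centred within each window. The trace is scaled by
`1/(N - 1)` by default so it lives on the same scale as `rho`
(`normalize_windowed = FALSE` gives the raw quotient). Note that with a
3-s window a 2-s synchrony event can never be strictly contained in a
single window; peak locations are therefore meaningful at window
resolution - in the built-in simulation the arg-max windows overlap the
injected intervals, with centres within about a second of them.

**Forward model.** `A = R_w W (W' R_w W)^(-1)`, using the *unshrunk*
`R_w`: the forward model describes the data, not the regulariser.
Columns of A are the spatial loadings drawn in facial topography plots.
A is homogeneous of degree -1 in each eigenvector (rescaling `w_k` by c
scales `A_k` by 1/c); the invariant object is the reconstruction
operator `A W'`, and with all D components retained at `gamma = 0` the
reconstruction `A W' X` reproduces the mean-centred data exactly (tested
to 1e-6).

**Shrinkage sensitivity.** `gamma_sweep()` refits at
gamma = 0.05, 0.1, 0.2, 0.5, 1 and reports the leading component's ISC
per group plus whether the rank order of groups is stable across the
sweep. On pure noise, increasing gamma never increases `rho_1` (tested);
rank instability across gamma is a symptom of sample sizes too small for
stable covariance estimates.

## The simulation generators

The generators are first-class, tested code: they define the study
conditions under which the statistical behaviour of the estimators is
validated.

**Head-movement study** (`simulate_head_movement_study()`): 30 subjects,
120 s at 1 Hz, independent unit-SD white Gaussian noise, and a shared
0.5 Hz sinusoidal template mixed in at weight alpha = 0.7
(`alpha x template + (1 - alpha) x noise`) during a synchrony event at
70-80 s. Two conventions deserve explanation:

* *Template phase.* A 0.5 Hz sine sampled at 1 Hz sits exactly at the
  Nyquist frequency: at phase 0 every sample is 0 and the "synchrony"
  vanishes. The default phase of pi/2 yields the alternating +1/-1
  sequence, the non-degenerate choice; the phase is configurable.
* *Segment alignment.* The event is placed on whole 5-s analysis
  segments: all segments whose closed span intersects the closed window
  70-80 s are injected (samples 70-84 s). With the window pooled over
  those three segments this puts every pooled segment fully inside the
  event, which is the regime in which the pooled real mean Fisher-Z is
  ~1.6 and the paired-test pair count is 435 x 3. A literal
  interpretation (injecting only samples 70-80) leaves the third pooled
  segment with a single injected sample and drags the pooled mean down
  to ~1.1; `align_events_to_segments = FALSE` selects it.

**Landmark study** (`simulate_landmark_study()`): 30 subjects, 60 s at
5 Hz. Faces start from the canonical 68-point template; between-subject
variance is a per-subject Gaussian offset of every landmark
(sigma = 5 px, constant over time); temporal noise is white and
independent per coordinate sample. Region-specific oscillations (e.g.
mouth `sin(t) + 0.5 sin(2t)`) are added to both coordinates of the
region's landmarks for designated subject subsets within stated windows
(defaults: mouth, subjects 1-15, 20-22 s; left eye, subjects 16-25,
30-32 s), each subject receiving an integer circular phase shift of up
to ±2 frames (±0.4 s) and an amplitude factor in [0.8, 1.2]. The
temporal noise SD defaults to 0.5 px: the injected signals (amplitudes
roughly 1-1.5 px) are meant to be *strongly* synchronous against the
noise, and at substantially larger noise the generalised-eigenvalue
noise floor at these dimensions (N = 30, D = 68, T = 300) overtakes the
weaker six-landmark eye event, which then no longer surfaces among the
leading components - no longer the regime the simulation is meant to
emulate.

**Raw CSV fixtures** (`simulate_raw_trace_csv()`): smooth sinusoidal
face motion sampled at jittered timestamps with a stated fraction of
dropped frames, written in the raw CSV dialect (JSON landmark cells,
millisecond timestamps, emotion columns) together with a ground-truth
manifest; the clean trajectories are returned as a closure so that
preprocessing can be checked against them end to end.

What the generators deliberately do *not* emulate: real facial dynamics
(nonstationary, non-Gaussian, anatomically correlated across landmarks),
tracker error structure (occlusion bursts, face re-acquisition jumps),
head pose changes, or drift. Passing tests therefore demonstrate that
the estimators recover what was injected under controlled conditions -
not that the measures are validated indices of engagement on real data.

## Numerical choices and degenerate inputs

* Correlations clipped at `1 - 1e-7` before `atanh`; zero-variance
  overlaps give z = 0 and are logged, never NaN.
* The circular-shuffle offset range `[segment, T - segment]` guarantees
  a genuine misalignment; series shorter than two segments are rejected.
* Covariance estimation uses `1/(T - 1)`; windows with fewer than two
  samples are rejected; low-rank warnings fire when T < D except inside
  the windowed estimator where T < D is expected and harmless (the
  quotient, not an inverse, is evaluated).
* `chol()` on the shrunk within covariance, with a symmetric-eigen
  fallback and an explicit singularity error recommending larger gamma.
* Timestamps in milliseconds are auto-detected (median gap > 10) and
  convertible explicitly; duplicated timestamps are averaged before
  interpolation.
* Reading processed CSVs goes through text + `strtod` so that the
  shortest-representation doubles written by the exporter round-trip
  bit-exactly.
* Seeds are threaded explicitly through every stochastic call; identical
  configuration and seed reproduce every numeric artifact byte for byte.

## Validation problem sizes

The test suite validates the estimators at the generators' native sizes:
the head-movement replication uses 20 independent seeds of the full
30-subject study with 100 surrogates per dyad; event recovery uses 20
seeds of the full landmark study; ES null calibration uses 200
white-noise dyad seeds; the component-ISC bound battery spans 200 fits
with N in [2, 30], D in [2, 10], T in [50, 2000] across the gamma sweep.
These sizes keep the whole suite within a few minutes on one CPU while
leaving the Monte-Carlo margins comfortably wider than the assertion
tolerances.

## Known limitations

* Scalarisation discards movement direction (see above).
* The component-ISC bound `|rho_k| <= 1` is an algebraic consequence of
  the covariance construction at gamma = 0; under shrinkage the
  denominator is perturbed and the bound can in principle be exceeded on
  strongly synchronised, anisotropic data - the package treats any
  excursion beyond 1 + 1e-8 as a numeric-integrity error rather than
  silently reporting it.
* Emotion-score channels are analysed with the same SUSY machinery as
  head movement, but classifier scores are bounded in [0, 1] and often
  heavily skewed; the Fisher-Z machinery is indifferent to this, the
  interpretation may not be.
* No inferential machinery is provided for CorrCA ISC values (no
  surrogate null for rho); the gamma sweep and per-subject spread are
  the available robustness checks.
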