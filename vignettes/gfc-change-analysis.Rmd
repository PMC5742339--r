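---
title: "Detecting session changes in global functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting session changes in global functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfconn)
```

## The problem and the model

Two resting-state scans of the same subjects bracket an intervention; the
question is which brain regions changed their coupling with the rest of the
brain between the scans. Testing every pairwise connection is the obvious
first move, but with `P` parcels there are `P(P−1)/2` tests and the per-edge
effect sizes in resting-state data are small, so that screen is typically
underpowered once multiplicity is controlled. `gfconn` therefore follows a
two-stage strategy:

1. **Regional screen.** Collapse each parcel's row of the Fisher-Z
   connectivity matrix into three global connectivity (gFC) sums — all
   entries, positive entries only, negative entries only — and test the
   session delta of each sum per parcel with a one-sample t-test across
   subjects, FDR-corrected. This trades edge-level resolution for an
   `O(P)` family and aggregated effects.
2. **Connection follow-up.** For each parcel the screen detects, test the
   session delta of its `P−1` individual connections, again FDR-corrected,
   to individuate which edges drive the regional change.

The split of gFC into positive-only and negative-only sums exists because
positive and negative correlations cancel in the plain sum; carrying all
three measures keeps the screen sensitive to one-sided changes. The
decomposition `gFC = gFC⁺ + gFC⁻` is maintained *exactly* in floating
point: the implementation computes the two signed sums and defines the
total as their sum, rather than summing the row independently (which would
agree only to rounding).

A detected region's positive sum has a subtle weakness: the set of edges
with positive z can differ per subject and session, so an increase could in
principle reflect support churn rather than genuine strengthening. The
**fixed positive set** validation addresses this: it selects, once, the
parcels whose seed connectivity is significantly positive across subjects
in *both* sessions (two-tailed uncorrected `p < alpha`, default 0.05, and
positive mean), and re-tests the seed's session delta summed over exactly
that fixed edge set. All member edges count, whatever their per-subject
sign — re-filtering by sign per subject would reintroduce the
variable-support problem the validation exists to remove.

### Statistical assumptions

- The one-sample t on session deltas assumes approximately normal deltas
  across subjects. Fisher-Z transformation of the correlations is the
  variance-stabilizing step that makes this reasonable; gFC sums of many
  z-values are close to normal by aggregation.
- Tests across parcels and across edges are strongly dependent (they share
  subjects and nodes). The default FDR procedure is therefore
  Benjamini–Yekutieli, whose control holds under arbitrary dependence, at
  the price of a `c(m) = Σ 1/j` penalty. Benjamini–Hochberg is available
  where its positive-dependence condition is considered acceptable.
- The FDR family for the regional screen is *per measure* (three separate
  families of size `P`) by default. Pooling all `3P` tests into one family
  is exposed as `family = "pooled"`; which convention is appropriate
  depends on whether the three measures are viewed as separate questions.
  Both are implemented; the default is the more common reading.

## Preprocessing chain and its conventions

The cleaning order is fixed and recorded in provenance flags — trim, then
band-pass, then (for voxel input) parcellation, then nuisance regression —
and re-running a stage on already-processed data is an error rather than a
silent no-op.

- **Trimming**: the first 6 volumes are dropped (magnetization
  equilibration at TR = 3 s; 120 acquired volumes leave 114).
- **Band-pass**: an ideal (brick-wall) frequency-domain filter at
  0.01–0.08 Hz — demean, FFT, zero every bin strictly outside the band,
  inverse FFT. The ideal filter was chosen over an IIR design because its
  contract is exactly testable (a 0.05 Hz tone passes with r > 0.999, a
  0.15 Hz tone retains < 1 % of its power) and it matches the dialect of
  the common resting-state toolboxes.
- **Confound filtering**: the motion/WM/CSF regressors are passed through
  the *same* band-pass before regression, so the regression cannot
  reintroduce energy outside the analysis band. The regression itself is
  exact OLS on an intercept plus confounds; rank deficiency fails loudly
  with the collinear column names.
- **Parcellation**: per parcel, the mean over atlas voxels inside the
  gray-matter mask; parcels sharing fewer than 5 voxels with the mask are
  excluded and reported.
- **Motion QC**: framewise displacement uses the translation-plus-arc-length
  formula with a 50 mm head sphere (rotations degrees→radians); session
  exclusion uses strict `>` against 2 mm / 2°, measured as deviation from
  the session's first volume.
- **Degenerate parcels** (zero variance after cleaning) are flagged and the
  correlation stage refuses them by name; correlation is undefined there
  and silent dropping would desynchronize parcel order across subjects.

## Numerical choices

- `fisher_z` clamps `|r| ≥ 1 − 1e−7` to `sign(r)·(1 − 1e−7)` (z ≈ 8.1) and
  counts the clamps. Real data never reaches `|r| = 1` but synthetic edge
  cases and duplicated signals can.
- The diagonal is `NA` after the transform and excluded from every sum.
- Ground-truth correlation matrices are repaired to the nearest positive
  semidefinite correlation matrix by eigenvalue clipping at zero plus
  diagonal rescaling. The repair leaves already-PSD matrices bit-identical,
  and a planted effect whose repair moves the planted edge by more than
  0.01 is treated as unrealizable and fails naming the edge.
- Zero z-values contribute to neither gFC⁺ nor gFC⁻ (a measure-zero event,
  pinned so the decomposition identity is exact).
- In the increase-count diagnostic (edges above the diagonal in a
  per-session t-vs-t scatter), ties `t₂ = t₁` do not count as increases.

## The synthetic generator

The generator exists so that every downstream stage can be tested against
known ground truth. Per subject and session it draws a stationary AR(1)
Gaussian process whose cross-sectional correlation equals the session's
ground-truth matrix: innovations `N(0, (1−φ²)Σ)`, initial state `N(0, Σ)`,
so no burn-in is needed and the stationary cross-correlation is exactly
`Σ`. Session 2 differs from session 1 only on the planted seed–target
edges, shifted on the Fisher-Z scale and mapped back through `tanh`.

Defaults encode the reference study design the package is calibrated
against: 44 subjects × 2 sessions × 463 parcels × 114 retained volumes at
TR = 3 s, with a focal seed-edge shift of 0.17 Fisher-Z units.
Parameter rationale:

- `ar_coefficient = 0.3`: a modest lag-1 autocorrelation representative of
  BOLD sampled at TR = 3 s; it inflates correlation sampling variance by
  `(1+φ²)/(1−φ²) ≈ 1.2` relative to white noise.
- `subject_sd_z = 0.22`: chosen so the across-subject SD of the focal-edge
  session delta is ≈ 0.26 at 114 timepoints — the dispersion implied by a
  group delta of 0.17 with t(43) ≈ 4.3 — once the `≈ 2·1.2/(T−3)` sampling
  variance of the delta is added. One shift per subject is drawn and shared
  across that subject's planted edges: the heterogeneity models a
  subject-level effect size, not independent per-edge wobble.
- `motion_step_sd = 0.019` (mm and degrees): a random-walk step size that
  yields a mean framewise displacement near 0.085 mm, typical of a
  compliant young-adult sample.
- `nuisance_amplitude = 0.3`: each parcel receives a random linear
  combination of the standardized motion/WM/CSF regressors at 0.3× the
  neural SD, giving the regression stage realistic work to do.
- `hf_noise_sd` (default 0) adds band-limited noise above 0.08 Hz —
  emulating aliased physiological power that only the filter, not the
  regression, can remove. It is off by default and used by the
  preprocessing-recovery tests.
- The block-community base network (4 equal communities, within r = 0.3,
  between r = 0.1) gives the mostly-positive correlation structure typical
  of parcelled resting-state data; a sparse random alternative exists for
  unstructured baselines.

**What the generator does not emulate**: hemodynamic response shapes,
spatially structured physiological noise, scanner drift, susceptibility
artifacts, inter-subject variation in the *baseline* network (only the
planted edges vary across subjects), or registration error. Passing tests
on synthetic data therefore demonstrate the correctness and calibration of
the statistics under a second-order Gaussian model — not robustness to
every artifact of real fMRI. The optional voxel-inflation path exists only
to exercise the parcellation code, not to claim image realism.

## Calibration of the stochastic checks

The detection-rate floors asserted by the acceptance checks were fixed by a
one-time calibration run of an independent straight-line implementation of
the reference design, before the package was built, and are not revisited:
under 44 subjects, 100 parcels, 114 timepoints and BY control at q = 0.05,

- the null design (no planted effect) must keep the family-level
  false-positive rate at or below 0.10 over 200 replicates;
- a diffuse planted increase of 0.10 Fisher-Z units on 30 % of the seed's
  edges must be detected on the ΔgFC⁺ measure in at least 25 % of
  replicates, with detection monotone non-decreasing in the planted shift
  (0 → 0.05 → 0.10);
- a focal planted edge of 0.17 Fisher-Z units must be detected by the
  seed-restricted screen in at least 35 % of replicates, and more often
  than by the whole-brain screen on the same data.

A note on the diffuse condition: at a per-edge shift of 0.05 the screen has
near-null power under these conditions — the row-sum of ~100 dependent
z-deltas carries substantial sampling noise, and the shared per-subject
shift adds between-subject variance proportional to the number of planted
edges. That point therefore serves as the middle of the monotonicity check
rather than a power floor. The 100-parcel simulation size (rather than the
full 463) keeps the replicated studies proportionate while preserving the
family-size regime of the correction; the full 463-parcel design is run
end-to-end once in the acceptance script.

## Behavioral layer

Questionnaire scoring is deliberately strict: 10 trait items in 1–4 summed
to 10–40; 17 stress-symptom items in 1–5 with the four anger-overlapping
items (5, 14, 16, 17) removed by default before summing; emotion-cluster
ratings in 0–6 averaged over available cells with missingness explicit;
regional volumes adjusted as `region/ICV`. Out-of-range responses fail
loudly — silent clamping of questionnaire data hides entry errors.
Brain–behavior associations use Spearman's rank correlation with average
ranks for ties and a t-approximation p-value (standard for n in the 20–60
range), pairwise-complete deletion with the used n always reported, and
BY adjustment within explicitly declared correction families; raw p-values
are always retained alongside adjusted ones because family definitions for
such exploratory layers are a reporting convention, not a property of the
data.

## Known limitations

- The whole-brain pairwise screen is a reconstruction: it applies the same
  paired-delta one-sample t with BY correction over all edges; other
  historical implementations of "test all pairwise maps" exist.
- The ideal filter assumes stationarity and produces mild ringing at
  series edges; with 114-point series this is shared by all parcels and
  cancels in correlation, but single-parcel absolute amplitudes should not
  be over-interpreted.
- BY under strong dependence is conservative; the observed null
  family-level rejection rate sits far below the nominal q, which costs
  power (reflected in the calibrated floors above).
- Group comparisons use Welch's t only; no nonparametric fallback is
  provided for very small groups.
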