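---
title: "Causal interaction profiles for eigenmode timeseries"
author: "ccmprofiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal interaction profiles for eigenmode timeseries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmprofiles)
```

## The method

Worm locomotion on a plate is well described by the amplitudes of a handful
of postural principal components — the "eigenworm" modes `a1..a4`. These
four channels are not independent: in a nonlinear dynamical system each
variable's influence on the others unfolds over a range of time lags. This
package quantifies those influences with convergent cross mapping (CCM)
and turns them into *interaction profiles*: curves of cross-mapping skill
versus target delay, one per ordered pair of modes. The 12-profile set for
an individual is a compact fingerprint of its behavioral dynamics, and
distances between fingerprints support comparisons between individuals,
behaviors and mutant strains.

### Cross mapping

CCM rests on attractor reconstruction. If mode `X` drives mode `Y`, then
`Y`'s history contains an imprint of `X`, so points on `Y`'s delay-embedded
(shadow) manifold can be used to estimate contemporaneous or past values of
`X`. Concretely, `cross_map(effect = x, predictor = y, E, tp)`:

1. embeds `y` as points `[y_t, y_(t-1), ..., y_(t-E+1)]` (lag step fixed at
   one sample);
2. draws a library of `library_size` embedded time indices, requiring every
   lag and the shifted target `x[t + tp]` to be observed (no imputation —
   gappy frames simply never enter a library);
3. predicts each library point's target from its `E + 1` nearest library
   neighbors (self excluded, plus any neighbor within `exclusion_radius`
   samples — a Theiler window against trivial serial-correlation matches),
   weighted `exp(-d_i / d_1)` as in simplex projection, with exact
   zero-distance ties sharing weight equally;
4. scores predictions against observations with Pearson correlation and
   averages the correlation over `n_repeats` independent libraries.

The skill is reported signed and unclamped; skill rising with library size
(see the convergence tests) is the operational signature of coupling.

### The displayed-delay axis

A profile scans the target offset `tp` (`<= 0`, in samples). For reading
off *generative* lags we use a displayed-delay axis
`d = -tp - offset(E)`, `offset(E) = 1 + ceiling((E - 2) / 2)`, anchored at
the **center** of the embedding window rather than its newest coordinate.
The reason is informational: in a lag-coupled pair the driver value
`x[t - L]` is recoverable from *consecutive* receiver samples throughout
the reconstruction window, so the skill maximum sits where the target lies
at lag `L` from the window's central coordinate. Empirically the argmax
separation is `L + 1 + (E - 2) / 2` — we measured separations 5, 7 and 9 at
`E` = 2, 5 and 10 for a lag-4 coupling — so a newest-coordinate axis would
shift the reported delay by about `E/2` and make it depend on `E`. The
centered axis recovers `L` at every `E`, keeps profiles computed at
different `E` aligned (their Spearman correlation across a delay grid
exceeds 0.99 between `E = 8` and `E = 12` on the worked example), and
reduces to the familiar `d = -tp - 1` at `E = 2`.

### The worked example

The package's reference system is a pair of coupled logistic maps,

$$x_{t+1} = x_t(3.8 - 3.8 x_t), \qquad
  y_{t+1} = y_t\big(3.5 - 3.5 y_t + \textstyle\sum_k c_k\, x_{t-L_k}\big),$$

with `x` autonomous (so causality runs strictly `x -> y`). With a single
coupling `(L = 4, c = 0.1)` the profile of `x`'s influence on `y` peaks at
displayed delay 4. With a second coupling at lag 11 the profile shows two
local maxima, at 4 and 11, and raising the second strength raises the
11-peak relative to the 4-peak.

Two configuration notes, both discoverable by experiment:

* **Embedding dimension for the dual-coupling example.** At `E = 10` the
  two skill humps (7 samples apart) merge into a single broad maximum;
  only a compact embedding resolves them. The dual-timescale analyses
  therefore run at `E = 2`, the natural dimension for this two-variable
  toy (the embedding-dimension scan on the logistic map itself selects
  `E = 2`). Single-coupling recovery is demonstrated at the production
  setting `E = 10`.
* **Feasible strengths.** The receiver map leaves `(0, 1)` once total
  coupling pushes its effective growth past `(r_y + c)^2/(4 r_y) \ge 1`
  (about `c = 0.21` at `r_y = 3.5`); the simulator checks the bound and
  refuses infeasible settings rather than diverging quietly. The
  dual-coupling strength progression used in validation is
  `c_2 in {0.04, 0.07, 0.1}` against `c_1 = 0.1`.

### Profiles, normalization, averaging

`lag_profile()` scans a `tp` (or displayed-delay) grid and reports raw and
min-max-normalized skill; normalization (each profile stretched to
`[0, 1]`, constants mapped to all zeros and flagged) removes
between-individual differences in absolute predictability, which vary with
recording quality and intrinsic noise. `profile_set()` builds the 12
ordered pairs of a 4-mode record on one grid. Averaging across individuals
(`average_profiles()`) normalizes first, then averages, then re-normalizes
— so the group profile reflects shape consensus, not whichever individual
cross-maps most strongly. Normalization is per pair: each pair's panel
spans `[0, 1]` on its own.

Profile comparison (`profile_similarity()`) is the mean Spearman rank
correlation over corresponding pair profiles. Because min-max scaling is
monotone, raw and normalized skills give identical similarities (asserted
in the tests); rank correlation also makes every downstream statistic
invariant to monotone rescalings of skill.

### Surrogate null

`phase_surrogate()` randomizes Fourier phases (Hermitian-symmetrically,
with a random sign for the Nyquist bin at even lengths), preserving the
power spectrum — hence autocorrelation, mean and variance — while
destroying nonlinear cross-dependence. Null bands for "is this pair really
coupled?" are built by profiling surrogate pairs; 19 surrogates bound a 5%
one-sided band. When the null-band calibration is itself under test we add
the standard Theiler window (`exclusion_radius = 10`, half a second at
20 Hz): without it, serially correlated neighbors inflate the real pair's
null skill slightly relative to its linearized surrogates.

### Group distinctness

`distinctness_test()` implements the directional permutation test: for
each unit of group A, find its most similar unit (self excluded) among A
and B; the observed statistic is the percentage of A-units whose nearest
profile is again in A, and the null shuffles group labels (sizes
preserved) 1000 times. The attained fraction is the share of permuted
percentages *strictly* below the observed one (ties count as not-less).
Nearest neighbors depend only on similarity ranks, so the test is
invariant to monotone rescaling; ties in similarity are broken by a seeded
random candidate order. Directionality is real: a tight cluster centered
inside a diffuse one is distinct from it, while the diffuse group —
whose members often find their nearest profile in the central cluster —
is not.

## The synthetic data generator

Real recordings are not required anywhere: `synthetic_eigenmodes()`
generates the study conditions. It emulates the *format and statistics*
of tracked postural-mode data — four standardized channels at 16-30 Hz
(default 20 Hz), optional frame-wide NaN dropouts with geometric gap
lengths (tracking losses hit all modes of a frame together), metadata and
a ground-truth coupling table — while the dynamics themselves are four
chaotic logistic maps with distinct growth parameters
(`r = 3.9, 3.6, 3.7, 3.8`) and lagged additive couplings, exactly the
mechanism of the worked example. Chaotic maps were chosen deliberately:
cross mapping assumes weakly coupled deterministic nonlinear dynamics
without synchrony, and short-memory chaos makes planted delays sharply
recoverable. Smooth narrowband oscillators were evaluated and rejected —
with enough phase noise to avoid synchrony, their multi-sample
autocorrelation smears the delay peak and the planted coupling drowns in
the process noise, so they cannot support parameter-recovery validation.

What passing tests on these data do show: the engine recovers planted
lags, directions and relative strengths; the statistics are calibrated
under their nulls; the machinery is deterministic under seeds. What they
do not show: anything about biomechanics, posture geometry, or the
particular timescales of real worm behavior — the generator's channels
are irregular chaotic oscillations, not eigenworm trajectories, and real
recordings bring slow nonstationarity the generator omits (its one
concession is the regime-switch construction used in the windowed-profile
tests).

Default generator conditions used across validation: 20 Hz, 12-60 s
records, coupling strength 0.1 (recovery sweeps also use 0.05 and 0.2),
observation noise 0.05 SD, NaN fraction 0 unless the quality filter is
under test.

## Numerical and design choices

* **Neighbor count** is `E + 1` (the simplex convention); distances are
  Euclidean in embedding space.
* **Library sampling** is without replacement within a repeat and
  independent across repeats; `library_size = "all"` uses every valid
  index (then repeats are redundant and the result is deterministic).
* **Exclusion radius** defaults to 0 (long foraging-style series); 10
  samples is the convention for short stimulus-response series and for
  null calibration.
* **Degenerate inputs**: a zero-variance observed or predicted segment
  makes that repeat's skill undefined (`NA` with a warning); a delay with
  no valid library indices is dropped from the profile with a warning; an
  all-missing profile is an error.
* **Ties**: equal skills in the embedding scan resolve to the smaller
  `E`; exact zero distances share simplex weight equally; similarity ties
  in the distinctness search are broken by a seeded shuffle.
* **Interpolation** (`resample_profile()`) is linear in `tp` seconds onto
  a 0.1 s grid, never extrapolates, and snaps to natively resolved delays
  (tolerance 1e-9 s) so coincident grid points reproduce resolved skills
  exactly.
* **Filters** read their thresholds strictly: records pass with NA
  fraction `< 0.25` and length `> 200` frames.
* **Determinism**: every stochastic operation takes a `seed`; a fixed
  seed reproduces skills, profiles and permutation results bit for bit.
  The generator may produce NaN fractions up to (not including) 1 so that
  filter-boundary behavior is itself testable.

### Problem sizes in the validation suite

The suite favors many small, seeded simulations over few large ones:
worked-example recovery uses 2000-step trajectories (100 library repeats
at `E = 10`; 50 at `E = 2`); recovery sweeps use 36 runs of 1200-2000
steps; null calibration uses 50 trials of 40 s records against 19
surrogates each plus 200 permutation-test replicates on 300-unit pools;
averaging and similarity experiments use 12-60 s records at 20 Hz. These
sizes put every Monte-Carlo assertion comfortably above its decision
threshold (margins were established by pilot simulation and are stated
with each test) while keeping the full suite to minutes.

## Known limitations

* The displayed-delay axis calibrates the peak *location*; peak width
  still grows with `E` and with the driver's autocorrelation time, so
  closely spaced couplings need compact embeddings to resolve.
* CCM's assumptions (deterministic nonlinear dynamics, weak-to-moderate
  coupling, no synchrony) are inherited wholesale; strongly synchronized
  or noise-dominated channels yield profiles whose peaks are not
  interpretable as lags.
* `profile_peaks()` is a deliberately simple prominence filter (default
  0.1 of the normalized range, calibrated on the worked example's noise
  floor), not a general peak-significance procedure.
* The package analyzes eigenmode tables; it does not extract eigenmodes
  from video, download public datasets, or parse their native HDF5
  layouts (the tidy-CSV reader documents the expected columns, and a
  converter is a straightforward extension).
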