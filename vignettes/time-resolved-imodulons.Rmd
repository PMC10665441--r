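---
title: "Time-resolved iModulon discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved iModulon discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynomodulon)
```

## The problem

Massively parallel microfluidic reporter platforms grow on the order of
two thousand *E. coli* promoter-GFP strains side by side and image them
every 10 minutes for days. A typical heavy-metal experiment flows one
metal over the chip for a 4-hour induction window, lets the cells recover
in minimal media, and repeats for the next metal. The result is, for every
promoter, a long fluorescence time series spanning six induction windows
and their recovery tails.

`dynomodulon` condenses such data into **iModulons**: sets of promoters
that move together across conditions, each paired with a temporal activity
profile. An iModulon is one column of a promoter-weight matrix $M$
together with the matching row of an activity matrix $A$, obtained from an
independent component analysis of the fold-change matrix $X \approx M A$.
Where classical transcriptomics gives one snapshot per condition, the
time-resolved matrix lets us ask not only *which* promoters respond to a
metal but *when* — immediately, mid-window, or steadily throughout.

## From raw fluorescence to the fold-change matrix

The preprocessing chain is fixed, in this order:

1. **Background correction**: `(raw - background) / background`, using the
   fluorescence measured just outside each cell trap. Units cancel; the
   result is signal amplification over background.
2. **Median filter**, kernel 11 (i.e. ±50 min on the 10-min grid), with
   zero-padded edges. This removes isolated imaging artifacts.
3. **Promoterless normalization**: `(s - c) / c` against the mean signal
   of promoterless control strains, processed identically. This removes
   shared trends (autofluorescence, focus drift, culture state).
4. **Windowed log2 fold change**: for each metal, the normalized signal at
   6 points spaced 40 min apart inside the induction window, as
   `log2(value(t_j) / value(t_ref))` with the window *start* as reference;
   for recovery, 20 points spaced 40 min apart referenced to the window
   *end*. Columns are ordered metal-major (`zinc:1 ... zinc:6, copper:1,
   ...`), so a six-metal design yields 36 induction columns and 120
   recovery columns. The reference point itself is not a column; six
   40-min steps exactly tile the 240-min window.

Three numerical choices deserve explanation:

* **Non-positive signal.** A normalized value can be ≤ 0 (signal below
  the control), where the log is undefined. Rows affected at any used
  time point get a small offset `eps = 1e-3 * median(positive values)`
  added to both numerator and denominator; rows still non-positive are
  dropped with a warning. The offset is applied **only** to affected
  rows: applying it globally would perturb every entry by ~1e-3 log2
  units, destroying the exactness of the ratio chain for well-expressed
  promoters for no benefit.
* **No interpolation.** Sampled times must sit on the raw 10-min grid
  (all 40-min offsets do); a missing grid point is an error naming the
  promoter, metal and time index, and a promoter with any dropped window
  is removed entirely — ICA needs complete rows.
* **Median filters are not transparent.** A running median reproduces a
  signal exactly wherever it is monotone within the filter span, removes
  isolated impulses on flat signal exactly, but *clips isolated peaks*:
  a peak at a sampled point is replaced by its larger flank (a fast
  activation spike sampled at its maximum loses about half its height),
  and an impulse landing mid-ramp shifts the running median by one rank
  — one 10-min step. These are properties of the median, shared by any
  implementation, and they shape what "exact round-trip" tests can
  honestly claim (below).

## The synthetic-data generator

Because no public accession accompanies the platform data, the package
ships a first-class generator that emulates the experiment end to end and
carries its planted ground truth alongside.

* **Planted structure.** `generate_truth()` draws `M_true` with
  non-overlapping binomial member supports per component (weights
  `weight_scale * (1 + N(0, 0.05^2))`) over a near-normal bulk
  (`N(0, (weight_scale/20)^2)`) — the bulk exists so the K² membership
  threshold has a realistic null to test against. `A_true` rows carry one
  of five activation templates (`fast`, `intermediate`, `steady`,
  `partial_steady`, `late`), max-normalized so amplitude lives entirely
  in the weights, mirroring the scale indeterminacy of ICA.
* **Raw signal model.** `generate_raw_fluorescence()` writes
  `raw(t) = background + baseline * c(t) * (1 + 2^{la(t)})` with `la`
  the promoter's planted log2 activity, and the promoterless control
  `background + baseline * c(t)`; `c(t)` is a slow linear culture trend
  shared by all strains (`control_drift_per_min`, default 2e-5).
  Preprocessing inverts this construction exactly: the normalized value
  is `2^{la(t)}` and the fold change recovers `la` itself. Within-window
  activity is interpolated from the template; after the window the final
  value is held for a 60-min plateau (GFP is stable; fluorescence does
  not vanish when transcription stops) and then decays exponentially with
  an ~80-min half-life, truncated to zero well before the next window.
  The plateau is also what makes the window-end sample locally monotone,
  hence preserved exactly by the median filter.
* **Noise model.** The platform publications give no quantitative noise
  model, so the defaults here are chosen for plausibility, not measured:
  per-sample Gaussian noise on log2 activity (`noise_sd`, default 0.1),
  impulse artifacts with probability `spike_prob` (default 1e-3), and the
  slow control drift. Each source can be switched off independently,
  which is how the exact round-trip check is constructed: with noise,
  spikes and drift all zero and monotone (steady/late) planted shapes,
  preprocessing reproduces the planted fold changes to ~1e-15. With
  peaked shapes the peak sample is clipped as described above — the
  generator does not hide what the filter does.
* **What it does not emulate.** Growth and trap-loading dynamics, plasmid
  copy number, image segmentation, correlated (non-white) noise, and
  promoter-specific reporter kinetics. Passing tests on this generator
  demonstrate that the pipeline inverts its own acquisition model and
  separates planted modules — not that real data are this clean.

Defaults describe the emulated study: 1805 promoters, six metals (zinc,
copper, lead, iron, cadmium, chromium), ten planted modules (four
zinc-associated covering the fast / intermediate / steady / partial-steady
shapes, steady + late copper, one steady module per remaining metal),
member sparsity 1% (≈18 promoters per module).

## Robust ensemble ICA

A single FastICA run is a local optimum from a random start; the robust
procedure keeps only structure that survives restarts:

1. **Dimension.** PCA on the column-centered matrix; `k` is the smallest
   number of components explaining 99% of the variance. Columns are
   centered but not variance-scaled — fold changes share units, and
   scaling would distort weight comparability across conditions.
2. **Ensemble.** `n_runs` (default 100) symmetric FastICA runs (log-cosh
   contrast, tolerance 1e-6) from seeded random orthogonal
   initializations, on data whitened once per ensemble. Sources live in
   promoter space (columns of $M$); mixing lives in condition space (rows
   of $A$). Each component is normalized to unit L2 and sign-oriented so
   its largest-magnitude weight is positive (ties broken by the lower row
   index), with $A$ rescaled so $m a$ is unchanged.
3. **Clustering.** All components from all runs are pooled and clustered
   by DBSCAN on the distance `1 - |Pearson r|` (a component and its
   negation coincide), radius 0.1, minimum cluster size
   `ceil(min_frac * n_runs)` (default: half the runs — one member per run
   for a reproducible component). Noise points are discarded. Cluster
   centroids — sign-aligned means, re-normalized, with activities scaled
   to preserve the mean reconstruction — are the candidate components.
4. **Repeat consistency.** The whole ensemble-plus-clustering procedure is
   repeated `n_repeats` times (default 100) with fresh seeds; a candidate
   from the first repeat is retained only if every other repeat produced a
   centroid matching it at `|r| > 1 - cluster_distance`, matched greedily
   by descending `|r|`. A `fast_test` setting (10 runs × 10 repeats) keeps
   exploratory work and the test suite interactive at reduced stringency.

**On convergence.** At realistic dimensions most whitened directions are
near-Gaussian, and the symmetric fixed point oscillates below the 1e-6
tolerance indefinitely — some initializations do not converge within any
practical iteration cap. A run that misses the cap (default 200
iterations) is retried once from a fresh seed; if the retry also misses,
its final iterate is used and counted, matching the behavior of the
standard FastICA implementations this field uses. The clustering and
repeat-consistency stages are precisely the machinery that discards
whatever unstable components such runs contribute.

**On pure noise.** A fixed noise matrix has finite-sample heavy-tailed
directions that are genuine attractors of the contrast function, and the
consistency filter reruns on the *same* matrix — so even pure Gaussian
data can yield a few reproducible components. This is not a defect of the
filter but a property of the data. In real libraries this component class
is typically dominated by one noisy promoter and is caught by the
single-promoter discard flag; on white-noise simulations the same class
appears as diffuse components that match no planted structure (near-zero
correlation to every planted module) and carry empty memberships.
Consequently the pipeline reports *reproducible* components, not *true*
ones; on planted data expect the planted set plus a few such extras.

**Recovery limits.** A useful diagnostic for simulation studies: any
ICA/PCA estimate of a gene-weight vector lies in the column space of the
data, so the correlation between an estimate and a planted column is
bounded by the planted column's projection onto that space. At member
weight/noise ratio 5 (15-member modules, 36 conditions) this ceiling is
roughly 0.82–0.90 — no estimator can match planted columns at `|r| > 0.9`
under those conditions, a bound worth computing before interpreting
recovery rates.

## Characterizing iModulons

* **Membership.** Promoters are removed from a weight column one at a
  time in order of decreasing `|weight|`, recomputing the D'Agostino K²
  normality statistic of the remainder, until K² < 800; the membership
  boundary is the `|weight|` of the last removed promoter, and only
  positively weighted removals become members. K² combines the
  transformed sample skewness and kurtosis and is scale-invariant, so
  membership does not depend on component normalization. The statistic
  grows with sample size: the fixed 800 cutoff is calibrated for
  ~1800-promoter libraries, and columns over a few hundred promoters may
  legitimately yield empty memberships. Below 20 remaining values the
  small-sample transforms are unstable, so the loop refuses to go there
  and flags the component as degenerate.
* **Discard flag.** A component whose membership is a single promoter, or
  where one promoter carries more than 70% (configurable) of the squared
  weight, is flagged as a noisy-promoter artifact — retained in outputs,
  marked `discarded`.
* **Primary metal.** The metal whose induction window has the largest
  aggregate (summed) activity; ties go to the earlier metal in the design
  order.
* **Temporal shape.** Within the primary metal's 6-point window, the
  center of mass `CM = Σ i·max(a_i,0) / Σ max(a_i,0)` and highest peak
  `HP = argmax a` (1-based, earliest on ties) feed the printed rules:
  Fast (`CM ≤ 4, HP ≤ 3`), Intermediate (`CM ≤ 4, HP ≤ 4`), Steady
  (`CM ≤ 5, HP ≥ 4`), else Other. The regions overlap (Fast's region is a
  subset of Intermediate's), so the classifier applies them in
  most-specific-first precedence, which makes it total: every finite
  6-vector gets exactly one label. Negative activities are *clipped*, not
  absolute-valued, in the CM — the quantity is meant to locate activation
  mass, and taking magnitudes would let repression shift it. Profiles
  with no positive activity get `cm = NA` and label Other. Two
  interpretive notes: a partial-steady profile (ramp, late collapse)
  lands in the Steady region under these rules (CM ≈ 3.7, HP = 5), and a
  late-activation profile (CM ≈ 5.3, HP = 6) fails all three — the
  printed rules name three shapes; finer labels are a reporting matter,
  which is why Other components carry their CM/HP for case-by-case
  inspection. Recovery-phase components (20-point windows) get CM/HP but
  no Fast/Intermediate/Steady label: the printed thresholds are specific
  to 6-point windows.
* **Category shift.** Given a user-supplied promoter → functional category
  table (such tables come from manual curation; the package consumes, not
  creates, them), member promoters are counted per category per phase,
  unannotated members counting as `other`.

## Problem sizes and reproducibility

The test suite and the acceptance script exercise the pipeline at reduced
but structurally faithful sizes chosen to keep a full run interactive on a
single core: round-trip checks at 40–60 promoters × 2 metals, recovery
experiments at 300 promoters × 36 conditions over 20 seeds with the
10×10 fast-test ensemble, and thresholding at the full 1805-promoter
column size. The analysis drivers under `analysis/` run the full
1805-promoter, six-metal simulation with a 20×10 ensemble. All
randomness flows from explicit seeds through a fixed derivation scheme;
identical seeds give bit-identical outputs, including the ICA ensembles.

## Known limitations

* The recovery-phase matrix has `n_metals × 20` columns; activity that
  has decayed to baseline contributes near-zero columns there.
* The shape classifier is tailored to 6-point induction windows; other
  designs fall back to Other + CM/HP.
* The K² cutoff is a fixed statistic value, not a p-value: its meaning
  shifts with library size (see above).
* Ensemble ICA cost scales with `n_runs × n_repeats`; the full 100×100
  default on a 1805×36 matrix is an overnight-scale computation on one
  core, which is what the reduced settings are for.
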