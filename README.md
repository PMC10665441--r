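# dynomodulon

Time-resolved iModulon discovery from promoter-reporter fluorescence time
series.

## What this is for

Microfluidic reporter platforms measure the activity of ~2000 *E. coli*
promoter-GFP strains every 10 minutes for days, across successive
heavy-metal induction windows and recovery periods. `dynomodulon` turns
that kind of data into **iModulons** — independently modulated promoter
sets, each with a temporal activity profile — and classifies *when* each
set responds: fast, mid-window, or steadily.

The pipeline is, end to end:

1. **Preprocessing** — background correction
   `(raw − background)/background`, kernel-11 median filter, normalization
   by the promoterless control `(s − c)/c`, then windowed log2 fold
   changes: 6 points × 40 min per induction window referenced to the
   window start (36 columns for six metals), or 20 points × 40 min per
   recovery period referenced to the window end.
2. **Robust ensemble ICA** — the fold-change matrix `X` (promoters ×
   conditions) is decomposed as `X ≈ M·A`. The PCA dimension explains 99%
   of the variance; 100 randomly restarted FastICA runs (log-cosh, tol
   1e-6) are clustered with DBSCAN on the distance `1 − |Pearson r|`
   (radius 0.1, minimum cluster size half the runs); cluster centroids are
   candidate components; the whole procedure is repeated 100 times and
   only components found in every repeat are kept. Columns of `M` are
   unit-norm, sign-oriented promoter weights; rows of `A` are activities
   per condition.
3. **Characterization** — per component: membership by iteratively
   removing the largest `|weight|` promoters until the D'Agostino K²
   normality statistic of the remainder drops below 800 (positive weights
   only); a discard flag for single-promoter-dominated components;
   primary metal = window with the largest aggregate activity; temporal
   shape from the center of mass (CM) and highest peak (HP) of the
   6-point window — Fast (CM ≤ 4, HP ≤ 3), Intermediate (CM ≤ 4, HP ≤ 4),
   Steady (CM ≤ 5, HP ≥ 4), else Other, applied most-specific-first.
4. **Category shift** — given a user-supplied promoter → function table,
   the member composition (stress/damage vs transcription/translation/
   synthesis vs other) is compared between induction and recovery.

A first-class synthetic-data generator plants known modules (weights,
member sets, activation shapes) and emulates the acquisition chain down to
raw fluorescence, so every stage is testable without any download. See the
methods vignette (`vignettes/time-resolved-imodulons.Rmd`) for the models,
parameter meanings and design choices.

## Worked example

```r
library(dynomodulon)

metals <- c("zinc", "copper", "lead", "iron", "cadmium", "chromium")
cfg <- synthetic_config(
  n_promoters = 200, metals = metals,
  shape_assignment = data.frame(metal = c("zinc", "copper", "iron"),
                                shape = c("fast", "steady", "late")),
  weight_sparsity = 0.05, noise_sd = 0, spike_prob = 0, seed = 5)

report <- run_pipeline(pipeline_config(
  synthetic = cfg, phases = "induction",
  ica = ica_config(fast_test = TRUE, base_seed = 5),
  out_dir = "demo_run", seed = 5))
print(report)
```

```
dynomodulon pipeline run -> demo_run
  induction: X is 200 x 36; k = 3; robust components = 3 (0 discarded)
```

Three planted modules, three robust components: the 200×36 fold-change
matrix needs k = 3 principal components for 99% of its variance, and all
three ICA components survive clustering and the repeat-consistency
filter. `demo_run/` now holds every intermediate artifact (raw series,
normalized series, `X_induction.tsv`, `M_induction.tsv`,
`A_induction.tsv`, the iModulon summary and membership tables), each with
a provenance header recording version and seed. The summary table labels
each component with its primary metal and temporal shape
(`zinc`/Fast, `copper`/Steady, `iron`/Other — late activation fails all
three printed shape rules by design and is reported as Other with its
CM/HP for inspection).

The numbered drivers under `analysis/` run the same workflow at full
scale (1805 promoters, six metals, ten planted modules, induction and
recovery phases) and write their tables under `results/`.

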