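#!/usr/bin/env Rscript
# Preprocess raw fluorescence into windowed log2 fold-change matrices.
#
# Chain: background correction -> kernel-11 median filter -> promoterless
# normalization -> log2 fold change against the window anchor (induction:
# window start, 6 points x 40 min; recovery: window end, 20 points x 40
# min), columns metal-major.
#
# Reads:  results/data/raw_series.tsv, raw_control.tsv
# Writes: results/X_induction.tsv, results/X_recovery.tsv

library(dynomodulon)

series <- read_series("results/data/raw_series.tsv")
control <- read_series("results/data/raw_control.tsv")
design <- experiment_design(c("zinc", "copper", "lead", "iron",
                              "cadmium", "chromium"))

normalized <- preprocess_series(series, control, kernel_size = 11)
for (phase in c("induction", "recovery")) {
  X <- build_fold_change_matrix(normalized, design, phase)
  write_fold_change_matrix(X, sprintf("results/X_%s.tsv", phase))
  cat(sprintf("%s matrix: %d promoters x %d conditions (dropped %d rows)\n",
              phase, nrow(X), ncol(X),
              length(unique(normalized$promoter_id)) - nrow(X)))
}
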