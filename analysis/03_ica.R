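#!/usr/bin/env Rscript
# Robust ensemble ICA of the induction and recovery matrices.
#
# For each matrix: PCA picks the dimension explaining 99% of the variance,
# an ensemble of randomly restarted FastICA runs is clustered with DBSCAN
# on the 1-|r| distance, and only components reproduced in every repeat of
# the whole procedure are kept. The ensemble here uses 20 runs x 10
# repeats, a reduced setting that keeps this driver interactive; the
# clustering and consistency thresholds are the pipeline defaults.
#
# Reads:  results/X_induction.tsv, results/X_recovery.tsv
# Writes: results/{M,A}_{induction,recovery}.tsv

library(dynomodulon)

conf <- ica_config(n_runs = 20, n_repeats = 10, base_seed = 20260927)
for (phase in c("induction", "recovery")) {
  X <- read_fold_change_matrix(sprintf("results/X_%s.tsv", phase))
  dec <- robust_ica(X, conf)
  write_decomposition(dec, sprintf("results/M_%s.tsv", phase),
                      sprintf("results/A_%s.tsv", phase))
  cat(sprintf("%s: k(99%% var) = %d, robust components = %d\n",
              phase, dec$k_pca, dec$n_robust))
}
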