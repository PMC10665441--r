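#!/usr/bin/env Rscript
# Turn robust components into annotated iModulons.
#
# Membership by iterative D'Agostino K-squared thresholding (cutoff 800,
# positive weights only), single-promoter discard flag, primary metal by
# largest within-window aggregate activity, and temporal shape (Fast /
# Intermediate / Steady / Other) from the center of mass and highest peak
# of the induction window. Recovered components are compared against the
# planted truth from 01_simulate.
#
# Reads:  results/{M,A}_{induction,recovery}.tsv, results/data/truth_*.tsv
# Writes: results/imodulon_summary_{phase}.tsv, results/membership_{phase}.tsv

library(dynomodulon)
library(data.table)

design <- experiment_design(c("zinc", "copper", "lead", "iron",
                              "cadmium", "chromium"))
M_true <- read_fold_change_matrix("results/data/truth_M.tsv")
truth_tab <- fread("results/data/truth_components.tsv")

for (phase in c("induction", "recovery")) {
  M <- read_fold_change_matrix(sprintf("results/M_%s.tsv", phase))
  A <- read_fold_change_matrix(sprintf("results/A_%s.tsv", phase))
  dec <- structure(list(M = M, A = A, col_means = rep(0, ncol(A)),
                        component_ids = colnames(M),
                        n_robust = ncol(M), k_pca = NA_integer_,
                        cluster_size = rep(NA_integer_, ncol(M)),
                        run_freq = rep(NA_real_, ncol(M))),
                   class = "ica_decomposition")
  im <- characterize_imodulons(dec, design, phase)
  fwrite(im$summary, sprintf("results/imodulon_summary_%s.tsv", phase),
         sep = "\t")
  fwrite(im$membership, sprintf("results/membership_%s.tsv", phase),
         sep = "\t")
  cat(sprintf("\n== %s phase: %d iModulons (%d discarded) ==\n", phase,
              nrow(im$summary), sum(im$summary$discarded)))
  print(im$summary[, c("imodulon_id", "n_members", "discarded",
                       "primary_metal", "cm", "hp", "shape")])
  if (phase == "induction") {
    R <- abs(cor(M, M_true[rownames(M), ]))
    best <- apply(R, 1, which.max)
    cat("\nmatch to planted modules (|r| of best match):\n")
    print(data.table(imodulon = colnames(M),
                     planted = colnames(M_true)[best],
                     planted_metal = truth_tab$metal[best],
                     planted_shape = truth_tab$shape[best],
                     r = round(R[cbind(seq_len(nrow(R)), best)], 3)))
  }
}
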