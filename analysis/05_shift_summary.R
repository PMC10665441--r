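#!/usr/bin/env Rscript
# Functional category shift between induction and recovery.
#
# Counts member promoters per functional category in each phase from a
# SYNTHETIC annotation table built off the planted truth (real analyses
# supply a literature-curated table instead): members of stress-associated
# planted modules are labeled stress/damage, a slice of the remaining
# library transcription/translation/synthesis, everything else other.
#
# Reads:  results/membership_{induction,recovery}.tsv, results/data/truth_*.tsv
# Writes: results/category_shift.tsv

library(dynomodulon)
library(data.table)

truth_tab <- fread("results/data/truth_components.tsv")
M_true <- read_fold_change_matrix("results/data/truth_M.tsv")
promoters <- rownames(M_true)

# synthetic annotation: planted module members -> stress/damage; an
# arbitrary fixed slice of non-members -> transcription/translation/synthesis
members_true <- unique(unlist(lapply(seq_len(ncol(M_true)), function(j)
  promoters[abs(M_true[, j]) >= 0.5])))
synth_pool <- setdiff(promoters, members_true)
annotation <- data.table(
  promoter_id = c(members_true, synth_pool),
  category = c(rep("stress/damage", length(members_true)),
               rep(c("transcription/translation/synthesis", "other"),
                   length.out = length(synth_pool))))

mem <- lapply(c("induction", "recovery"), function(phase) {
  mm <- fread(sprintf("results/membership_%s.tsv", phase))
  summ <- fread(sprintf("results/imodulon_summary_%s.tsv", phase))
  keep <- summ$imodulon_id[!summ$discarded]
  unique(mm$promoter_id[mm$imodulon_id %in% keep])
})

shift <- summarize_category_shift(mem[[1]], mem[[2]], annotation)
fwrite(shift, "results/category_shift.tsv", sep = "\t")
cat("category composition of iModulon members by phase:\n")
print(shift)
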