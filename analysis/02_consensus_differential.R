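#!/usr/bin/env Rscript
# Build replicate-consensus ATAC peaks per condition (>= 2 of 3
# replicates), combine conditions into the final peak universe, and
# filter the differential table to decreased ("dependent") sites at
# FDR < 0.05 and fold change < -1.5.

suppressPackageStartupMessages(library(sepeaks))

reps <- function(cond) lapply(1:3, function(i)
  read_peaks(sprintf("scratch/synthetic/atac_%s_rep%d.bed", cond, i),
             "bed"))
cons <- lapply(c(control = "control", treatment = "treatment"),
               function(cond) consensus_peaks(reps(cond), 2, cond))
for (cs in cons) print(cs)

combined <- combine_conditions(cons)
write_peaks(combined, "results/combined_peaks.bed")
cat("combined universe:", length(combined), "peaks\n")

diff_tab <- read_differential_table("scratch/synthetic/differential.tsv")
decreased <- filter_differential(diff_tab, fdr_max = 0.05,
                                 fold_min = 1.5, "decreased")
write_peaks(decreased, "results/decreased_sites.bed")
cat("decreased sites (FDR<0.05, fold < -1.5):", length(decreased), "\n")
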