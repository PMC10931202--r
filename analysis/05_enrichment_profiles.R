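#!/usr/bin/env Rscript
# Overlap statistics tying the stages together: the fraction of
# super-enhancers overlapping a decreased ATAC site, hypergeometric
# enrichment of decreased sites among enhancers over the peak universe,
# an UpSet-style multiway overlap table, and H3K27ac metaprofiles at
# decreased vs other sites.

suppressPackageStartupMessages(library(sepeaks))

combined <- read_peaks("results/combined_peaks.bed", "bed")
decreased <- read_peaks("results/decreased_sites.bed", "bed")
enh <- read_peaks("results/enhancers.bed", "bed")
supers <- read_peaks("results/superenhancers.bed", "bed")
h3k27ac <- read_fragments("scratch/synthetic/h3k27ac_fragments.bed")

frac <- intersect_sets(supers, decreased)$n_a_overlap / length(supers)
cat(sprintf("super-enhancers overlapping a decreased site: %.3f\n", frac))

in_enh <- intersect_sets(combined, enh)$a_hit
in_dec <- intersect_sets(combined, decreased)$a_hit
hg <- hypergeometric_enrichment(length(combined), sum(in_enh),
                                sum(in_dec), sum(in_enh & in_dec))
hg$fdr <- bh_adjust(hg$p_value)
write.table(hg, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("enhancer x decreased enrichment: k=%d, p=%.3g\n",
            hg$overlap_k, hg$p_value))

upset <- multiway_overlap_counts(list(decreased = decreased,
                                      enhancers = enh,
                                      superenhancers = supers))
write.table(upset, "results/upset_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

other <- combined[!intersect_sets(combined, decreased)$a_hit]
prof <- rbind(
  signal_profile(decreased, h3k27ac, class_label = "decreased"),
  signal_profile(other, h3k27ac, class_label = "other"))
write.table(prof, "results/h3k27ac_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
agg <- aggregate(mean_cpm ~ class_label, prof, mean)
cat("mean H3K27ac CPM in +/-2 kb window by site class:\n")
print(agg, row.names = FALSE)
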