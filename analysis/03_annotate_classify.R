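#!/usr/bin/env Rscript
# Annotate the peak universe and the decreased sites to their nearest
# TSS, bin distances (the decreased sites should be strongly TSS-distal),
# and classify H3K27ac sites into promoters and enhancers from
# histone-mark co-occurrence.

suppressPackageStartupMessages(library(sepeaks))

genes <- read_gene_table("scratch/synthetic/genes.tsv")
combined <- read_peaks("results/combined_peaks.bed", "bed")
decreased <- read_peaks("results/decreased_sites.bed", "bed")

for (nm in c("combined", "decreased")) {
  ann <- annotate_nearest_tss(get(nm), genes)
  bins <- bin_tss_distances(ann)
  write.table(bins, sprintf("results/tss_bins_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(nm, "TSS distance bins (% of peaks):\n")
  print(bins, row.names = FALSE)
}

marks <- lapply(c(h3k4me3 = "h3k4me3", h3k4me1 = "h3k4me1",
                  h3k27ac = "h3k27ac"), function(m)
  read_peaks(sprintf("scratch/synthetic/%s.bed", m), "bed"))
el <- classify_elements(marks$h3k4me3, marks$h3k4me1, marks$h3k27ac,
                        genes)
write.table(el, "results/elements.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_peaks(element_ranges(el, "enhancer"), "results/enhancers.bed")
write_peaks(element_ranges(el, "promoter"), "results/promoters.bed")
cat("classified:", sum(el$element_class == "promoter"), "promoters,",
    sum(el$element_class == "enhancer"), "enhancers\n")
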