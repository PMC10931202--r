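#!/usr/bin/env Rscript
# Stitch active enhancers within 12.5 kb, score stitched regions by
# input-subtracted H3K27ac CPM, rank, and call super-enhancers past the
# slope-1 tangent of the normalized rank-signal curve. Writes the
# hockey-stick table for plotting.

suppressPackageStartupMessages(library(sepeaks))

enh <- read_peaks("results/enhancers.bed", "bed")
h3k27ac <- read_fragments("scratch/synthetic/h3k27ac_fragments.bed")
input <- read_fragments("scratch/synthetic/input_fragments.bed")

stitched <- stitch_enhancers(enh, stitch_bp = 12500)
stitched <- score_regions(stitched, h3k27ac, input)
call <- call_superenhancers(stitched)
print(call)

rep <- hockey_stick_report(call)
write.table(rep$table, "results/hockey_stick.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
supers <- call$regions[S4Vectors::mcols(call$regions)$is_super]
write_peaks(supers, "results/superenhancers.bed")
cat(sprintf("%d stitched regions -> %d super-enhancers (cutoff %.1f)\n",
            length(stitched), call$n_super, call$cutoff_score))
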