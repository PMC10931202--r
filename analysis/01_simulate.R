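#!/usr/bin/env Rscript
# Generate the synthetic study genome: 4 chromosomes x 10 Mb, 240 genes,
# 200 typical enhancers, 40 planted super-enhancer clusters, 3 ATAC
# replicates per condition with negative-binomial noise, and 75% of
# distal sites / SE clusters planted as dependent (log2FC -2).
# Writes the full input bundle under scratch/synthetic/ (regenerable; large fragment BEDs stay out of results/).

suppressPackageStartupMessages(library(sepeaks))

seed <- 20260924
cfg <- synthetic_config(seed = seed)
bundle <- generate_synthetic(cfg)
print(bundle)

paths <- write_synthetic_bundle(bundle, "scratch/synthetic")
cat(length(paths), "files written under scratch/synthetic/ (regenerable; large fragment BEDs stay out of results/)\n")
cat(sprintf("planted dependent sites: %d of %d ATAC sites\n",
            sum(bundle$sites$dependent), nrow(bundle$sites)))
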