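# sepeaks

Regulatory-genomics analysis of chromatin accessibility and histone-mark
peak data. The package addresses the question a perturbation experiment
asks of its epigenome: after acutely depleting a chromatin remodeler,
*which accessible sites depend on it, are those sites enhancers, and are
super-enhancers disproportionately affected?* It is aimed at analysts
holding ATAC-seq replicate peak sets, CUT&RUN/ChIP peak sets for
H3K4me3 / H3K4me1 / H3K27ac, fragment files, and a differential
accessibility table.

## What it computes

- **Replicate-consensus peaks** — single-linkage clustering of replicate
  peaks, keeping clusters supported by ≥ 2 replicates, then a combined
  cross-condition peak universe.
- **Dependent accessible sites** — threshold filtering of a differential
  table at FDR < 0.05 and linear fold change < −1.5.
- **Promoter/enhancer classification** — promoters are H3K4me3⁺H3K27ac⁺
  sites; enhancers are H3K27ac⁺H3K4me1⁺ sites lacking H3K4me3 and lying
  > 1 kb from the nearest TSS (peak-center distance).
- **Super-enhancer calling** — enhancers within 12.5 kb are stitched;
  each stitched region *r* is scored by input-subtracted normalized
  signal, *S(r) = (n_t/N_t − n_c/N_c)·10⁶* (fragment midpoints in CPM);
  regions are ranked and rescaled to the unit square, and
  super-enhancers are the regions past the point where a line of slope 1
  is tangent to the rank–signal curve, i.e. past
  *argmax_i (i/n − s_(i)/s_max)* — the classic "hockey-stick" cutoff.
- **Overlap statistics** — exact upper-tail hypergeometric enrichment
  *P(X ≥ k)* for set overlaps over an explicit universe,
  Benjamini–Hochberg adjustment, UpSet-style multiway overlap counts,
  nearest-TSS distance binning, and binned CPM metaprofiles (100 bp bins,
  ± 2 kb) around site classes.
- **Synthetic genome with planted truth** — a seeded generator of genes,
  promoters, typical enhancers, stitchable super-enhancer clusters,
  replicate ATAC peaks with negative-binomial noise, fragment libraries
  and a differential table, for end-to-end validation against known
  ground truth.

## Worked example

```r
library(sepeaks)
bundle <- generate_synthetic(synthetic_config(seed = 7))
res <- run_pipeline(bundle)
res
#> <pipeline_result>
#>   consensus peaks: control=691, treatment=691
#>   combined universe: 691 peaks
#>   decreased sites: 238
#>   promoters/enhancers: 240 / 371
#>   stitched regions: 240; super-enhancers: 40
#>   super-enhancers overlapping a decreased site: 0.750
```

Reading the output: 691 consensus ATAC peaks survive the two-replicate
rule in each condition; 238 of them lose accessibility at FDR < 0.05 and
fold < −1.5; the histone marks classify 240 promoters and 371 enhancers
(200 typical + 171 super-enhancer constituents); stitching collapses the
enhancers into 240 regions, of which the tangent cutoff calls 40
super-enhancers — exactly the 40 planted clusters — and 75 % of them
overlap a decreased site, matching the planted dependence rate.

The staged version of the same workflow lives in `analysis/01_simulate.R`
… `analysis/05_enrichment_profiles.R`; each script prints what it found
and writes its tables under `results/` (the bulky synthetic input bundle
itself is regenerated under `scratch/`).

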