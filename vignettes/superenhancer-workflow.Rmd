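---
title: "Methods: consensus peaks, enhancer classification, and super-enhancer calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus peaks, enhancer classification, and super-enhancer calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepeaks)
```

# Scope and model

`sepeaks` implements the downstream half of a regulatory-genomics
experiment in which chromatin accessibility (ATAC-seq) is profiled across
replicates before and after perturbing a chromatin remodeler, and
CUT&RUN peak sets for H3K4me3, H3K4me1 and H3K27ac are used to interpret
the accessibility changes. Everything upstream of peak sets — read
trimming, alignment, peak calling, and the negative-binomial differential
count model — is out of scope: the package consumes peak files and a
differential table (interval, log2 fold change, FDR) and produces
consensus sets, element classes, super-enhancer calls, and overlap
statistics.

All coordinates are BED-convention 0-based half-open at every file
boundary and in every constructor; internally intervals are `GRanges`.
Chromosome names compare as exact strings — no silent `chr` aliasing —
because aliasing corrupts overlap counts irrecoverably. Strand is ignored
by all overlap operations (peaks are unstranded); it is used only to sign
TSS distances.

# The pipeline stages and their parameters

**Consensus peaks** (`consensus_peaks`). Replicate peaks are clustered by
single-linkage >= 1 bp overlap; clusters drawing peaks from at least
`min_support` distinct replicates (default 2, the usual
"two of three replicates" rule) are kept, with the *union span* of the
cluster as the output interval. The union is deliberately conservative:
intersection spans shrink with replicate jitter and can split
downstream overlap counts. `combine_conditions` merges the per-condition
consensus sets at gap 0 into the peak universe used for counting and
enrichment.

**Differential filtering** (`filter_differential`). Dependent
("decreased") sites are records with FDR < `fdr_max` (default 0.05,
strict) and linear fold change <= −`fold_min` (default 1.5, i.e.
log2FC <= −log2 1.5 ≈ −0.585). The fold threshold is interpreted on the
linear scale because differential-binding tools conventionally report a
linear "Fold"; `fold_scale = "log2"` switches the interpretation for
tables that carry log2 thresholds directly. Decreased and increased sets
are disjoint by construction and both gates are monotone: relaxing either
never shrinks the selection.

**TSS annotation** (`annotate_nearest_tss`). Distance is measured from
the *peak center* (`floor((start+end)/2)`) to the nearest TSS on the same
chromosome, matching the HOMER-style convention; gene-body containment is
not considered. Exact ties break to the lexicographically smaller gene
id, which makes annotation deterministic and permutation-invariant. The
default distance bins are the conventional log-decades (1, 10, 100 kb).
"Proximal" means distance <= 1 kb — the threshold is a strict
"more than 1 kb" for distal, so a site at exactly 1000 bp is proximal.

**Element classification** (`classify_elements`). A site is a *promoter*
if it overlaps (>= 1 bp) both an H3K4me3 and an H3K27ac peak, and an
*enhancer* if it overlaps H3K27ac and H3K4me1, overlaps no H3K4me3 peak,
and is TSS-distal (> 1 kb from the center). Everything else — including
single-mark sites, for which the field defines no class — stays
`unclassified`. H3K4me3 absence is a binary peak-overlap test; a
signal-ratio alternative ("relatively lacked") would need matched
libraries and is not implemented. Because both rules require H3K27ac,
the candidate universe defaults to the H3K27ac peaks themselves.

**Super-enhancer calling** (`stitch_enhancers`, `score_regions`,
`call_superenhancers`). Active enhancers within 12.5 kb are stitched
(gap measured as `next start − previous end`); each stitched region is
scored as treatment CPM minus control CPM of fragment-midpoint counts
(`(n_t/N_t − n_c/N_c) × 10^6`). Midpoint membership is used because it is
unambiguous for fragments straddling region edges and exactly testable.
Negative scores (control exceeding treatment) are kept, not floored: they
rank lowest, and flooring would be a silent data-dependent filter. For
the cutoff, scores are sorted ascending and mapped to the unit square
(rank i → x = i/n; scores, shifted so the minimum is zero when negatives
exist, → y = s/max s). The cutoff is the tangent point of a slope-1 line
under the curve — the index maximizing x − y — and all regions above it
are super-enhancers. Tie handling is explicit: indices whose gap is
within 1e-12 of the maximum count as tied and resolve to the largest
index, so an exactly-linear curve (slope 1 everywhere) calls nothing,
and regions tied with the cutoff score fall on the non-super side. The
call is invariant to positive rescaling of scores, and every called
super-enhancer outscores every typical region.

Two orderings were possible for "normalize and subtract": we subtract
*CPM-normalized* values (subtract after per-library normalization). The
other order (subtract raw counts, then normalize) changes scores by a
library-size-dependent factor and is not scale-free across libraries.
Promoter-proximal constituents are not re-excluded at the stitching
stage; the enhancer definition already removed them upstream.

**Enrichment** (`hypergeometric_enrichment`, `bh_adjust`,
`multiway_overlap_counts`, `signal_profile`). Overlap significance is the
exact upper-tail hypergeometric probability P(X >= k), computed from the
log-space tail (no normal approximation); the test is one-sided for
enrichment, with `lower = TRUE` for depletion. The universe is always an
explicit argument — interval-level tests here use the combined consensus
peak set — because the p-value is acutely sensitive to it and no default
can be defended silently. Multiple testing uses Benjamini–Hochberg.
Multiway (UpSet-style) interval counts are reported *per source set*:
">= 1 bp overlap" is not an equivalence relation, so cell counts can
legitimately differ depending on which set's intervals are being counted,
and both directions are reported rather than guessed between. Signal
metaprofiles count fragment midpoints in 100 bp bins across ±2 kb from
site centers and average CPM across sites, with no per-site rescaling.

# The synthetic genome

`generate_synthetic` builds the study conditions the pipeline is
validated under. Defaults: 4 chromosomes × 10 Mb; 240 genes placed with
>= 20 kb spacing; 200 typical enhancers; 40 super-enhancer clusters of
3–6 constituents with intra-cluster gaps drawn uniformly from 1–12 kb
(below the 12.5 kb stitch distance, so every planted cluster must stitch
into exactly one region); planted blocks separated by >= 20 kb (above the
stitch distance, so nothing stitches *across* blocks and the expected
stitched-region count is exactly `n_typical + n_clusters`). Promoters
carry H3K4me3+H3K27ac at the TSS; enhancers and constituents carry
H3K27ac+H3K4me1; constituent H3K27ac fragment intensity is 10× the
typical level, so planted clusters dominate the ranked-signal curve by
roughly cluster-size × 10. ATAC sites exist at every planted element plus
uniformly placed background peaks (rejection-sampled away from planted
sites so site identities stay unambiguous).

Dependence is planted at 75% of typical enhancers (site-level) and 75% of
clusters (cluster-level, constituents inherit), echoing the qualitative
"roughly three quarters of super-enhancers lose accessibility" regime
this class of experiment reports; promoters and background sites never
change. Replicate counts are negative-binomial around lognormal site
means (size parameter 20 by default — mild overdispersion typical of
accessibility counts), with treatment means scaled by `2^planted_log2fc`
(default −2) at dependent sites; a peak appears in a replicate when its
count clears a fixed detection threshold, with small uniform edge jitter
so consensus union spans are exercised. The differential table is a
deliberate stand-in for an external count model: a Welch t-test on
log2(count+1) across replicates with BH adjustment. It is labelled as
such; its only job is to produce an FDR/log2FC table with realistic null
behaviour (empirical FDR on null sites is checked in the tests), not to
reproduce a negative-binomial fit.

With 3-vs-3 replicates, a planted log2FC of −2 and dispersion 20, the
per-site power of the stand-in test is high but not 1 (~85–90% at the
FDR+fold gates); cluster-level recovery is effectively 1 because a
cluster counts as "decreased" if any of its 3–6 constituents passes. That
is why the reported super-enhancer dependent fraction concentrates
tightly on the planted 0.75.

What the generator does *not* emulate: sequence content, GC and
mappability bias, fragment-length distributions, peak-shape profiles,
copy-number variation, and inter-replicate correlation structure beyond
NB noise. Passing the planted-recovery checks therefore demonstrates the
*algorithmic* correctness of the pipeline under its stated assumptions,
not performance on real libraries.

# Numerical choices and degenerate inputs

- Sorting is by (chromosome lexicographic, start, end, name) everywhere;
  all operations are permutation-stable.
- `merge_adjacent(S, 0)` merges overlapping *and* book-ended intervals
  (gap <= 0); replicate clustering uses strict overlap (gap < 0), because
  book-ended peaks share no base.
- Tangent-cutoff ties: tolerance 1e-12 on the unit square (see above).
  Fewer than two regions, or an all-equal score vector, yields zero
  super-enhancers with a warning rather than an error.
- Peaks on chromosomes with no annotated gene get `NA` gene and infinite
  distance with a warning; they count as distal and are excluded from
  bin percentages.
- Hypergeometric inputs are validated against the support of the
  distribution (k between max(0, K+n−N) and min(K, n)); violations are
  usage errors, not silent clamps.

# Validation scale

The shipped tests validate the interval algebra against per-base bitmap
and union-find oracles on 1000 random instances per operation, the
hypergeometric tail against exhaustive enumeration for all universes up
to N = 12 and a 10^6-draw sampling check at N = 1000, BH against an
independently coded step-up rule on 1000 random vectors, the
super-enhancer caller against an exhaustive per-index tangent oracle and
its analytic limits over 100 seeded instances, and the full pipeline on
the default synthetic genome (691 peaks, 240 stitched regions) plus five
independent seeds for the dependent-fraction recovery. These sizes keep
the whole suite within a few minutes while leaving every code path
exercised; the generator scales to larger genomes if heavier validation
is wanted.

# Known limitations

- The enhancer rule is binary peak-overlap; borderline H3K4me3 signal at
  weak promoters will classify differently than a signal-ratio rule.
- Nearest-TSS annotation ignores gene bodies; a peak inside a long gene
  may annotate to a neighbouring gene's closer TSS.
- The differential stand-in underestimates dispersion uncertainty at
  very low counts; it is not a substitute for count-model inference on
  real data — real differential tables should be supplied as input.
- Super-enhancer target-gene assignment (e.g. via chromatin loops) is
  out of scope; calls are reported as regions only.

# A worked run

```{r, eval = FALSE}
bundle <- generate_synthetic(synthetic_config(seed = 1))
res <- run_pipeline(bundle)
res$summary
```

See the repository's `analysis/` scripts for the staged version of the
same workflow, writing each stage's tables under `results/`.
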