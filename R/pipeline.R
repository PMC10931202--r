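#' Run the full regulatory-genomics pipeline on an input bundle
#'
#' Orchestrates the stages end-to-end: replicate-consensus peaks per
#' condition, the combined peak universe, differential filtering to
#' dependent ("decreased") sites, nearest-TSS annotation and distance
#' binning, promoter/enhancer classification from the histone marks,
#' enhancer stitching, signal scoring and super-enhancer calling, and the
#' overlap summaries relating super-enhancers and enhancers to decreased
#' sites (including a hypergeometric enrichment of decreased sites among
#' enhancers over the combined universe).
#'
#' The pipeline is a pure function of its inputs and thresholds; with a
#' deterministic bundle the result (and any files written via `out_dir`)
#' is reproducible.
#'
#' @param bundle A `synthetic_bundle`, or any list with the same
#'   components (`genes`, `marks`, `atac_replicates`, `differential`,
#'   `fragments`).
#' @param fdr_max,fold_min Differential gates (defaults 0.05 and 1.5; see
#'   [filter_differential()]).
#' @param proximal_bp TSS-proximity threshold, default 1000.
#' @param stitch_bp Enhancer stitching distance, default 12500.
#' @param min_support Replicate support for consensus peaks, default 2.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written as BED/TSV plus an md5 `manifest.tsv`.
#' @return A list of class `pipeline_result` with stage outputs
#'   (`consensus`, `combined`, `decreased`, `annotated`, `tss_bins`,
#'   `elements`, `se_call`, `hockey`, `enrichment`) and a `summary` list
#'   of the headline counts, including `se_decreased_fraction`, the
#'   fraction of called super-enhancers overlapping a decreased site.
#' @export
run_pipeline <- function(bundle, fdr_max = 0.05, fold_min = 1.5,
                         proximal_bp = 1000, stitch_bp = 12500,
                         min_support = 2L, out_dir = NULL) {
  stopifnot(fdr_max > 0, proximal_bp > 0, stitch_bp >= 0)
  chrom_ok <- unique(unlist(lapply(bundle$marks, function(g)
    as.character(seqnames(g)))))
  gene_chr <- unique(bundle$genes$chrom)
  if (!all(gene_chr %in% chrom_ok) && length(chrom_ok) > 0) {
    stop("chromosome namespace mismatch between gene table and marks: ",
         paste(setdiff(gene_chr, chrom_ok), collapse = ", "),
         call. = FALSE)
  }

  consensus <- lapply(names(bundle$atac_replicates), function(cond) {
    consensus_peaks(bundle$atac_replicates[[cond]],
                    min_support = min_support, condition = cond)
  })
  names(consensus) <- names(bundle$atac_replicates)
  combined <- combine_conditions(consensus)

  decreased <- filter_differential(bundle$differential, fdr_max = fdr_max,
                                   fold_min = fold_min,
                                   direction = "decreased")

  annotated <- annotate_nearest_tss(combined, bundle$genes)
  tss_bins <- bin_tss_distances(annotated)

  elements <- classify_elements(bundle$marks$h3k4me3, bundle$marks$h3k4me1,
                                bundle$marks$h3k27ac, bundle$genes,
                                proximal_bp = proximal_bp)
  enhancers <- element_ranges(elements, "enhancer")

  stitched <- stitch_enhancers(enhancers, stitch_bp = stitch_bp)
  stitched <- score_regions(stitched, bundle$fragments$h3k27ac,
                            bundle$fragments$input)
  se_call <- call_superenhancers(stitched)
  hockey <- hockey_stick_report(se_call)

  supers <- se_call$regions[mcols(se_call$regions)$is_super]
  se_dec <- if (length(supers) > 0 && length(decreased) > 0) {
    intersect_sets(supers, decreased)
  } else NULL
  se_frac <- if (length(supers) > 0) {
    if (is.null(se_dec)) 0 else se_dec$n_a_overlap / length(supers)
  } else NA_real_

  enh_dec <- if (length(enhancers) > 0 && length(decreased) > 0) {
    intersect_sets(enhancers, decreased)
  } else NULL
  enrichment <- if (!is.null(enh_dec)) {
    # universe: combined consensus peak set; membership by >= 1 bp overlap
    in_enh <- intersect_sets(combined, enhancers)$a_hit
    in_dec <- intersect_sets(combined, decreased)$a_hit
    hypergeometric_enrichment(length(combined), sum(in_enh), sum(in_dec),
                              sum(in_enh & in_dec))
  } else NULL

  summary <- list(
    n_replicate_peaks = vapply(unlist(bundle$atac_replicates,
                                      recursive = FALSE), length, 1L),
    n_consensus = vapply(consensus, function(x) length(x$peaks), 1L),
    n_combined = length(combined),
    n_decreased = length(decreased),
    n_promoters = sum(elements$element_class == "promoter"),
    n_enhancers = sum(elements$element_class == "enhancer"),
    n_stitched = length(stitched),
    n_super = se_call$n_super,
    se_cutoff_score = se_call$cutoff_score,
    se_decreased_fraction = se_frac,
    enrichment_p = if (!is.null(enrichment)) enrichment$p_value else NA
  )

  res <- structure(list(consensus = consensus, combined = combined,
                        decreased = decreased, annotated = annotated,
                        tss_bins = tss_bins, elements = elements,
                        se_call = se_call, hockey = hockey,
                        enrichment = enrichment, summary = summary),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_result>\n")
  cat(sprintf("  consensus peaks: %s\n",
              paste(sprintf("%s=%d", names(s$n_consensus), s$n_consensus),
                    collapse = ", ")))
  cat(sprintf("  combined universe: %d peaks\n", s$n_combined))
  cat(sprintf("  decreased sites: %d\n", s$n_decreased))
  cat(sprintf("  promoters/enhancers: %d / %d\n", s$n_promoters,
              s$n_enhancers))
  cat(sprintf("  stitched regions: %d; super-enhancers: %d\n",
              s$n_stitched, s$n_super))
  cat(sprintf("  super-enhancers overlapping a decreased site: %.3f\n",
              s$se_decreased_fraction))
  invisible(x)
}

#' Write pipeline stage outputs and an md5 manifest
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_bed <- function(gr, name) {
    p <- file.path(out_dir, name)
    write_peaks(gr, p)
    files <<- c(files, p)
  }
  put_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
  }
  put_bed(result$combined, "combined_peaks.bed")
  put_bed(result$decreased, "decreased_sites.bed")
  put_tsv(result$elements, "elements.tsv")
  put_tsv(result$tss_bins, "tss_distance_bins.tsv")
  put_tsv(result$hockey$table, "stitched_regions.tsv")
  if (!is.null(result$enrichment)) {
    put_tsv(result$enrichment, "enrichment.tsv")
  }
  su <- result$summary
  put_tsv(data.frame(
    metric = c("n_combined", "n_decreased", "n_promoters", "n_enhancers",
               "n_stitched", "n_super", "se_cutoff_score",
               "se_decreased_fraction"),
    value = c(su$n_combined, su$n_decreased, su$n_promoters,
              su$n_enhancers, su$n_stitched, su$n_super,
              su$se_cutoff_score, su$se_decreased_fraction)),
    "summary.tsv")
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
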