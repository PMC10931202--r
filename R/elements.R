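#' Classify sites into promoters, enhancers, or unclassified
#'
#' Applies the histone-mark co-occurrence rules used to separate active
#' regulatory elements:
#'
#' * promoter: overlaps both an H3K4me3 peak and an H3K27ac peak;
#' * enhancer: overlaps H3K27ac and H3K4me1 peaks, does **not** overlap
#'   any H3K4me3 peak, and its center lies more than `proximal_bp`
#'   (default 1 kb) from every TSS;
#' * everything else: unclassified (sites with a single mark get no
#'   invented class).
#'
#' Mark presence is >= 1 bp overlap with the mark's peak set. Since both
#' rules require H3K27ac, the candidate universe defaults to the H3K27ac
#' peaks themselves.
#'
#' @param h3k4me3,h3k4me1,h3k27ac Sorted `GRanges` of the mark peak sets.
#' @param genes Gene table (see [read_gene_table()]).
#' @param candidate_sites Optional `GRanges` of sites to classify;
#'   defaults to `h3k27ac`.
#' @param proximal_bp TSS-proximity threshold in bp, default 1000.
#' @return A data.frame with one row per candidate: BED coordinates, the
#'   logical mark columns, `tss_distance`, and `element_class`.
#' @export
classify_elements <- function(h3k4me3, h3k4me1, h3k27ac, genes,
                              candidate_sites = NULL, proximal_bp = 1000) {
  if (is.null(candidate_sites)) candidate_sites <- h3k27ac
  if (length(h3k27ac) == 0) {
    warning("empty H3K27ac set: no active elements detectable",
            call. = FALSE)
  }
  cand <- sort_peaks(candidate_sites)
  has <- function(marks) {
    if (length(marks) == 0) rep(FALSE, length(cand))
    else GenomicRanges::countOverlaps(cand, marks, minoverlap = 1L,
                                      ignore.strand = TRUE) > 0
  }
  me3 <- has(h3k4me3)
  me1 <- has(h3k4me1)
  ac <- has(h3k27ac)
  ann <- annotate_nearest_tss(cand, genes)
  distal <- classify_tss_proximity(ann, proximal_bp) == "distal"
  cls <- rep("unclassified", length(cand))
  cls[ac & me3] <- "promoter"
  cls[ac & me1 & !me3 & distal] <- "enhancer"
  df <- as_bed_df(cand)
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             H3K4me3 = me3, H3K4me1 = me1, H3K27ac = ac,
             tss_distance = ann$abs_distance,
             element_class = cls, stringsAsFactors = FALSE)
}

#' Extract one element class as a GRanges
#'
#' @param elements Output of [classify_elements()].
#' @param class One of `"promoter"`, `"enhancer"`, `"unclassified"`.
#' @return A sorted `GRanges` named by the class.
#' @export
element_ranges <- function(elements,
                           class = c("enhancer", "promoter",
                                     "unclassified")) {
  class <- match.arg(class)
  sel <- elements[elements$element_class == class, , drop = FALSE]
  if (nrow(sel) == 0) return(GenomicRanges::GRanges())
  peak_ranges(sel$chrom, sel$start, sel$end,
              name = rep(class, nrow(sel)))
}
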