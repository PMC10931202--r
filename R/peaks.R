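#' Replicate-consensus peaks
#'
#' Clusters peaks across replicates by single-linkage overlap (>= 1 bp)
#' and keeps clusters supported by at least `min_support` distinct
#' replicates — the standard "minimum of two replicates per condition"
#' rule. The output interval is the union span of each retained cluster.
#'
#' @param replicates A list of `GRanges`, one per replicate.
#' @param min_support Minimum number of distinct replicates a cluster must
#'   draw peaks from (default 2).
#' @param condition Optional condition label carried in the result.
#' @return An object of class `consensus_peaks`: a list with `peaks` (a
#'   sorted `GRanges` with a `support` metadata column), `condition`, and
#'   `n_replicates`.
#' @export
consensus_peaks <- function(replicates, min_support = 2L, condition = NA) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  if (min_support > length(replicates)) {
    stop("min_support exceeds the number of replicates", call. = FALSE)
  }
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  rep_id <- rep(seq_along(replicates), vapply(replicates, length, 1L))
  all_peaks <- suppressWarnings(do.call(c, unname(lapply(replicates,
                                                         function(g) {
    mcols(g) <- NULL
    g
  }))))
  if (length(all_peaks) == 0) {
    return(structure(list(peaks = GenomicRanges::GRanges(),
                          condition = condition,
                          n_replicates = length(replicates)),
                     class = "consensus_peaks"))
  }
  o <- order(as.integer(seqnames(all_peaks)), BiocGenerics::start(all_peaks),
             BiocGenerics::end(all_peaks))
  all_peaks <- all_peaks[o]
  rep_id <- rep_id[o]
  # min.gapwidth = 0: merge only truly overlapping peaks (book-ended peaks
  # share no base and stay separate)
  clusters <- GenomicRanges::reduce(all_peaks, min.gapwidth = 0L,
                                    with.revmap = TRUE, ignore.strand = TRUE)
  support <- vapply(mcols(clusters)$revmap,
                    function(i) length(unique(rep_id[i])), 1L)
  keep <- support >= min_support
  out <- clusters[keep]
  mcols(out) <- NULL
  mcols(out)$support <- support[keep]
  structure(list(peaks = sort_peaks(out), condition = condition,
                 n_replicates = length(replicates)),
            class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat(sprintf("<consensus_peaks: %d peaks from %d replicates%s>\n",
              length(x$peaks), x$n_replicates,
              if (!is.na(x$condition)) paste0(", condition ", x$condition)
              else ""))
  invisible(x)
}

#' Combine consensus sets across conditions into a final peak universe
#'
#' Union of all consensus peak sets, merged at gap 0 and sorted; this is
#' the universe used for counting and enrichment.
#'
#' @param consensus_sets A list of `consensus_peaks` objects (or bare
#'   `GRanges`).
#' @return A sorted `GRanges`.
#' @export
combine_conditions <- function(consensus_sets) {
  stopifnot(length(consensus_sets) >= 1)
  grs <- lapply(consensus_sets, function(x) {
    g <- if (inherits(x, "consensus_peaks")) x$peaks else x
    mcols(g) <- NULL
    g
  })
  merged <- merge_adjacent(suppressWarnings(do.call(c, unname(grs))),
                           max_gap = 0)
  mcols(merged) <- NULL
  merged
}

#' Filter a differential-peak table at FDR and fold-change thresholds
#'
#' Selects "dependent" accessible sites with the conventional gates
#' FDR < `fdr_max` and linear |fold change| >= `fold_min` (i.e.
#' |log2fc| >= log2(fold_min)). `direction = "decreased"` keeps sites
#' losing accessibility (log2fc <= -log2(fold_min)), `"increased"` the
#' mirror image, `"both"` their union.
#'
#' @param table A data.frame with columns `chrom`, `start`, `end` (BED
#'   coordinates), `log2fc`, `fdr`.
#' @param fdr_max FDR gate, default 0.05 (strict `<`).
#' @param fold_min Linear fold-change gate, must be > 1; default 1.5. Set
#'   `fold_scale = "log2"` to interpret `fold_min` directly on the log2
#'   scale.
#' @param direction One of `"decreased"`, `"increased"`, `"both"`.
#' @param fold_scale `"linear"` (default) or `"log2"`.
#' @return A sorted `GRanges` of the passing intervals, with `log2fc` and
#'   `fdr` metadata columns.
#' @export
filter_differential <- function(table, fdr_max = 0.05, fold_min = 1.5,
                                direction = c("decreased", "increased",
                                              "both"),
                                fold_scale = c("linear", "log2")) {
  direction <- match.arg(direction)
  fold_scale <- match.arg(fold_scale)
  need <- c("chrom", "start", "end", "log2fc", "fdr")
  stopifnot(all(need %in% names(table)))
  if (fold_scale == "linear") {
    if (fold_min <= 1) stop("fold_min must be > 1 on the linear scale",
                            call. = FALSE)
    lfc_min <- log2(fold_min)
  } else {
    if (fold_min < 0) stop("log2 fold_min must be >= 0", call. = FALSE)
    lfc_min <- fold_min
  }
  sig <- table$fdr < fdr_max
  dec <- sig & table$log2fc <= -lfc_min
  inc <- sig & table$log2fc >= lfc_min
  keep <- switch(direction, decreased = dec, increased = inc,
                 both = dec | inc)
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) == 0) return(GenomicRanges::GRanges())
  peak_ranges(tab$chrom, tab$start, tab$end,
              name = if ("name" %in% names(tab)) tab$name else NULL,
              score = tab$log2fc) -> gr
  # re-attach stats in sorted order
  key <- paste(tab$chrom, tab$start, tab$end)
  m <- match(paste(as.character(seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr)), key)
  mcols(gr)$log2fc <- tab$log2fc[m]
  mcols(gr)$fdr <- tab$fdr[m]
  mcols(gr)$score <- NULL
  gr
}
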