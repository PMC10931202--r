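#' Annotate peaks with their nearest TSS
#'
#' Assigns every peak the gene whose TSS is closest to the peak center
#' (`floor((start + end) / 2)` in BED coordinates) on the same chromosome,
#' the convention used by HOMER-style distance-to-TSS annotation. The
#' signed distance is `center - tss`, with the sign flipped for genes on
#' the minus strand so that positive always means downstream of the TSS.
#' Exact distance ties break to the lexicographically smaller `gene_id`.
#'
#' @param peaks A sorted `GRanges`.
#' @param genes A data.frame with columns `gene_id`, `chrom`, `tss`,
#'   `strand` (one row per TSS).
#' @return A data.frame with one row per peak: `chrom`, `start`, `end`,
#'   `center`, `nearest_gene`, `signed_distance`, `abs_distance`. Peaks on
#'   chromosomes without genes get `NA` gene and infinite distance, with a
#'   warning.
#' @export
annotate_nearest_tss <- function(peaks, genes) {
  stopifnot(nrow(genes) >= 1)
  df <- as_bed_df(peaks)
  n <- nrow(df)
  center <- floor((df$start + df$end) / 2)
  nearest_gene <- rep(NA_character_, n)
  signed <- rep(Inf, n)
  # per chromosome: sorted TSS vector + findInterval, then a local scan to
  # collect all equally-near TSSs for deterministic tie-breaking
  genes <- genes[order(genes$chrom, genes$tss, genes$gene_id), , drop = FALSE]
  by_chr <- split(genes, genes$chrom)
  for (chr in unique(df$chrom)) {
    idx <- which(df$chrom == chr)
    g <- by_chr[[chr]]
    if (is.null(g)) next
    tssv <- g$tss
    ids <- g$gene_id
    strv <- g$strand
    lo <- findInterval(center[idx], tssv)
    for (j in seq_along(idx)) {
      p <- idx[j]
      c0 <- center[p]
      i_lo <- lo[j]
      d_lo <- if (i_lo >= 1) c0 - tssv[i_lo] else Inf
      d_hi <- if (i_lo < length(tssv)) tssv[i_lo + 1] - c0 else Inf
      dmin <- min(d_lo, d_hi)
      # gather every TSS at distance dmin (duplicated TSS positions and
      # left/right ties) and take the smallest gene_id
      cand <- integer(0)
      k <- i_lo
      while (k >= 1 && c0 - tssv[k] == dmin) {
        cand <- c(cand, k); k <- k - 1
      }
      k <- i_lo + 1
      while (k <= length(tssv) && tssv[k] - c0 == dmin) {
        cand <- c(cand, k); k <- k + 1
      }
      best <- cand[order(ids[cand])][1]
      nearest_gene[p] <- ids[best]
      d <- c0 - tssv[best]
      signed[p] <- if (strv[best] == "-") -d else d
    }
  }
  if (anyNA(nearest_gene)) {
    warning(sum(is.na(nearest_gene)),
            " peak(s) on chromosomes with no annotated gene", call. = FALSE)
  }
  data.frame(chrom = df$chrom, start = df$start, end = df$end,
             center = center, nearest_gene = nearest_gene,
             signed_distance = signed, abs_distance = abs(signed),
             stringsAsFactors = FALSE)
}

#' Bin absolute TSS distances and report percentages
#'
#' Default edges give the conventional log-decade bins
#' `[0,1kb]`, `(1kb,10kb]`, `(10kb,100kb]`, `>100kb`. Percentages are over
#' peaks with a non-missing annotation and sum to 100.
#'
#' @param annotated Output of [annotate_nearest_tss()].
#' @param edges Strictly increasing positive distance thresholds in bp.
#' @return A data.frame with `bin`, `n`, `percent`.
#' @export
bin_tss_distances <- function(annotated, edges = c(1e3, 1e4, 1e5)) {
  stopifnot(all(edges > 0), !is.unsorted(edges, strictly = TRUE))
  d <- annotated$abs_distance
  d <- d[!is.na(annotated$nearest_gene) & is.finite(d)]
  brk <- c(-1, edges, Inf)
  fmt <- function(x) {
    ifelse(x >= 1000, paste0(x / 1000, "kb"), paste0(x, "bp"))
  }
  labs <- c(paste0("0-", fmt(edges[1])),
            if (length(edges) > 1)
              paste0(fmt(edges[-length(edges)]), "-", fmt(edges[-1])),
            paste0(">", fmt(edges[length(edges)])))
  bins <- cut(d, breaks = brk, labels = labs)
  n <- as.integer(table(bins))
  data.frame(bin = labs, n = n,
             percent = if (sum(n) > 0) 100 * n / sum(n) else rep(0, length(n)),
             stringsAsFactors = FALSE)
}

#' Classify peaks as TSS-proximal or distal
#'
#' Distal means strictly more than `proximal_bp` from the nearest TSS
#' (a peak exactly at the threshold is proximal).
#'
#' @param annotated Output of [annotate_nearest_tss()].
#' @param proximal_bp Distance threshold in bp, default 1000.
#' @return Character vector, `"proximal"` or `"distal"` per peak (`NA`
#'   annotations are distal: no TSS on the chromosome at all).
#' @export
classify_tss_proximity <- function(annotated, proximal_bp = 1000) {
  stopifnot(proximal_bp > 0)
  ifelse(annotated$abs_distance > proximal_bp, "distal", "proximal")
}
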