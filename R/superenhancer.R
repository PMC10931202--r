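# Super-enhancer calling in the Whyte/ROSE tradition: stitch active
# enhancers within 12.5 kb, score each stitched region by input-subtracted
# CPM-normalized signal, rank, and cut the normalized rank-signal
# ("hockey-stick") curve at the point where a line of slope 1 is tangent.

#' Stitch active enhancers into candidate super-enhancer regions
#'
#' Merges enhancers separated by at most `stitch_bp` (default 12.5 kb)
#' into larger regions; singleton enhancers become single-constituent
#' regions. TSS-proximal sites are assumed already removed upstream by the
#' enhancer definition, so no promoter exclusion happens here.
#'
#' @param enhancers A sorted `GRanges` of active enhancers.
#' @param stitch_bp Maximum gap in bp for stitching, default 12500.
#' @return A sorted `GRanges` of stitched regions with `n_constituents`
#'   and `revmap` metadata columns (indices into the sorted input).
#' @export
stitch_enhancers <- function(enhancers, stitch_bp = 12500) {
  if (length(enhancers) == 0) return(GenomicRanges::GRanges())
  merge_adjacent(enhancers, max_gap = stitch_bp)
}

#' Score regions by input-subtracted normalized signal
#'
#' For each region, counts treatment and control fragments whose midpoint
#' falls inside the region, converts both to counts per million of their
#' library, and subtracts:
#' `score = (n_treat / treat_size - n_ctrl / ctrl_size) * 1e6`.
#' Negative scores (control exceeding treatment) are retained and rank
#' lowest.
#'
#' @param regions A `GRanges` of stitched regions.
#' @param treatment,control [signal_library()] objects (e.g. H3K27ac and
#'   input/IgG).
#' @return The regions with a `signal_score` metadata column added.
#' @export
score_regions <- function(regions, treatment, control) {
  stopifnot(inherits(treatment, "signal_library"),
            inherits(control, "signal_library"))
  nt <- GenomicRanges::countOverlaps(
    regions, fragment_midpoints(treatment$fragments), ignore.strand = TRUE)
  nc <- GenomicRanges::countOverlaps(
    regions, fragment_midpoints(control$fragments), ignore.strand = TRUE)
  mcols(regions)$signal_score <-
    (nt / treatment$library_size - nc / control$library_size) * 1e6
  regions
}

#' Slope-1 tangent cutoff on the normalized rank-signal curve
#'
#' Given scores sorted ascending and scaled to `[0, 1]` on both axes
#' (rank `i` maps to `x_i = i/n`; scores, shifted so the minimum is 0 when
#' negatives exist, map to `y_i = s_i / max(s)`), the cutoff is the point
#' where a line of slope 1 is tangent to the curve from below — the
#' index maximizing `x_i - y_i`. Ties (including the exactly-linear curve,
#' where `x_i - y_i` is constant) resolve to the largest index, so a
#' linear curve yields zero super-enhancers. Everything above the cutoff
#' index is super.
#'
#' @param scores Numeric vector of region scores.
#' @return A list: `order` (ascending permutation), `cutoff_index` (into
#'   the sorted scores), `cutoff_score`, `is_super` (logical, in input
#'   order), `scaled_rank`, `scaled_signal` (in sorted order).
#' @keywords internal
tangent_cutoff <- function(scores) {
  n <- length(scores)
  o <- order(scores)
  s <- scores[o]
  shift <- if (s[1] < 0) -s[1] else 0
  y_raw <- s + shift
  x <- seq_len(n) / n
  if (max(y_raw) <= 0) {
    # all-equal (or all-nonpositive) scores: no curve, nothing is super
    return(list(order = o, cutoff_index = n, cutoff_score = s[n],
                is_super = rep(FALSE, n), scaled_rank = x,
                scaled_signal = rep(0, n)))
  }
  y <- y_raw / max(y_raw)
  gap <- x - y
  # ties within numerical tolerance (both axes live on [0,1]) resolve to
  # the largest index, so an exactly-linear curve calls nothing
  cutoff <- max(which(gap >= max(gap) - 1e-12))
  cutoff_score <- s[cutoff]
  super_sorted <- seq_len(n) > cutoff & s > cutoff_score
  is_super <- rep(FALSE, n)
  is_super[o] <- super_sorted
  list(order = o, cutoff_index = cutoff, cutoff_score = cutoff_score,
       is_super = is_super, scaled_rank = x, scaled_signal = y)
}

#' Call super-enhancers from scored stitched regions
#'
#' Sorts regions ascending by `signal_score`, rescales rank and score to
#' the unit square, and flags as super-enhancers all regions past the
#' slope-1 tangent point of the curve (see [tangent_cutoff()]). Regions
#' tied with the cutoff score fall on the non-super side.
#'
#' @param regions A `GRanges` with a `signal_score` metadata column (from
#'   [score_regions()]).
#' @return An object of class `se_call`: a list with `regions` (the input
#'   plus `rank`, `scaled_rank`, `scaled_signal`, `is_super` columns),
#'   `cutoff_score`, `cutoff_index`, `n_super`, `n_typical`. With fewer
#'   than 2 regions everything is flagged not-super, with a warning.
#' @export
call_superenhancers <- function(regions) {
  stopifnot(!is.null(mcols(regions)$signal_score))
  n <- length(regions)
  if (n < 2) {
    warning("fewer than 2 regions: no super-enhancers callable",
            call. = FALSE)
    if (n == 1) {
      mcols(regions)$rank <- 1L
      mcols(regions)$scaled_rank <- 1
      mcols(regions)$scaled_signal <- 1
      mcols(regions)$is_super <- FALSE
    }
    return(structure(list(regions = regions, cutoff_score = NA_real_,
                          cutoff_index = NA_integer_, n_super = 0L,
                          n_typical = n),
                     class = "se_call"))
  }
  tc <- tangent_cutoff(mcols(regions)$signal_score)
  rank <- integer(n)
  rank[tc$order] <- seq_len(n)
  mcols(regions)$rank <- rank
  mcols(regions)$scaled_rank <- tc$scaled_rank[rank]
  mcols(regions)$scaled_signal <- tc$scaled_signal[rank]
  mcols(regions)$is_super <- tc$is_super
  structure(list(regions = regions, cutoff_score = tc$cutoff_score,
                 cutoff_index = tc$cutoff_index,
                 n_super = sum(tc$is_super),
                 n_typical = n - sum(tc$is_super)),
            class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat(sprintf(
    "<se_call: %d regions, %d super-enhancers (cutoff score %.3f)>\n",
    length(x$regions), x$n_super,
    if (is.na(x$cutoff_score)) NA else x$cutoff_score))
  invisible(x)
}

#' Hockey-stick plot data for a super-enhancer call
#'
#' Emits the ordered rank/score table behind the ranked-signal
#' ("hockey-stick") plot, plus the cutoff and super/typical counts.
#'
#' @param call An `se_call` from [call_superenhancers()].
#' @return A list with `table` (data.frame sorted by rank: `rank`,
#'   `signal_score`, `scaled_rank`, `scaled_signal`, `is_super`, BED
#'   coordinates), `cutoff_score`, `n_super`, `n_typical`.
#' @export
hockey_stick_report <- function(call) {
  stopifnot(inherits(call, "se_call"))
  gr <- call$regions
  if (length(gr) == 0) {
    return(list(table = data.frame(rank = integer(), signal_score = numeric(),
                                   scaled_rank = numeric(),
                                   scaled_signal = numeric(),
                                   is_super = logical()),
                cutoff_score = call$cutoff_score, n_super = 0L,
                n_typical = 0L))
  }
  df <- cbind(as_bed_df(gr)[c("chrom", "start", "end")],
              as.data.frame(mcols(gr)[c("rank", "signal_score",
                                        "scaled_rank", "scaled_signal",
                                        "is_super")]))
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  list(table = df, cutoff_score = call$cutoff_score,
       n_super = call$n_super, n_typical = call$n_typical)
}
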