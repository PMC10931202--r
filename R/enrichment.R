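#' @importFrom stats phyper p.adjust rnbinom rpois runif setNames pt
NULL

#' Hypergeometric overlap enrichment
#'
#' Exact upper-tail hypergeometric test for the overlap between two sets
#' drawn from a finite universe: with `X ~ Hypergeometric(N = universe_n,
#' K = set_a_n, n = set_b_n)`, reports `p = P(X >= overlap_k)` (the
#' enrichment direction; `lower = TRUE` gives the depletion tail
#' `P(X <= k)`). Computed via the exact tail of the distribution, not a
#' normal approximation; the roles of the two sets are exchangeable.
#'
#' @param universe_n Universe size `N`.
#' @param set_a_n,set_b_n Sizes of the two sets.
#' @param overlap_k Observed overlap.
#' @param lower If `TRUE` test for depletion instead.
#' @return A one-row data.frame: `universe_n`, `set_a_n`, `set_b_n`,
#'   `overlap_k`, `expected_k`, `p_value`.
#' @examples
#' hypergeometric_enrichment(10, 5, 4, 3)  # p = 55/210
#' @export
hypergeometric_enrichment <- function(universe_n, set_a_n, set_b_n,
                                      overlap_k, lower = FALSE) {
  stopifnot(length(universe_n) == 1, length(overlap_k) == 1)
  if (set_a_n > universe_n || set_b_n > universe_n) {
    stop("set sizes cannot exceed the universe", call. = FALSE)
  }
  if (overlap_k > min(set_a_n, set_b_n)) {
    stop("overlap exceeds the smaller set", call. = FALSE)
  }
  if (overlap_k < max(0, set_a_n + set_b_n - universe_n)) {
    stop("overlap below the forced minimum for these counts",
         call. = FALSE)
  }
  p <- if (lower) {
    phyper(overlap_k, set_a_n, universe_n - set_a_n, set_b_n)
  } else {
    # P(X >= k) computed stably from the log upper tail
    exp(phyper(overlap_k - 1, set_a_n, universe_n - set_a_n, set_b_n,
               lower.tail = FALSE, log.p = TRUE))
  }
  data.frame(universe_n = universe_n, set_a_n = set_a_n,
             set_b_n = set_b_n, overlap_k = overlap_k,
             expected_k = set_a_n * set_b_n / universe_n,
             p_value = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: sort ascending, take
#' `adj_i = min_{j >= i} (p_j * m / j)` capped at 1, return in the
#' original order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Exclusive multiway overlap counts (UpSet-style)
#'
#' For 2-4 named sets, partitions members into the `2^m - 1` exclusive
#' combination cells. Character vectors are treated as gene-id sets and
#' partitioned exactly. `GRanges` inputs are interval sets: each interval
#' is assigned to the combination of all sets it overlaps by >= 1 bp, and
#' counts are reported per source set (interval overlap is not an
#' equivalence relation, so cell sizes may differ between sources).
#'
#' @param named_sets A named list of 2-4 character vectors, or of 2-4
#'   `GRanges`.
#' @return For gene sets: a data.frame `combination`, `degree`, `n`. For
#'   interval sets: a data.frame `combination`, `degree`, `source_set`,
#'   `n`.
#' @export
multiway_overlap_counts <- function(named_sets) {
  m <- length(named_sets)
  if (m < 2 || m > 4) {
    stop("between 2 and 4 named sets are required", call. = FALSE)
  }
  nms <- names(named_sets)
  if (is.null(nms) || anyDuplicated(nms) || any(nms == "")) {
    stop("sets must carry unique names", call. = FALSE)
  }
  combo_label <- function(mask) paste(nms[mask], collapse = "&")
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
  if (all(vapply(named_sets, is.character, TRUE))) {
    universe <- unique(unlist(named_sets))
    member <- vapply(named_sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1) member <- matrix(member, nrow = 1)
    key <- apply(member, 1, function(r) combo_label(r))
    out <- data.frame(
      combination = apply(masks, 1, function(r) combo_label(unlist(r))),
      degree = rowSums(masks),
      stringsAsFactors = FALSE)
    out$n <- vapply(out$combination, function(cb) sum(key == cb), 1L)
    rownames(out) <- NULL
    return(out[order(-out$degree, out$combination), , drop = FALSE])
  }
  if (!all(vapply(named_sets, function(x) methods::is(x, "GRanges"), TRUE))) {
    stop("sets must be all character vectors or all GRanges", call. = FALSE)
  }
  res <- do.call(rbind, lapply(seq_len(m), function(si) {
    src <- named_sets[[si]]
    hit <- vapply(named_sets, function(s)
      GenomicRanges::countOverlaps(src, s, minoverlap = 1L,
                                   ignore.strand = TRUE) > 0,
      logical(length(src)))
    if (length(src) == 1) hit <- matrix(hit, nrow = 1)
    hit[, si] <- TRUE  # every interval belongs to its own set
    key <- apply(hit, 1, function(r) combo_label(r))
    data.frame(combination = apply(masks, 1,
                                   function(r) combo_label(unlist(r))),
               degree = rowSums(masks),
               source_set = nms[si],
               n = vapply(apply(masks, 1, function(r)
                 combo_label(unlist(r))), function(cb) sum(key == cb), 1L),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(-res$degree, res$combination, res$source_set), , drop = FALSE]
}

#' Binned signal metaprofile around site centers
#'
#' Counts fragment midpoints in uniform bins (default 100 bp) across a
#' window (default +/- 2 kb) centered on each site's midpoint, converts
#' counts to CPM of the signal library, and averages across sites — the
#' standard average-signal metaplot used to compare, e.g., dependent
#' sites against all other sites.
#'
#' @param sites A non-empty `GRanges`.
#' @param signal A [signal_library()].
#' @param half_window_bp Half window in bp (default 2000); must be a
#'   multiple of `bin_bp`.
#' @param bin_bp Bin width in bp (default 100).
#' @param class_label Optional label carried into the output.
#' @return A data.frame with one row per bin: `offset_start`,
#'   `offset_mid`, `offset_end` (bp relative to center), `mean_cpm`,
#'   `n_sites`, `class_label`.
#' @export
signal_profile <- function(sites, signal, half_window_bp = 2000,
                           bin_bp = 100, class_label = NA_character_) {
  if (length(sites) == 0) stop("no sites supplied", call. = FALSE)
  stopifnot(inherits(signal, "signal_library"))
  if (half_window_bp %% bin_bp != 0) {
    stop("half_window_bp must be divisible by bin_bp", call. = FALSE)
  }
  nbin <- 2L * half_window_bp / bin_bp
  df <- as_bed_df(sites)
  center <- floor((df$start + df$end) / 2)
  offs <- seq(-half_window_bp, half_window_bp - bin_bp, by = bin_bp)
  # one range per (site, bin); bin b covers [center+off, center+off+bin)
  bin_start0 <- rep(center, each = nbin) + rep(offs, length(sites))
  keep <- bin_start0 >= 0
  bins <- GenomicRanges::GRanges(
    rep(df$chrom, each = nbin)[keep],
    IRanges::IRanges(start = bin_start0[keep] + 1L, width = bin_bp))
  counts <- numeric(nbin * length(sites))
  counts[keep] <- GenomicRanges::countOverlaps(
    bins, fragment_midpoints(signal$fragments), ignore.strand = TRUE)
  total_per_bin <- rowSums(matrix(counts, nrow = nbin))
  data.frame(offset_start = offs,
             offset_mid = offs + bin_bp / 2,
             offset_end = offs + bin_bp,
             mean_cpm = total_per_bin / length(sites) /
               signal$library_size * 1e6,
             n_sites = length(sites),
             class_label = class_label,
             stringsAsFactors = FALSE)
}
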