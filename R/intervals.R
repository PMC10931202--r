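#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<- seqlevelsInUse
#' @importFrom methods is
NULL

# Coordinates are BED-style 0-based half-open at every file boundary and in
# every user-facing constructor; internally intervals live in GRanges
# (1-based closed).  peak_ranges()/as_bed_df() own the conversion, so the
# off-by-one never leaks.

#' Build a sorted GRanges from BED-style coordinates
#'
#' Constructs a `GRanges` from 0-based half-open coordinates (the BED
#' convention used by all peak files this package reads and writes) and
#' sorts it with the package-wide order: chromosome (lexicographic), start,
#' end, name.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, exclusive end positions; must satisfy
#'   `start < end`.
#' @param name Optional character vector of interval labels.
#' @param score Optional numeric score.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A sorted `GRanges` with optional `name` and `score` metadata
#'   columns.
#' @examples
#' peak_ranges("chr1", c(100, 0), c(200, 50), name = c("a", "b"))
#' @export
peak_ranges <- function(chrom, start, end, name = NULL, score = NULL,
                        strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)) ||
      any(start != floor(start)) || any(end != floor(end))) {
    stop("interval coordinates must be integers", call. = FALSE)
  }
  if (any(start < 0)) stop("interval start must be >= 0", call. = FALSE)
  if (any(start >= end)) {
    stop("invalid interval: start >= end", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand
  )
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  sort_peaks(gr)
}

#' Sort intervals by (chromosome, start, end, name)
#'
#' Chromosome names compare lexicographically (no "chr" aliasing); ties on
#' coordinates break on the `name` metadata column when present.
#'
#' @param gr A `GRanges`.
#' @return The same `GRanges`, reordered.
#' @export
sort_peaks <- function(gr) {
  seqlevels(gr) <- sort(seqlevels(gr))
  nm <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else
    rep("", length(gr))
  o <- order(as.integer(seqnames(gr)), BiocGenerics::start(gr),
             BiocGenerics::end(gr), nm)
  gr[o]
}

#' Convert a GRanges back to a BED-style data frame
#'
#' @param gr A `GRanges`.
#' @return A `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `name`, `score`, `strand`.
#' @export
as_bed_df <- function(gr) {
  data.frame(
    chrom = as.character(seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name) else ".",
    score = if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Do two intervals overlap by at least `min_bp` bases?
#'
#' Strand is ignored; chromosomes must match exactly. With half-open
#' coordinates, abutting intervals (`end == start`) share zero bases and do
#' not overlap.
#'
#' @param a,b `GRanges` of the same length (recycled if length 1).
#' @param min_bp Minimum number of shared bases (default 1).
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  if (length(a) == 1 && length(b) > 1) a <- rep(a, length(b))
  if (length(b) == 1 && length(a) > 1) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  inter <- pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
    pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L
  same & inter >= min_bp
}

#' Pair up overlapping intervals between two sets
#'
#' Reports, for two peak sets, which intervals of each set are hit by at
#' least one interval of the other (>= `min_bp` shared bases), together
#' with the full pairing. Counts are directional: `n_a_overlap` counts
#' distinct a-intervals, `n_b_overlap` distinct b-intervals — the two need
#' not agree, so both are reported.
#'
#' @param a,b Sorted `GRanges`.
#' @param min_bp Minimum shared bases for a hit (default 1).
#' @return A list with `pairs` (data.frame of a/b indices), logical masks
#'   `a_hit`, `b_hit`, and counts `n_a_overlap`, `n_b_overlap`, `n_a_only`,
#'   `n_b_only`.
#' @export
intersect_sets <- function(a, b, min_bp = 1L) {
  stopifnot(min_bp >= 1)
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = min_bp,
                                      ignore.strand = TRUE)
  a_hit <- rep(FALSE, length(a)); a_hit[queryHits(hits)] <- TRUE
  b_hit <- rep(FALSE, length(b)); b_hit[subjectHits(hits)] <- TRUE
  list(
    pairs = data.frame(a = queryHits(hits), b = subjectHits(hits)),
    a_hit = a_hit,
    b_hit = b_hit,
    n_a_overlap = sum(a_hit),
    n_b_overlap = sum(b_hit),
    n_a_only = sum(!a_hit),
    n_b_only = sum(!b_hit)
  )
}

#' Merge intervals whose gap is at most `max_gap`
#'
#' The stitching engine: intervals on the same chromosome are merged
#' transitively whenever the gap between them (`next start - previous end`
#' in BED coordinates) is `<= max_gap`. `max_gap = 0` merges overlapping
#' and book-ended intervals; the super-enhancer caller uses
#' `max_gap = 12500`, the conventional 12.5 kb stitching distance.
#'
#' @param gr A `GRanges`.
#' @param max_gap Non-negative integer gap threshold in bp.
#' @return A sorted `GRanges` of merged spans with metadata columns
#'   `n_constituents` and `revmap` (an `IntegerList` of indices into the
#'   sorted input).
#' @export
merge_adjacent <- function(gr, max_gap) {
  if (length(max_gap) != 1 || !is.finite(max_gap) || max_gap < 0) {
    stop("max_gap must be a single non-negative number", call. = FALSE)
  }
  gr <- sort_peaks(gr)
  # reduce() merges when gap < min.gapwidth; gap <= max_gap  <=>
  # min.gapwidth = max_gap + 1
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1,
                                  with.revmap = TRUE, ignore.strand = TRUE)
  mcols(merged)$n_constituents <- lengths(mcols(merged)$revmap)
  sort_peaks(merged)
}

#' Total bases covered by a set of intervals
#'
#' @param gr A `GRanges`.
#' @return Number of distinct covered bases.
#' @export
covered_bases <- function(gr) {
  sum(BiocGenerics::width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))
}
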