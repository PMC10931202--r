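#' @importFrom data.table fread fwrite
#' @importFrom utils write.table
NULL

#' Read a BED or narrowPeak peak file
#'
#' Reads MACS2-style peak files into a sorted `GRanges`. BED files need at
#' least 3 tab-separated columns; columns 4 and 5, when present, map to
#' `name` and `score`. narrowPeak files must have the full ENCODE 10
#' columns, with `signalValue` (column 7) mapped to `score`. Coordinates
#' are 0-based half-open on disk.
#'
#' @param path Path to the file. No header is expected.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return A sorted `GRanges` (empty for an empty file).
#' @export
read_peaks <- function(path, format = c("bed", "narrowPeak")) {
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop("unknown peak format: ", format[1], call. = FALSE))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  dt <- fread(path, sep = "\t", header = FALSE, data.table = FALSE,
              colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(GenomicRanges::GRanges())
  }
  need <- if (format == "narrowPeak") 10L else 3L
  if (ncol(dt) < need) {
    stop(sprintf("%s: expected >= %d tab-separated fields, found %d",
                 path, need, ncol(dt)), call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(dt[[2]]))
  end <- suppressWarnings(as.numeric(dt[[3]]))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end) |
                 start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("%s: malformed interval at line %d", path, bad[1]),
         call. = FALSE)
  }
  name <- if (ncol(dt) >= 4) as.character(dt[[4]]) else NULL
  score <- if (format == "narrowPeak") {
    suppressWarnings(as.numeric(dt[[7]]))
  } else if (ncol(dt) >= 5) {
    suppressWarnings(as.numeric(dt[[5]]))
  } else NULL
  strand <- if (ncol(dt) >= 6 && all(dt[[6]] %in% c("+", "-", "."))) {
    ifelse(dt[[6]] == ".", "*", dt[[6]])
  } else "*"
  peak_ranges(dt[[1]], start, end, name = name, score = score,
              strand = strand)
}

#' Write peaks as BED6
#'
#' Emits sorted, tab-separated BED6 (no header); missing names become "."
#' and missing scores 0. Round-trips coordinates and scores exactly with
#' [read_peaks()].
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_peaks <- function(gr, path) {
  df <- as_bed_df(sort_peaks(gr))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with a header and columns `gene_id`, `chrom`, `tss`,
#' `strand`; extra columns are ignored. One row per TSS (multi-isoform
#' genes must be pre-flattened by the caller).
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with the four canonical columns.
#' @export
read_gene_table <- function(path) {
  df <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  if (any(df$tss < 0)) stop("tss positions must be >= 0", call. = FALSE)
  if (!all(df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  df[order(df$chrom, df$tss, df$gene_id), , drop = FALSE]
}

#' Read a differential-peak table
#'
#' Tab-separated with a header; requires columns `chrom`, `start`, `end`
#' (BED coordinates), `log2fc` and `fdr`, and tolerates extra columns.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` suitable for [filter_differential()].
#' @export
read_differential_table <- function(path) {
  df <- fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "start", "end", "log2fc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("differential table missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$log2fc))) {
    stop("log2fc must be finite", call. = FALSE)
  }
  if (any(df$fdr < 0 | df$fdr > 1)) {
    stop("fdr must lie in [0, 1]", call. = FALSE)
  }
  df
}

#' Read a fragment BED file into a signal library
#'
#' Fragments are BED3+ spans of sequenced fragments; the library size is
#' the fragment count and is the CPM denominator everywhere downstream.
#'
#' @param path Path to the fragment BED.
#' @return A [signal_library()].
#' @export
read_fragments <- function(path) {
  signal_library(read_peaks(path, "bed"))
}

#' Bundle fragments with their library size
#'
#' @param fragments A `GRanges` of fragment spans.
#' @param library_size Total fragment count; defaults to
#'   `length(fragments)`.
#' @return An object of class `signal_library`.
#' @export
signal_library <- function(fragments, library_size = length(fragments)) {
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  if (length(fragments) > library_size) {
    stop("library_size smaller than fragment count", call. = FALSE)
  }
  structure(list(fragments = fragments, library_size = library_size),
            class = "signal_library")
}

#' @export
print.signal_library <- function(x, ...) {
  cat(sprintf("<signal_library: %d fragments, library size %d>\n",
              length(x$fragments), x$library_size))
  invisible(x)
}

#' Fragment midpoints as width-1 ranges
#'
#' The midpoint of a fragment spanning `[s, e)` in BED coordinates is
#' `floor((s + e) / 2)`; counting midpoints makes region membership
#' unambiguous for fragments straddling region edges.
#'
#' @param fragments A `GRanges` of fragments.
#' @return A `GRanges` of width-1 midpoint positions.
#' @export
fragment_midpoints <- function(fragments) {
  s0 <- BiocGenerics::start(fragments) - 1L
  e0 <- BiocGenerics::end(fragments)
  mid0 <- floor((s0 + e0) / 2)
  GenomicRanges::GRanges(seqnames(fragments),
                         IRanges::IRanges(mid0 + 1L, width = 1L))
}
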