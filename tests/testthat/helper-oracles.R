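# Brute-force reference implementations used as independent oracles.
# These deliberately share no code with the package: bitmaps, all-pairs
# scans, union-find, exhaustive enumeration.

# random interval set on a toy chromosome, returned as a BED data frame
random_bed <- function(n, chrom_len = 1e5, chroms = c("chrA", "chrB"),
                       max_width = 2000) {
  start <- floor(runif(n, 0, chrom_len - max_width))
  width <- sample(seq_len(max_width), n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

bed_to_gr <- function(df) peak_ranges(df$chrom, df$start, df$end)

# order-preserving variant for row-wise pairing against an oracle
bed_to_gr_unsorted <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}

# per-base bitmap union of intervals on one namespace of chromosomes
oracle_covered_bases <- function(df, chrom_len = 1e5 + 2000) {
  total <- 0L
  for (ch in unique(df$chrom)) {
    bits <- logical(chrom_len)
    sub <- df[df$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      bits[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    total <- total + sum(bits)
  }
  total
}

# all-pairs overlap scan
oracle_pair_overlap <- function(a, b, min_bp = 1) {
  a$chrom == b$chrom &
    (pmin(a$end, b$end) - pmax(a$start, b$start)) >= min_bp
}

oracle_intersect_counts <- function(da, db, min_bp = 1) {
  hit_a <- logical(nrow(da))
  hit_b <- logical(nrow(db))
  for (i in seq_len(nrow(da))) {
    for (j in seq_len(nrow(db))) {
      if (da$chrom[i] == db$chrom[j] &&
          min(da$end[i], db$end[j]) - max(da$start[i], db$start[j]) >=
            min_bp) {
        hit_a[i] <- TRUE
        hit_b[j] <- TRUE
      }
    }
  }
  list(n_a_overlap = sum(hit_a), n_b_overlap = sum(hit_b),
       n_a_only = sum(!hit_a), n_b_only = sum(!hit_b))
}

# transitive-closure merge via union-find
oracle_merge <- function(df, max_gap) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && df$chrom[i] == df$chrom[j]) {
        gap <- max(df$start[i], df$start[j]) - min(df$end[i], df$end[j])
        if (gap <= max_gap) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    sub <- df[comp == cc, , drop = FALSE]
    data.frame(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# exhaustive nearest-TSS scan
oracle_nearest_tss <- function(centers, chroms, genes) {
  vapply(seq_along(centers), function(i) {
    g <- genes[genes$chrom == chroms[i], , drop = FALSE]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(centers[i] - g$tss)
    cand <- g$gene_id[d == min(d)]
    sort(cand)[1]
  }, character(1))
}

# exact hypergeometric upper tail by direct summation of the pmf
# (binomial coefficients, no distribution functions)
oracle_hyper_upper <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j) {
    choose(K, j) * choose(N - K, n - j)
  }, 1)) / choose(N, n)
}

# independently coded BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  pmin(adj, 1)
}

# exhaustive tangent-cutoff scan: tries every index as the touch point of
# a slope-1 line and keeps the one where the whole curve lies on/above it
oracle_super_set <- function(scores) {
  n <- length(scores)
  o <- order(scores)
  s <- scores[o]
  if (min(s) < 0) s <- s - min(s)
  if (max(s) <= 0) return(rep(FALSE, n))
  y <- s / max(s)
  x <- seq_len(n) / n
  feasible <- vapply(seq_len(n), function(c0) {
    all(y - x >= (y[c0] - x[c0]) - 1e-12)
  }, logical(1))
  cutoff <- max(which(feasible))
  sup_sorted <- seq_len(n) > cutoff & s > s[cutoff]
  out <- logical(n)
  out[o] <- sup_sorted
  out
}
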