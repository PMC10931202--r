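test_that("consensus keeps clusters supported by >= min_support replicates", {
  r1 <- peak_ranges("chr1", c(100, 5000), c(300, 5400))
  r2 <- peak_ranges("chr1", c(150, 9000), c(350, 9200))
  r3 <- peak_ranges("chr1", 9100, 9300)
  cs <- consensus_peaks(list(r1, r2, r3), min_support = 2)
  df <- as_bed_df(cs$peaks)
  # the 100-350 cluster (reps 1+2) and the 9000-9300 cluster (reps 2+3)
  expect_equal(nrow(df), 2)
  expect_equal(df$start, c(100, 9000))
  expect_equal(df$end, c(350, 9300))
  expect_equal(S4Vectors::mcols(cs$peaks)$support, c(2, 2))
  # the singleton at 5000 is dropped
  expect_false(any(df$start == 5000))
})

test_that("identical replicates give support = n and unchanged peaks", {
  r <- bed_to_gr(random_bed(30))
  r <- merge_adjacent(r, 0)  # make replicate internally non-overlapping
  S4Vectors::mcols(r) <- NULL
  cs <- consensus_peaks(list(r, r, r), min_support = 2)
  expect_equal(as_bed_df(cs$peaks)[1:3], as_bed_df(r)[1:3])
  expect_true(all(S4Vectors::mcols(cs$peaks)$support == 3))
})

test_that("min_support = 1 equals merging all replicates at gap 0", {
  set.seed(61)
  reps <- lapply(1:3, function(i) bed_to_gr(random_bed(40)))
  cs <- consensus_peaks(reps, min_support = 1)
  merged <- merge_adjacent(do.call(c, reps), 0)
  expect_equal(as_bed_df(cs$peaks)[1:3], as_bed_df(merged)[1:3])
  expect_error(consensus_peaks(reps, min_support = 4), "min_support")
})

test_that("combine_conditions unions consensus sets into one universe", {
  a <- peak_ranges("chr1", c(0, 1000), c(100, 1100))
  b <- peak_ranges("chr2", 500, 600)
  u <- combine_conditions(list(a, b))
  expect_length(u, 3)
  expect_equal(as_bed_df(combine_conditions(list(a, a)))[1:3],
               as_bed_df(a)[1:3])
  set.seed(71)
  d1 <- random_bed(80)
  d2 <- random_bed(80)
  u2 <- combine_conditions(list(bed_to_gr(d1), bed_to_gr(d2)))
  expect_equal(sum(as_bed_df(u2)$end - as_bed_df(u2)$start),
               oracle_covered_bases(rbind(d1, d2)))
})

test_that("differential filtering applies the FDR and fold gates", {
  tab <- data.frame(
    chrom = "chr1",
    start = c(0, 100, 200, 300, 400) * 10,
    end = c(0, 100, 200, 300, 400) * 10 + 50,
    log2fc = c(-1.0, -0.30, -3.0, 1.2, -0.59),
    fdr = c(0.01, 0.01, 0.20, 0.01, 0.01))
  dec <- filter_differential(tab, direction = "decreased")
  # fold -2.0 passes; fold ~-1.23 fails the fold gate; fdr 0.20 fails the
  # FDR gate; increased site excluded; log2fc -0.59 > log2(1.5) passes
  expect_equal(as_bed_df(dec)$start, c(0, 4000))
  inc <- filter_differential(tab, direction = "increased")
  expect_equal(as_bed_df(inc)$start, 3000)
  both <- filter_differential(tab, direction = "both")
  expect_length(both, 3)
  expect_error(filter_differential(tab, fold_min = 1), "fold_min")
})

test_that("log2-scale fold interpretation is available as a switch", {
  tab <- data.frame(chrom = "chr1", start = 0, end = 50,
                    log2fc = -1.0, fdr = 0.01)
  expect_length(filter_differential(tab, fold_min = 1.5,
                                    fold_scale = "log2"), 0)
  expect_length(filter_differential(tab, fold_min = 1.5), 1)
})

test_that("decreased and increased are disjoint; relaxation is monotone", {
  set.seed(81)
  for (rep in 1:5) {
    tab <- data.frame(chrom = "chr1",
                      start = seq(0, 990, 10) * 100,
                      end = seq(0, 990, 10) * 100 + 500,
                      log2fc = rnorm(100, 0, 1.5),
                      fdr = runif(100))
    dec <- filter_differential(tab, direction = "decreased")
    inc <- filter_differential(tab, direction = "increased")
    expect_equal(intersect_sets(dec, inc)$n_a_overlap, 0)
    strict <- length(filter_differential(tab, 0.05, 2, "decreased"))
    loose_fdr <- length(filter_differential(tab, 0.20, 2, "decreased"))
    loose_fold <- length(filter_differential(tab, 0.05, 1.2, "decreased"))
    expect_gte(loose_fdr, strict)
    expect_gte(loose_fold, strict)
  }
})

test_that("differential table reader validates and tolerates extras", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "chr1", start = 0, end = 100, log2fc = -2,
                   fdr = 0.01, extra = "x")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_differential_table(path)
  expect_equal(got$log2fc, -2)
  bad <- df
  bad$fdr <- 1.5
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_differential_table(path), "fdr")
})
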