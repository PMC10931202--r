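scored_regions <- function(scores) {
  n <- length(scores)
  gr <- peak_ranges("chr1", seq_len(n) * 1e5, seq_len(n) * 1e5 + 1000)
  S4Vectors::mcols(gr)$signal_score <- scores
  gr
}

super_scores <- function(scores) {
  call <- call_superenhancers(scored_regions(scores))
  S4Vectors::mcols(call$regions)$is_super
}

test_that("stitching at 12.5 kb merges the canonical example", {
  enh <- peak_ranges("chr1", c(0, 12900), c(500, 13400))
  st <- stitch_enhancers(enh)
  expect_length(st, 1)
  st2 <- stitch_enhancers(peak_ranges("chr1", c(0, 20500), c(500, 21000)))
  expect_length(st2, 2)
  expect_length(stitch_enhancers(GenomicRanges::GRanges()), 0)
  set.seed(121)
  df <- random_bed(50, chrom_len = 5e5, chroms = "chr1")
  got <- as_bed_df(stitch_enhancers(bed_to_gr(df), 12500))
  want <- oracle_merge(df, 12500)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
})

test_that("region scores equal input-subtracted CPM of midpoint counts", {
  region <- peak_ranges("chr1", 1000, 2000)
  # 50 treatment fragments inside, library padded to 1e6 with a distant pile
  inside_t <- peak_ranges("chr1", rep(1400, 50), rep(1600, 50))
  inside_c <- peak_ranges("chr1", rep(1400, 20), rep(1600, 20))
  treat <- signal_library(inside_t, library_size = 1e6)
  ctrl <- signal_library(inside_c, library_size = 1e6)
  got <- score_regions(region, treat, ctrl)
  expect_equal(S4Vectors::mcols(got)$signal_score, 30.0)
  same <- score_regions(region, treat, treat)
  expect_equal(S4Vectors::mcols(same)$signal_score, 0)
})

test_that("midpoint counting matches a per-fragment membership scan", {
  set.seed(131)
  regions <- bed_to_gr(random_bed(20, chrom_len = 5e4, chroms = "chr1"))
  regions <- merge_adjacent(regions, 0)
  frag_df <- random_bed(500, chrom_len = 5e4, chroms = "chr1",
                        max_width = 300)
  treat <- signal_library(bed_to_gr(frag_df))
  ctrl <- signal_library(bed_to_gr(random_bed(400, chrom_len = 5e4,
                                              chroms = "chr1",
                                              max_width = 300)))
  got <- score_regions(regions, treat, ctrl)
  rdf <- as_bed_df(regions)
  count_in <- function(fd, rg) {
    mid <- floor((fd$start + fd$end) / 2)
    sum(mid >= rg["start"] & mid < rg["end"])
  }
  for (i in seq_along(regions)) {
    nt <- count_in(frag_df, c(start = rdf$start[i], end = rdf$end[i]))
    nc <- count_in(as_bed_df(ctrl$fragments),
                   c(start = rdf$start[i], end = rdf$end[i]))
    want <- (nt / treat$library_size - nc / ctrl$library_size) * 1e6
    expect_equal(S4Vectors::mcols(got)$signal_score[i], want)
  }
  expect_error(signal_library(bed_to_gr(frag_df), library_size = 0),
               "library_size")
})

test_that("a perfectly linear rank-signal curve calls nothing", {
  expect_false(any(super_scores(seq_len(50))))
  expect_false(any(super_scores(3.7 * seq_len(20))))
})

test_that("a single dominant region is always called", {
  expect_equal(sum(super_scores(c(rep(1, 9), 91))), 1)
  expect_true(super_scores(c(rep(1, 9), 91))[10])
  set.seed(141)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    base <- runif(n - 1, 0.5, 1.5)
    scores <- sample(c(base, max(base) * runif(1, 10, 50)))
    sup <- super_scores(scores)
    expect_equal(sum(sup), 1)
    expect_true(sup[which.max(scores)])
  }
})

test_that("called set matches the exhaustive tangent oracle on random
          curves, with and without negative scores", {
  set.seed(151)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    scores <- switch(1 + i %% 3,
                     rlnorm(n, 3, 1),
                     rnorm(n, 10, 8),          # includes negatives
                     sample(rep(rlnorm(5, 2, 1), length.out = n)))  # ties
    expect_equal(super_scores(scores), oracle_super_set(scores),
                 info = sprintf("instance %d", i))
  }
})

test_that("the call is invariant to positive rescaling of scores", {
  set.seed(161)
  for (i in 1:20) {
    scores <- rlnorm(sample(10:100, 1), 3, 1.2)
    base <- super_scores(scores)
    expect_equal(super_scores(scores * 7.3), base)
    expect_equal(super_scores(scores * 1e-4), base)
  }
})

test_that("every super-enhancer outscores every typical region", {
  set.seed(171)
  for (i in 1:20) {
    scores <- rlnorm(80, 2, 1.5)
    sup <- super_scores(scores)
    if (any(sup) && any(!sup)) {
      expect_gt(min(scores[sup]), max(scores[!sup]))
    }
  }
})

test_that("adding a region below the cutoff never drops an existing
          super-enhancer", {
  set.seed(181)
  for (i in 1:20) {
    scores <- rlnorm(60, 3, 1)
    call <- call_superenhancers(scored_regions(scores))
    if (call$n_super == 0) next
    newcomer <- call$cutoff_score * runif(1)
    sup2 <- super_scores(c(scores, newcomer))
    expect_true(all(sup2[seq_along(scores)][super_scores(scores)]))
    expect_false(sup2[length(scores) + 1])
  }
})

test_that("degenerate inputs: tiny n and all-equal scores", {
  expect_warning(one <- call_superenhancers(scored_regions(5)),
                 "fewer than 2")
  expect_equal(one$n_super, 0)
  flat <- call_superenhancers(scored_regions(rep(2, 10)))
  expect_equal(flat$n_super, 0)
})

test_that("hockey-stick report is consistent with the call", {
  set.seed(191)
  scores <- c(rlnorm(30, 2, 0.3), 500, 900)
  call <- call_superenhancers(scored_regions(scores))
  rep <- hockey_stick_report(call)
  expect_equal(nrow(rep$table), 32)
  expect_equal(sum(rep$table$is_super), call$n_super)
  expect_equal(rep$n_typical, 32 - call$n_super)
  expect_false(is.unsorted(rep$table$signal_score))
  expect_equal(rep$table$rank, 1:32)
  # scaled columns live on the unit square
  expect_equal(max(rep$table$scaled_rank), 1)
  expect_equal(max(rep$table$scaled_signal), 1)
})
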