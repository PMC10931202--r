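test_that("hypergeometric p matches enumeration on the worked example", {
  # N=10, K=5, n=4: P(X >= 3) = (C(5,3)C(5,1) + C(5,4)) / C(10,4) = 55/210
  res <- hypergeometric_enrichment(10, 5, 4, 3)
  expect_equal(res$p_value, 55 / 210)
  expect_equal(res$p_value, oracle_hyper_upper(10, 5, 4, 3))
  expect_equal(hypergeometric_enrichment(100, 30, 40, 0)$p_value, 1)
})

test_that("hypergeometric roles are exchangeable and monotone in k", {
  set.seed(201)
  for (i in 1:20) {
    N <- sample(20:500, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(max(0, K + n - N):min(K, n), 1)
    expect_equal(hypergeometric_enrichment(N, K, n, k)$p_value,
                 hypergeometric_enrichment(N, n, K, k)$p_value)
  }
  ps <- vapply(10:30, function(k)
    hypergeometric_enrichment(1000, 100, 100, k)$p_value, 1)
  expect_false(is.unsorted(rev(ps)))
})

test_that("hypergeometric rejects inconsistent counts", {
  expect_error(hypergeometric_enrichment(10, 5, 4, 5), "overlap")
  expect_error(hypergeometric_enrichment(10, 12, 4, 2), "universe")
  expect_error(hypergeometric_enrichment(10, 8, 8, 2), "forced minimum")
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(211)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH output dominates raw p and is monotone in the p-order", {
  set.seed(221)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_false(is.unsorted(adj[order(p)]))
})

test_that("multiway gene-set partition matches brute-force enumeration", {
  two <- multiway_overlap_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(two$n[two$combination == "A&B"], 2)
  expect_equal(sum(two$n), 2)

  disj <- multiway_overlap_counts(list(A = "x", B = "y", C = "z"))
  expect_equal(disj$n[disj$degree == 1], rep(1, 3))
  expect_equal(sum(disj$n[disj$degree > 1]), 0)

  set.seed(231)
  pool <- sprintf("gene%03d", 1:120)
  sets <- list(A = sample(pool, 60), B = sample(pool, 40),
               C = sample(pool, 50))
  got <- multiway_overlap_counts(sets)
  uni <- unique(unlist(sets))
  for (r in seq_len(nrow(got))) {
    in_sets <- strsplit(got$combination[r], "&", fixed = TRUE)[[1]]
    want <- sum(vapply(uni, function(g) {
      all(vapply(names(sets), function(s)
        (g %in% sets[[s]]) == (s %in% in_sets), TRUE))
    }, TRUE))
    expect_equal(got$n[r], want)
  }
  expect_error(multiway_overlap_counts(c(sets, sets[1])), "unique")
  expect_error(multiway_overlap_counts(list(A = "x")), "2 and 4")
})

test_that("multiway interval counts assign each interval to all sets it
          touches, per source set", {
  a <- peak_ranges("chr1", c(0, 1000), c(100, 1100))
  b <- peak_ranges("chr1", c(50, 5000), c(150, 5100))
  got <- multiway_overlap_counts(list(A = a, B = b))
  n_of <- function(cb, src)
    got$n[got$combination == cb & got$source_set == src]
  expect_equal(n_of("A&B", "A"), 1)
  expect_equal(n_of("A&B", "B"), 1)
  expect_equal(n_of("A", "A"), 1)   # the 1000-1100 peak touches only A
  expect_equal(n_of("B", "B"), 1)
})

test_that("signal profiles have the documented bin layout", {
  site <- peak_ranges("chr1", 10000, 10100)  # center 10050
  frags <- peak_ranges("chr1", rep(9000, 5), rep(9200, 5))  # mid 9100
  prof <- signal_profile(site, signal_library(frags, 1e6))
  expect_equal(nrow(prof), 40)
  expect_equal(prof$offset_start[1], -2000)
  expect_equal(prof$offset_end[40], 2000)
  # mid 9100 is 950 bp left of center: bin [-1000, -900)
  hit <- prof$mean_cpm > 0
  expect_equal(prof$offset_start[hit], -1000)
  expect_equal(prof$mean_cpm[hit], 5)
  expect_error(signal_profile(GenomicRanges::GRanges(),
                              signal_library(frags)), "sites")
  expect_error(signal_profile(site, signal_library(frags),
                              half_window_bp = 2050), "divisible")
})

test_that("uniform coverage gives a flat profile", {
  set.seed(241)
  mids <- seq(25, 99975, by = 50)  # strictly uniform fragment grid
  frags <- peak_ranges("chr1", mids - 20, mids + 20)
  sites <- peak_ranges("chr1", seq(20000, 70000, by = 5000),
                       seq(20000, 70000, by = 5000) + 400)
  prof <- signal_profile(sites, signal_library(frags))
  expect_equal(max(prof$mean_cpm) - min(prof$mean_cpm), 0)
})

test_that("profile of a union of site sets is the count-weighted mean", {
  set.seed(251)
  lib <- signal_library(bed_to_gr(random_bed(2000, chroms = "chr1",
                                             max_width = 200)))
  s1 <- bed_to_gr(random_bed(15, chroms = "chr1"))
  s2 <- bed_to_gr(random_bed(25, chroms = "chr1"))
  p1 <- signal_profile(s1, lib)
  p2 <- signal_profile(s2, lib)
  p12 <- signal_profile(c(s1, s2), lib)
  expect_equal(p12$mean_cpm,
               (15 * p1$mean_cpm + 25 * p2$mean_cpm) / 40)
})
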