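# Seeded generator of a toy multi-chromosome genome with planted
# regulatory architecture: promoters (H3K4me3+H3K27ac at TSSs), TSS-distal
# typical enhancers (H3K27ac+H3K4me1), clustered high-H3K27ac enhancer
# groups that must stitch into single super-enhancer regions, replicate
# ATAC peak sets with negative-binomial count noise, fragment libraries
# for signal scoring, and a differential-accessibility table with planted
# decreases at "dependent" sites.

#' Configuration for the synthetic-genome generator
#'
#' Defaults describe the study conditions the pipeline is validated
#' under: 4 chromosomes of 10 Mb; 240 genes spaced >= 20 kb apart; 200
#' TSS-distal typical enhancers; 40 super-enhancer clusters of 3-6
#' constituents whose intra-cluster gaps are drawn uniformly from
#' 1-12 kb (always below the 12.5 kb stitch distance, so each planted
#' cluster must stitch into exactly one region); H3K27ac fragment
#' intensity at cluster constituents 10x the typical-enhancer level; 75%
#' of distal sites and 75% of clusters planted as dependent with a true
#' log2 fold change of -2; 3 replicates per condition with
#' negative-binomial count noise.
#'
#' @param seed Integer RNG seed (mandatory determinism contract).
#' @param n_chroms,chrom_len_bp Genome shape.
#' @param n_genes,n_typical_enhancers,n_se_clusters Element counts.
#' @param se_cluster_size Length-2 integer range of constituents per
#'   cluster.
#' @param se_signal_multiplier H3K27ac intensity excess of cluster
#'   constituents over typical enhancers.
#' @param frac_brg1_dependent_distal Fraction of typical (distal)
#'   enhancers planted as dependent.
#' @param frac_brg1_dependent_se Fraction of clusters planted as
#'   dependent (all constituents inherit the flag).
#' @param planted_log2fc True log2 fold change at dependent sites.
#' @param replicates Replicates per condition.
#' @param nb_dispersion Negative-binomial size parameter of replicate
#'   counts (larger = less overdispersed).
#' @param background_peak_rate Background ATAC peaks per bp.
#' @param noise If `FALSE`, counts and fragment numbers are set to their
#'   expectations (noise-free mode for exact-recovery checks).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 4L,
                             chrom_len_bp = 1e7,
                             n_genes = 240L,
                             n_typical_enhancers = 200L,
                             n_se_clusters = 40L,
                             se_cluster_size = c(3L, 6L),
                             se_signal_multiplier = 10,
                             frac_brg1_dependent_distal = 0.75,
                             frac_brg1_dependent_se = 0.75,
                             planted_log2fc = -2,
                             replicates = 3L,
                             nb_dispersion = 20,
                             background_peak_rate = 2e-6,
                             noise = TRUE) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len_bp = as.numeric(chrom_len_bp),
              n_genes = as.integer(n_genes),
              n_typical_enhancers = as.integer(n_typical_enhancers),
              n_se_clusters = as.integer(n_se_clusters),
              se_cluster_size = as.integer(se_cluster_size),
              se_signal_multiplier = se_signal_multiplier,
              frac_brg1_dependent_distal = frac_brg1_dependent_distal,
              frac_brg1_dependent_se = frac_brg1_dependent_se,
              planted_log2fc = planted_log2fc,
              replicates = as.integer(replicates),
              nb_dispersion = nb_dispersion,
              background_peak_rate = background_peak_rate,
              noise = isTRUE(noise))
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_len_bp > 0,
            length(cfg$se_cluster_size) == 2,
            cfg$se_cluster_size[1] >= 2,
            cfg$se_cluster_size[1] <= cfg$se_cluster_size[2],
            cfg$frac_brg1_dependent_distal >= 0,
            cfg$frac_brg1_dependent_distal <= 1,
            cfg$frac_brg1_dependent_se >= 0,
            cfg$frac_brg1_dependent_se <= 1,
            cfg$replicates >= 2)
  structure(cfg, class = "synthetic_config")
}

# fixed generator constants (element geometry and sequencing depth)
.syn <- list(
  promoter_width = 1500L,
  enh_width_range = c(600L, 1000L),
  cluster_gap_range = c(1000L, 12000L),
  block_sep = 20000L,      # min gap between planted blocks; > stitch_bp
  margin = 20000L,
  bg_peak_width = 500L,
  detect_threshold = 20,   # counts needed to call a peak in a replicate
  edge_jitter = 50L,
  frag_len = 200L,
  promoter_frags = 200,
  enhancer_frags = 80,
  bg_frags_per_mb = 1250,
  input_frags_per_mb = 2500,
  atac_mean = c(promoter = 300, enhancer = 200, se_constituent = 250,
                background = 100)
)

#' Generate a synthetic input bundle with planted ground truth
#'
#' Produces everything the pipeline consumes — gene table, histone-mark
#' peak sets, per-replicate ATAC peak sets for a control and a depleted
#' ("treatment") condition, H3K27ac and input fragment libraries, and a
#' differential table — together with the planted truth. Runs with the
#' same config (including seed) are identical.
#'
#' The differential table is a synthetic stand-in for an external count
#' model: a Welch t-test on log2(count+1) across replicates with BH
#' adjustment, not a negative-binomial fit.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_bundle` with components `genes`,
#'   `marks` (list of three `GRanges`), `atac_replicates` (per-condition
#'   lists of `GRanges`), `sites` (the true ATAC site table), `counts`
#'   (sites x replicates matrix), `differential`, `fragments` (list of
#'   [signal_library()]: `h3k27ac`, `input`), `truth` (planted promoters /
#'   enhancers / SE regions / dependent sites), and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- .syn
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))

  # ---- block layout ------------------------------------------------------
  rr <- function(n) chroms[(seq_len(n) - 1L) %% config$n_chroms + 1L]
  blocks <- rbind(
    data.frame(type = "gene", id = seq_len(config$n_genes),
               chrom = rr(config$n_genes), width = k$promoter_width),
    data.frame(type = "enhancer", id = seq_len(config$n_typical_enhancers),
               chrom = rr(config$n_typical_enhancers),
               width = sample(k$enh_width_range[1]:k$enh_width_range[2],
                              config$n_typical_enhancers, replace = TRUE)),
    data.frame(type = "cluster", id = seq_len(config$n_se_clusters),
               chrom = rr(config$n_se_clusters), width = NA)
  )
  cl_sizes <- sample(config$se_cluster_size[1]:config$se_cluster_size[2],
                     config$n_se_clusters, replace = TRUE)
  cl_widths <- lapply(seq_len(config$n_se_clusters), function(i) {
    sample(k$enh_width_range[1]:k$enh_width_range[2], cl_sizes[i],
           replace = TRUE)
  })
  cl_gaps <- lapply(seq_len(config$n_se_clusters), function(i) {
    if (cl_sizes[i] > 1)
      sample(k$cluster_gap_range[1]:k$cluster_gap_range[2],
             cl_sizes[i] - 1, replace = TRUE)
    else integer(0)
  })
  blocks$width[blocks$type == "cluster"] <-
    vapply(seq_len(config$n_se_clusters),
           function(i) sum(cl_widths[[i]]) + sum(cl_gaps[[i]]), 1)

  place_chrom <- function(b) {
    nb <- nrow(b)
    b <- b[sample(nb), , drop = FALSE]
    needed <- sum(b$width) + (nb - 1) * k$block_sep + 2 * k$margin
    if (needed > config$chrom_len_bp) {
      stop("infeasible placement: too many elements for chromosome size",
           call. = FALSE)
    }
    slack <- config$chrom_len_bp - needed
    u <- sort(runif(nb, 0, slack))
    b$start <- floor(k$margin + u + (seq_len(nb) - 1) * k$block_sep +
                       cumsum(c(0, b$width[-nb])))
    b
  }
  placed <- do.call(rbind, lapply(chroms, function(ch) {
    place_chrom(blocks[blocks$chrom == ch, , drop = FALSE])
  }))

  # ---- genes and promoters ----------------------------------------------
  g <- placed[placed$type == "gene", ]
  g <- g[order(g$id), ]
  genes <- data.frame(gene_id = sprintf("gene%04d", g$id),
                      chrom = g$chrom,
                      tss = floor(g$start + g$width / 2),
                      strand = sample(c("+", "-"), nrow(g), replace = TRUE),
                      stringsAsFactors = FALSE)
  promoters <- data.frame(chrom = g$chrom, start = g$start,
                          end = g$start + g$width,
                          name = sprintf("prom%04d", g$id))

  # ---- typical enhancers -------------------------------------------------
  e <- placed[placed$type == "enhancer", ]
  e <- e[order(e$id), ]
  typical <- data.frame(chrom = e$chrom, start = e$start,
                        end = e$start + e$width,
                        name = sprintf("enh%04d", e$id))

  # ---- SE clusters -------------------------------------------------------
  cl <- placed[placed$type == "cluster", ]
  cl <- cl[order(cl$id), ]
  constituents <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    id <- cl$id[i]
    w <- cl_widths[[id]]
    gp <- cl_gaps[[id]]
    s <- cl$start[i] + cumsum(c(0, w[-length(w)] + gp))
    data.frame(chrom = cl$chrom[i], start = s, end = s + w,
               name = sprintf("se%02d_c%d", id, seq_along(w)),
               cluster = id)
  }))
  se_regions <- data.frame(
    chrom = cl$chrom,
    start = vapply(cl$id, function(id)
      min(constituents$start[constituents$cluster == id]), 1),
    end = vapply(cl$id, function(id)
      max(constituents$end[constituents$cluster == id]), 1),
    name = sprintf("SE%02d", cl$id))

  # ---- mark peak sets ----------------------------------------------------
  enh_all <- rbind(typical[c("chrom", "start", "end", "name")],
                   constituents[c("chrom", "start", "end", "name")])
  marks <- list(
    h3k4me3 = peak_ranges(promoters$chrom, promoters$start, promoters$end,
                          name = promoters$name),
    h3k4me1 = peak_ranges(enh_all$chrom, enh_all$start, enh_all$end,
                          name = enh_all$name),
    h3k27ac = peak_ranges(c(promoters$chrom, enh_all$chrom),
                          c(promoters$start, enh_all$start),
                          c(promoters$end, enh_all$end),
                          name = c(promoters$name, enh_all$name))
  )

  # ---- ATAC site table ---------------------------------------------------
  sites <- rbind(
    data.frame(promoters[c("chrom", "start", "end", "name")],
               type = "promoter", cluster = NA_integer_),
    data.frame(typical[c("chrom", "start", "end", "name")],
               type = "enhancer", cluster = NA_integer_),
    data.frame(constituents[c("chrom", "start", "end", "name")],
               type = "se_constituent",
               cluster = constituents$cluster)
  )
  # background peaks in free space (rejection sampling against planted
  # sites keeps site identities unambiguous)
  n_bg <- round(config$background_peak_rate * config$n_chroms *
                  config$chrom_len_bp)
  if (n_bg > 0) {
    occupied <- peak_ranges(sites$chrom, sites$start, sites$end)
    bg <- NULL
    tries <- 0
    while ((is.null(bg) || length(bg) < n_bg) && tries < 50) {
      m <- n_bg - if (is.null(bg)) 0 else length(bg)
      cand <- peak_ranges(
        sample(chroms, m, replace = TRUE),
        s0 <- floor(runif(m, 0, config$chrom_len_bp - k$bg_peak_width)),
        s0 + k$bg_peak_width)
      free <- GenomicRanges::countOverlaps(cand, occupied) == 0 &
        GenomicRanges::countOverlaps(cand, cand) == 1
      cand <- cand[free]
      bg <- if (is.null(bg)) cand else
        sort_peaks(suppressWarnings(c(bg, cand)))
      occupied <- sort_peaks(suppressWarnings(c(occupied, cand)))
      tries <- tries + 1
    }
    bgdf <- as_bed_df(bg)
    sites <- rbind(sites,
                   data.frame(chrom = bgdf$chrom, start = bgdf$start,
                              end = bgdf$end,
                              name = sprintf("bg%04d", seq_len(nrow(bgdf))),
                              type = "background",
                              cluster = NA_integer_))
  }
  sites <- sites[order(sites$chrom, sites$start, sites$end), ]
  rownames(sites) <- NULL

  # ---- plant dependence --------------------------------------------------
  n_dep_enh <- round(config$frac_brg1_dependent_distal *
                       config$n_typical_enhancers)
  dep_enh <- sample(which(sites$type == "enhancer"), n_dep_enh)
  n_dep_cl <- round(config$frac_brg1_dependent_se * config$n_se_clusters)
  dep_clusters <- sort(sample(seq_len(config$n_se_clusters), n_dep_cl))
  dep_const <- which(sites$type == "se_constituent" &
                       sites$cluster %in% dep_clusters)
  sites$dependent <- FALSE
  sites$dependent[c(dep_enh, dep_const)] <- TRUE
  sites$true_log2fc <- ifelse(sites$dependent, config$planted_log2fc, 0)

  # ---- replicate counts and peak sets ------------------------------------
  base_mean <- k$atac_mean[sites$type] *
    exp(if (config$noise) stats::rnorm(nrow(sites), 0, 0.15) else 0)
  sites$base_mean <- unname(base_mean)
  draw <- function(mu) {
    if (config$noise) rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
    else round(mu)
  }
  counts <- sapply(seq_len(2 * config$replicates), function(r) {
    mu <- if (r <= config$replicates) base_mean
    else base_mean * 2^sites$true_log2fc
    draw(mu)
  })
  colnames(counts) <- c(sprintf("control_rep%d", seq_len(config$replicates)),
                        sprintf("treatment_rep%d",
                                seq_len(config$replicates)))
  rep_peaks <- function(col) {
    ok <- counts[, col] >= k$detect_threshold
    if (!any(ok)) return(GenomicRanges::GRanges())
    s <- sites[ok, ]
    j1 <- if (config$noise) floor(runif(nrow(s), 0, k$edge_jitter)) else 0
    j2 <- if (config$noise) floor(runif(nrow(s), 0, k$edge_jitter)) else 0
    peak_ranges(s$chrom, pmax(0, s$start - j1), s$end + j2, name = s$name)
  }
  atac_replicates <- list(
    control = lapply(sprintf("control_rep%d", seq_len(config$replicates)),
                     rep_peaks),
    treatment = lapply(sprintf("treatment_rep%d",
                               seq_len(config$replicates)), rep_peaks)
  )

  # ---- differential table (synthetic stand-in, Welch t on log counts) ----
  lc <- log2(counts + 1)
  ic <- seq_len(config$replicates)
  it <- config$replicates + ic
  m1 <- rowMeans(lc[, ic, drop = FALSE])
  m2 <- rowMeans(lc[, it, drop = FALSE])
  v1 <- apply(lc[, ic, drop = FALSE], 1, stats::var)
  v2 <- apply(lc[, it, drop = FALSE], 1, stats::var)
  se2 <- v1 / length(ic) + v2 / length(it)
  tstat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), ifelse(m2 == m1, 0, Inf))
  dfree <- ifelse(se2 > 0,
                  se2^2 / (v1^2 / (length(ic)^2 * (length(ic) - 1)) +
                             v2^2 / (length(it)^2 * (length(it) - 1))),
                  1)
  pval <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), dfree),
                 0)
  differential <- data.frame(chrom = sites$chrom, start = sites$start,
                             end = sites$end, name = sites$name,
                             log2fc = m2 - m1, fdr = bh_adjust(pval),
                             stringsAsFactors = FALSE)

  # ---- fragment libraries ------------------------------------------------
  frag_intensity <- c(promoter = k$promoter_frags,
                      enhancer = k$enhancer_frags,
                      se_constituent = k$enhancer_frags *
                        config$se_signal_multiplier,
                      background = 0)[sites$type]
  el_frags <- function(row_mu) {
    nfr <- if (config$noise) rpois(length(row_mu), row_mu) else round(row_mu)
    idx <- rep(seq_along(row_mu), nfr)
    mid <- floor(runif(sum(nfr), sites$start[idx], sites$end[idx]))
    data.frame(chrom = sites$chrom[idx],
               start = pmax(0, mid - k$frag_len %/% 2),
               end = mid + k$frag_len %/% 2)
  }
  sig <- el_frags(frag_intensity)
  n_bg_frags <- round(k$bg_frags_per_mb * config$n_chroms *
                        config$chrom_len_bp / 1e6)
  bg_frags <- data.frame(
    chrom = sample(chroms, n_bg_frags, replace = TRUE),
    start = s0 <- floor(runif(n_bg_frags, 0,
                              config$chrom_len_bp - k$frag_len)))
  bg_frags$end <- bg_frags$start + k$frag_len
  n_in <- round(k$input_frags_per_mb * config$n_chroms *
                  config$chrom_len_bp / 1e6)
  input <- data.frame(
    chrom = sample(chroms, n_in, replace = TRUE),
    start = s0 <- floor(runif(n_in, 0, config$chrom_len_bp - k$frag_len)))
  input$end <- input$start + k$frag_len
  sig_all <- rbind(sig, bg_frags)
  fragments <- list(
    h3k27ac = signal_library(peak_ranges(sig_all$chrom, sig_all$start,
                                         sig_all$end)),
    input = signal_library(peak_ranges(input$chrom, input$start,
                                       input$end))
  )

  truth <- list(
    promoters = peak_ranges(promoters$chrom, promoters$start,
                            promoters$end, name = promoters$name),
    enhancers = peak_ranges(enh_all$chrom, enh_all$start, enh_all$end,
                            name = enh_all$name),
    se_regions = peak_ranges(se_regions$chrom, se_regions$start,
                             se_regions$end, name = se_regions$name),
    dependent_clusters = dep_clusters,
    dependent_sites = {
      d <- sites[sites$dependent, ]
      peak_ranges(d$chrom, d$start, d$end, name = d$name)
    }
  )

  structure(list(genes = genes, marks = marks,
                 atac_replicates = atac_replicates, sites = sites,
                 counts = counts, differential = differential,
                 fragments = fragments, truth = truth, config = config),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_bundle: %d chrom x %.0f bp, %d genes, %d ATAC sites ",
    "(%d dependent), %d SE clusters>\n"),
    x$config$n_chroms, x$config$chrom_len_bp, nrow(x$genes),
    nrow(x$sites), sum(x$sites$dependent), x$config$n_se_clusters))
  invisible(x)
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Emits BED peak files per mark and per ATAC replicate, fragment BEDs,
#' the gene and differential TSVs, and a ground-truth TSV. Output is
#' deterministic: identical bundles produce byte-identical files.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the written paths.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wp <- function(gr, name) {
    p <- file.path(dir, name)
    write_peaks(gr, p)
    paths <<- c(paths, p)
  }
  for (mk in names(bundle$marks)) wp(bundle$marks[[mk]],
                                     paste0(mk, ".bed"))
  for (cond in names(bundle$atac_replicates)) {
    reps <- bundle$atac_replicates[[cond]]
    for (i in seq_along(reps)) {
      wp(reps[[i]], sprintf("atac_%s_rep%d.bed", cond, i))
    }
  }
  wp(bundle$fragments$h3k27ac$fragments, "h3k27ac_fragments.bed")
  wp(bundle$fragments$input$fragments, "input_fragments.bed")
  wt <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(bundle$genes, "genes.tsv")
  wt(bundle$differential, "differential.tsv")
  wt(bundle$sites, "ground_truth_sites.tsv")
  wt(as_bed_df(bundle$truth$se_regions), "ground_truth_se_regions.tsv")
  invisible(paths)
}
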