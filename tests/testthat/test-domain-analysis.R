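test_that("features land in the bin containing their midpoint", {
  g <- genome_description("c1", 2e6)
  f <- data.frame(chrom = "c1", start = c(499849, 499850), end = c(500149, 500150))
  # midpoints 499999 and 500000
  b <- bin_features(f, g, bin_size = 5e5)
  expect_equal(b$n[1:2], c(1L, 1L))
  expect_equal(sum(b$n), 2)
  expect_error(bin_features(data.frame(chrom = "c1", start = 1.99e6, end = 2.1e6),
                            g, bin_size = 5e5), "midpoint beyond")
})

test_that("bin counts agree with brute-force midpoint bucketing", {
  set.seed(61)
  g <- genome_description(c("c1", "c2"), c(1e6, 7e5))
  f <- random_interval_df(10000, g, max_len = 300)
  b <- bin_features(f, g, bin_size = 1e5)
  expect_equal(sum(b$n), nrow(f))
  mid <- (f$start + f$end) / 2
  for (chrom in g$chrom) {
    expected <- table(factor(floor(mid[f$chrom == chrom] / 1e5),
                             levels = 0:(ceiling(g$length[g$chrom == chrom] / 1e5) - 1)))
    expect_equal(b$n[b$chrom == chrom], as.integer(expected))
  }
})

test_that("domain calling follows the hand-computed quantile example", {
  # nonzero-bin counts {1,5,6,7,1}: q75 = 5.75; bins with 6 and 7 qualify,
  # they are non-adjacent -> 2 single-bin domains
  g <- genome_description("c1", 6000)
  f <- features_from_counts(c(1, 5, 6, 0, 7, 1))
  b <- bin_features(f, g, bin_size = 1000)
  d <- call_bads(b, quantile = 0.75)
  expect_equal(attr(d, "threshold"), 5.75)
  expect_equal(nrow(d), 2)
  expect_equal(d$n_bins, c(1, 1))
  expect_equal(d$n_features, c(6, 7))
})

test_that("all features in one bin give exactly one domain containing it", {
  g <- genome_description("c1", 5000)
  f <- features_from_counts(c(0, 4, 0, 0, 0))
  d <- call_bads(bin_features(f, g, bin_size = 1000))
  expect_equal(nrow(d), 1)
  expect_gte(d$start, 1000)
  expect_lte(d$end, 2000)
  expect_equal(d$n_features, 4)
})

test_that("equal bin counts give zero domains with a warning", {
  g <- genome_description("c1", 4000)
  f <- features_from_counts(c(2, 2, 2, 2))
  expect_warning(d <- call_bads(bin_features(f, g, bin_size = 1000)),
                 "zero domains")
  expect_equal(nrow(d), 0)
})

test_that("domain calling equals a brute-force threshold/run-merge oracle", {
  set.seed(71)
  for (i in 1:100) {
    nb <- sample(5:30, 1)
    counts <- rpois(nb, sample(1:4, 1)) * rbinom(nb, 1, 0.6)
    if (all(counts == 0)) counts[1] <- 2
    g <- genome_description("c1", nb * 1000)
    b <- bin_features(features_from_counts(counts), g, bin_size = 1000)
    thr <- as.numeric(quantile(counts[counts >= 1], 0.75, type = 4))
    mask <- counts > thr
    # degenerate rule: a unique occupied bin is itself the top quantile
    if (!any(mask) && sum(counts >= 1) == 1) mask <- counts >= thr
    r <- rle(mask)
    runs_n <- r$lengths[r$values]
    if (!any(mask)) {
      expect_warning(d <- call_bads(b), "zero domains")
      expect_equal(nrow(d), 0)
    } else {
      d <- call_bads(b)
      expect_equal(nrow(d), length(runs_n))
      expect_equal(d$n_bins, runs_n)
      # trimmed interval contained in the union of qualifying bins
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      k <- 0
      for (j in which(r$values)) {
        k <- k + 1
        expect_gte(d$start[k], (starts[j] - 1) * 1000)
        expect_lte(d$end[k], ends[j] * 1000)
      }
    }
  }
})

test_that("domains are invariant under chromosome reordering and the
          quantile is monotone", {
  set.seed(81)
  g <- genome_description(c("c1", "c2"), c(2e4, 2e4))
  f <- rbind(features_from_counts(rpois(20, 2), "c1"),
             features_from_counts(rpois(20, 2), "c2"))
  b <- bin_features(f, g, bin_size = 1000)
  g2 <- genome_description(c("c2", "c1"), c(2e4, 2e4))
  b2 <- bin_features(f, g2, bin_size = 1000)
  d <- call_bads(b); d2 <- call_bads(b2)
  key <- function(d) sort(paste(d$chrom, d$start, d$end, d$n_features))
  expect_equal(key(d), key(d2))
  # raising the quantile never increases qualifying bins
  n_qual <- function(q) {
    dd <- tryCatch(suppressWarnings(call_bads(b, quantile = q)),
                   error = function(e) NULL)
    if (is.null(dd) || nrow(dd) == 0) 0 else sum(dd$n_bins)
  }
  qs <- c(0.5, 0.75, 0.9)
  expect_true(all(diff(sapply(qs, n_qual)) <= 0))
  # no two domains on one chromosome are adjacent
  for (chrom in unique(d$chrom)) {
    dc <- d[d$chrom == chrom, ]
    if (nrow(dc) > 1) {
      bin_end <- ceiling(dc$end / 1000)
      bin_start <- floor(dc$start / 1000)
      expect_true(all(bin_start[-1] > bin_end[-nrow(dc)]))
    }
  }
})

test_that("domain-LAD overlap matches the exact combinatorial example", {
  # population 100 bins, 40 LAD bins, 10 domain bins, 9 overlapping
  g <- genome_description("c1", 100 * 1000)
  lad <- annotation_track("lads", data.frame(chrom = "c1", start = 0, end = 40 * 1000))
  # domains: 9 bins inside the LAD region, 1 outside
  dom <- data.frame(chrom = "c1",
                    start = c(0:8 * 1000 + 10, 50 * 1000 + 10),
                    end = c(0:8 * 1000 + 900, 50 * 1000 + 900))
  o <- domain_overlap(dom, lad, g, bin_size = 1000)
  expect_equal(o$pop_bins, 100)
  expect_equal(o$lad_bins, 40)
  expect_equal(o$domain_bins, 10)
  expect_equal(o$overlap_bins, 9)
  expect_equal(o$p_hyper, hyper_tail_oracle(9, 40, 100, 10), tolerance = 1e-12)
})

test_that("saturated LAD coverage gives fraction 1 and p = 1", {
  g <- genome_description("c1", 1e4)
  lad <- annotation_track("lads", data.frame(chrom = "c1", start = 0, end = 1e4))
  dom <- data.frame(chrom = "c1", start = c(0, 5000), end = c(1000, 6000))
  o <- domain_overlap(dom, lad, g, bin_size = 1000)
  expect_equal(o$fraction, 1)
  expect_equal(o$p_hyper, 1)
  expect_warning(o0 <- domain_overlap(dom[0, ], lad, g), "undefined")
  expect_true(is.na(o0$fraction))
})

test_that("hypergeometric p equals combinatorial summation on random cases", {
  set.seed(91)
  for (i in 1:50) {
    N <- sample(20:500, 1)
    m <- sample.int(N, 1)
    k <- sample.int(N, 1)
    x <- sample(max(0, m + k - N):min(m, k), 1)
    if (x == 0) next
    expect_equal(phyper(x - 1, m, N - m, k, lower.tail = FALSE),
                 hyper_tail_oracle(x, m, N, k), tolerance = 1e-12)
  }
})

test_that("landscape correlation behaves at the identity and antisymmetry limits", {
  g <- genome_description("c1", 1e4)
  f <- features_from_counts(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  b <- bin_features(f, g, bin_size = 1000)
  expect_equal(landscape_correlation(b, b)$rho, 1)
  frev <- features_from_counts(rev(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)))
  brev <- bin_features(frev, g, bin_size = 1000)
  expect_equal(landscape_correlation(b, brev)$rho, -1)
  # fewer than 3 informative bins -> NA
  g2 <- genome_description("c1", 2000)
  b2 <- bin_features(features_from_counts(c(1, 1)), g2, bin_size = 1000)
  expect_true(is.na(landscape_correlation(b2, b2)$rho))
})

test_that("X-like peaks placed away from hypo domains anticorrelate with DMRs", {
  out <- tiny_simulation(seed = 57, auto_len = 3e6, x_len = 3e6, n_domains = 2)
  cfg <- out$config
  sim <- out$sim
  tk <- simulate_tracks(cfg, sim$ground_truth)
  m <- sim$methylomes
  d <- call_dmrs(m[c("control_rep1", "control_rep2")],
                 m$treatment_rep1, m$treatment_rep2, cfg$genome)
  bd <- bin_features(d, cfg$genome, bin_size = 2.5e5)
  bp <- bin_features(tk$tracks$peaks$intervals, cfg$genome, bin_size = 2.5e5)
  rho <- landscape_correlation(bd, bp)
  expect_lt(rho$rho[rho$chrom == "aX"], 0)
})
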