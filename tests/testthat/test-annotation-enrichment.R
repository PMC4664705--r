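test_that("feature-to-element assignment uses >= 1 bp half-open overlap", {
  tracks <- list(e1 = annotation_track("e1", data.frame(chrom = "c1",
                                                        start = 399, end = 500)),
                 e2 = annotation_track("e2", data.frame(chrom = "c1",
                                                        start = 400, end = 500)))
  f <- data.frame(chrom = "c1", start = 100, end = 400)
  a <- assign_to_elements(f, tracks)
  expect_equal(a$n_features, c(1, 0))
})

test_that("assignment counts equal the quadratic all-pairs oracle", {
  set.seed(33)
  g <- genome_description(c("c1", "c2"), c(1e5, 1e5))
  feats <- random_interval_df(1000, g)
  tr <- annotation_track("t", random_interval_df(200, g, max_len = 2000))
  a <- assign_to_elements(feats, list(t = tr))
  expect_equal(a$n_features, sum(overlap_pairs_oracle(feats, tr$intervals)))
})

test_that("tracks on unknown chromosomes are ignored with a warning", {
  g <- genome_description("c1", 1e4)
  tr <- annotation_track("t", data.frame(chrom = c("c1", "zz"),
                                         start = c(0, 0), end = c(100, 100)))
  f <- data.frame(chrom = "c1", start = 0, end = 50)
  expect_warning(a <- assign_to_elements(f, list(t = tr), genome = g),
                 "unknown chromosome")
  expect_equal(a$n_features, 1)
})

test_that("enrichment is the feature fraction over the genome fraction", {
  g <- genome_description("c1", 1e6)
  tr <- annotation_track("t", data.frame(chrom = "c1", start = 0, end = 1e5))
  set.seed(1)
  inside <- data.frame(chrom = "c1", start = 0:29 * 1000, end = 0:29 * 1000 + 100)
  outside <- data.frame(chrom = "c1",
                        start = seq(2e5, 9e5, length.out = 70),
                        end = seq(2e5, 9e5, length.out = 70) + 100)
  e <- element_enrichment(rbind(inside, outside), tr, g)
  expect_equal(e$enrichment, (30 / 100) / 0.1)
  # track = whole genome: enrichment identically 1
  whole <- annotation_track("w", data.frame(chrom = "c1", start = 0, end = 1e6))
  expect_equal(element_enrichment(inside, whole, g)$enrichment, 1)
})

test_that("uniformly scattered features have enrichment near 1", {
  set.seed(202)
  g <- genome_description("c1", 1e6)
  tr <- annotation_track("t", data.frame(chrom = "c1", start = 3e5, end = 4e5))
  s <- floor(runif(1e4) * (1e6 - 50))
  feats <- data.frame(chrom = "c1", start = s, end = s + 50)
  e <- element_enrichment(feats, tr, g)
  expect_equal(e$enrichment, 1, tolerance = 0.05)
})

test_that("width-1 features partition between a track and its complement", {
  set.seed(9)
  g <- genome_description("c1", 1e5)
  tr <- data.frame(chrom = "c1", start = c(1e4, 5e4), end = c(2e4, 7e4))
  comp <- data.frame(chrom = "c1", start = c(0, 2e4, 7e4), end = c(1e4, 5e4, 1e5))
  pos <- sample.int(1e5, 500) - 1
  feats <- data.frame(chrom = "c1", start = pos, end = pos + 1)
  fin <- element_enrichment(feats, annotation_track("t", tr), g)$fraction_of_features
  fout <- element_enrichment(feats, annotation_track("c", comp), g)$fraction_of_features
  expect_equal(fin + fout, 1)
})

test_that("permutation significance has the right sign behaviour", {
  g <- genome_description("c1", 1e5)
  tr <- annotation_track("t", data.frame(chrom = "c1", start = 0, end = 5e4))
  # all features outside a track covering half the chromosome: observed count
  # (0) is below the permutation median -> p > 0.5
  f <- data.frame(chrom = "c1", start = seq(6e4, 9e4, by = 1e3),
                  end = seq(6e4, 9e4, by = 1e3) + 100)
  expect_gt(enrichment_significance(f, tr, g, n_perm = 100, seed = 1), 0.5)
  # track spanning the whole chromosome: every permutation ties
  whole <- annotation_track("w", data.frame(chrom = "c1", start = 0, end = 1e5))
  expect_equal(enrichment_significance(f, whole, g, n_perm = 100, seed = 1), 1)
  expect_error(enrichment_significance(
    data.frame(chrom = "c1", start = 0, end = 2e5), tr, g, n_perm = 100),
    "wider than")
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(55)
  g <- genome_description("c1", 1e5)
  tr <- annotation_track("t", data.frame(chrom = "c1", start = 2e4, end = 4e4))
  ps <- vapply(1:40, function(i) {
    s <- floor(runif(60) * (1e5 - 200))
    f <- data.frame(chrom = "c1", start = s, end = s + 200)
    enrichment_significance(f, tr, g, n_perm = 199, seed = 1000 + i)
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.75)
  expect_lt(mean(ps <= 0.25), 0.5)
})

test_that("band shift table is an identity-respecting partition", {
  out <- tiny_simulation(seed = 41, auto_len = 5e5, x_len = 5e5, n_domains = 1)
  g <- out$config$genome
  m <- out$sim$methylomes
  ctl <- pool_methylomes(m[c("control_rep1", "control_rep2")])
  tr <- list(t = annotation_track("t", data.frame(chrom = c("a1", "aX"),
                                                  start = c(0, 0),
                                                  end = c(5e5, 5e5))))
  # treatment == control -> all mean differences 0
  b0 <- band_shift_table(ctl, ctl, tr, g)
  expect_true(all(abs(b0$mean_diff[b0$n_instances > 0]) < 1e-12))
  # uniform +10% shift (fractional counts keep it exact) -> every covered
  # band shifts by exactly 10
  shifted <- ctl
  shifted$sites$meth <- ctl$sites$meth + 0.1 * ctl$sites$total
  ok <- shifted$sites$meth <= shifted$sites$total
  shifted$sites <- shifted$sites[ok, ]
  ctl2 <- ctl; ctl2$sites <- ctl$sites[ok, ]
  b10 <- band_shift_table(ctl2, shifted, tr, g)
  expect_equal(b10$mean_diff[b10$n_instances > 0],
               rep(10, sum(b10$n_instances > 0)), tolerance = 1e-9)
  # bands partition the covered instances; with a whole-genome track the
  # instances are exactly the grid cells covered in both conditions
  trt <- pool_methylomes(m[c("treatment_rep1", "treatment_rep2")])
  b <- band_shift_table(ctl, trt, tr, g)
  covered <- function(mm) {
    s <- mm$sites[mm$sites$total > 0, ]
    unique(paste(s$chrom, s$pos %/% 300))
  }
  expect_equal(sum(b$n_instances),
               length(intersect(covered(ctl), covered(trt))))
})

test_that("planted hyper domains shift the high-coverage band upward", {
  out <- tiny_simulation(seed = 47, auto_len = 2e6, x_len = 2e6, n_domains = 2)
  g <- out$config$genome
  m <- out$sim$methylomes
  dom <- out$sim$ground_truth$domains
  hyper <- dom[dom$direction == "hyper", ]
  ctl <- pool_methylomes(m[c("control_rep1", "control_rep2")])
  trt <- pool_methylomes(m[c("treatment_rep1", "treatment_rep2")])
  tr <- list(hy = annotation_track("hy", hyper[, c("chrom", "start", "end")]))
  b <- band_shift_table(ctl, trt, tr, g)
  # inside hyper domains the control sits in the PMD band and gains ~ +40
  pmd <- b[b$band == "PMD", ]
  expect_gt(pmd$n_instances, 100)
  expect_equal(pmd$mean_diff, 40, tolerance = 3)
})
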