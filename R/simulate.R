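# Seeded synthetic WGBS generator: paired methylomes with planted
# differentially methylated domains, plus annotation tracks, LADs, peaks and
# a labelled gene table, with ground truth for recovery scoring.

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_rng <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Poisson truncated at >= 1
rpois_pos <- function(n, lambda) {
  x <- stats::rpois(n, lambda)
  z <- which(x == 0)
  while (length(z)) {
    x[z] <- stats::rpois(length(z), lambda)
    z <- z[x[z] == 0]
  }
  x
}

#' Default synthetic genome
#'
#' Three autosome-like chromosomes and one X-like chromosome, 10 Mb each.
#'
#' @return a `genome_description`
#' @export
default_genome <- function() {
  genome_description(c("chr1", "chr2", "chr3", "chrX"),
                     rep(1e7, 4), x_like = c(FALSE, FALSE, FALSE, TRUE))
}

#' Configuration of the synthetic methylome generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' ~25x coverage WGBS of two conditions with two replicates each, a mostly
#' methylated background (80%) broken by unmethylated CpG-island-like
#' regions (10%), planted hypermethylation domains on autosome-like
#' chromosomes (+0.4 on a partially methylated 0.45 pre-shift background)
#' and hypomethylation domains on the X-like chromosome (-0.4 from 0.8),
#' and a LAD track constructed to cover a controlled fraction (default 0.6)
#' of the planted autosomal domains.
#'
#' @param seed integer seed; the seed fully determines all outputs
#' @param genome a `genome_description` (default [default_genome()])
#' @param cpg_spacing_mean mean CpG spacing in bp (geometric point process)
#' @param coverage_mean mean read coverage per site (Poisson, truncated >= 1)
#' @param baseline_meth background and island true methylation levels
#' @param domain_baseline pre-shift level inside planted hyper domains (PMD-like,
#'   so the +delta shift stays inside \[0, 1\] without clipping)
#' @param n_planted_domains planted domains per chromosome
#' @param domain_delta named shifts applied in the treatment condition inside
#'   planted domains: `autosome` (hyper) and `x` (hypo)
#' @param domain_length_range planted domain length range in bp
#' @param lad_overlap_fraction target fraction of planted autosomal domains
#'   covered by generated LADs
#' @param n_replicates replicates per condition
#' @param replicate_jitter half-width of the uniform per-replicate,
#'   per-site jitter on true levels (biological replicate noise)
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L,
                              genome = default_genome(),
                              cpg_spacing_mean = 100,
                              coverage_mean = 25,
                              baseline_meth = c(background = 0.8, island = 0.1),
                              domain_baseline = 0.45,
                              n_planted_domains = 3L,
                              domain_delta = c(autosome = 0.4, x = -0.4),
                              domain_length_range = c(3e5, 2e6),
                              lad_overlap_fraction = 0.6,
                              n_replicates = 2L,
                              replicate_jitter = 0.02) {
  probs <- c(baseline_meth, domain_baseline, lad_overlap_fraction)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  structure(list(seed = as.integer(seed), genome = genome,
                 cpg_spacing_mean = cpg_spacing_mean,
                 coverage_mean = coverage_mean,
                 baseline_meth = baseline_meth,
                 domain_baseline = domain_baseline,
                 n_planted_domains = as.integer(n_planted_domains),
                 domain_delta = domain_delta,
                 domain_length_range = domain_length_range,
                 lad_overlap_fraction = lad_overlap_fraction,
                 n_replicates = as.integer(n_replicates),
                 replicate_jitter = replicate_jitter),
            class = "simulation_config")
}

# non-overlapping random intervals on one chromosome; the length range is
# shrunk on chromosomes too small to hold it
place_domains <- function(chrom, chrom_len, n, len_range, margin = 1e5) {
  hi <- min(len_range[2], chrom_len / 2)
  lo <- min(len_range[1], hi / 2)
  margin <- min(margin, chrom_len / 20)
  placed <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    len <- stats::runif(1, lo, hi)
    for (try in 1:200) {
      s <- floor(stats::runif(1, 0, chrom_len - len))
      cand <- c(s, s + len)
      ok <- !nrow(placed) ||
        all(cand[2] + margin <= placed$start | cand[1] >= placed$end + margin)
      if (ok) {
        placed <- rbind(placed, data.frame(chrom = chrom, start = cand[1],
                                           end = cand[2]))
        break
      }
    }
  }
  placed
}

#' Simulate paired WGBS methylomes with planted domains
#'
#' Generates CpG positions per chromosome as a geometric-spacing point
#' process, assigns true methylation levels (background / islands / planted
#' domains), and draws, for each condition and replicate, coverage
#' `~ Poisson(coverage_mean)` truncated at >= 1 and methylated reads
#' `~ Binomial(coverage, level)`, with per-replicate true levels jittered
#' uniformly by `+/- replicate_jitter`. Treatment levels are shifted by
#' `domain_delta` inside planted domains only and clipped to \[0.01, 0.99\]
#' (clipping is reported via `message()`).
#'
#' @param config a [simulation_config()]
#' @return a list with `methylomes` (list of `2 x n_replicates` `methylome`
#'   objects named e.g. `control_rep1`) and `ground_truth` (planted
#'   `domains` with a `direction` column, island intervals, and per-site
#'   true levels for both conditions)
#' @export
simulate_methylomes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_rng(config$seed, {
    g <- config$genome
    sites <- list(); islands <- list(); domains <- list()
    for (i in seq_len(nrow(g))) {
      chrom <- g$chrom[i]; L <- g$length[i]
      n_exp <- ceiling(L / config$cpg_spacing_mean * 1.3) + 100
      gaps <- stats::rgeom(n_exp, 1 / config$cpg_spacing_mean) + 2
      pos <- cumsum(gaps)
      pos <- pos[pos < L]
      sites[[chrom]] <- data.frame(chrom = chrom, pos = pos,
                                   strand = sample(c("+", "-"), length(pos),
                                                   replace = TRUE),
                                   stringsAsFactors = FALSE)
      n_isl <- max(1L, round(L / 1e5))
      is_len <- stats::runif(n_isl, 500, 2000)
      is_start <- floor(stats::runif(n_isl, 0, L - is_len))
      islands[[chrom]] <- merge_intervals(
        data.frame(chrom = chrom, start = is_start, end = is_start + is_len))
      if (config$n_planted_domains > 0) {
        d <- place_domains(chrom, L, config$n_planted_domains,
                           config$domain_length_range)
        d$direction <- if (g$x_like[i]) "hypo" else "hyper"
        domains[[chrom]] <- d
      }
    }
    sites <- do.call(rbind, sites)
    islands <- do.call(rbind, islands)
    domains <- if (length(domains)) do.call(rbind, domains) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 direction = character(), stringsAsFactors = FALSE)
    rownames(sites) <- rownames(islands) <- rownames(domains) <- NULL

    pos_iv <- data.frame(chrom = sites$chrom, start = sites$pos,
                         end = sites$pos + 1)
    in_island <- overlaps_any(pos_iv, islands)
    base <- ifelse(in_island, config$baseline_meth[["island"]],
                   config$baseline_meth[["background"]])
    treat <- base
    if (nrow(domains)) {
      hyper <- domains[domains$direction == "hyper", , drop = FALSE]
      hypo <- domains[domains$direction == "hypo", , drop = FALSE]
      in_hyper <- overlaps_any(pos_iv, hyper)
      in_hypo <- overlaps_any(pos_iv, hypo)
      # planted hyper domains sit on a PMD-like pre-shift background so the
      # +delta shift does not saturate at 1
      base[in_hyper & !in_island] <- config$domain_baseline
      treat <- base
      treat[in_hyper] <- treat[in_hyper] + config$domain_delta[["autosome"]]
      treat[in_hypo] <- treat[in_hypo] + config$domain_delta[["x"]]
      n_clip <- sum(treat < 0.01 | treat > 0.99)
      if (n_clip) message(n_clip, " site level(s) clipped to [0.01, 0.99]")
      treat <- pmin(pmax(treat, 0.01), 0.99)
    }

    n <- nrow(sites)
    draw <- function(level, condition, rep) {
      jit <- stats::runif(n, -config$replicate_jitter, config$replicate_jitter)
      lvl <- pmin(pmax(level + jit, 0.005), 0.995)
      cov <- rpois_pos(n, config$coverage_mean)
      s <- sites
      s$meth <- stats::rbinom(n, cov, lvl)
      s$total <- cov
      s$context <- "CpG"
      methylome(sprintf("%s_rep%d", condition, rep), condition, rep, s)
    }
    meths <- list()
    for (r in seq_len(config$n_replicates))
      meths[[sprintf("control_rep%d", r)]] <- draw(base, "control", r)
    for (r in seq_len(config$n_replicates))
      meths[[sprintf("treatment_rep%d", r)]] <- draw(treat, "treatment", r)

    list(methylomes = meths,
         ground_truth = list(
           domains = domains, islands = islands,
           site_levels = data.frame(chrom = sites$chrom, pos = sites$pos,
                                    control_level = base,
                                    treatment_level = treat)))
  })
}

# uniform random intervals, optionally forced inside or kept away from regions
random_intervals <- function(genome, chroms, n_per, len_range,
                             within = NULL, avoid = NULL) {
  out <- list()
  for (chrom in chroms) {
    L <- chrom_length(genome, chrom)
    len <- stats::runif(n_per, len_range[1], len_range[2])
    if (!is.null(within)) {
      w <- within[within$chrom == chrom, , drop = FALSE]
      if (!nrow(w)) next
      pick <- sample.int(nrow(w), n_per, replace = TRUE)
      len <- pmin(len, (w$end - w$start)[pick])
      s <- floor(w$start[pick] +
                   stats::runif(n_per) * (w$end[pick] - w$start[pick] - len))
      df <- data.frame(chrom = chrom, start = pmax(0, s), end = pmax(0, s) + len)
    } else {
      s <- floor(stats::runif(n_per) * (L - len))
      df <- data.frame(chrom = chrom, start = s, end = s + len)
    }
    if (!is.null(avoid) && nrow(avoid)) {
      for (try in 1:50) {
        hit <- overlaps_any(df, avoid)
        if (!any(hit)) break
        k <- sum(hit)
        s <- floor(stats::runif(k) * (L - (df$end[hit] - df$start[hit])))
        df$end[hit] <- s + (df$end[hit] - df$start[hit])
        df$start[hit] <- s
      }
      df <- df[!overlaps_any(df, avoid), , drop = FALSE]
    }
    out[[chrom]] <- df
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(res) <- NULL
  res
}

#' Simulate annotation tracks, LADs, peaks and a gene table
#'
#' Builds element tracks with the regional biases the downstream statistics
#' are designed to detect: satellite-like elements preferentially inside
#' planted hyper domains, enhancer-like elements preferentially inside
#' planted X-like hypo domains, LINE-like elements uniform, CpG islands
#' taken from the methylome ground truth with shores derived from them, a
#' LAD track constructed so that `lad_overlap_fraction` of the planted
#' autosomal domains intersect at least one LAD (the rest of the LADs are
#' background kept away from all planted domains), a ChIP-peak-like track
#' placed away from X-like planted domains and near autosomal hyper
#' domains, and a gene table in which repressed genes are preferentially
#' placed inside or near planted domains.
#'
#' @param config the [simulation_config()] used for [simulate_methylomes()]
#' @param ground_truth the `ground_truth` element returned by
#'   [simulate_methylomes()]
#' @return a list with `tracks` (named list of `annotation_track`s:
#'   `satellites`, `lines`, `enhancers`, `cgi`, `shores`, `lads`, `peaks`)
#'   and `genes` (gene data frame with `status` labels)
#' @export
simulate_tracks <- function(config, ground_truth) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$genome
  auto <- g$chrom[!g$x_like]; xchr <- g$chrom[g$x_like]
  dom <- ground_truth$domains
  hyper <- dom[dom$direction == "hyper", , drop = FALSE]
  hypo <- dom[dom$direction == "hypo", , drop = FALSE]

  frac <- config$lad_overlap_fraction
  if (frac > 0 && nrow(hyper) == 0)
    stop("requested LAD overlap fraction ", frac,
         " unreachable: no planted autosomal domains (achievable maximum is 0)")

  with_rng(config$seed + 1000003L, {
    sat_in <- random_intervals(g, auto, 6, c(2e3, 1e4), within = hyper)
    sat_out <- random_intervals(g, c(auto, xchr), 4, c(2e3, 1e4), avoid = dom)
    lines_tr <- random_intervals(g, g$chrom, 40, c(1e3, 6e3))
    enh_x <- random_intervals(g, xchr, 25, c(500, 1500), within = hypo)
    enh_bg <- random_intervals(g, g$chrom, 20, c(500, 1500))
    cgi <- annotation_track("cgi", ground_truth$islands)
    shores <- derive_shores(cgi, 2000, genome = g)

    # LADs: one covering LAD per selected hyper domain, extended into free
    # space only (clipped against neighbouring planted domains so the
    # unselected domains stay LAD-free), plus background LADs elsewhere
    # randomized rounding keeps the expected realized fraction at the target
    kf <- frac * nrow(hyper)
    k <- floor(kf) + (stats::runif(1) < kf - floor(kf))
    lads <- data.frame(chrom = character(), start = numeric(), end = numeric())
    if (k > 0) {
      idx <- sample.int(nrow(hyper), k)
      rows <- lapply(idx, function(j) {
        d <- hyper[j, ]
        others <- dom[dom$chrom == d$chrom, , drop = FALSE]
        others <- others[others$start != d$start, , drop = FALSE]
        s <- max(0, d$start - stats::runif(1, 0, 3e5))
        e <- min(chrom_length(g, d$chrom), d$end + stats::runif(1, 0, 3e5))
        left <- others$end[others$end <= d$start]
        right <- others$start[others$start >= d$end]
        if (length(left)) s <- max(s, max(left))
        if (length(right)) e <- min(e, min(right))
        data.frame(chrom = d$chrom, start = floor(s), end = floor(e))
      })
      lads <- do.call(rbind, rows)
    }
    bg <- random_intervals(g, auto, 2, c(3e5, 1.5e6), avoid = dom)
    lads <- rbind(lads, bg)

    # peaks: away from X-like hypo domains, near autosomal hyper domains
    pk_x <- random_intervals(g, xchr, 150, c(500, 2000), avoid = hypo)
    pk_a_in <- random_intervals(g, auto, 30, c(500, 2000), within = hyper)
    pk_a_bg <- random_intervals(g, auto, 30, c(500, 2000))
    peaks <- rbind(pk_x, pk_a_in, pk_a_bg)

    # genes: repressed genes preferentially inside/near planted domains
    genes <- list()
    for (chrom in g$chrom) {
      L <- chrom_length(g, chrom)
      n_gene <- round(L / 5e4)
      status <- sample(c("repressed", "activated", "unchanged"), n_gene,
                       replace = TRUE, prob = c(0.15, 0.15, 0.7))
      len <- stats::runif(n_gene, 2e3, 2e4)
      s <- floor(stats::runif(n_gene) * (L - len))
      d_chr <- dom[dom$chrom == chrom, , drop = FALSE]
      near <- status == "repressed" & stats::runif(n_gene) < 0.7
      if (nrow(d_chr) && any(near)) {
        pick <- sample.int(nrow(d_chr), sum(near), replace = TRUE)
        span <- d_chr$end[pick] - d_chr$start[pick]
        s[near] <- floor(d_chr$start[pick] +
                           stats::runif(sum(near)) * pmax(1, span - len[near]))
      }
      genes[[chrom]] <- data.frame(
        gene_id = sprintf("%s_g%04d", chrom, seq_len(n_gene)), chrom = chrom,
        start = s, end = pmin(s + len, L),
        strand = sample(c("+", "-"), n_gene, replace = TRUE),
        status = status, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    rownames(genes) <- NULL

    list(tracks = list(satellites = annotation_track("satellites",
                                                     rbind(sat_in, sat_out)),
                       lines = annotation_track("lines", lines_tr),
                       enhancers = annotation_track("enhancers",
                                                    rbind(enh_x, enh_bg)),
                       cgi = cgi, shores = shores,
                       lads = annotation_track("lads", lads),
                       peaks = annotation_track("peaks", peaks)),
         genes = genes)
  })
}
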