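# Megabase-scale structure: 0.5 Mb binning of DMRs/peaks, domain calling
# as contiguous top-quartile bin runs, LAD overlap with a hypergeometric
# test, and rank correlation of binned landscapes.

#' Bin features into fixed-width genomic bins
#'
#' Each feature is assigned to the bin containing its midpoint (this
#' avoids double-counting short features straddling a bin edge). Bins tile
#' each chromosome from position 0; direction-split counts are kept when
#' the features carry a `direction` column.
#'
#' @param features interval data frame (optionally with `direction` in
#'   `hyper`/`hypo`), or a `dmr_set`
#' @param genome a `genome_description`
#' @param bin_size bin width in bp (default 5e5)
#' @return a `binned_track`: per-bin data frame (`chrom`, `start`, `end`,
#'   `n`, `n_hyper`, `n_hypo`) covering every bin of the genome, with the
#'   assigned features kept as attribute `"features"`
#' @export
bin_features <- function(features, genome, bin_size = 5e5) {
  if (inherits(features, "dmr_set")) features <- features$dmrs
  validate_intervals(features, "features")
  bins <- tile_windows(genome, bin_size)
  bins$n <- bins$n_hyper <- bins$n_hypo <- 0L
  mid <- (features$start + features$end) / 2
  L <- chrom_length(genome, features$chrom)
  if (any(mid >= L))
    stop("feature midpoint beyond chromosome length")
  ci <- match(features$chrom, genome$chrom)
  bidx <- floor(mid / bin_size)
  # global row index of each feature's bin
  n_bins_per <- ceiling(genome$length / bin_size)
  offset <- cumsum(c(0, n_bins_per))[ci]
  row <- offset + bidx + 1
  tab <- table(factor(row, levels = seq_len(nrow(bins))))
  bins$n <- as.integer(tab)
  dir <- if (!is.null(features$direction)) features$direction else
    rep(NA_character_, nrow(features))
  bins$n_hyper <- as.integer(table(factor(row[dir %in% "hyper"],
                                          levels = seq_len(nrow(bins)))))
  bins$n_hypo <- as.integer(table(factor(row[dir %in% "hypo"],
                                         levels = seq_len(nrow(bins)))))
  feats <- features
  feats$bin_row <- row
  structure(bins, class = c("binned_track", "data.frame"),
            bin_size = bin_size, genome = genome, features = feats)
}

#' Call domains as contiguous runs of top-quartile bins
#'
#' The qualifying threshold is the `quantile` quantile (empirical CDF with
#' linear interpolation) of the genome-wide DMR-count distribution over
#' bins containing at least one feature; bins qualify when their count is
#' STRICTLY greater than the threshold. Maximal runs of adjacent
#' qualifying bins on one chromosome form domains. Each domain's interval
#' is trimmed to span from the first to the last feature inside its
#' terminal bins (so a single-bin domain can be shorter than one bin).
#' Direction is the majority direction of member features; ties resolve to
#' `hyper` with a warning.
#'
#' @param binned a `binned_track` from [bin_features()]
#' @param quantile qualifying quantile of nonzero bin counts (default 0.75)
#' @return data frame of domains: `chrom`, `start`, `end`, `n_bins`,
#'   `n_features`, `direction`, `length_bp`
#' @export
call_bads <- function(binned, quantile = 0.75) {
  stopifnot(inherits(binned, "binned_track"))
  nz <- binned$n[binned$n >= 1]
  if (length(nz) == 0) stop("no bin contains a feature")
  thr <- as.numeric(stats::quantile(nz, quantile, type = 4, names = FALSE))
  qual <- binned$n > thr
  # degenerate single-nonzero-bin distribution: the strictly-greater rule
  # can never qualify the unique occupied bin, which by construction holds
  # the whole top quantile; call it
  if (!any(qual) && length(nz) == 1) qual <- binned$n >= thr
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_bins = integer(), n_features = integer(),
                      direction = character(), length_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(qual)) {
    warning("no bin exceeds the quantile threshold (", thr, "); zero domains")
    return(empty)
  }
  feats <- attr(binned, "features")
  dir <- if (!is.null(feats$direction)) feats$direction else
    rep(NA_character_, nrow(feats))
  out <- list()
  for (chrom in unique(binned$chrom)) {
    rows <- which(binned$chrom == chrom)
    r <- rle(qual[rows])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      brows <- rows[starts[j]:ends[j]]
      member <- feats$bin_row %in% brows
      # trim to terminal feature extent inside the first and last bin
      first_rows <- feats$bin_row == brows[1]
      last_rows <- feats$bin_row == brows[length(brows)]
      dstart <- min(feats$start[member & first_rows])
      dend <- max(feats$end[member & last_rows])
      nh <- sum(dir[member] %in% "hyper"); nl <- sum(dir[member] %in% "hypo")
      if (nh == nl && nh > 0)
        warning("direction tie in domain ", chrom, ":", dstart, "-", dend,
                "; labelled hyper")
      d <- if (nh == 0 && nl == 0) NA_character_ else
        if (nl > nh) "hypo" else "hyper"
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = dstart, end = dend,
        n_bins = length(brows), n_features = sum(member), direction = d,
        length_bp = dend - dstart, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  attr(res, "threshold") <- thr
  res
}

#' Overlap of domains with a LAD track
#'
#' A domain overlaps a LAD iff they share at least 1 bp; the fraction of
#' overlapping domains is reported descriptively. Significance uses bin
#' units: population = all genome bins, successes = bins containing >= 1
#' LAD bp, draws = bins intersecting domains, observed = domain bins
#' containing >= 1 LAD bp; the p-value is the hypergeometric upper tail.
#'
#' @param domains domain data frame (from [call_bads()]) or any intervals
#' @param lad_track an `annotation_track` of LADs
#' @param genome a `genome_description`
#' @param bin_size bin width for the hypergeometric unit (default 5e5)
#' @return a list: `n_domains`, `n_overlapping`, `fraction`, and the
#'   hypergeometric test components (`pop_bins`, `lad_bins`, `domain_bins`,
#'   `overlap_bins`, `p_hyper`)
#' @export
domain_overlap <- function(domains, lad_track, genome, bin_size = 5e5) {
  if (nrow(domains) == 0) {
    warning("empty domain set; overlap fraction undefined")
    return(list(n_domains = 0L, n_overlapping = 0L, fraction = NA_real_,
                pop_bins = NA, lad_bins = NA, domain_bins = NA,
                overlap_bins = NA, p_hyper = NA_real_))
  }
  lads <- lad_track$intervals
  hit <- overlaps_any(domains, lads)
  bins <- tile_windows(genome, bin_size)
  in_lad <- overlaps_any(bins, lads)
  in_dom <- overlaps_any(bins, domains)
  m <- sum(in_lad)                 # successes in population
  N <- nrow(bins)                  # population
  k <- sum(in_dom)                 # draws
  x <- sum(in_lad & in_dom)        # observed successes
  p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
  list(n_domains = nrow(domains), n_overlapping = sum(hit),
       fraction = mean(hit), pop_bins = N, lad_bins = m, domain_bins = k,
       overlap_bins = x, p_hyper = p)
}

#' Rank correlation of two binned landscapes, per chromosome
#'
#' Spearman rank correlation of per-bin counts, computed per chromosome
#' over bins where either track is nonzero. Chromosomes with fewer than 3
#' informative bins are reported `NA`.
#'
#' @param binned_a,binned_b `binned_track`s on the same genome and bin size
#' @return data frame with `chrom`, `n_bins_used`, `rho`
#' @export
landscape_correlation <- function(binned_a, binned_b) {
  stopifnot(inherits(binned_a, "binned_track"), inherits(binned_b, "binned_track"))
  if (!identical(attr(binned_a, "bin_size"), attr(binned_b, "bin_size")) ||
      !identical(dim(binned_a), dim(binned_b)))
    stop("binned tracks must share genome and bin size")
  chroms <- unique(binned_a$chrom)
  res <- do.call(rbind, lapply(chroms, function(chrom) {
    i <- binned_a$chrom == chrom
    a <- binned_a$n[i]; b <- binned_b$n[i]
    use <- a > 0 | b > 0
    rho <- if (sum(use) >= 3)
      stats::cor(a[use], b[use], method = "spearman") else NA_real_
    data.frame(chrom = chrom, n_bins_used = sum(use), rho = rho,
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Export per-bin counts as bedGraph
#'
#' One record per bin with a nonzero count for the requested direction.
#'
#' @param binned a `binned_track`
#' @param path output path
#' @param direction `"all"`, `"hyper"` or `"hypo"`
#' @export
write_bin_bedgraph <- function(binned, path, direction = "all") {
  col <- switch(direction, all = "n", hyper = "n_hyper", hypo = "n_hypo",
                stop("direction must be all/hyper/hypo"))
  b <- binned[binned[[col]] > 0, ]
  writeLines(sprintf("%s\t%d\t%d\t%d", b$chrom, as.integer(b$start),
                     as.integer(b$end), b[[col]]), path)
  invisible(path)
}
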