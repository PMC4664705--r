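# Genomic-element enrichment of DMRs/peaks: overlap counts, length-and-
# abundance-normalized enrichment ratios, permutation significance, and
# Low/PMD/High methylation-band shift tables.

#' Assign features to element tracks by overlap
#'
#' A feature (DMR or peak) counts toward a track iff it overlaps at least
#' 1 bp of it; assignment is non-exclusive across tracks, so one feature
#' may count for several element classes. Track intervals on chromosomes
#' absent from the genome are dropped with a warning.
#'
#' @param features interval data frame of DMRs or peaks
#' @param tracks named list of `annotation_track`s
#' @param genome optional `genome_description` used to validate track
#'   chromosomes
#' @return data frame with per-track `n_features` and `fraction_of_features`
#' @export
assign_to_elements <- function(features, tracks, genome = NULL) {
  validate_intervals(features, "features")
  n_tot <- nrow(features)
  rows <- lapply(tracks, function(tr) {
    iv <- tr$intervals
    if (!is.null(genome)) {
      bad <- !iv$chrom %in% genome$chrom
      if (any(bad)) {
        warning("track '", tr$name, "': ignoring ", sum(bad),
                " interval(s) on unknown chromosomes")
        iv <- iv[!bad, , drop = FALSE]
      }
    }
    n <- sum(overlaps_any(features, iv))
    data.frame(element = tr$name, n_features = n,
               fraction_of_features = if (n_tot > 0) n / n_tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Length-and-abundance-normalized element enrichment
#'
#' The proportion of features overlapping an element, normalized by the
#' fraction of the genome the element (merged) covers:
#' `(n_overlapping / n_features) / (track_bp / genome_bp)`. A value of 1
#' means the element collects features in proportion to its genomic share.
#'
#' @param features interval data frame of DMRs or peaks
#' @param track an `annotation_track`
#' @param genome a `genome_description`
#' @return one-row data frame: `element`, `n_features`,
#'   `fraction_of_features`, `genome_fraction`, `enrichment`
#' @export
element_enrichment <- function(features, track, genome) {
  stopifnot(nrow(features) > 0)
  genome_bp <- sum(genome$length)
  gf <- track$total_bp / genome_bp
  n <- sum(overlaps_any(features, track$intervals))
  ff <- n / nrow(features)
  data.frame(element = track$name, n_features = n, fraction_of_features = ff,
             genome_fraction = gf,
             enrichment = if (gf > 0) ff / gf else NA_real_,
             stringsAsFactors = FALSE)
}

#' Permutation significance of element enrichment
#'
#' Null model: each feature is re-drawn uniformly within its own
#' chromosome, preserving its width (this respects chromosome-scale
#' composition differences). The p-value is
#' `(1 + #\{permutation counts >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams element_enrichment
#' @param n_perm number of permutations (>= 100)
#' @param seed RNG seed
#' @return the permutation p-value
#' @export
enrichment_significance <- function(features, track, genome,
                                    n_perm = 1000, seed = 1L) {
  stopifnot(n_perm >= 100)
  width <- features$end - features$start
  L <- chrom_length(genome, features$chrom)
  if (any(width > L))
    stop("feature wider than its chromosome")
  obs <- sum(overlaps_any(features, track$intervals))
  with_rng(seed, {
    hits <- vapply(seq_len(n_perm), function(i) {
      s <- floor(stats::runif(length(width)) * (L - width + 1))
      perm <- data.frame(chrom = features$chrom, start = s, end = s + width)
      sum(overlaps_any(perm, track$intervals))
    }, numeric(1))
    (1 + sum(hits >= obs)) / (n_perm + 1)
  })
}

#' Methylation-band shift table
#'
#' Partitions element instances by their CONTROL methylation level into
#' Low (0-25%), PMD (25-75%) and High (75-100%) bands and reports the mean
#' treatment-minus-control difference (in percent) per element per band.
#' An "element instance" is the intersection of the element's intervals
#' with the `window_size` bp tiling grid, so band statistics stay
#' comparable to window-level DMR statistics; instances need read coverage
#' in both conditions. Empty bands are reported as `NA`.
#'
#' @param control,treatment `methylome` objects (pool replicates first)
#' @param tracks named list of `annotation_track`s
#' @param genome a `genome_description`
#' @param window_size grid width in bp (default 300)
#' @return data frame with `element`, `band`, `n_instances`, `mean_diff`
#' @export
band_shift_table <- function(control, treatment, tracks, genome,
                             window_size = 300) {
  grid <- tile_windows(genome, window_size)
  bands <- c("Low", "PMD", "High")
  ctrl_s <- control$sites[control$sites$context == "CpG" & control$sites$total > 0, ]
  trt_s <- treatment$sites[treatment$sites$context == "CpG" & treatment$sites$total > 0, ]
  rows <- list()
  for (tr in tracks) {
    pieces <- grid_pieces(grid, tr$intervals)
    if (nrow(pieces) == 0) next
    pc <- assign_sites_sum(pieces, ctrl_s)
    pt <- assign_sites_sum(pieces, trt_s)
    ok <- pc$total > 0 & pt$total > 0
    ctl_pct <- 100 * pc$meth[ok] / pc$total[ok]
    diff_pct <- 100 * pt$meth[ok] / pt$total[ok] - ctl_pct
    band <- cut(ctl_pct, breaks = c(0, 25, 75, 100), labels = bands,
                include.lowest = TRUE, right = TRUE)
    md <- tapply(diff_pct, band, mean)
    nn <- tapply(diff_pct, band, length)
    rows[[tr$name]] <- data.frame(element = tr$name, band = bands,
                                  n_instances = ifelse(is.na(nn[bands]), 0L,
                                                       as.integer(nn[bands])),
                                  mean_diff = as.numeric(md[bands]),
                                  stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# per-cell intersection pieces of a tiling grid with (merged) track
# intervals; adjacent cells stay distinct instances, unlike a plain
# interval-set intersection which would merge them
grid_pieces <- function(grid, intervals) {
  iv <- merge_intervals(intervals)
  ov <- suppress_seqlevel_warning(
    GenomicRanges::findOverlaps(as_granges(grid), as_granges(iv)))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  data.frame(chrom = grid$chrom[qh],
             start = pmax(grid$start[qh], iv$start[sh]),
             end = pmin(grid$end[qh], iv$end[sh]),
             stringsAsFactors = FALSE)
}

# pooled meth/total counts of sites falling in each interval piece
assign_sites_sum <- function(pieces, sites) {
  pieces$meth <- pieces$total <- 0
  if (nrow(sites) == 0) return(pieces)
  pos_iv <- data.frame(chrom = sites$chrom, start = sites$pos,
                       end = sites$pos + 1)
  ov <- suppress_seqlevel_warning(
    GenomicRanges::findOverlaps(as_granges(pos_iv), as_granges(pieces)))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  if (length(qh)) {
    agg <- rowsum(cbind(sites$meth[qh], sites$total[qh]), sh)
    idx <- as.integer(rownames(agg))
    pieces$meth[idx] <- agg[, 1]
    pieces$total[idx] <- agg[, 2]
  }
  pieces
}
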