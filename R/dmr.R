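# Core inference: 300 bp window tiling, Fisher's exact test per window and
# replicate against the pooled control, genome-wide Benjamini-Hochberg
# control, and DMR calling with a reproducible >= 25% methylation difference.

#' Methylation level of pooled counts
#'
#' `100 * methylated reads / total reads`. Sites or windows with zero total
#' reads are undefined (`NA`), never 0, and are excluded from summaries.
#'
#' @param meth_reads methylated read count(s)
#' @param total_reads total read count(s)
#' @return methylation level(s) in percent
#' @export
methylation_level <- function(meth_reads, total_reads) {
  if (any(meth_reads < 0) || any(total_reads < meth_reads))
    stop("need 0 <= meth_reads <= total_reads")
  ifelse(total_reads > 0, 100 * meth_reads / total_reads, NA_real_)
}

#' Tile a genome into fixed-width windows
#'
#' Non-overlapping consecutive windows anchored at position 0 of each
#' chromosome; the terminal partial window is retained, so the windows
#' cover every base exactly once.
#'
#' @param genome a `genome_description`
#' @param window_size window width in bp (default 300)
#' @return interval data frame of all windows
#' @export
tile_windows <- function(genome, window_size = 300) {
  stopifnot(window_size > 0)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    starts <- seq(0, L - 1, by = window_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + window_size, L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided Fisher's exact test on 2x2 count tables, vectorized
#'
#' For each table (methylated vs unmethylated by sample) computes the exact
#' two-sided p-value: the sum of probabilities, over all tables with the
#' same margins, whose hypergeometric probability does not exceed that of
#' the observed table (a relative tolerance of 1e-7 absorbs floating-point
#' ties). Degenerate tables with a zero margin give p = 1 by convention
#' (reported via `message()`). Vectorization keeps genome-wide window
#' testing fast; agreement with `stats::fisher.test` is part of the test
#' suite.
#'
#' @param meth_a,unmeth_a methylated/unmethylated counts in sample A
#' @param meth_b,unmeth_b methylated/unmethylated counts in sample B
#' @return vector of two-sided p-values
#' @export
fisher_window <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  stopifnot(length(unmeth_a) == n, length(meth_b) == n, length(unmeth_b) == n)
  if (any(c(meth_a, unmeth_a, meth_b, unmeth_b) < 0))
    stop("counts must be non-negative")
  m <- meth_a + meth_b        # methylated margin
  u <- unmeth_a + unmeth_b    # unmethylated margin
  ka <- meth_a + unmeth_a     # sample A margin
  kb <- meth_b + unmeth_b     # sample B margin
  p <- rep(1, n)
  degenerate <- m == 0 | u == 0 | ka == 0 | kb == 0
  if (any(degenerate))
    message(sum(degenerate), " table(s) with a zero margin: p = 1 by convention")
  rel <- 1 + 1e-7
  for (i in which(!degenerate)) {
    lo <- max(0, ka[i] - u[i]); hi <- min(ka[i], m[i])
    d <- stats::dhyper(lo:hi, m[i], u[i], ka[i])
    p[i] <- min(1, sum(d[d <= d[meth_a[i] - lo + 1] * rel]))
  }
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Monotone step-up FDR adjustment (delegates to
#' `stats::p.adjust(method = "BH")`). Empty input gives empty output.
#'
#' @param p_values vector of p-values in \[0, 1\]
#' @return adjusted q-values
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# pooled per-window counts for one methylome: key -> meth, total, n_cpg
window_counts <- function(m, genome, window_size, contexts = "CpG") {
  s <- m$sites
  s <- s[s$context %in% contexts & s$total > 0, , drop = FALSE]
  ci <- match(s$chrom, genome$chrom)
  if (anyNA(ci))
    stop("methylome has sites on chromosomes absent from the genome: ",
         paste(unique(s$chrom[is.na(ci)]), collapse = ", "))
  key <- ci * 2^40 + s$pos %/% window_size
  agg <- rowsum(cbind(meth = s$meth, total = s$total, n_cpg = 1), key)
  data.frame(key = as.numeric(rownames(agg)), meth = agg[, "meth"],
             total = agg[, "total"], n_cpg = agg[, "n_cpg"],
             row.names = NULL)
}

#' Pool several methylomes into one
#'
#' Sums methylated and total counts over samples, by (chrom, pos, strand).
#'
#' @param ms list of `methylome` objects
#' @param sample_id identifier for the pooled sample
#' @return a `methylome`
#' @export
pool_methylomes <- function(ms, sample_id = "pooled") {
  if (inherits(ms, "methylome")) return(ms)
  stopifnot(length(ms) >= 1, all(vapply(ms, inherits, TRUE, "methylome")))
  all_sites <- do.call(rbind, lapply(ms, function(m) m$sites))
  id <- paste(all_sites$chrom, all_sites$pos, all_sites$strand, sep = "\r")
  agg <- rowsum(cbind(all_sites$meth, all_sites$total), id, reorder = FALSE)
  first <- !duplicated(id)
  sites <- all_sites[first, c("chrom", "pos", "strand", "context")]
  o <- match(rownames(agg), id[first])
  sites <- sites[o, ]
  sites$meth <- agg[, 1]
  sites$total <- agg[, 2]
  methylome(sample_id, ms[[1]]$condition, 1L, sites)
}

# window-level Fisher/BH comparison of one sample against another
test_windows <- function(control, treatment, genome, window_size = 300,
                         min_total_reads = 5, smooth = FALSE, smooth_k = 5) {
  wa <- window_counts(control, genome, window_size)
  wb <- window_counts(treatment, genome, window_size)
  i <- match(wa$key, wb$key)
  keep <- !is.na(i)
  wa <- wa[keep, ]; wb <- wb[i[keep], ]
  keep <- wa$total >= min_total_reads & wb$total >= min_total_reads
  wa <- wa[keep, ]; wb <- wb[keep, ]
  ci <- wa$key %/% 2^40
  widx <- wa$key - ci * 2^40
  res <- data.frame(chrom = genome$chrom[ci], start = widx * window_size,
                    end = pmin((widx + 1) * window_size, genome$length[ci]),
                    n_cpg = wa$n_cpg,
                    meth_a = wa$meth, unmeth_a = wa$total - wa$meth,
                    meth_b = wb$meth, unmeth_b = wb$total - wb$meth,
                    stringsAsFactors = FALSE)
  res <- res[order(match(res$chrom, genome$chrom), res$start), ]
  rownames(res) <- NULL
  res$frac_a <- res$meth_a / (res$meth_a + res$unmeth_a)
  res$frac_b <- res$meth_b / (res$meth_b + res$unmeth_b)
  if (smooth) {
    run_mean <- function(x) {
      as.numeric(stats::filter(x, rep(1 / smooth_k, smooth_k), sides = 2))
    }
    for (chrom in unique(res$chrom)) {
      j <- which(res$chrom == chrom)
      if (length(j) >= smooth_k) {
        sa <- run_mean(res$frac_a[j]); sb <- run_mean(res$frac_b[j])
        ok <- !is.na(sa)
        res$frac_a[j][ok] <- sa[ok]; res$frac_b[j][ok] <- sb[ok]
      }
    }
  }
  res$diff <- res$frac_b - res$frac_a
  res$p <- fisher_window(res$meth_a, res$unmeth_a, res$meth_b, res$unmeth_b)
  res$q <- bh_adjust(res$p)
  res
}

#' Call differentially methylated regions
#'
#' Tiles the genome into `window_size` bp windows, pools CpG read counts
#' per window, and tests each treatment replicate against the pooled
#' control with Fisher's exact test, adjusting p-values genome-wide within
#' each replicate comparison (Benjamini-Hochberg). A window is a DMR iff in
#' BOTH replicate comparisons the adjusted value is below `alpha`, the
#' methylation difference is at least `min_diff` in absolute value (ties at
#' exactly `min_diff` are included), and the sign of the difference agrees.
#' Direction is `hyper` when treatment methylation exceeds control, `hypo`
#' otherwise. Windows with pooled total reads below `min_total_reads` in
#' any compared sample are skipped.
#'
#' @param control a `methylome` or list of control `methylome`s (pooled)
#' @param treatment_rep1,treatment_rep2 treatment replicate `methylome`s
#' @param genome a `genome_description`
#' @param window_size tiling window width in bp
#' @param min_diff minimum absolute methylation difference (fraction scale)
#' @param alpha BH-adjusted significance threshold
#' @param min_total_reads per-sample pooled coverage floor per window
#' @param smooth if `TRUE`, apply a centered running-mean smoother over
#'   `smooth_k` windows to the window fractions before the difference
#'   filter (off by default; p-values always use raw counts)
#' @param smooth_k smoother width in windows
#' @return an object of class `dmr_set`: the DMR table plus the two
#'   window-level test tables and the call parameters
#' @export
call_dmrs <- function(control, treatment_rep1, treatment_rep2, genome,
                      window_size = 300, min_diff = 0.25, alpha = 0.1,
                      min_total_reads = 5, smooth = FALSE, smooth_k = 5) {
  ctrl <- pool_methylomes(control, "control_pooled")
  w1 <- test_windows(ctrl, treatment_rep1, genome, window_size,
                     min_total_reads, smooth, smooth_k)
  w2 <- test_windows(ctrl, treatment_rep2, genome, window_size,
                     min_total_reads, smooth, smooth_k)
  if (nrow(w1) == 0 || nrow(w2) == 0) {
    warning("zero testable windows")
    dmrs <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       direction = character(), diff_rep1 = numeric(),
                       diff_rep2 = numeric(), q_rep1 = numeric(),
                       q_rep2 = numeric(), stringsAsFactors = FALSE)
  } else {
    id1 <- paste(w1$chrom, w1$start)
    id2 <- paste(w2$chrom, w2$start)
    i <- match(id1, id2)
    both <- !is.na(i)
    a <- w1[both, ]; b <- w2[i[both], ]
    hit <- a$q < alpha & b$q < alpha &
      abs(a$diff) >= min_diff & abs(b$diff) >= min_diff &
      sign(a$diff) == sign(b$diff) & a$diff != 0
    dmrs <- data.frame(chrom = a$chrom[hit], start = a$start[hit],
                       end = a$end[hit],
                       direction = ifelse(a$diff[hit] > 0, "hyper", "hypo"),
                       diff_rep1 = a$diff[hit], diff_rep2 = b$diff[hit],
                       q_rep1 = a$q[hit], q_rep2 = b$q[hit],
                       stringsAsFactors = FALSE)
    rownames(dmrs) <- NULL
  }
  structure(list(dmrs = dmrs, windows = list(rep1 = w1, rep2 = w2),
                 genome = genome,
                 params = list(window_size = window_size, min_diff = min_diff,
                               alpha = alpha, min_total_reads = min_total_reads,
                               smooth = smooth)),
            class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  d <- x$dmrs
  cat(sprintf(paste0("<dmr_set> %d DMRs (%d hyper, %d hypo) from %d/%d ",
                     "testable windows (rep1/rep2)\n"),
              nrow(d), sum(d$direction == "hyper"), sum(d$direction == "hypo"),
              nrow(x$windows$rep1), nrow(x$windows$rep2)))
  cat(sprintf("  window %d bp, |diff| >= %.2f, BH q < %.2f, coverage >= %d\n",
              x$params$window_size, x$params$min_diff, x$params$alpha,
              x$params$min_total_reads))
  invisible(x)
}

#' @export
#' @method summary dmr_set
summary.dmr_set <- function(object, ...) {
  d <- object$dmrs
  g <- object$genome
  per <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    k <- d$chrom == g$chrom[i]
    data.frame(chrom = g$chrom[i], n_dmr = sum(k),
               n_hyper = sum(k & d$direction == "hyper"),
               n_hypo = sum(k & d$direction == "hypo"),
               density = sum(k) / g$length[i], stringsAsFactors = FALSE)
  }))
  per$pct_hyper <- ifelse(per$n_dmr > 0, round(100 * per$n_hyper / per$n_dmr, 1), NA)
  per$pct_hypo <- ifelse(per$n_dmr > 0, round(100 * per$n_hypo / per$n_dmr, 1), NA)
  per
}

#' @export
#' @method as.data.frame dmr_set
as.data.frame.dmr_set <- function(x, ...) x$dmrs

#' @export
#' @method plot dmr_set
plot.dmr_set <- function(x, ...) {
  s <- summary(x)
  m <- t(as.matrix(s[, c("n_hyper", "n_hypo")]))
  colnames(m) <- s$chrom
  graphics::barplot(m, beside = TRUE, col = c("firebrick", "steelblue"),
                    legend.text = c("hyper", "hypo"),
                    ylab = "DMR count", ...)
  invisible(x)
}

#' Export a DMR set as BED6
#'
#' Name column carries the direction; score is `round(1000 * |mean diff|)`.
#'
#' @param x a `dmr_set` (or its DMR data frame)
#' @param path output path
#' @export
write_dmr_bed <- function(x, path) {
  d <- if (inherits(x, "dmr_set")) x$dmrs else x
  d$name <- d$direction
  d$score <- round(1000 * abs((d$diff_rep1 + d$diff_rep2) / 2))
  write_bed(d, path)
}

#' Per-chromosome methylation and DMR summary
#'
#' For each chromosome and sample, the site-level mean methylation percent
#' (mean of `100 * meth / total` over CpG sites with coverage > 0; a
#' chromosome with no covered site is reported `NA`, not 0), the mean and
#' sd over treatment replicates, DMR counts split by direction with
#' percentages, and DMR density (count per bp of chromosome). Unweighted
#' grand means over autosome-like chromosomes are attached as attribute
#' `"autosome_means"`.
#'
#' @param methylomes named list of `methylome` objects
#' @param dmrs a `dmr_set` or DMR data frame with `chrom` and `direction`
#' @param genome a `genome_description`
#' @return a per-chromosome data frame
#' @export
summarize_chromosomes <- function(methylomes, dmrs, genome) {
  d <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  out <- data.frame(chrom = genome$chrom, length = genome$length,
                    x_like = genome$x_like, stringsAsFactors = FALSE)
  for (nm in names(methylomes)) {
    s <- methylomes[[nm]]$sites
    s <- s[s$context == "CpG" & s$total > 0, ]
    lv <- methylation_level(s$meth, s$total)
    mm <- tapply(lv, factor(s$chrom, levels = genome$chrom), mean)
    out[[paste0("mean_", nm)]] <- as.numeric(mm)
  }
  treat_cols <- grep("^mean_treatment", names(out), value = TRUE)
  if (length(treat_cols) >= 2) {
    tm <- as.matrix(out[, treat_cols])
    out$treatment_mean <- rowMeans(tm)
    out$treatment_sd <- apply(tm, 1, stats::sd)
  }
  k <- factor(d$chrom, levels = genome$chrom)
  out$n_dmr <- as.integer(table(k))
  out$n_hyper <- as.integer(table(k[d$direction == "hyper"]))
  out$n_hypo <- as.integer(table(k[d$direction == "hypo"]))
  out$pct_hyper <- ifelse(out$n_dmr > 0, round(100 * out$n_hyper / out$n_dmr, 1), NA)
  out$pct_hypo <- ifelse(out$n_dmr > 0, round(100 * out$n_hypo / out$n_dmr, 1), NA)
  out$density <- out$n_dmr / out$length
  auto <- out[!out$x_like, ]
  num <- vapply(auto, is.numeric, TRUE)
  attr(out, "autosome_means") <- colMeans(auto[, num], na.rm = TRUE)
  out
}
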