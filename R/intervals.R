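#' Genomic interval conventions
#'
#' All coordinates inside the package are 0-based, half-open `[start, end)`.
#' Intervals are plain data frames with columns `chrom` (character),
#' `start` and `end` (numeric, `0 <= start < end`). File I/O converts to the
#' convention of each external format (1-based positions for cytosine
#' reports, 0-based half-open for BED/bedGraph).
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open coordinates
#' @return a validated interval data frame
#' @export
genomic_intervals <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop(what, ": chromosome names must be non-empty")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(what, ": need 0 <= start < end (first offending row ", bad[1], ")")
  invisible(df)
}

# 0-based half-open data frame -> GRanges (1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

# GRanges -> 0-based half-open data frame
granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge overlapping intervals into their union
#'
#' @param df interval data frame
#' @return interval data frame of the merged union, sorted
#' @export
merge_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  out <- granges_to_df(GenomicRanges::reduce(as_granges(df)))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Total base pairs covered by a set of intervals
#'
#' Overlaps are merged before summing, so each base is counted once.
#'
#' @param df interval data frame
#' @return total covered bp (numeric scalar)
#' @export
total_bp <- function(df) {
  m <- merge_intervals(df)
  if (nrow(m) == 0) return(0)
  sum(m$end - m$start)
}

# disjoint chromosome sets legitimately mean "no overlap"; drop the GRanges
# seqlevel warning for that case
suppress_seqlevel_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("sequence levels in common", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# logical: does each query interval share >= 1 bp with any subject interval?
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  suppress_seqlevel_warning(
    IRanges::overlapsAny(as_granges(query), as_granges(subject)))
}

count_overlapping <- function(query, subject) {
  if (nrow(query) == 0) return(integer(0))
  if (nrow(subject) == 0) return(integer(nrow(query)))
  suppress_seqlevel_warning(
    GenomicRanges::countOverlaps(as_granges(query), as_granges(subject)))
}

# intersection pieces between two interval sets (0-based half-open)
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  granges_to_df(GenomicRanges::intersect(as_granges(a), as_granges(b)))
}

#' Describe a genome as named chromosomes with lengths
#'
#' @param chrom unique chromosome names
#' @param length chromosome lengths in bp (> 0)
#' @param x_like logical flag per chromosome: `TRUE` marks an X-like
#'   chromosome (expected direction of planted/observed methylation change
#'   is hypo), `FALSE` an autosome-like one.
#' @return a `genome_description` data frame
#' @export
genome_description <- function(chrom, length, x_like = FALSE) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  g <- data.frame(chrom = chrom, length = as.numeric(length),
                  x_like = rep_len(as.logical(x_like), length(chrom)),
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_description", "data.frame")
  g
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$length[i]
}
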