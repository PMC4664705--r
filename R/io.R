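#' Construct a methylome table
#'
#' A methylome table holds per-cytosine methylation evidence for one sample:
#' for every covered C (0-based position of the C itself, stranded), the
#' number of reads calling it methylated and the total read count. Sites on
#' the two strands of a CpG are kept as independent observations; they are
#' not collapsed into dinucleotide units.
#'
#' @param sample_id sample identifier
#' @param condition `"control"` or `"treatment"`
#' @param replicate replicate number (integer >= 1)
#' @param sites data frame with columns `chrom`, `pos` (0-based), `strand`
#'   (`+`/`-`), `meth` (methylated read count), `total` (total read count),
#'   `context` (`CpG`, `CHG` or `CHH`)
#' @return an object of class `methylome`
#' @export
methylome <- function(sample_id, condition, replicate, sites) {
  condition <- match.arg(condition, c("control", "treatment"))
  need <- c("chrom", "pos", "strand", "meth", "total", "context")
  stopifnot(all(need %in% names(sites)))
  sites <- sites[, need]
  if (nrow(sites)) {
    if (any(sites$meth < 0) || any(sites$total < sites$meth))
      stop("need 0 <= meth <= total at every site")
    sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
    if (anyDuplicated(sites[, c("chrom", "pos", "strand")]))
      stop("duplicate (chrom, pos, strand) records")
    rownames(sites) <- NULL
  }
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = as.integer(replicate), sites = sites),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("<methylome> %s (%s, replicate %d): %d sites on %d chromosome(s)\n",
              x$sample_id, x$condition, x$replicate, nrow(x$sites),
              length(unique(x$sites$chrom))))
  if (nrow(x$sites)) {
    cpg <- x$sites$context == "CpG"
    cat(sprintf("  CpG sites: %d (%.1f%%), mean coverage %.1fx\n",
                sum(cpg), 100 * mean(cpg), mean(x$sites$total)))
  }
  invisible(x)
}

#' Read a cytosine report
#'
#' Parses the 7-column tab-separated cytosine report dialect: chromosome,
#' 1-based position, strand, methylated count, unmethylated count, context,
#' trinucleotide. Positions are converted to the package's 0-based
#' convention; `total = methylated + unmethylated`. Lines starting with `#`
#' are ignored. Non-CpG contexts are retained (they are excluded from
#' downstream statistics, which are CpG-centric).
#'
#' @inheritParams methylome
#' @param path file path
#' @return a `methylome` object
#' @export
read_cytosine_report <- function(path, sample_id, condition, replicate) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    warning("empty cytosine report: ", path)
    sites <- data.frame(chrom = character(), pos = numeric(),
                        strand = character(), meth = numeric(),
                        total = numeric(), context = character(),
                        stringsAsFactors = FALSE)
    return(methylome(sample_id, condition, replicate, sites))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7))
    stop("malformed cytosine report line ", lineno[which(nf != 7)[1]],
         ": expected 7 tab-separated fields")
  m <- matrix(unlist(fields), ncol = 7, byrow = TRUE)
  pos1 <- suppressWarnings(as.numeric(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 4]))
  unmeth <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(pos1) | is.na(meth) | is.na(unmeth))
  if (length(bad))
    stop("malformed cytosine report line ", lineno[bad[1]],
         ": non-numeric position or counts")
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative counts in cytosine report line ",
         lineno[which(meth < 0 | unmeth < 0)[1]])
  sites <- data.frame(chrom = m[, 1], pos = pos1 - 1, strand = m[, 3],
                      meth = meth, total = meth + unmeth, context = m[, 6],
                      stringsAsFactors = FALSE)
  methylome(sample_id, condition, replicate, sites)
}

#' Write a methylome as a cytosine report
#'
#' Inverse of [read_cytosine_report()]: positions are written 1-based and
#' counts split back into methylated/unmethylated. A round trip preserves
#' all counts and coordinates exactly.
#'
#' @param x a `methylome`
#' @param path output path
#' @export
write_cytosine_report <- function(x, path) {
  s <- x$sites
  tri <- ifelse(s$context == "CpG", "CGN", "CNN")
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s", s$chrom, as.integer(s$pos + 1),
                   s$strand, as.integer(s$meth), as.integer(s$total - s$meth),
                   s$context, tri)
  writeLines(c(sprintf("# cytosine report: %s", x$sample_id), lines), path)
  invisible(path)
}

#' Export per-site methylation percentages as bedGraph
#'
#' One 0-based half-open record per covered CpG site with the methylation
#' level `100 * meth / total` as the value.
#'
#' @inheritParams write_cytosine_report
#' @export
write_bedgraph <- function(x, path) {
  s <- x$sites[x$sites$context == "CpG" & x$sites$total > 0, ]
  lines <- sprintf("%s\t%d\t%d\t%.4f", s$chrom, as.integer(s$pos),
                   as.integer(s$pos + 1), 100 * s$meth / s$total)
  writeLines(lines, path)
  invisible(path)
}

#' Construct an annotation track
#'
#' A named set of genomic intervals (an element class such as satellites,
#' LINEs, enhancers, CpG islands or shores; a LAD track; a peak set).
#' `total_bp` is always computed on the merged union of the intervals.
#'
#' @param name track name
#' @param intervals interval data frame (0-based half-open)
#' @return an object of class `annotation_track`
#' @export
annotation_track <- function(name, intervals) {
  validate_intervals(intervals, what = paste0("track '", name, "'"))
  intervals <- intervals[, c("chrom", "start", "end")]
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(name = name, intervals = intervals,
                 total_bp = total_bp(intervals)),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %s: %d intervals, %s bp merged\n",
              x$name, nrow(x$intervals), format(x$total_bp, big.mark = ",")))
  invisible(x)
}

#' Read a BED3+ file as an annotation track
#'
#' @param path BED file (0-based half-open; `track`/`browser`/`#` lines
#'   skipped; columns beyond the third ignored)
#' @param name track name
#' @return an `annotation_track`
#' @export
read_bed <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lines <- lines[keep]
  if (length(lines) == 0)
    return(annotation_track(name, data.frame(chrom = character(),
                                             start = numeric(), end = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("BED line with fewer than 3 fields in ", path)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1),
                   start = as.numeric(vapply(fields, `[`, "", 2)),
                   end = as.numeric(vapply(fields, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  if (any(is.na(df$start) | is.na(df$end)))
    stop("non-numeric BED coordinates in ", path)
  if (any(df$start >= df$end))
    stop("BED interval with start >= end in ", path)
  annotation_track(name, df)
}

#' Write intervals as BED
#'
#' @param x an `annotation_track` or interval data frame; optional columns
#'   `name` and `score` become BED columns 4-5
#' @param path output path
#' @export
write_bed <- function(x, path) {
  df <- if (inherits(x, "annotation_track")) x$intervals else x
  lines <- sprintf("%s\t%d\t%d", df$chrom, as.integer(df$start), as.integer(df$end))
  if (!is.null(df$name)) {
    score <- if (is.null(df$score)) 0L else as.integer(df$score)
    lines <- sprintf("%s\t%s\t%d\t%s", lines, df$name, score,
                     if (is.null(df$strand)) "." else df$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive CpG island shores
#'
#' Shores are the regions up to `flank_bp` upstream and downstream of each
#' CpG island, clipped to chromosome bounds and excluding any base that
#' lies inside an island (inter-island bp are never double-counted).
#'
#' @param cgi_track `annotation_track` of CpG islands
#' @param flank_bp shore width on each side (default 2000)
#' @param genome optional `genome_description` used to clip shores at
#'   chromosome ends
#' @return an `annotation_track` named `"shores"`
#' @export
derive_shores <- function(cgi_track, flank_bp = 2000, genome = NULL) {
  isl <- cgi_track$intervals
  if (nrow(isl) == 0) stop("CpG island track is empty")
  up <- data.frame(chrom = isl$chrom, start = pmax(0, isl$start - flank_bp),
                   end = isl$start, stringsAsFactors = FALSE)
  down <- data.frame(chrom = isl$chrom, start = isl$end,
                     end = isl$end + flank_bp, stringsAsFactors = FALSE)
  fl <- rbind(up, down)
  if (!is.null(genome)) {
    lim <- chrom_length(genome, fl$chrom)
    clipped <- fl$end > lim
    if (any(clipped)) {
      message(sum(clipped), " shore flank(s) clipped at chromosome end")
      fl$end <- pmin(fl$end, lim)
    }
  }
  fl <- fl[fl$start < fl$end, , drop = FALSE]
  shores <- granges_to_df(GenomicRanges::setdiff(as_granges(fl), as_granges(isl)))
  annotation_track("shores", shores)
}

#' Read a gene table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `start`, `end`,
#' `strand`, `status`; `status` must be one of `repressed`, `activated`,
#' `unchanged`. Header lines may start with `#`.
#'
#' @param path file path
#' @return a data frame of gene records
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand", "status")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$status), c("repressed", "activated", "unchanged"))
  if (length(bad))
    stop("unknown gene status: ", paste(bad, collapse = ", "))
  validate_intervals(df, what = "gene table")
  df
}

#' Write a gene table
#'
#' @param genes gene data frame (see [read_gene_table()])
#' @param path output path
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
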