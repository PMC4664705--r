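# Summarize pre-computed per-chromosome tables: ingest published
# per-chromosome methylation and DMR-count summaries and recompute every
# derived column (replicate means/sd, percentages, densities, totals).
# Transcriptions of the published HEK-CT vs HEK-BAHD1 summary tables ship
# under inst/extdata/.

#' Read a per-chromosome methylation summary table
#'
#' Tab-separated with header `chrom`, `control`, `treatment_rep1`,
#' `treatment_rep2` (methylation percentages) and a logical `x_like`
#' column; `#` lines are comments.
#'
#' @param path file path
#' @return data frame
#' @export
read_chromosome_methylation <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "control", "treatment_rep1", "treatment_rep2", "x_like")
  if (!all(need %in% names(df)))
    stop("methylation summary must have columns: ", paste(need, collapse = ", "))
  df
}

#' Recompute derived columns of a methylation summary
#'
#' Adds the treatment replicate mean and sd per chromosome, and attaches
#' unweighted grand means over autosome-like chromosomes (attribute
#' `"autosome_means"`, components `control` and `treatment`).
#'
#' @param tbl data frame from [read_chromosome_methylation()]
#' @return the table with `treatment_mean`/`treatment_sd` columns
#' @export
summarize_methylation <- function(tbl) {
  reps <- as.matrix(tbl[, c("treatment_rep1", "treatment_rep2")])
  tbl$treatment_mean <- rowMeans(reps)
  tbl$treatment_sd <- apply(reps, 1, stats::sd)
  auto <- !tbl$x_like
  attr(tbl, "autosome_means") <- c(control = mean(tbl$control[auto]),
                                   treatment = mean(tbl$treatment_mean[auto]))
  tbl
}

#' Read a per-chromosome DMR count table
#'
#' Tab-separated with header `chrom`, `total`, `hyper`, `hypo`,
#' `length_bp`, `x_like`.
#'
#' @param path file path
#' @return data frame
#' @export
read_dmr_count_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "total", "hyper", "hypo", "length_bp", "x_like")
  if (!all(need %in% names(df)))
    stop("DMR count table must have columns: ", paste(need, collapse = ", "))
  if (any(df$hyper + df$hypo != df$total))
    stop("hyper + hypo must equal total on every chromosome")
  df
}

#' Recompute derived columns of a DMR count table
#'
#' Per chromosome: hyper/hypo percentages and DMR density (count per bp);
#' plus totals over autosome-like chromosomes with their pooled
#' percentages, and the overall DMR count.
#'
#' @param tbl data frame from [read_dmr_count_table()]
#' @return a list with `per_chromosome` (table with `pct_hyper`,
#'   `pct_hypo`, `density`), `autosome_totals` (named vector: `total`,
#'   `hyper`, `hypo`, `pct_hyper`, `pct_hypo`) and `total_dmrs`
#' @export
summarize_dmr_counts <- function(tbl) {
  tbl$pct_hyper <- 100 * tbl$hyper / tbl$total
  tbl$pct_hypo <- 100 * tbl$hypo / tbl$total
  tbl$density <- tbl$total / tbl$length_bp
  auto <- tbl[!tbl$x_like, ]
  at <- c(total = sum(auto$total), hyper = sum(auto$hyper),
          hypo = sum(auto$hypo))
  at <- c(at, pct_hyper = 100 * at[["hyper"]] / at[["total"]],
          pct_hypo = 100 * at[["hypo"]] / at[["total"]])
  list(per_chromosome = tbl, autosome_totals = at,
       total_dmrs = sum(tbl$total))
}
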