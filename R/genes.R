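# DMR-to-gene association within flanking windows and per-chromosome
# hyper/hypo count histograms by expression status.

#' Associate DMRs with genes within a flanking window
#'
#' Each gene's window is its interval extended by `flank` bp on both sides
#' (strand-agnostic, clipped at 0). A DMR counts toward a gene iff it
#' overlaps the window by at least 1 bp; counts are split by direction and
#' one DMR may count for several genes.
#'
#' @param genes gene data frame (see [read_gene_table()])
#' @param dmrs a `dmr_set` or DMR data frame with `chrom`, `start`, `end`,
#'   `direction`
#' @param flank window extension in bp on each side (default 10000)
#' @return data frame: `gene_id`, `chrom`, `status`, window bounds,
#'   `n_hyper`, `n_hypo`
#' @export
associate_dmrs <- function(genes, dmrs, flank = 10000) {
  d <- if (inherits(dmrs, "dmr_set")) dmrs$dmrs else dmrs
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(0, genes$start - flank),
                    end = genes$end + flank)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    status = genes$status,
                    window_start = win$start, window_end = win$end,
                    n_hyper = 0L, n_hypo = 0L, stringsAsFactors = FALSE)
  if (nrow(d)) {
    out$n_hyper <- count_overlapping(win, d[d$direction == "hyper", , drop = FALSE])
    out$n_hypo <- count_overlapping(win, d[d$direction == "hypo", , drop = FALSE])
  }
  out
}

#' Per-chromosome DMR-count histogram by gene expression status
#'
#' For each chromosome and status, sums the hyper- and hypo-DMR counts
#' over the associated genes (DMRs are counted, not genes, so one gene
#' with two overlapping hyper DMRs contributes 2). Genes with status
#' `unchanged` are reported in their own rows, separate from the
#' differentially expressed classes. The fraction of repressed genes
#' having at least one associated DMR is attached as attribute
#' `"fraction_repressed_with_dmr"`.
#'
#' @param associations output of [associate_dmrs()]
#' @param genome a `genome_description`
#' @return data frame: `chrom`, `status`, `n_hyper`, `n_hypo`, `n_genes`
#' @export
association_histogram <- function(associations, genome) {
  statuses <- c("repressed", "activated", "unchanged")
  grid <- expand.grid(chrom = genome$chrom, status = statuses,
                      stringsAsFactors = FALSE)
  grid$n_hyper <- grid$n_hypo <- grid$n_genes <- 0L
  for (i in seq_len(nrow(grid))) {
    k <- associations$chrom == grid$chrom[i] &
      associations$status == grid$status[i]
    grid$n_genes[i] <- sum(k)
    grid$n_hyper[i] <- sum(associations$n_hyper[k])
    grid$n_hypo[i] <- sum(associations$n_hypo[k])
  }
  rep_genes <- associations$status == "repressed"
  attr(grid, "fraction_repressed_with_dmr") <-
    if (any(rep_genes))
      mean(associations$n_hyper[rep_genes] + associations$n_hypo[rep_genes] >= 1)
    else NA_real_
  grid
}
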