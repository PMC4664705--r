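# End-to-end orchestration: simulate (optional) -> call-dmrs -> enrich ->
# band-shift -> domains -> overlap -> genes, with deterministic outputs
# and a checksum manifest.

#' Pipeline configuration
#'
#' Flat key/value configuration for [run_pipeline()]. Missing values take
#' the standard defaults (300 bp windows, 25% minimum difference, BH alpha
#' 0.1, 0.5 Mb bins, 0.75 quantile, 10 kb gene flank). When
#' `simulate = TRUE` inputs are generated with [simulate_methylomes()] and
#' [simulate_tracks()]; otherwise `control_reports`, `treatment_reports`
#' (cytosine reports), `track_beds` (named BED paths, one of which may be
#' `lads`) and `gene_table` must point to existing files.
#'
#' @param out_dir output directory (created if missing)
#' @param seed RNG seed for every stochastic stage
#' @param simulate generate synthetic inputs?
#' @param genome a `genome_description` (required when simulating)
#' @param window_size,min_diff,alpha,min_total_reads DMR-calling parameters
#' @param bin_size,quantile domain-calling parameters
#' @param flank gene association window extension
#' @param n_perm permutations for enrichment significance
#' @param control_reports,treatment_reports,track_beds,gene_table input
#'   paths when `simulate = FALSE`
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            genome = default_genome(), window_size = 300,
                            min_diff = 0.25, alpha = 0.1, min_total_reads = 5,
                            bin_size = 5e5, quantile = 0.75, flank = 1e4,
                            n_perm = 200, control_reports = NULL,
                            treatment_reports = NULL, track_beds = NULL,
                            gene_table = NULL) {
  stopifnot(window_size > 0, min_diff >= 0, min_diff <= 1,
            alpha > 0, alpha <= 1, bin_size > 0,
            quantile >= 0, quantile <= 1, flank >= 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, genome = genome,
                 window_size = window_size, min_diff = min_diff,
                 alpha = alpha, min_total_reads = min_total_reads,
                 bin_size = bin_size, quantile = quantile, flank = flank,
                 n_perm = n_perm, control_reports = control_reports,
                 treatment_reports = treatment_reports,
                 track_beds = track_beds, gene_table = gene_table),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()]; a `genome` key
#' may hold parallel lists `chrom`, `length`, `x_like`.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$genome))
    y$genome <- genome_description(unlist(y$genome$chrom),
                                   unlist(y$genome$length),
                                   unlist(y$genome$x_like))
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate (optional), DMR calling, element enrichment with
#' permutation significance, the methylation band-shift table, 0.5 Mb
#' binning and domain calling, LAD overlap, occupancy-landscape
#' correlation and gene association, writing every report into
#' `config$out_dir` together with a `manifest.tsv` of MD5 checksums.
#' Identical config and seed reproduce identical checksums. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) a list of in-memory stage results plus the manifest
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  g <- config$genome

  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", {
      cfg <- simulation_config(seed = config$seed, genome = g)
      s <- simulate_methylomes(cfg)
      tk <- simulate_tracks(cfg, s$ground_truth)
      for (nm in names(s$methylomes))
        write_cytosine_report(s$methylomes[[nm]], out(paste0(nm, ".cov")))
      gt <- s$ground_truth$domains
      gt$name <- gt$direction
      write_bed(gt, out("ground_truth_domains.bed"))
      c(s, tk)
    })
    methylomes <- sim$methylomes
    tracks <- sim$tracks
    genes <- sim$genes
  } else {
    methylomes <- stage("read-methylomes", {
      if (is.null(config$control_reports) || is.null(config$treatment_reports))
        stop("control_reports and treatment_reports are required")
      ms <- list()
      for (i in seq_along(config$control_reports))
        ms[[paste0("control_rep", i)]] <-
          read_cytosine_report(config$control_reports[i],
                               paste0("control_rep", i), "control", i)
      for (i in seq_along(config$treatment_reports))
        ms[[paste0("treatment_rep", i)]] <-
          read_cytosine_report(config$treatment_reports[i],
                               paste0("treatment_rep", i), "treatment", i)
      ms
    })
    tracks <- stage("read-tracks", {
      if (is.null(config$track_beds)) list() else
        lapply(stats::setNames(names(config$track_beds), names(config$track_beds)),
               function(nm) read_bed(config$track_beds[[nm]], nm))
    })
    genes <- stage("read-genes", {
      if (is.null(config$gene_table)) NULL else read_gene_table(config$gene_table)
    })
  }

  dmr_res <- stage("call-dmrs", {
    ctrl <- methylomes[grep("^control", names(methylomes))]
    trt <- methylomes[grep("^treatment", names(methylomes))]
    if (length(trt) < 2) stop("two treatment replicates are required")
    r <- call_dmrs(ctrl, trt[[1]], trt[[2]], g,
                   window_size = config$window_size,
                   min_diff = config$min_diff, alpha = config$alpha,
                   min_total_reads = config$min_total_reads)
    write_dmr_bed(r, out("dmrs.bed"))
    utils::write.table(r$windows$rep1, out("windows_rep1.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(r$windows$rep2, out("windows_rep2.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    chrsum <- summarize_chromosomes(methylomes, r, g)
    utils::write.table(chrsum, out("chromosome_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r
  })

  element_tracks <- tracks[setdiff(names(tracks), c("lads", "peaks"))]
  enr <- stage("enrich", {
    if (!length(element_tracks) || nrow(dmr_res$dmrs) == 0) NULL else {
      rows <- lapply(element_tracks, function(tr) {
        e <- element_enrichment(dmr_res$dmrs, tr, g)
        e$p_perm <- enrichment_significance(dmr_res$dmrs, tr, g,
                                            n_perm = config$n_perm,
                                            seed = config$seed + 17L)
        e
      })
      tab <- do.call(rbind, rows)
      rownames(tab) <- NULL
      utils::write.table(tab, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tab
    }
  })

  shift <- stage("band-shift", {
    if (!length(element_tracks)) NULL else {
      ctrl <- pool_methylomes(methylomes[grep("^control", names(methylomes))],
                              "control_pooled")
      trt <- pool_methylomes(methylomes[grep("^treatment", names(methylomes))],
                             "treatment_pooled")
      tab <- band_shift_table(ctrl, trt, element_tracks, g,
                              window_size = config$window_size)
      utils::write.table(tab, out("band_shift.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tab
    }
  })

  dom <- stage("domains", {
    if (nrow(dmr_res$dmrs) == 0) stop("no DMRs to bin")
    binned <- bin_features(dmr_res$dmrs, g, bin_size = config$bin_size)
    bads <- call_bads(binned, quantile = config$quantile)
    b <- bads; b$name <- b$direction; b$score <- b$n_features
    write_bed(b, out("bads.bed"))
    write_bin_bedgraph(binned, out("bin_counts_hyper.bedGraph"), "hyper")
    write_bin_bedgraph(binned, out("bin_counts_hypo.bedGraph"), "hypo")
    list(binned = binned, bads = bads)
  })

  ovl <- stage("overlap", {
    if (is.null(tracks$lads)) NULL else {
      hyper <- dom$bads[dom$bads$direction %in% "hyper", , drop = FALSE]
      o <- domain_overlap(hyper, tracks$lads, g, bin_size = config$bin_size)
      utils::write.table(as.data.frame(o), out("lad_overlap.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      o
    }
  })

  corr <- stage("correlate", {
    if (is.null(tracks$peaks)) NULL else {
      pk <- bin_features(tracks$peaks$intervals, g, bin_size = config$bin_size)
      tab <- landscape_correlation(dom$binned, pk)
      utils::write.table(tab, out("landscape_correlation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      tab
    }
  })

  assoc <- stage("genes", {
    if (is.null(genes)) NULL else {
      a <- associate_dmrs(genes, dmr_res, flank = config$flank)
      utils::write.table(a, out("gene_associations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      h <- association_histogram(a, g)
      utils::write.table(h, out("gene_histogram.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(associations = a, histogram = h)
    }
  })

  files <- setdiff(list.files(config$out_dir), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(dmrs = dmr_res, enrichment = enr, band_shift = shift,
                 domains = dom, lad_overlap = ovl, correlation = corr,
                 genes = assoc, manifest = manifest))
}
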