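# Small in-code fixtures shared by several test files.

tiny_genome <- function(auto_len = 2e6, x_len = 2e6) {
  genome_description(c("a1", "aX"), c(auto_len, x_len), c(FALSE, TRUE))
}

# a methylome with given per-site counts on one chromosome
make_methylome <- function(pos, meth, total, chrom = "a1",
                           sample_id = "s", condition = "control",
                           replicate = 1) {
  methylome(sample_id, condition, replicate,
            data.frame(chrom = chrom, pos = pos, strand = "+",
                       meth = meth, total = total, context = "CpG",
                       stringsAsFactors = FALSE))
}

# fabricate a feature set whose per-bin counts equal `counts` on one chromosome
features_from_counts <- function(counts, chrom = "c1", bin_size = 1000) {
  rows <- list()
  for (b in seq_along(counts)) {
    n <- counts[b]
    if (n == 0) next
    s <- (b - 1) * bin_size + seq(100, 800, length.out = n)
    rows[[b]] <- data.frame(chrom = chrom, start = floor(s), end = floor(s) + 50,
                            direction = "hyper", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

tiny_simulation <- function(seed = 7, auto_len = 2e6, x_len = 2e6,
                            n_domains = 2, ...) {
  cfg <- simulation_config(seed = seed,
                           genome = tiny_genome(auto_len, x_len),
                           n_planted_domains = n_domains, ...)
  list(config = cfg, sim = suppressMessages(simulate_methylomes(cfg)))
}
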