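# Shared fixture builders; everything is generated in code at test time.

# Pool a reference panel's tissue replicates into one column per tissue.
pool_reference <- function(panel) {
  methylome_counts(
    panel$truth$site_coords,
    sapply(panel$counts, function(m) rowSums(m$meth)),
    sapply(panel$counts, function(m) rowSums(m$total))
  )
}

# Tiny MethylomeCounts from explicit matrices.
toy_counts <- function(meth, total, pos = NULL, chrom = "chr1") {
  meth <- as.matrix(meth)
  if (is.null(pos)) pos <- (seq_len(nrow(meth)) - 1L) * 1000L
  methylome_counts(data.frame(chrom = chrom, pos = as.integer(pos)),
                   meth, as.matrix(total))
}

# Single-site regions for a panel: sites are >= 1000 bp apart so a +/-250 bp
# window around each site contains exactly that site.
single_site_regions <- function(counts, sites) {
  aggregate_regions(counts, sites, flank_bp = 250)
}

# Grid-search oracle for a one-sample two-tissue mixture: maximizes the
# binomial likelihood over alpha_1 at the stated resolution with beta fixed.
grid_alpha_oracle <- function(x, d, beta1, beta2, step = 0.001) {
  grid <- seq(0, 1, by = step)
  ll <- vapply(grid, function(a) {
    p <- a * beta1 + (1 - a) * beta2
    sum(dbinom(x, d, p, log = TRUE))
  }, numeric(1))
  grid[which.max(ll)]
}
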