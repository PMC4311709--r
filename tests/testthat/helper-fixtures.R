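# shared fixture builders for the test suite

# tiny OTU table: n_samples x n_taxa, metadata for a paired 2-ecosystem design
tiny_table <- function(n_eco = 2, n_rep = 2, n_taxa = 30, depth = 200,
                       seed = 42) {
  design <- generate_design(n_eco, 2, n_rep)
  set.seed(seed)
  counts <- t(sapply(seq_len(nrow(design)), function(i) {
    pr <- stats::rlnorm(n_taxa, 0, 1.5)
    stats::rmultinom(1, depth, pr / sum(pr))[, 1]
  }))
  dimnames(counts) <- list(design$unit, sprintf("OTU%03d", seq_len(n_taxa)))
  md <- design
  names(md)[1] <- "sample"
  otu_table(counts, md)
}

# paired sample straight from count vectors
make_pair <- function(dry, rewet, ...) {
  names(dry) <- names(rewet) <- sprintf("OTU%02d", seq_along(dry))
  paired_sample(dry, rewet, ...)
}

# independent Bray-Curtis oracle (scalar loop over the definition)
bc_oracle <- function(x, y) {
  num <- 0
  for (i in seq_along(x)) num <- num + min(x[i], y[i])
  1 - 2 * num / (sum(x) + sum(y))
}
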