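# small in-code fixtures shared across tests

tiny_genome <- function(lengths = c(chr1 = 2400), bin = 200) {
  genome_build(names(lengths), unname(lengths), bin)
}

# BinaryTrack from 0/1 vectors (one per chromosome)
calls_track <- function(genome, ...) {
  v <- list(...)
  binary_track(genome, lapply(v, as.logical))
}

# BinnedVector from numeric vectors
counts_track <- function(genome, ...) {
  binned_vector(genome, list(...))
}

# GRanges from 0-based half-open triples
gr0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
}

# Poisson upper tail P(X >= x | lambda) by direct series summation,
# independent of stats::ppois
pois_upper_tail <- function(x, lambda) {
  if (x <= 0) return(1)
  k <- 0:(x - 1)
  1 - sum(exp(-lambda + k * log(lambda) - lfactorial(k)))
}

expect_track_equal <- function(a, b) {
  expect_identical(lapply(a$calls, as.logical), lapply(b$calls, as.logical))
}
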