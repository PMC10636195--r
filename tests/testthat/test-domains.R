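test_that("largest block finds the maximal run with leftmost tie-break", {
  gb <- tiny_genome(c(chr1 = 1600, chr2 = 1000))
  tr <- calls_track(gb, chr1 = c(0, 1, 1, 1, 0, 1, 1, 0),
                        chr2 = c(1, 1, 0, 1, 1))
  expect_equal(largest_block(tr, "chr1"), c(1L, 3L))
  expect_equal(largest_block(tr, "chr2"), c(0L, 1L))                # tie
  expect_equal(largest_block(tr, "chr2", "rightmost"), c(3L, 4L))
  empty <- calls_track(gb, chr1 = rep(0, 8), chr2 = rep(0, 5))
  expect_null(largest_block(empty, "chr1"))
  expect_error(largest_block(tr, "chr9"), "unknown chromosome")
})

test_that("extension bridges sub-limit gaps and stops at the limit", {
  gb <- tiny_genome(c(chr1 = 2400))
  tr <- calls_track(gb, chr1 = c(0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 1))
  seed <- largest_block(tr, "chr1")
  expect_equal(seed, c(1L, 3L))
  # 2-bin gap bridged to bin 6; the 4-bin gap (>= 3) stops extension
  expect_equal(extend_block(tr, "chr1", seed, gap_limit_bins = 3),
               c(1L, 6L))
  # gap_limit 1: any single negative bin stops extension
  expect_equal(extend_block(tr, "chr1", seed, gap_limit_bins = 1),
               seed)
  # a gap of exactly gap_limit bins is NOT bridged
  expect_equal(extend_block(tr, "chr1", seed, gap_limit_bins = 2),
               c(1L, 3L))
  # the trailing gap is exactly 4 bins: still not bridged at gap_limit 4
  expect_equal(extend_block(tr, "chr1", seed, gap_limit_bins = 4),
               c(1L, 6L))
  expect_equal(extend_block(tr, "chr1", seed, gap_limit_bins = 5),
               c(1L, 11L))
  expect_error(extend_block(tr, "chr1", c(0L, 3L)), "positive bins")
})

test_that("extension stops quietly at chromosome boundaries", {
  gb <- tiny_genome(c(chr1 = 1000))
  tr <- calls_track(gb, chr1 = c(1, 1, 0, 0, 1))
  expect_equal(extend_block(tr, "chr1", c(0L, 1L), gap_limit_bins = 3),
               c(0L, 4L))
  expect_equal(extend_block(tr, "chr1", c(0L, 1L), gap_limit_bins = 2),
               c(0L, 1L))
})

test_that("call_domains reports the worked example coverage exactly", {
  gb <- tiny_genome(c(chr1 = 2400))
  tr <- calls_track(gb, chr1 = c(0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 1))
  ds <- call_domains(tr, domain_call_config(gap_limit_bins = 3))
  expect_equal(ds$domains$first_bin, 1L)
  expect_equal(ds$domains$last_bin, 6L)
  expect_equal(ds$coverage_fraction, 4 / 5)
  expect_equal(ds$seed_blocks$first_bin, 1L)
  expect_equal(ds$domains$start_bp, 200)
  expect_equal(ds$domains$end_bp, 1400)
})

test_that("coverage denominator counts positives on every chromosome", {
  gb <- tiny_genome(c(chr1 = 1000, chr2 = 1000))
  tr <- calls_track(gb, chr1 = c(0, 1, 1, 0, 0), chr2 = rep(0, 5))
  ds <- call_domains(tr, domain_call_config(3))
  expect_equal(nrow(ds$domains), 1L)       # no domain on the silent chr2
  expect_equal(ds$coverage_fraction, 1.0)  # every positive is in one run
  all0 <- calls_track(gb, chr1 = rep(0, 5), chr2 = rep(0, 5))
  expect_error(call_domains(all0, domain_call_config(3)), "undefined")
})

test_that("coverage fraction is non-decreasing in the gap limit", {
  set.seed(11)
  gb <- tiny_genome(c(chr1 = 200 * 400, chr2 = 200 * 400))
  for (i in 1:5) {
    tr <- calls_track(gb, chr1 = runif(400) < 0.08,
                          chr2 = runif(400) < 0.2)
    if (n_positive(tr) == 0) next
    cov <- vapply(c(1, 2, 4, 8, 16, 64), function(gl)
      call_domains(tr, domain_call_config(gl))$coverage_fraction, 0)
    expect_true(all(diff(cov) >= 0))
  }
})

test_that("scanning construction agrees exhaustively with the brute-force oracle at small scale", {
  # full exhaustive sweep at acceptance scale lives in the acceptance tests;
  # this covers every vector up to 12 bins for gap limits 1..4
  for (gl in 1:4) {
    for (len in c(1, 2, 5, 12)) {
      expect_identical(domain_scan_all(len, gl),
                       domain_oracle_all(len, gl),
                       label = sprintf("len=%d gap=%d", len, gl))
    }
  }
})

test_that("call_domains matches the enumeration kernels case-for-case", {
  # the wrapper must agree with the kernel-level enumeration it delegates to
  gb <- tiny_genome(c(chr1 = 200 * 10))
  oracle <- domain_oracle_all(10, 2)
  set.seed(3)
  for (case in sample.int(2^10, 50)) {
    calls <- as.logical(intToBits(case - 1))[1:10]
    if (!any(calls)) next
    ds <- call_domains(binary_track(gb, list(chr1 = calls)),
                       domain_call_config(2))
    expect_equal(c(ds$domains$first_bin, ds$domains$last_bin),
                 unname(oracle[case, ]))
  }
})

test_that("anchors partition by half-open domain membership", {
  gb <- tiny_genome(c(chr1 = 2400, chr2 = 2400))
  tr <- calls_track(gb, chr1 = c(0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 1),
                        chr2 = rep(0, 12))
  ds <- call_domains(tr, domain_call_config(3))  # chr1 domain [200, 1400)
  a <- anchor_set(c("chr1", "chr1", "chr1", "chr2"),
                  c(200, 1399, 1400, 500), genome = gb)
  cls <- classify_anchors_by_domain(a, ds)
  expect_equal(as.character(cls),
               c("centromere_proximal", "centromere_proximal", "arm", "arm"))
})

test_that("domains export as BED with bp coordinates", {
  gb <- tiny_genome(c(chr1 = 2400))
  tr <- calls_track(gb, chr1 = c(0, 1, 1, 1, 0, 0, 1, 0, 0, 0, 0, 1))
  ds <- call_domains(tr, domain_call_config(3))
  f <- withr::local_tempfile(fileext = ".bed")
  write_domains_bed(ds, f)
  gr <- read_bed(f)
  expect_equal(GenomicRanges::start(gr) - 1L, 200L)
  expect_equal(GenomicRanges::end(gr), 1400L)
  expect_equal(gr$name, "chr1_centromere_proximal")
})
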