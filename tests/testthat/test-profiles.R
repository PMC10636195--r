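test_that("input normalization cancels depth and is 1 under symmetry", {
  gb <- tiny_genome(c(chr1 = 1000))
  chip <- counts_track(gb, chr1 = c(3, 1, 4, 1, 5))
  rt <- input_normalize(chip, chip)
  expect_equal(rt$values$chr1, rep(1, 5))
  # chip at twice the depth of a flat control still gives 1 everywhere
  flat1 <- counts_track(gb, chr1 = rep(4, 5))
  flat2 <- counts_track(gb, chr1 = rep(2, 5))
  expect_equal(input_normalize(flat1, flat2)$values$chr1, rep(1, 5))
  # empty bins give pseudocount over pseudocount = 1
  z <- counts_track(gb, chr1 = c(0, 0, 0, 0, 10))
  expect_equal(input_normalize(z, z)$values$chr1[1], 1)
  expect_error(input_normalize(counts_track(gb, chr1 = rep(0, 5)), chip),
               "degenerate")
  # enrichment direction: doubled depth-share gives a value above 1
  up <- counts_track(gb, chr1 = c(8, 4, 4, 4, 4))
  ref <- counts_track(gb, chr1 = rep(4, 5))
  expect_gt(input_normalize(up, ref)$values$chr1[1], 1)
})

test_that("signal matrices are constant on constant tracks and strand-reversed", {
  gb <- tiny_genome(c(chr1 = 20000))
  flat <- counts_track(gb, chr1 = rep(3, 100))
  a <- anchor_set(c("chr1", "chr1"), c(5000, 12000))
  m <- compute_matrix(flat, a, window_bp = 2000, profile_bin_bp = 50)
  expect_equal(dim(m$matrix), c(2L, 80L))
  expect_true(all(m$matrix == 3))

  # asymmetric step: minus-strand row is the plus-strand row reversed
  step <- counts_track(gb, chr1 = c(rep(0, 50), rep(6, 50)))
  plus <- anchor_set("chr1", 10000, "+")
  minus <- anchor_set("chr1", 10000, "-")
  mp <- compute_matrix(step, plus, 2000, 50)
  mm <- compute_matrix(step, minus, 2000, 50)
  expect_equal(mm$matrix[1, ], rev(mp$matrix[1, ]))
})

test_that("cells beyond the chromosome are masked, not zero-filled", {
  gb <- tiny_genome(c(chr1 = 20000))
  flat <- counts_track(gb, chr1 = rep(2, 100))
  near <- anchor_set("chr1", 100)
  m <- compute_matrix(flat, near, window_bp = 5000, profile_bin_bp = 50)
  expect_true(all(is.na(m$matrix[1, 1:98])))   # [-5000, -100) off-chromosome
  expect_true(all(m$matrix[1, 99:200] == 2))
  expect_error(compute_matrix(flat, near, window_bp = 5000,
                              profile_bin_bp = 33), "divisible")
})

test_that("cells straddling grid bins are length-weighted", {
  gb <- tiny_genome(c(chr1 = 2000))
  tr <- counts_track(gb, chr1 = c(0, 10, 0, 0, 0, 0, 0, 0, 0, 0))
  # one 100-bp cell covering [150, 250): half in bin 0 (value 0), half in
  # bin 1 (value 10) -> 5
  m <- compute_matrix(tr, anchor_set("chr1", 250), window_bp = 100,
                      profile_bin_bp = 100)
  expect_equal(m$matrix[1, ], c(5, 10))
})

test_that("metagene averages unmasked cells and flags empty columns", {
  gb <- tiny_genome(c(chr1 = 20000))
  tr <- counts_track(gb, chr1 = rep(c(0, 2), 50))
  single <- compute_matrix(tr, anchor_set("chr1", 10000), 1000, 200)
  prof <- metagene(single)
  expect_equal(prof$profile, single$matrix[1, ])  # single row: the row itself
  m <- single
  m$matrix <- rbind(c(0, 2, NA, NA, NA, NA, NA, NA, NA, NA),
                    c(2, 0, NA, NA, NA, NA, NA, NA, NA, NA))
  prof2 <- metagene(m)
  expect_equal(prof2$profile[1:2], c(1, 1))
  expect_true(all(is.na(prof2$profile[3:10])))    # fully masked -> missing
  expect_equal(prof2$n, c(2L, 2L, rep(0L, 8)))
})

test_that("metagene profiles are symmetric around symmetric planted signal", {
  set.seed(21)
  gb <- tiny_genome(c(chr1 = 2e6))
  nb <- unname(n_bins(gb))
  pos <- seq(50000, 1950000, by = 10000)
  rate <- rep(1, nb)
  for (p in pos) {
    d <- abs((seq_len(nb) - 0.5) * 200 - p)
    rate <- rate + 8 * exp(-d^2 / (2 * 400^2))
  }
  tr <- counts_track(gb, chr1 = rpois(nb, rate))
  prof <- metagene(compute_matrix(tr, anchor_set("chr1", pos), 2000, 200))$profile
  expect_equal(prof, rev(prof), tolerance = 0.1)
  expect_gt(prof[10], 2 * prof[1])  # enrichment peaks at the anchor
})

test_that("pairwise Pearson has unit diagonal, detects sign, ignores affine scale", {
  set.seed(31)
  gb <- tiny_genome(c(chr1 = 200 * 5000))
  x <- rpois(5000, 5)
  tx <- counts_track(gb, chr1 = x)
  tneg <- counts_track(gb, chr1 = max(x) - x)   # negation about a constant
  cm <- pairwise_pearson(list(a = tx, b = tneg), summary_bin_bp = 200)
  expect_equal(unname(diag(cm)), c(1, 1))
  expect_equal(cm["a", "b"], -1)
  # affine rescaling leaves correlations unchanged
  ty <- counts_track(gb, chr1 = rpois(5000, 5) + 0.2 * x)
  c1 <- pairwise_pearson(list(tx, ty), 1000)[1, 2]
  sc <- counts_track(gb, chr1 = 7 * x + 3)
  c2 <- pairwise_pearson(list(sc, ty), 1000)[1, 2]
  expect_equal(c1, c2)
  # zero-variance track: NA against partners, 1 on the diagonal
  const <- counts_track(gb, chr1 = rep(2, 5000))
  cz <- pairwise_pearson(list(tx, const), 1000)
  expect_true(is.na(cz[1, 2]) && cz[2, 2] == 1)
})

test_that("aggregation to summary bins averages the grid", {
  gb <- tiny_genome(c(chr1 = 1200))
  a <- counts_track(gb, chr1 = c(0, 2, 4, 6, 8, 10))
  b <- counts_track(gb, chr1 = c(10, 8, 6, 4, 2, 0))
  cm <- pairwise_pearson(list(a, b), summary_bin_bp = 400)
  # summary means: a = (1,5,9), b = (9,5,1) -> correlation -1
  expect_equal(cm[1, 2], -1)
})
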