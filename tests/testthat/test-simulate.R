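# shared small configuration: 2 x 4 Mb chromosomes keeps these tests fast
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 17, n_chrom = 2, chrom_len_bp = 4e6,
         centromere_halfwidth_bp = 4e5, n_tss = 300),
    list(...))
  do.call(sim_config, args)
}

test_that("identical seeds reproduce the experiment byte for byte", {
  s1 <- simulate_genome(small_cfg())
  s2 <- simulate_genome(small_cfg())
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.data.frame(s1$tss), as.data.frame(s2$tss))
  t1 <- simulate_tracks(s1, "H3T3ph", "mitotic")
  t2 <- simulate_tracks(s2, "H3T3ph", "mitotic")
  expect_identical(lapply(t1, `[[`, "values"), lapply(t2, `[[`, "values"))
  s3 <- simulate_genome(small_cfg(seed = 18))
  expect_false(identical(s1$truth$speckle, s3$truth$speckle))
})

test_that("annotation truth matches the configuration", {
  sim <- simulate_genome(small_cfg())
  expect_equal(nrow(sim$truth$domains), 2L)       # one domain per chromosome
  expect_equal(nrow(as.data.frame(sim$tss)), 300L)
  expect_equal(nrow(sim$truth$escapers), round(0.003 * 300))
  # TSSs respect the guard band
  expect_true(all(sim$tss$pos >= 5e4 & sim$tss$pos < 4e6 - 5e4))
  # speckled bins are confined to the configured centromeric interval
  for (ch in c("chr1", "chr2")) {
    w <- which(sim$truth$speckle[[ch]]) - 1L
    expect_true(all(w * 200 >= 2e6 - 4e5 - 200 & w * 200 < 2e6 + 4e5))
  }

  empty <- simulate_genome(small_cfg(n_tss = 0))
  expect_equal(nrow(as.data.frame(empty$tss)), 0L)
  expect_equal(nrow(empty$truth$escapers), 0L)

  noesc <- simulate_genome(small_cfg(dp_promoter_frac = 0))
  expect_equal(nrow(noesc$truth$escapers), 0L)

  expect_error(simulate_genome(small_cfg(tss_guard_bp = 2.5e6)),
               "infeasible")
})

test_that("input counts are Poisson around the background rate", {
  sim <- simulate_genome(small_cfg())
  inp <- simulate_tracks(sim, "input", "mitotic", n_replicates = 1)[[1]]
  v <- unlist(inp$values)
  se <- sqrt(0.5 / length(v))
  expect_lt(abs(mean(v) - 0.5), 3 * se)
  # index of dispersion near 1 for Poisson
  expect_lt(abs(var(v) / mean(v) - 1), 0.05)
})

test_that("a null configuration makes H3T3ph indistinguishable from input", {
  sim <- simulate_genome(small_cfg(t3_fold = 1, t3_escaper_fold = 1,
                                   promoter_t3_depletion_frac = 1))
  t3 <- simulate_tracks(sim, "H3T3ph", "mitotic", n_replicates = 1)[[1]]
  inp <- simulate_tracks(sim, "input", "mitotic", n_replicates = 1)[[1]]
  # two-sample Poisson rate test on the totals
  pt <- stats::poisson.test(c(track_total(t3), track_total(inp)))
  expect_gt(pt$p.value, 0.01)
  # and per-bin means agree within sampling error
  expect_lt(abs(mean(unlist(t3$values)) - mean(unlist(inp$values))),
            3 * sqrt(2 * 0.5 / sum(n_bins(sim$genome))))
})

test_that("the mitotic H3T3ph rate structure is present in the counts", {
  sim <- simulate_genome(small_cfg())
  t3 <- simulate_tracks(sim, "H3T3ph", "mitotic", n_replicates = 1)[[1]]
  sp <- sim$truth$speckle$chr1
  v <- t3$values$chr1
  expect_gt(mean(v[sp]), 6)          # enriched speckle, rate 8
  expect_lt(mean(v[!sp]), 1)         # background elsewhere
  async <- simulate_tracks(sim, "H3T3ph", "async", n_replicates = 1)[[1]]
  expect_lt(mean(unlist(async$values)), 1)  # the mark is mitosis-specific
})

test_that("H3K4me2/3 carries the NDR dip only in asynchronous chromatin", {
  sim <- simulate_genome(small_cfg(n_tss = 400))
  k4a <- simulate_tracks(sim, "H3K4me23", "async", n_replicates = 1)[[1]]
  k4m <- simulate_tracks(sim, "H3K4me23", "mitotic", n_replicates = 1)[[1]]
  ma <- metagene(compute_matrix(k4a, sim$tss, 1000, 200))
  mm <- metagene(compute_matrix(k4m, sim$tss, 1000, 200))
  center <- 5:6   # columns covering [-200, 200) around the TSS
  flank <- c(3, 8)  # [-600, -400) and [400, 600), outside the NDR
  # async: center depressed relative to flank; mitotic: filled in
  expect_lt(mean(ma$profile[center]), 0.6 * mean(ma$profile[flank]))
  expect_gt(mean(mm$profile[center]), mean(mm$profile[flank]))
})

test_that("overdispersion inflates variance beyond Poisson", {
  sim <- simulate_genome(small_cfg(overdispersion = 0.5))
  inp <- simulate_tracks(sim, "input", "mitotic", n_replicates = 1)[[1]]
  v <- unlist(inp$values)
  # var = mu + od * mu^2 = 0.5 + 0.125 -> dispersion index 1.25
  expect_gt(var(v) / mean(v), 1.1)
})

test_that("simulated experiments serialize to standard text formats", {
  sim <- simulate_genome(small_cfg(n_chrom = 1, chrom_len_bp = 4e5,
                                   centromere_halfwidth_bp = 5e4,
                                   n_tss = 20))
  out <- withr::local_tempdir()
  paths <- write_simulated_experiment(sim, out)
  gb <- read_chrom_sizes(paths$chrom_sizes)
  expect_identical(gb$chrom_names, "chr1")
  tss <- read_anchors_bed(paths$tss, gb)
  expect_equal(tss$pos, sim$tss$pos)
  expect_equal(tss$strand, sim$tss$strand)
  back <- read_bedgraph(paths$H3T3ph_mitotic_rep1, gb)
  orig <- simulate_tracks(sim, "H3T3ph", "mitotic")[[1]]
  expect_equal(back$values, orig$values)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$domains$first_bin, sim$truth$domains$first_bin)
})
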