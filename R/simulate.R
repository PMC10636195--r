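#' Simulation settings for synthetic ChIP-seq experiments
#'
#' Defines a small multi-chromosome genome with, per chromosome, one broad
#' speckled H3T3ph-enriched region centered on a designated "centromere";
#' TSSs with H3K4me2/3 promoter enrichment (NDR dip present in
#' asynchronous chromatin, filled in mitosis); selective H3T3ph depletion
#' within +/- 1 kb of promoters; a designed minority of "escaper" promoters
#' that carry strong promoter-scale H3T3ph; replicate Poisson count tracks;
#' and a flat input control.  Identical seeds give byte-identical output.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_chrom Number of chromosomes (default 3).
#' @param chrom_len_bp Length of each chromosome (default 20 Mb).
#' @param bin_size_bp Grid bin width (default 200).
#' @param centromere_center_frac Centromere midpoint as a fraction of
#'   chromosome length (default 0.5; recycled across chromosomes).
#' @param centromere_halfwidth_bp Half-width of the enriched region
#'   (default 1 Mb, i.e. a 2 Mb domain).
#' @param background_rate Expected fragments per bin per replicate outside
#'   any feature (default 0.5).
#' @param t3_fold H3T3ph enrichment of speckled centromeric bins over
#'   background (default 16, strong mitotic centromeric enrichment: high
#'   enough that enriched bins are called in most replicates, so the
#'   largest contiguous block of calls falls in the centromere).
#' @param t3_positive_density Probability that a centromeric bin is
#'   enriched (default 0.5): the domain is speckled, not solid, so the
#'   gap-tolerant extension is genuinely exercised.
#' @param t3_escaper_fold H3T3ph enrichment at escaper promoters (default
#'   20): escapers are promoters where the phosphorylation mark is
#'   genuinely deposited, so their signal is promoter-peak-scale.
#' @param t3_escaper_halfwidth_bp Half-width of the escaper H3T3ph patch
#'   (default 500): detectable promoter H3T3ph spans a few bins around the
#'   TSS, not the whole +/- 1 kb window.
#' @param promoter_t3_depletion_frac Multiplier applied to the H3T3ph rate
#'   within +/- 1 kb of every non-escaper TSS (default 0.1): the selective
#'   depletion of the phosphorylation mark at methylated promoters.
#' @param n_tss Number of TSSs, placed uniformly outside a guard band
#'   (default 2000).
#' @param tss_guard_bp Guard band excluded from TSS placement at each
#'   chromosome end (default 50 kb).
#' @param k4_fold Peak H3K4me2/3 enrichment over background (default 30).
#' @param k4_peak_halfwidth_bp Gaussian sigma of the promoter H3K4me2/3
#'   envelope (default 500).
#' @param ndr_width_bp Half-width of the nucleosome-depleted region at the
#'   TSS (default 300).
#' @param ndr_depth_frac Fraction of coverage remaining at the NDR in
#'   asynchronous chromatin (default 0.3); in mitosis the dip is filled.
#' @param dp_promoter_frac Designed fraction of K4 promoters that are
#'   H3T3ph escapers (default 0.003); the escaper count is the rounded
#'   fraction, the positions are random.
#' @param n_replicates Replicates per track (default 3).
#' @param depth_per_replicate Multiplier on all rates (default 1).
#' @param overdispersion Extra-Poisson noise: per-bin rates are
#'   gamma-jittered with squared coefficient of variation equal to this
#'   value (default 0 = pure Poisson).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 3L,
                       chrom_len_bp = 20e6,
                       bin_size_bp = 200L,
                       centromere_center_frac = 0.5,
                       centromere_halfwidth_bp = 1e6,
                       background_rate = 0.5,
                       t3_fold = 16,
                       t3_positive_density = 0.5,
                       t3_escaper_fold = 20,
                       t3_escaper_halfwidth_bp = 500,
                       promoter_t3_depletion_frac = 0.1,
                       n_tss = 2000L,
                       tss_guard_bp = 50e3,
                       k4_fold = 30,
                       k4_peak_halfwidth_bp = 500,
                       ndr_width_bp = 300,
                       ndr_depth_frac = 0.3,
                       dp_promoter_frac = 0.003,
                       n_replicates = 3L,
                       depth_per_replicate = 1,
                       overdispersion = 0) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chrom >= 1, chrom_len_bp >= bin_size_bp,
              background_rate >= 0, t3_fold >= 0,
              t3_positive_density >= 0, t3_positive_density <= 1,
              promoter_t3_depletion_frac >= 0,
              dp_promoter_frac >= 0, dp_promoter_frac <= 1,
              ndr_depth_frac >= 0, ndr_depth_frac <= 1,
              n_replicates >= 1, depth_per_replicate > 0,
              overdispersion >= 0)
  })
  cfg$seed <- as.integer(seed)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate the genome, TSS annotation and ground truth
#'
#' Lays out the chromosomes, draws the speckled centromeric H3T3ph bins,
#' places TSSs uniformly outside the guard band, and designates the escaper
#' promoters.  The returned truth record carries everything downstream
#' recovery tests compare against: the true domain interval per chromosome
#' (outermost enriched bins), the enriched-bin masks, and the escaper TSS
#' set.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `SimulatedGenome`: `genome` ([genome_build()]),
#'   `tss` ([anchor_set()]), `config`, and `truth` (list with `domains`
#'   data.frame, `speckle` logical masks per chromosome, `escapers`
#'   data.frame of escaper TSSs).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  genome <- genome_build(chroms, rep(cfg$chrom_len_bp, cfg$n_chrom),
                         cfg$bin_size_bp)
  b <- cfg$bin_size_bp
  cc_frac <- rep_len(cfg$centromere_center_frac, cfg$n_chrom)

  speckle <- list()
  dom_rows <- list()
  for (i in seq_len(cfg$n_chrom)) {
    ch <- chroms[i]
    nb <- genome$n_bins[[ch]]
    center <- cc_frac[i] * cfg$chrom_len_bp
    lo_bin <- max(0L, floor((center - cfg$centromere_halfwidth_bp) / b))
    hi_bin <- min(nb - 1L,
                  floor((center + cfg$centromere_halfwidth_bp - 1) / b))
    mask <- logical(nb)
    idx <- lo_bin:hi_bin
    mask[idx + 1L] <- runif(length(idx)) < cfg$t3_positive_density
    speckle[[ch]] <- mask
    w <- which(mask)
    dom_rows[[ch]] <- data.frame(
      chrom = ch,
      first_bin = if (length(w)) w[1L] - 1L else NA_integer_,
      last_bin = if (length(w)) w[length(w)] - 1L else NA_integer_,
      start_bp = if (length(w)) (w[1L] - 1) * b else NA_real_,
      end_bp = if (length(w)) min(w[length(w)] * b, cfg$chrom_len_bp)
               else NA_real_,
      centromere_center_bp = center,
      stringsAsFactors = FALSE)
  }

  if (cfg$n_tss > 0 && 2 * cfg$tss_guard_bp >= cfg$chrom_len_bp)
    stop("infeasible TSS placement: guard band covers the chromosome")
  n_tss <- as.integer(cfg$n_tss)
  if (n_tss > 0) {
    tss_chrom <- sample(chroms, n_tss, replace = TRUE)
    tss_pos <- floor(runif(n_tss, cfg$tss_guard_bp,
                           cfg$chrom_len_bp - cfg$tss_guard_bp))
    tss_strand <- sample(c("+", "-"), n_tss, replace = TRUE)
    ord <- order(match(tss_chrom, chroms), tss_pos)
    tss <- anchor_set(tss_chrom[ord], tss_pos[ord], tss_strand[ord],
                      genome = genome, label = "simulated TSSs")
  } else {
    tss <- anchor_set(character(), numeric(), label = "simulated TSSs")
  }

  n_esc <- round(cfg$dp_promoter_frac * n_tss)
  esc_idx <- if (n_esc > 0) sort(sample.int(n_tss, n_esc)) else integer()
  escapers <- as.data.frame(tss)[esc_idx, c("chrom", "pos", "strand"),
                                 drop = FALSE]
  rownames(escapers) <- NULL

  structure(list(genome = genome, tss = tss, config = cfg,
                 truth = list(domains = do.call(rbind, dom_rows),
                              speckle = speckle,
                              escaper_idx = esc_idx,
                              escapers = escapers)),
            class = "SimulatedGenome")
}

# per-chromosome expected-count rate field for one mark/condition
.rate_field <- function(sim, mark, condition, chrom) {
  cfg <- sim$config
  g <- sim$genome
  b <- cfg$bin_size_bp
  nb <- g$n_bins[[chrom]]
  centers <- (seq_len(nb) - 0.5) * b
  bg <- cfg$background_rate
  rate <- rep(bg, nb)
  if (mark == "input") return(rate)

  tss <- as.data.frame(sim$tss)
  tss <- tss[tss$chrom == chrom, , drop = FALSE]
  esc <- sim$truth$escapers
  esc_pos <- esc$pos[esc$chrom == chrom]

  if (mark == "H3K4me23") {
    if (nrow(tss)) {
      p <- sort(tss$pos)
      j <- findInterval(centers, p)
      d_left <- ifelse(j >= 1, centers - p[pmax(j, 1L)], Inf)
      d_right <- ifelse(j < length(p), p[pmin(j + 1L, length(p))] - centers,
                        Inf)
      d <- pmin(abs(d_left), abs(d_right))
      shape <- exp(-d^2 / (2 * cfg$k4_peak_halfwidth_bp^2))
      rate <- bg * (1 + cfg$k4_fold * shape)
      if (condition == "async") {
        ndr <- d < cfg$ndr_width_bp
        rate[ndr] <- rate[ndr] * cfg$ndr_depth_frac
      }
    }
    return(rate)
  }

  if (mark == "H3T3ph") {
    if (condition != "mitotic") return(rate)  # mitosis-specific mark
    rate[sim$truth$speckle[[chrom]]] <- bg * cfg$t3_fold
    win <- 1000
    if (nrow(tss)) {
      dep <- logical(nb)
      non_esc <- setdiff(tss$pos, esc_pos)
      for (p in non_esc) {
        lo <- max(1L, floor((p - win) / b) + 1L)
        hi <- min(nb, floor((p + win - 1) / b) + 1L)
        dep[lo:hi] <- TRUE
      }
      rate[dep] <- rate[dep] * cfg$promoter_t3_depletion_frac
      ew <- cfg$t3_escaper_halfwidth_bp
      for (p in esc_pos) {
        lo <- max(1L, floor((p - ew) / b) + 1L)
        hi <- min(nb, floor((p + ew - 1) / b) + 1L)
        rate[lo:hi] <- bg * cfg$t3_escaper_fold
      }
    }
    return(rate)
  }
  stop("unknown mark: ", mark)
}

#' Simulate replicate count tracks for one mark and condition
#'
#' Draws per-bin Poisson counts (optionally gamma-overdispersed) around the
#' configured rate field: input is flat background; mitotic H3T3ph is
#' enriched on the speckled centromeric bins, depleted within +/- 1 kb of
#' non-escaper TSSs and strongly enriched at escaper promoters;
#' asynchronous H3T3ph is background (the mark is mitosis-specific);
#' H3K4me2/3 carries promoter-flanking enrichment with an NDR dip in
#' asynchronous chromatin that is filled in mitosis.  The replicate draws
#' for each (mark, condition) pair are seeded deterministically from the
#' configuration seed.
#'
#' @param sim A [simulate_genome()] result.
#' @param mark `"H3T3ph"`, `"H3K4me23"` or `"input"`.
#' @param condition `"mitotic"` or `"async"`.
#' @param n_replicates Number of replicate tracks (default from the
#'   configuration).
#' @return List of [binned_vector()] count tracks, one per replicate.
#' @export
simulate_tracks <- function(sim, mark = c("H3T3ph", "H3K4me23", "input"),
                            condition = c("mitotic", "async"),
                            n_replicates = NULL) {
  stopifnot(inherits(sim, "SimulatedGenome"))
  mark <- match.arg(mark)
  condition <- match.arg(condition)
  cfg <- sim$config
  if (is.null(n_replicates)) n_replicates <- cfg$n_replicates
  g <- sim$genome
  mark_i <- match(mark, c("H3T3ph", "H3K4me23", "input"))
  cond_i <- match(condition, c("mitotic", "async"))
  set.seed((abs(cfg$seed) * 7 + mark_i * 1000003 + cond_i * 10007) %%
             2147483647)
  rates <- lapply(g$chrom_names, function(ch)
    .rate_field(sim, mark, condition, ch) * cfg$depth_per_replicate)
  names(rates) <- g$chrom_names
  lapply(seq_len(n_replicates), function(r) {
    vals <- lapply(rates, function(lam) {
      if (cfg$overdispersion > 0) {
        shp <- 1 / cfg$overdispersion
        lam <- lam * stats::rgamma(length(lam), shape = shp, rate = shp)
      }
      as.numeric(rpois(length(lam), lam))
    })
    binned_vector(g, vals)
  })
}

#' Write a simulated experiment to disk
#'
#' Emits chrom.sizes, TSS BED6, truth JSON, and per-replicate bedGraph
#' count tracks for mitotic H3T3ph, mitotic and asynchronous H3K4me2/3,
#' and input.
#'
#' @param sim A [simulate_genome()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of emitted paths.
#' @export
write_simulated_experiment <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- sim$genome
  paths <- list(chrom_sizes = file.path(outdir, "genome.chrom.sizes"),
                tss = file.path(outdir, "tss.bed"),
                truth = file.path(outdir, "truth.json"))
  writeLines(paste(g$chrom_names, format_bp(g$chrom_lengths_bp), sep = "\t"),
             paths$chrom_sizes)
  write_anchors_bed(sim$tss, paths$tss)
  truth <- sim$truth
  truth$speckle <- lapply(truth$speckle, function(m) which(m) - 1L)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  combos <- list(c("H3T3ph", "mitotic"), c("H3K4me23", "mitotic"),
                 c("H3K4me23", "async"), c("input", "mitotic"))
  for (co in combos) {
    reps <- simulate_tracks(sim, co[1L], co[2L])
    for (r in seq_along(reps)) {
      p <- file.path(outdir,
                     sprintf("%s_%s_rep%d.bedgraph", co[1L], co[2L], r))
      write_bedgraph(reps[[r]], p)
      paths[[sprintf("%s_%s_rep%d", co[1L], co[2L], r)]] <- p
    }
  }
  invisible(paths)
}
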