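#' Default pipeline configuration
#'
#' Every analysis parameter surfaces as a named key at its standard value:
#' 200-bp bins, Poisson tail threshold 1e-4, union replicate merge,
#' 3000-bin (600 kb) gap limit, +/- 1 kb promoter windows, +/- 5 kb
#' metagene windows at 50-bp resolution, 10-kb correlation bins.
#'
#' @param seed Seed for the simulated inputs.
#' @return Nested list of per-stage settings.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    simulate = list(seed = as.integer(seed)),
    binarize = list(p_threshold = 1e-4, lambda_floor = 1.0,
                    control_smooth_bins = 0L),
    merge = list(mode = "union"),
    domains = list(gap_limit_bins = 3000L),
    cooccur = list(window_bp = 1000L, min_replicates = 2L),
    profiles = list(window_bp = 5000L, profile_bin_bp = 50L,
                    summary_bin_bp = 10000L, pseudocount = 1.0)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

read_stage <- function(stage, what, path, loader) {
  if (is.null(path) || !file.exists(path))
    stop("[", stage, "] missing input file for ", what, ": ",
         if (is.null(path)) "<unset>" else path)
  loader(path)
}

#' Run the full analysis pipeline
#'
#' Executes binarize -> merge -> call-domains -> co-occurrence -> profiles
#' on either a seeded simulated experiment (config section `simulate`) or
#' user-supplied files (config section `inputs` naming `chrom_sizes`,
#' `tss`, per-replicate `t3_chip`/`k4_chip` bedGraphs, an `input` bedGraph,
#' and optional per-replicate `k4_peaks` BEDs).  When no peak files are
#' given, per-replicate H3K4me2/3 peaks are derived from each replicate's
#' binarized positive runs (peak calling itself is outside this package).
#' Deterministic given the configuration; artifacts and a JSON report are
#' written under `outdir`.
#'
#' @param config Path to a YAML configuration, or an equivalent nested
#'   list.  Unset keys fall back to [default_pipeline_config()].
#' @param outdir Output directory (default `config$outdir`, else a
#'   tempdir subdirectory).
#' @return A list of class `PipelineReport` (also written as
#'   `report.json`): coverage fraction, per-chromosome domain table,
#'   promoter co-occurrence counts and fraction, sample correlation
#'   matrix, paths of emitted artifacts, and the effective configuration.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("[config] file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) outdir <- file.path(tempdir(), "phosdomain_run")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  simulated <- is.null(cfg$inputs)
  if (simulated) {
    sim_cfg <- do.call(sim_config, cfg$simulate)
    sim <- simulate_genome(sim_cfg)
    genome <- sim$genome
    tss <- sim$tss
    t3_reps <- simulate_tracks(sim, "H3T3ph", "mitotic")
    k4_reps <- simulate_tracks(sim, "H3K4me23", "mitotic")
    input_reps <- simulate_tracks(sim, "input", "mitotic")
    k4_peak_sets <- NULL
  } else {
    inp <- cfg$inputs
    genome <- read_stage("inputs", "chrom_sizes", inp$chrom_sizes,
                         function(p) read_chrom_sizes(p, inp$bin_size_bp %||% 200L))
    tss <- read_stage("inputs", "tss", inp$tss,
                      function(p) read_anchors_bed(p, genome))
    load_bg <- function(p) read_bedgraph(p, genome)
    t3_reps <- lapply(inp$t3_chip, function(p)
      read_stage("inputs", "t3_chip", p, load_bg))
    k4_reps <- lapply(inp$k4_chip, function(p)
      read_stage("inputs", "k4_chip", p, load_bg))
    input_reps <- lapply(inp$input %||% inp$control, function(p)
      read_stage("inputs", "input", p, load_bg))
    k4_peak_sets <- if (!is.null(inp$k4_peaks))
      lapply(inp$k4_peaks, function(p) read_stage("inputs", "k4_peaks", p,
                                                  read_bed))
  }
  rep_input <- function(i) input_reps[[min(i, length(input_reps))]]

  # --- binarize ------------------------------------------------------------
  bcfg <- binarize_config(p_threshold = cfg$binarize$p_threshold,
                          lambda_floor = cfg$binarize$lambda_floor,
                          control_smooth_bins = cfg$binarize$control_smooth_bins)
  t3_bin <- lapply(seq_along(t3_reps), function(i)
    poisson_binarize(t3_reps[[i]], rep_input(i), bcfg))
  k4_bin <- lapply(seq_along(k4_reps), function(i)
    poisson_binarize(k4_reps[[i]], rep_input(i), bcfg))

  # --- merge + domains -----------------------------------------------------
  t3_merged <- merge_replicates(t3_bin, mode = cfg$merge$mode)
  domains <- call_domains(t3_merged,
                          domain_call_config(cfg$domains$gap_limit_bins))

  # --- co-occurrence -------------------------------------------------------
  if (is.null(k4_peak_sets))
    k4_peak_sets <- lapply(k4_bin, function(tr) {
      runs <- positive_runs(tr)
      GenomicRanges::GRanges(runs$chrom,
                             IRanges::IRanges(runs$start + 1, runs$end))
    })
  k4_peaks <- replicate_consistent_peaks(k4_peak_sets,
                                         cfg$cooccur$min_replicates)
  dp <- double_positive_bins(t3_bin, k4_bin)
  promoters <- classify_promoters(tss, dp, k4_peaks,
                                  window_bp = cfg$cooccur$window_bp)

  # --- profiles ------------------------------------------------------------
  ratio_tracks <- c(
    setNames(lapply(seq_along(t3_reps), function(i)
      input_normalize(t3_reps[[i]], rep_input(i), cfg$profiles$pseudocount)),
      paste0("H3T3ph_rep", seq_along(t3_reps))),
    setNames(lapply(seq_along(k4_reps), function(i)
      input_normalize(k4_reps[[i]], rep_input(i), cfg$profiles$pseudocount)),
      paste0("H3K4me23_rep", seq_along(k4_reps))))
  cor_mat <- pairwise_pearson(ratio_tracks, cfg$profiles$summary_bin_bp)
  k4_matrix <- compute_matrix(ratio_tracks[[length(t3_reps) + 1L]], tss,
                              window_bp = cfg$profiles$window_bp,
                              profile_bin_bp = cfg$profiles$profile_bin_bp)
  k4_profile <- metagene(k4_matrix)

  # --- artifacts -----------------------------------------------------------
  paths <- list(
    domains_bed = file.path(outdir, "domains.bed"),
    promoters_tsv = file.path(outdir, "promoters.tsv"),
    metagene_tsv = file.path(outdir, "metagene_H3K4me23.tsv"),
    report = file.path(outdir, "report.json"))
  write_domains_bed(domains, paths$domains_bed)
  write.table(promoters$table, paths$promoters_tsv, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(position_bp = k4_profile$positions_bp,
                         mean_signal = round(k4_profile$profile, 6),
                         n = k4_profile$n),
              paths$metagene_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)

  report <- list(
    coverage_fraction = domains$coverage_fraction,
    domains = domains$domains,
    n_positive_bins = n_positive(t3_merged),
    n_k4_tss = promoters$n_k4_tss,
    n_double_positive_tss = promoters$n_double_positive_tss,
    promoter_fraction = promoters$fraction,
    correlation = round(cor_mat, 6),
    paths = lapply(paths, normalizePath, mustWork = FALSE),
    config = cfg)
  class(report) <- "PipelineReport"
  jsonlite::write_json(
    lapply(unclass(report), function(x)
      if (is.numeric(x)) round(x, 10) else x),
    paths$report, auto_unbox = TRUE, digits = 10, dataframe = "columns",
    matrix = "rowmajor")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport\n")
  cat(sprintf("  positive-bin coverage by domains: %.1f%%\n",
              100 * x$coverage_fraction))
  cat(sprintf("  domains: %d chromosome(s)\n", nrow(x$domains)))
  cat(sprintf("  K4-marked promoters: %d; double-positive: %d (%.2f%%)\n",
              x$n_k4_tss, x$n_double_positive_tss,
              100 * x$promoter_fraction))
  invisible(x)
}
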