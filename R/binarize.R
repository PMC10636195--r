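#' Per-bin presence/absence calls for one mark
#'
#' @param genome A [genome_build()].
#' @param calls Named list of logical vectors, one per chromosome, on the
#'   genome's bin grid.  Missing chromosomes are all-`FALSE`.
#' @return An object of class `BinaryTrack`.
#' @export
binary_track <- function(genome, calls = NULL) {
  stopifnot(inherits(genome, "GenomeBuild"))
  nb <- genome$n_bins
  if (is.null(calls)) {
    calls <- lapply(nb, function(n) logical(n))
  } else {
    calls <- setNames(lapply(genome$chrom_names, function(ch) {
      v <- calls[[ch]]
      if (is.null(v)) return(logical(nb[[ch]]))
      if (length(v) != nb[[ch]])
        stop("calls for ", ch, " do not match the bin grid")
      as.logical(v)
    }), genome$chrom_names)
  }
  structure(list(genome = genome, calls = calls), class = "BinaryTrack")
}

#' @export
print.BinaryTrack <- function(x, ...) {
  np <- n_positive(x)
  nt <- sum(x$genome$n_bins)
  cat("BinaryTrack:", format(np, big.mark = ","), "positive of",
      format(nt, big.mark = ","), "bins",
      sprintf("(%.3f%%)\n", 100 * np / nt))
  invisible(x)
}

#' Number of positive bins
#' @param track A [binary_track()].
#' @export
n_positive <- function(track) sum(vapply(track$calls, sum, 0))

#' Binarization settings
#'
#' @param p_threshold Poisson upper-tail probability at or below which a bin
#'   is called positive (default `1e-4`, the default of the binarization
#'   tool this model follows).
#' @param control_scaling `"depth"` scales the control expectation by total
#'   ChIP / total control signal; `"none"` uses raw control counts.
#' @param lambda_floor Minimal per-bin expectation (default 1), preventing
#'   spuriously significant calls where the control is empty.
#' @param control_smooth_bins Half-width, in bins, of a running-mean window
#'   applied to the control before scaling (default 0 = no smoothing).
#' @return A list of class `BinarizeConfig`.
#' @export
binarize_config <- function(p_threshold = 1e-4,
                            control_scaling = c("depth", "none"),
                            lambda_floor = 1.0,
                            control_smooth_bins = 0L) {
  control_scaling <- match.arg(control_scaling)
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("p_threshold must be in (0, 1)")
  if (lambda_floor <= 0) stop("lambda_floor must be positive")
  structure(list(p_threshold = p_threshold,
                 control_scaling = control_scaling,
                 lambda_floor = lambda_floor,
                 control_smooth_bins = as.integer(control_smooth_bins)),
            class = "BinarizeConfig")
}

# running mean over +/- w bins with shrinking windows at chromosome ends
running_mean <- function(x, w) {
  if (w <= 0L || length(x) < 2L) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Poisson binarization of a ChIP track against its input control
#'
#' Bin `i` is called positive when the Poisson upper tail
#' `P(X >= chip_i | lambda_i)` is at or below `p_threshold`, with
#' `lambda_i = max(lambda_floor, control_i * total_chip / total_control)`
#' under depth scaling (the input for each sample is the control data set).
#' With no control the genome-wide mean ChIP count per bin is used as a
#' flat expectation.  A bin with zero ChIP signal is never positive
#' (`P(X >= 0) = 1`).
#'
#' @param chip ChIP counts, a [binned_vector()].
#' @param control Matched input counts sharing the ChIP genome, or `NULL`.
#' @param cfg A [binarize_config()].
#' @return A [binary_track()].
#' @export
poisson_binarize <- function(chip, control = NULL, cfg = binarize_config()) {
  stopifnot(inherits(chip, "BinnedVector"), inherits(cfg, "BinarizeConfig"))
  g <- chip$genome
  out <- binary_track(g)
  if (is.null(control)) {
    lam_flat <- max(cfg$lambda_floor, track_total(chip) / sum(g$n_bins))
    for (ch in g$chrom_names) {
      x <- chip$values[[ch]]
      out$calls[[ch]] <- x >= 1 &
        ppois(x - 1, lam_flat, lower.tail = FALSE) <= cfg$p_threshold
    }
    return(out)
  }
  stopifnot(inherits(control, "BinnedVector"))
  check_same_genome(g, control$genome, "chip and control")
  tot_ctrl <- track_total(control)
  if (tot_ctrl == 0) stop("degenerate control: total control signal is zero")
  s <- if (cfg$control_scaling == "depth") track_total(chip) / tot_ctrl else 1
  for (ch in g$chrom_names) {
    x <- chip$values[[ch]]
    ctl <- control$values[[ch]]
    if (cfg$control_smooth_bins > 0L)
      ctl <- running_mean(ctl, cfg$control_smooth_bins)
    lam <- pmax(cfg$lambda_floor, ctl * s)
    out$calls[[ch]] <- x >= 1 &
      ppois(x - 1, lam, lower.tail = FALSE) <= cfg$p_threshold
  }
  out
}

#' Merge replicate binary tracks
#'
#' @param tracks List of one or more [binary_track()]s on the same genome.
#' @param mode `"union"` (positive in any replicate; the default used ahead
#'   of broad-domain calling), `"intersection"` (positive in all), or
#'   `"majority"` (positive in more than half).
#' @return A [binary_track()].
#' @export
merge_replicates <- function(tracks,
                             mode = c("union", "intersection", "majority")) {
  mode <- match.arg(mode)
  if (!length(tracks)) stop("need at least one track to merge")
  stopifnot(all(vapply(tracks, inherits, TRUE, "BinaryTrack")))
  g <- tracks[[1L]]$genome
  for (t in tracks[-1L]) check_same_genome(g, t$genome, "replicates")
  k <- length(tracks)
  out <- binary_track(g)
  for (ch in g$chrom_names) {
    votes <- Reduce(`+`, lapply(tracks, function(t) as.integer(t$calls[[ch]])))
    out$calls[[ch]] <- switch(mode,
      union        = votes >= 1L,
      intersection = votes == k,
      majority     = votes > k / 2)
  }
  out
}

#' Positive-bin runs as 0-based half-open intervals
#'
#' Collapses each maximal run of consecutive positive bins into one
#' interval, the representation used when binarized tracks are exported as
#' BED or consumed as peak-like regions.
#'
#' @param track A [binary_track()].
#' @return data.frame with `chrom`, `start`, `end` (bp, 0-based half-open),
#'   `first_bin`, `last_bin` (0-based, inclusive).
#' @export
positive_runs <- function(track) {
  g <- track$genome
  b <- g$bin_size_bp
  res <- lapply(g$chrom_names, function(ch) {
    v <- track$calls[[ch]]
    if (!any(v)) return(NULL)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(chrom = ch,
               start = (starts[keep] - 1) * b,
               end   = pmin(ends[keep] * b, g$chrom_lengths_bp[[ch]]),
               first_bin = starts[keep] - 1L,
               last_bin  = ends[keep] - 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), first_bin = integer(),
                      last_bin = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
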