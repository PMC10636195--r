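#' Retain peaks supported by multiple replicates
#'
#' A peak is retained when peaks from at least `min_replicates` replicates
#' (counting its own) overlap it by at least 1 bp; the retained peaks are
#' then sorted and merged.  With the default `min_replicates = 2` this
#' keeps peaks called in more than one replicate.
#'
#' @param peak_sets List of `GRanges`, one per replicate (e.g. from
#'   [read_bed()]).
#' @param min_replicates Minimal number of supporting replicates.
#' @return A sorted, merged `GRanges` of reproducible peak regions.
#' @export
replicate_consistent_peaks <- function(peak_sets, min_replicates = 2L) {
  if (length(peak_sets) < min_replicates)
    stop("need at least ", min_replicates, " replicate peak sets")
  stopifnot(all(vapply(peak_sets, inherits, TRUE, "GRanges")))
  lv <- unique(unlist(lapply(peak_sets, GenomeInfoDb::seqlevels)))
  peak_sets <- lapply(peak_sets, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  kept <- lapply(seq_along(peak_sets), function(r) {
    pk <- peak_sets[[r]]
    if (!length(pk)) return(pk)
    support <- rep(1L, length(pk))  # own replicate
    for (s in seq_along(peak_sets)) {
      if (s == r) next
      support <- support +
        (GenomicRanges::countOverlaps(pk, peak_sets[[s]]) > 0L)
    }
    pk[support >= min_replicates]
  })
  merged <- GenomicRanges::reduce(sort(do.call(c, unname(kept))))
  merged
}

#' Bins positive for two marks in every replicate
#'
#' A bin is double-positive when it is called positive in every replicate
#' of mark A and every replicate of mark B — the intersection across all
#' tracks of both marks.
#'
#' @param markA_reps,markB_reps Non-empty lists of [binary_track()]s
#'   sharing one genome.
#' @return A [binary_track()] of double-positive bins.
#' @export
double_positive_bins <- function(markA_reps, markB_reps) {
  if (!length(markA_reps) || !length(markB_reps))
    stop("both marks need at least one replicate track")
  merge_replicates(c(markA_reps, markB_reps), mode = "intersection")
}

#' Classify promoters by mark co-occurrence
#'
#' Each (deduplicated) TSS is tested for a reproducible H3K4me2/3 peak and
#' for a double-positive bin within the half-open window
#' `[pos - window_bp, pos + window_bp)` (strand-ignored).  The summary
#' fraction is the share of K4-marked promoters that also carry the
#' phosphorylation mark — the quantity that measures how rarely the two
#' marks co-occur at promoters.
#'
#' @param tss An [anchor_set()] of transcription start sites.
#' @param dp A [double_positive_bins()] track.
#' @param k4_peaks Reproducible peaks, a `GRanges` (see
#'   [replicate_consistent_peaks()]).
#' @param window_bp Half-width of the promoter window (default 1000).
#' @param dedup Collapse duplicate `(chrom, pos, strand)` anchors (multiple
#'   isoforms of one promoter) before counting.  Default `TRUE`.
#' @return List of class `PromoterCallTable`: `table` (per-TSS data.frame
#'   with `chrom`, `pos`, `strand`, `has_k4_peak`, `has_double_positive`),
#'   `n_k4_tss`, `n_double_positive_tss` (K4-marked TSSs that also have a
#'   double-positive bin), and `fraction` = `n_double_positive_tss /
#'   n_k4_tss`.
#' @export
classify_promoters <- function(tss, dp, k4_peaks, window_bp = 1000L,
                               dedup = TRUE) {
  stopifnot(inherits(tss, "AnchorSet"), inherits(dp, "BinaryTrack"),
            inherits(k4_peaks, "GRanges"))
  g <- dp$genome
  df <- as.data.frame(tss)[, c("chrom", "pos", "strand")]
  if (dedup) df <- unique(df)
  n <- nrow(df)
  has_k4 <- logical(n)
  has_dp <- logical(n)
  if (n) {
    win_start0 <- pmax(df$pos - window_bp, 0)
    win_end0 <- pmin(df$pos + window_bp, g$chrom_lengths_bp[df$chrom])
    win <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(win_start0 + 1, win_end0))
    has_k4 <- GenomicRanges::countOverlaps(win, k4_peaks) > 0L
    b <- g$bin_size_bp
    b1 <- floor(win_start0 / b)
    b2 <- floor((win_end0 - 1) / b)
    for (i in seq_len(n)) {
      calls <- dp$calls[[df$chrom[i]]]
      lo <- b1[i] + 1L
      hi <- min(b2[i] + 1L, length(calls))
      has_dp[i] <- lo <= hi && any(calls[lo:hi])
    }
  }
  n_k4 <- sum(has_k4)
  if (n_k4 == 0)
    stop("no TSS with a reproducible H3K4me2/3 peak: fraction undefined")
  n_dp <- sum(has_k4 & has_dp)
  out <- list(
    table = data.frame(df, has_k4_peak = has_k4,
                       has_double_positive = has_dp,
                       stringsAsFactors = FALSE),
    n_k4_tss = n_k4,
    n_double_positive_tss = n_dp,
    fraction = n_dp / n_k4)
  class(out) <- "PromoterCallTable"
  out
}

#' @export
print.PromoterCallTable <- function(x, ...) {
  cat("PromoterCallTable:", nrow(x$table), "promoters;",
      x$n_k4_tss, "with H3K4me2/3;",
      x$n_double_positive_tss, "also with H3T3ph",
      sprintf("(%.2f%%)\n", 100 * x$fraction))
  invisible(x)
}
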