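#' Input-normalized ratio track
#'
#' Scales ChIP and control to counts-per-million and reports the
#' pseudocounted ratio per bin:
#' `(chip_i * 1e6 / total_chip + pc) / (control_i * 1e6 / total_control + pc)`.
#' With identical tracks (or flat tracks at different depths) every bin is
#' exactly 1, so the ratio isolates local enrichment from sequencing depth.
#'
#' @param chip,control [binned_vector()]s on one genome, both with positive
#'   total signal.
#' @param pseudocount Added to both depth-scaled values (default 1).
#' @return A [binned_vector()] with additional class `RatioTrack` and
#'   attribute `pseudocount`.
#' @export
input_normalize <- function(chip, control, pseudocount = 1.0) {
  stopifnot(inherits(chip, "BinnedVector"), inherits(control, "BinnedVector"))
  check_same_genome(chip$genome, control$genome, "chip and control")
  tc <- track_total(chip)
  tk <- track_total(control)
  if (tc <= 0 || tk <= 0)
    stop("degenerate input: both tracks need positive total signal")
  sc <- 1e6 / tc
  sk <- 1e6 / tk
  out <- binned_vector(chip$genome)
  for (ch in chip$genome$chrom_names)
    out$values[[ch]] <- (chip$values[[ch]] * sc + pseudocount) /
      (control$values[[ch]] * sk + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("RatioTrack", "BinnedVector")
  out
}

#' Reference-point signal matrix around anchors
#'
#' One row per anchor, one column per `profile_bin_bp` step across the
#' window `[pos - window_bp, pos + window_bp)`.  Each cell is the
#' length-weighted mean of the track over its base-pair span; rows of
#' minus-strand anchors are reversed so upstream is always on the left.
#' Cells whose span extends beyond the chromosome are masked (`NA`), not
#' zero-filled.
#'
#' @param track A [binned_vector()] or [input_normalize()] ratio track.
#' @param anchors An [anchor_set()] on the track's genome.
#' @param window_bp Half-width of the window (default 5000, i.e. a 10-kb
#'   region centered on each anchor).
#' @param profile_bin_bp Column width in bp (default 50); `2 * window_bp`
#'   must be divisible by it.
#' @return List of class `SignalMatrix`: `matrix` (anchors x columns, `NA`
#'   = masked), `anchors`, `window_bp`, `profile_bin_bp`.
#' @export
compute_matrix <- function(track, anchors, window_bp = 5000L,
                           profile_bin_bp = 50L) {
  stopifnot(inherits(track, "BinnedVector"), inherits(anchors, "AnchorSet"))
  window_bp <- as.integer(window_bp)
  profile_bin_bp <- as.integer(profile_bin_bp)
  if ((2L * window_bp) %% profile_bin_bp != 0L)
    stop("2 * window_bp must be divisible by profile_bin_bp")
  g <- track$genome
  ncol <- 2L * window_bp %/% profile_bin_bp
  nr <- nrow(anchors)
  mat <- matrix(NA_real_, nrow = nr, ncol = ncol)
  if (nr) {
    unknown <- setdiff(unique(anchors$chrom), g$chrom_names)
    if (length(unknown)) stop("anchor on unknown chromosome: ", unknown[1L])
    B <- g$bin_size_bp
    pb <- profile_bin_bp
    offs <- (seq_len(ncol) - 1L) * pb
    for (ch in unique(anchors$chrom)) {
      rows <- which(anchors$chrom == ch)
      v <- track$values[[ch]]
      L <- g$chrom_lengths_bp[[ch]]
      # cell start coordinates, rows x cols
      S <- outer(anchors$pos[rows] - window_bp, offs, `+`)
      valid <- S >= 0 & (S + pb) <= L
      b1 <- S %/% B
      b2 <- (S + pb - 1L) %/% B
      acc <- matrix(0, nrow = length(rows), ncol = ncol)
      max_span <- max(b2[valid] - b1[valid], 0L) + 1L
      for (k in seq_len(max_span) - 1L) {
        bk <- b1 + k
        use <- valid & bk <= b2
        ov <- pmin((bk + 1) * B, S + pb) - pmax(bk * B, S)
        idx <- bk + 1L
        idx[!use] <- 1L  # placeholder, zero-weighted below
        acc <- acc + ifelse(use, ov * v[idx], 0)
      }
      cell <- acc / pb
      cell[!valid] <- NA_real_
      mat[rows, ] <- cell
    }
    flip <- which(anchors$strand == "-")
    if (length(flip)) mat[flip, ] <- mat[flip, ncol:1, drop = FALSE]
  }
  structure(list(matrix = mat, anchors = anchors, window_bp = window_bp,
                 profile_bin_bp = profile_bin_bp),
            class = "SignalMatrix")
}

#' Metagene profile of a signal matrix
#'
#' Column means over unmasked cells, with the per-column number of
#' contributing anchors, plus a heatmap row order (descending row mean).
#' A fully masked column is reported as `NA`, never as zero.
#'
#' @param mat A [compute_matrix()] result.
#' @return List of class `MetageneProfile`: `profile` (column means),
#'   `n` (unmasked cells per column), `positions_bp` (column-center offsets
#'   from the anchor), `row_order`.
#' @export
metagene <- function(mat) {
  stopifnot(inherits(mat, "SignalMatrix"))
  m <- mat$matrix
  n <- colSums(!is.na(m))
  prof <- ifelse(n > 0, colMeans(m, na.rm = TRUE), NA_real_)
  pos <- -mat$window_bp + (seq_len(ncol(m)) - 0.5) * mat$profile_bin_bp
  rm_ <- rowMeans(m, na.rm = TRUE)
  structure(list(profile = as.numeric(prof), n = as.integer(n),
                 positions_bp = pos,
                 row_order = order(rm_, decreasing = TRUE)),
            class = "MetageneProfile")
}

#' Genome-binned Pearson correlation between tracks
#'
#' Each track is aggregated to `summary_bin_bp` bins by averaging its grid
#' bins, then all pairwise Pearson correlations are computed over the
#' concatenated summary bins.  A zero-variance track yields `NA` against
#' its partners; the diagonal is 1 by definition.
#'
#' @param tracks Named (or unnamed) list of two or more [binned_vector()]s
#'   on one genome.
#' @param summary_bin_bp Aggregation bin size in bp (default 10000).
#' @return Symmetric correlation matrix.
#' @export
pairwise_pearson <- function(tracks, summary_bin_bp = 10000L) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  stopifnot(all(vapply(tracks, inherits, TRUE, "BinnedVector")))
  g <- tracks[[1L]]$genome
  for (t in tracks[-1L]) check_same_genome(g, t$genome)
  fold <- max(1L, summary_bin_bp %/% g$bin_size_bp)
  agg <- vapply(tracks, function(t) {
    unlist(lapply(g$chrom_names, function(ch) {
      v <- t$values[[ch]]
      grp <- (seq_along(v) - 1L) %/% fold
      as.numeric(tapply(v, grp, mean))
    }), use.names = FALSE)
  }, numeric(sum(ceiling(g$n_bins / fold))))
  cm <- suppressWarnings(cor(agg))
  diag(cm) <- 1
  nm <- names(tracks)
  if (!is.null(nm)) dimnames(cm) <- list(nm, nm)
  cm
}

#' Write a signal matrix as TSV
#' @param mat A [compute_matrix()] result.
#' @param path Output path (plain TSV; one row per anchor).
#' @export
write_matrix_tsv <- function(mat, path) {
  a <- mat$anchors
  df <- data.frame(chrom = a$chrom, pos = a$pos, strand = a$strand,
                   mat$matrix, check.names = FALSE)
  colnames(df)[-(1:3)] <- paste0("bp_",
    -mat$window_bp + (seq_len(ncol(mat$matrix)) - 1L) * mat$profile_bin_bp)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
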