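#' Per-chromosome binned signal
#'
#' A `BinnedVector` holds one numeric value per grid bin of a
#' [genome_build()], typically fragment counts for one sequencing track
#' (ChIP replicate or input) or a derived ratio.
#'
#' @param genome A [genome_build()] object.
#' @param values Named list of numeric vectors, one per chromosome, each of
#'   length `n_bins(genome)[chrom]`.  Missing chromosomes are zero-filled.
#' @return An object of class `BinnedVector` with elements `genome` and
#'   `values`.
#' @export
binned_vector <- function(genome, values = NULL) {
  stopifnot(inherits(genome, "GenomeBuild"))
  nb <- genome$n_bins
  if (is.null(values)) {
    values <- lapply(nb, function(n) numeric(n))
  } else {
    full <- lapply(genome$chrom_names, function(ch) {
      v <- values[[ch]]
      if (is.null(v)) return(numeric(nb[[ch]]))
      if (length(v) != nb[[ch]])
        stop("values for ", ch, " have length ", length(v),
             " but the grid has ", nb[[ch]], " bins")
      as.numeric(v)
    })
    values <- setNames(full, genome$chrom_names)
  }
  structure(list(genome = genome, values = values), class = "BinnedVector")
}

#' @export
print.BinnedVector <- function(x, ...) {
  cat("BinnedVector:", length(x$values), "chromosome(s), total signal",
      format(track_total(x), big.mark = ","), "\n")
  invisible(x)
}

#' Total signal in a binned track
#' @param track A [binned_vector()].
#' @export
track_total <- function(track) sum(vapply(track$values, sum, 0))

#' Assign fragments to grid bins
#'
#' Each fragment increments exactly one bin: in `"midpoint"` mode (the
#' default, emulating fragment-center placement) the bin containing
#' `floor((start + end) / 2)` of the 0-based half-open fragment, in
#' `"start"` mode the bin containing the fragment start.  Fragments on
#' chromosomes absent from the build are skipped and tallied in the
#' `n_skipped` attribute of the result.
#'
#' @param fragments A `GRanges` (as returned by [read_bed()]) or a
#'   data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @param genome A [genome_build()].
#' @param assignment `"midpoint"` or `"start"`.
#' @return A [binned_vector()] of counts; attribute `n_skipped` counts
#'   fragments on unknown chromosomes.
#' @export
bin_fragments <- function(fragments, genome,
                          assignment = c("midpoint", "start")) {
  assignment <- match.arg(assignment)
  if (inherits(fragments, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(fragments)),
      start = GenomicRanges::start(fragments) - 1L,
      end   = GenomicRanges::end(fragments),
      stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(fragments)
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop("fragments need chrom/start/end columns")
  }
  if (nrow(df) && any(df$end <= df$start))
    stop("malformed fragment: end must exceed start")
  known <- df$chrom %in% genome$chrom_names
  n_skipped <- sum(!known)
  if (n_skipped)
    message(n_skipped, " fragment(s) on unknown chromosomes skipped")
  df <- df[known, , drop = FALSE]
  pos <- if (assignment == "midpoint")
    floor((df$start + df$end) / 2) else df$start
  bin <- floor(pos / genome$bin_size_bp)
  out <- binned_vector(genome)
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    b <- bin[sel]
    b <- pmin(b, genome$n_bins[[ch]] - 1L)  # midpoint of a boundary-straddling fragment
    tab <- tabulate(b + 1L, nbins = genome$n_bins[[ch]])
    out$values[[ch]] <- out$values[[ch]] + tab
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a BED file as GRanges
#'
#' Thin wrapper over [rtracklayer::import.bed()]; coordinates come back
#' 1-based closed per `GRanges` convention.
#'
#' @param path BED3/BED6 file.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write GRanges (or a 0-based interval data.frame) as BED
#' @param intervals A `GRanges` or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) and optional `strand`, `name`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  if (!inherits(intervals, "GRanges")) {
    df <- as.data.frame(intervals)
    intervals <- GenomicRanges::GRanges(
      df$chrom,
      IRanges::IRanges(df$start + 1L, df$end),
      strand = if ("strand" %in% names(df)) df$strand else "*")
    if ("name" %in% names(df)) intervals$name <- df$name
  }
  rtracklayer::export(intervals, path, format = "BED")
  invisible(path)
}

#' Read a bedGraph file onto the bin grid
#'
#' Grid-aligned intervals map losslessly onto bins.  Intervals that cross
#' bin boundaries are length-weighted into the bins they overlap (a message
#' notes this); base pairs not covered by any interval count as zero, so a
#' bin's value is `sum(value * covered_bp) / bin_width`.  Overlapping
#' intervals are a format error.
#'
#' @param path Four-column bedGraph file.
#' @param genome A [genome_build()].
#' @return A [binned_vector()].
#' @export
read_bedgraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- binned_vector(genome)
  if (!length(gr)) return(out)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% genome$chrom_names]
  if (!length(gr)) return(out)
  if (!IRanges::isDisjoint(gr))
    stop("overlapping bedGraph intervals in ", path)
  b <- genome$bin_size_bp
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  if (any(s0 %% b != 0 | e0 %% b != 0))
    message("bedGraph intervals not aligned to the ", b,
            " bp grid; length-weighted averaging applied")
  chs <- as.character(GenomicRanges::seqnames(gr))
  sc <- as.numeric(gr$score)
  for (ch in unique(chs)) {
    sel <- chs == ch
    L <- genome$chrom_lengths_bp[[ch]]
    nb <- genome$n_bins[[ch]]
    acc <- numeric(nb)
    st <- pmax(s0[sel], 0); en <- pmin(e0[sel], L); v <- sc[sel]
    for (i in seq_along(st)) {
      if (en[i] <= st[i]) next
      b1 <- st[i] %/% b; b2 <- (en[i] - 1) %/% b
      bins <- b1:b2
      ov <- pmin((bins + 1) * b, en[i]) - pmax(bins * b, st[i])
      acc[bins + 1L] <- acc[bins + 1L] + v[i] * ov
    }
    width <- pmin((seq_len(nb)) * b, L) - (seq_len(nb) - 1) * b
    out$values[[ch]] <- acc / width
  }
  out
}

#' Write a binned track as bedGraph
#'
#' Adjacent equal-valued bins are run-length merged; zero-valued runs are
#' omitted (absence of coverage reads back as zero).
#'
#' @param track A [binned_vector()].
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  g <- track$genome
  b <- g$bin_size_bp
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in g$chrom_names) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    start_bp <- starts_bin[keep] * b
    end_bp <- pmin(ends_bin[keep] * b, g$chrom_lengths_bp[[ch]])
    lines <- paste(ch, format_bp(start_bp), format_bp(end_bp),
                   format(r$values[keep], scientific = FALSE, trim = TRUE,
                          digits = 15),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
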