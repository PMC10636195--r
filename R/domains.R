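#' Largest contiguous block of positive bins on a chromosome
#'
#' The seed of the broad-domain construction: the maximal run of
#' consecutive positive bins, which on mitotic H3T3ph data corresponds to
#' the centromere.  Ties in length are broken per `tie_break` (default
#' leftmost, for determinism).
#'
#' @param track A [binary_track()].
#' @param chrom Chromosome name.
#' @param tie_break `"leftmost"` or `"rightmost"`.
#' @return Integer vector `c(first_bin, last_bin)` (0-based, inclusive), or
#'   `NULL` when the chromosome has no positive bin.
#' @export
largest_block <- function(track, chrom, tie_break = c("leftmost", "rightmost")) {
  tie_break <- match.arg(tie_break)
  calls <- track_calls(track, chrom)
  blk <- .largest_block_run(calls, tie_break)
  if (is.null(blk)) return(NULL)
  blk - 1L  # to 0-based
}

# 1-based [first, last] of the longest TRUE run, or NULL
.largest_block_run <- function(calls, tie_break = "leftmost") {
  if (!any(calls)) return(NULL)
  r <- rle(as.logical(calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos_runs <- which(r$values)
  lens <- r$lengths[pos_runs]
  best <- if (tie_break == "leftmost")
    pos_runs[which.max(lens)]
  else
    pos_runs[max(which(lens == max(lens)))]
  c(starts[best], ends[best])
}

#' Extend a block of positive bins across sub-threshold gaps
#'
#' Scans outward from both ends of the seed block.  Moving right, a counter
#' of consecutive negative bins resets to zero at every positive bin, which
#' becomes the new domain end; the scan stops when the counter reaches
#' `gap_limit_bins` or the chromosome end.  The leftward scan is symmetric.
#' Consequently a gap of `gap_limit_bins - 1` or fewer negative bins is
#' bridged, a gap of `gap_limit_bins` or more terminates the extension, and
#' both returned endpoints are positive bins (the terminating gap is never
#' part of the domain).
#'
#' @inheritParams largest_block
#' @param block Seed `c(first_bin, last_bin)` (0-based), a run of positive
#'   bins as returned by [largest_block()].
#' @param gap_limit_bins Number of consecutive signal-free bins that stops
#'   the extension (default 3000, i.e. 600 kb at 200-bp bins).
#' @return Integer vector `c(first_bin, last_bin)` (0-based, inclusive).
#' @export
extend_block <- function(track, chrom, block, gap_limit_bins = 3000L) {
  calls <- track_calls(track, chrom)
  block1 <- as.integer(block) + 1L
  if (block1[1L] < 1L || block1[2L] > length(calls) ||
      !all(calls[block1[1L]:block1[2L]]))
    stop("seed block must be a run of positive bins on ", chrom)
  .extend_run(calls, block1, as.integer(gap_limit_bins)) - 1L
}

# core scan on 1-based coordinates; block = c(first, last) of positive run
.extend_run <- function(calls, block, gap_limit) {
  pos <- which(calls)
  gaps <- diff(pos) - 1L               # negatives between pos[k] and pos[k+1]
  blocked <- which(gaps >= gap_limit)  # uncrossable gap after pos[k]
  i0 <- match(block[1L], pos)
  i1 <- match(block[2L], pos)
  rb <- blocked[blocked >= i1]
  j_hi <- if (length(rb)) rb[1L] else length(pos)
  lb <- blocked[blocked < i0]
  j_lo <- if (length(lb)) lb[length(lb)] + 1L else 1L
  c(pos[j_lo], pos[j_hi])
}

track_calls <- function(track, chrom) {
  stopifnot(inherits(track, "BinaryTrack"))
  if (!chrom %in% track$genome$chrom_names)
    stop("unknown chromosome: ", chrom)
  track$calls[[chrom]]
}

#' Domain-calling settings
#'
#' @param gap_limit_bins Consecutive signal-free bins terminating the
#'   outward extension (default 3000 bins = 600 kb at the 200-bp grid).
#' @param tie_break Tie rule for equal largest blocks.
#' @export
domain_call_config <- function(gap_limit_bins = 3000L,
                               tie_break = c("leftmost", "rightmost")) {
  gap_limit_bins <- as.integer(gap_limit_bins)
  if (is.na(gap_limit_bins) || gap_limit_bins < 1L)
    stop("gap_limit_bins must be >= 1")
  structure(list(gap_limit_bins = gap_limit_bins,
                 tie_break = match.arg(tie_break)),
            class = "DomainCallConfig")
}

#' Call one broad centromere-proximal domain per chromosome
#'
#' For every chromosome with at least one positive bin, the largest
#' contiguous block of positive bins is found ([largest_block()]) and
#' extended outward across gaps shorter than `gap_limit_bins`
#' ([extend_block()]).  The coverage fraction reports how many of the
#' genome-wide positive bins fall inside the called domains — the statistic
#' that quantifies how centromere-concentrated the mark is.
#'
#' @param track A merged [binary_track()].
#' @param cfg A [domain_call_config()].
#' @return An object of class `DomainSet`: list with
#'   * `domains`: data.frame (`chrom`, `first_bin`, `last_bin`, `start_bp`,
#'     `end_bp`, `n_bins`, `n_positive`), one row per chromosome with signal;
#'   * `seed_blocks`: data.frame of the seeding largest blocks;
#'   * `coverage_fraction`: positive bins inside domains / positive bins
#'     genome-wide.
#' @export
call_domains <- function(track, cfg = domain_call_config()) {
  stopifnot(inherits(track, "BinaryTrack"), inherits(cfg, "DomainCallConfig"))
  g <- track$genome
  b <- g$bin_size_bp
  total_pos <- n_positive(track)
  if (total_pos == 0)
    stop("no positive bins genome-wide: coverage fraction undefined")
  dom_rows <- list(); seed_rows <- list()
  covered <- 0
  for (ch in g$chrom_names) {
    calls <- track$calls[[ch]]
    blk <- .largest_block_run(calls, cfg$tie_break)
    if (is.null(blk)) next
    dom <- .extend_run(calls, blk, cfg$gap_limit_bins)
    npos <- sum(calls[dom[1L]:dom[2L]])
    covered <- covered + npos
    dom_rows[[ch]] <- data.frame(
      chrom = ch,
      first_bin = dom[1L] - 1L, last_bin = dom[2L] - 1L,
      start_bp = (dom[1L] - 1) * b,
      end_bp = min(dom[2L] * b, g$chrom_lengths_bp[[ch]]),
      n_bins = dom[2L] - dom[1L] + 1L,
      n_positive = npos,
      stringsAsFactors = FALSE)
    seed_rows[[ch]] <- data.frame(
      chrom = ch,
      first_bin = blk[1L] - 1L, last_bin = blk[2L] - 1L,
      stringsAsFactors = FALSE)
  }
  out <- list(
    domains = df_rbind(dom_rows,
                       c("chrom", "first_bin", "last_bin", "start_bp",
                         "end_bp", "n_bins", "n_positive")),
    seed_blocks = df_rbind(seed_rows, c("chrom", "first_bin", "last_bin")),
    coverage_fraction = covered / total_pos)
  class(out) <- "DomainSet"
  out
}

df_rbind <- function(rows, cols) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$chrom <- character(0)
    return(out[, cols])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.DomainSet <- function(x, ...) {
  cat("DomainSet:", nrow(x$domains), "domain(s);",
      sprintf("%.1f%% of positive bins covered\n",
              100 * x$coverage_fraction))
  if (nrow(x$domains)) print(x$domains, ...)
  invisible(x)
}

#' Export called domains as BED6
#' @param domains A [call_domains()] result.
#' @param path Output path.
#' @export
write_domains_bed <- function(domains, path) {
  d <- domains$domains
  df <- data.frame(chrom = d$chrom, start = d$start_bp, end = d$end_bp,
                   name = paste0(d$chrom, "_centromere_proximal"),
                   score = round(1000 * d$n_positive /
                                   sum(d$n_positive)),
                   strand = ".")
  write.table(data.frame(df$chrom, format_bp(df$start), format_bp(df$end),
                         df$name, df$score, df$strand),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Partition anchors into centromere-proximal vs arm
#'
#' An anchor is centromere-proximal when its position falls inside its
#' chromosome's domain base-pair interval (half-open `[start_bp, end_bp)`);
#' anchors on domain-free chromosomes are arm anchors.
#'
#' @param anchors An [anchor_set()].
#' @param domains A [call_domains()] result.
#' @return Factor with levels `centromere_proximal`, `arm`, one per anchor.
#' @export
classify_anchors_by_domain <- function(anchors, domains) {
  d <- domains$domains
  lab <- rep("arm", nrow(anchors))
  if (nrow(d)) {
    m <- match(anchors$chrom, d$chrom)
    hit <- !is.na(m) &
      anchors$pos >= d$start_bp[m] & anchors$pos < d$end_bp[m]
    lab[hit] <- "centromere_proximal"
  }
  factor(lab, levels = c("centromere_proximal", "arm"))
}

#' Brute-force reference for the domain construction
#'
#' Independent validation oracle: enumerates every binary call vector of a
#' given length and, for each, every candidate interval with positive
#' endpoints that contains the (leftmost) largest block and whose internal
#' gaps between consecutive positive bins are all shorter than
#' `gap_limit_bins`, returning the widest.  Implemented in C++ so the
#' exhaustive comparison against the scanning algorithm is tractable; used
#' only in validation, never in the calling path.
#'
#' @param length_bins Vector length (1..25).
#' @param gap_limit_bins Gap limit.
#' @return Integer matrix with `2^length_bins` rows and columns
#'   `first_bin`, `last_bin` (0-based; -1/-1 for vectors with no positive
#'   bin), row `k` corresponding to the vector whose bin `i` is positive
#'   iff bit `i` of `k - 1` is set.
#' @export
domain_oracle_all <- function(length_bins, gap_limit_bins) {
  stopifnot(length_bins >= 1L, length_bins <= 25L, gap_limit_bins >= 1L)
  out <- cpp_domain_oracle_enumerate(as.integer(length_bins),
                                     as.integer(gap_limit_bins))
  colnames(out) <- c("first_bin", "last_bin")
  out
}

#' Scanning domain construction over all binary vectors of one length
#'
#' Runs the production scan kernel (the same code path as
#' [call_domains()]) on every binary vector of `length_bins` bins, in the
#' same case order as [domain_oracle_all()].  Exists so the exhaustive
#' oracle comparison can drive the real implementation at full scale.
#'
#' @inheritParams domain_oracle_all
#' @export
domain_scan_all <- function(length_bins, gap_limit_bins) {
  stopifnot(length_bins >= 1L, length_bins <= 25L)
  n <- bitwShiftL(1L, length_bins)
  out <- matrix(-1L, nrow = n, ncol = 2L,
                dimnames = list(NULL, c("first_bin", "last_bin")))
  chunk <- 65536L
  for (lo in seq.int(0L, n - 1L, by = chunk)) {
    hi <- min(lo + chunk - 1L, n - 1L)
    bits <- matrix(as.logical(intToBits(lo:hi)), nrow = 32L)
    for (k in lo:hi) {
      calls <- bits[seq_len(length_bins), k - lo + 1L]
      blk <- .largest_block_run(calls, "leftmost")
      if (is.null(blk)) next
      out[k + 1L, ] <- .extend_run(calls, blk, gap_limit_bins) - 1L
    }
  }
  out
}
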