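#' Genome build: ordered chromosomes plus a global binning grid
#'
#' A `GenomeBuild` fixes the chromosome names and lengths of an assembly and
#' lays a left-to-right grid of fixed-width bins over every chromosome,
#' starting at coordinate 0.  Bin `i` (0-based) covers the half-open
#' base-pair interval `[i * bin_size, min((i + 1) * bin_size, length))`, so
#' the final bin may be partial and a chromosome shorter than one bin still
#' owns exactly one bin.  All binned tracks in the package
#' ([BinnedVector][binned_vector], [BinaryTrack][binary_track]) refer back
#' to a `GenomeBuild` and share its layout.
#'
#' @param chrom_names Character vector of unique chromosome identifiers, in
#'   display order.
#' @param chrom_lengths_bp Positive integer lengths, one per chromosome.
#' @param bin_size_bp Width of the binning grid in base pairs (default 200,
#'   the resolution used for signal binarization).
#'
#' @return An object of class `GenomeBuild`: a list with elements
#'   `chrom_names`, `chrom_lengths_bp` (named), `bin_size_bp` and `n_bins`
#'   (named per-chromosome bin counts, `ceiling(length / bin_size)`).
#'
#' @examples
#' gb <- genome_build(c("chr1", "chr2"), c(1001, 100), bin_size_bp = 200)
#' n_bins(gb)   # chr1 has 6 bins (last is 1 bp), chr2 has 1
#' @export
genome_build <- function(chrom_names, chrom_lengths_bp, bin_size_bp = 200L) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths_bp <- as.numeric(chrom_lengths_bp)
  if (length(chrom_names) != length(chrom_lengths_bp))
    stop("chrom_names and chrom_lengths_bp must have equal length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome name: ",
         chrom_names[duplicated(chrom_names)][1L])
  if (any(is.na(chrom_lengths_bp)) || any(chrom_lengths_bp <= 0))
    stop("chromosome lengths must be positive")
  bin_size_bp <- as.integer(bin_size_bp)
  if (is.na(bin_size_bp) || bin_size_bp < 1L)
    stop("bin_size_bp must be a positive integer")
  gb <- list(
    chrom_names      = chrom_names,
    chrom_lengths_bp = setNames(chrom_lengths_bp, chrom_names),
    bin_size_bp      = bin_size_bp,
    n_bins           = setNames(as.integer(ceiling(chrom_lengths_bp / bin_size_bp)),
                                chrom_names)
  )
  class(gb) <- "GenomeBuild"
  gb
}

#' Read a chrom.sizes table into a GenomeBuild
#'
#' Parses the standard two-column TSV (`name<TAB>length`) used by the UCSC
#' tool chain and attaches the binning grid.
#'
#' @param path Path to a two-column chromosome-sizes file.
#' @inheritParams genome_build
#' @return A [genome_build()] object.
#' @export
read_chrom_sizes <- function(path, bin_size_bp = 200L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty chrom.sizes file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2L || is.na(suppressWarnings(as.numeric(f[2L]))))
      stop("malformed chrom.sizes line ", i, ": ", lines[i])
    if (as.numeric(f[2L]) <= 0)
      stop("non-positive chromosome length on line ", i, ": ", lines[i])
  }
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    i <- which(duplicated(nm))[1L]
    stop("duplicate chromosome on line ", i, ": ", lines[i])
  }
  genome_build(nm, vapply(fields, function(f) as.numeric(f[2L]), 0),
               bin_size_bp)
}

#' @export
print.GenomeBuild <- function(x, ...) {
  cat("GenomeBuild:", length(x$chrom_names), "chromosome(s),",
      "bin size", x$bin_size_bp, "bp,",
      format(sum(x$n_bins), big.mark = ","), "bins\n")
  invisible(x)
}

#' Per-chromosome bin counts
#' @param genome A [genome_build()] object.
#' @return Named integer vector of bin counts.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "GenomeBuild"))
  genome$n_bins
}

#' Bin index of a base-pair coordinate
#'
#' @param pos_bp 0-based base-pair coordinate(s).
#' @param genome A [genome_build()] object.
#' @return 0-based bin indices, `floor(pos / bin_size)`.
#' @export
bin_index <- function(pos_bp, genome) {
  as.integer(floor(pos_bp / genome$bin_size_bp))
}

same_genome <- function(a, b) {
  identical(a$chrom_names, b$chrom_names) &&
    identical(unname(a$chrom_lengths_bp), unname(b$chrom_lengths_bp)) &&
    identical(a$bin_size_bp, b$bin_size_bp)
}

check_same_genome <- function(a, b, what = "tracks") {
  if (!same_genome(a, b))
    stop("incompatible GenomeBuilds: ", what,
         " must share chromosome names, lengths and bin size")
  invisible(TRUE)
}

#' Stranded anchor points (TSSs or peak centers)
#'
#' An `AnchorSet` is the set of reference points that metagene windows and
#' promoter classifications are centered on.  Positions are 0-based base
#' pairs; strand `"."` is treated as `"+"`.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos_bp 0-based positions within chromosome bounds.
#' @param strand Strand per anchor, one of `"+"`, `"-"`, `"."`.
#' @param genome Optional [genome_build()] used to bounds-check positions.
#' @param label Free-text label for the set.
#' @return A data.frame of class `AnchorSet` with columns `chrom`, `pos`,
#'   `strand`.
#' @export
anchor_set <- function(chrom, pos_bp, strand = ".", genome = NULL,
                       label = "anchors") {
  n <- length(chrom)
  strand <- rep_len(as.character(strand), n)
  strand[strand == "."] <- "+"
  if (!all(strand %in% c("+", "-")))
    stop("strand must be one of '+', '-', '.'")
  pos_bp <- as.numeric(pos_bp)
  if (n && (any(is.na(pos_bp)) || any(pos_bp < 0)))
    stop("anchor positions must be non-negative")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(chrom), genome$chrom_names)
    if (length(unknown))
      stop("anchor on unknown chromosome: ", unknown[1L])
    if (n && any(pos_bp >= genome$chrom_lengths_bp[chrom]))
      stop("anchor position beyond chromosome end")
  }
  out <- data.frame(chrom = as.character(chrom), pos = pos_bp,
                    strand = strand, stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("AnchorSet", "data.frame")
  out
}

#' Read anchors from a BED6 file
#'
#' For `+`/`.` features the anchor is the BED start; for `-` features it is
#' `end - 1` (the 5' end), following the usual TSS convention.
#'
#' @param path BED file; a strand column is used when present.
#' @inheritParams anchor_set
#' @export
read_anchors_bed <- function(path, genome = NULL, label = basename(path)) {
  gr <- read_bed(path)
  if (!length(gr)) return(anchor_set(character(), numeric(), label = label))
  str <- as.character(GenomicRanges::strand(gr))
  str[str == "*"] <- "+"
  pos <- ifelse(str == "-",
                GenomicRanges::end(gr) - 1L,   # 1-based end == 0-based end-1
                GenomicRanges::start(gr) - 1L) # 1-based start -> 0-based
  anchor_set(as.character(GenomicRanges::seqnames(gr)), pos, str,
             genome = genome, label = label)
}

#' Write anchors as 1-bp BED6 features
#' @param anchors An [anchor_set()].
#' @param path Output path.
#' @export
write_anchors_bed <- function(anchors, path) {
  df <- data.frame(chrom = anchors$chrom,
                   start = format_bp(anchors$pos),
                   end   = format_bp(anchors$pos + 1),
                   name  = paste0("anchor_", seq_len(nrow(anchors))),
                   score = 0L,
                   strand = anchors$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
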