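#' Validate and normalise a genome object
#'
#' A genome is represented as a named character vector of nucleotide
#' sequences.  Case is preserved: lowercase letters mark soft-masked
#' (repeat) bases, which downstream reporting uses as a repetitive-content
#' proxy.  Accepts a named character vector or any Biostrings `XStringSet`.
#'
#' @param x Named character vector of sequences, or an `XStringSet`.
#' @return A named character vector, validated (unique names, length >= 1,
#'   IUPAC alphabet only).
#' @examples
#' g <- as_genome(c(chr1 = "ACGTACGT"))
#' @export
as_genome <- function(x) {
  if (methods::is(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x)) {
    stop("a genome must be a named character vector of sequences")
  }
  if (length(x) == 0L) {
    stop("empty genome")
  }
  nm <- names(x)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every sequence must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate sequence names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (any(nchar(x) < 1L)) {
    stop("zero-length sequence: ", paste(nm[nchar(x) < 1L], collapse = ", "))
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(x))
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(nm[bad], collapse = ", "))
  }
  x
}

#' Sequence lengths of a genome
#'
#' @param genome A genome (see [as_genome()]).
#' @return Named integer vector of sequence lengths in bp.
#' @export
genome_lengths <- function(genome) {
  genome <- as_genome(genome)
  stats::setNames(nchar(genome), names(genome))
}

#' Read a genome from FASTA
#'
#' Wraps `Biostrings::readBStringSet()` so that soft-masking case is
#' preserved.  Gzipped input is handled transparently.  Sequence names are
#' truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (optionally `.gz`).
#' @return A named character vector (see [as_genome()]).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  as_genome(ss)
}

#' Write a genome to FASTA
#'
#' @param genome A genome (see [as_genome()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::BStringSet(genome), path,
                              compress = grepl("\\.gz$", path),
                              width = width)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED is 0-based half-open on disk; the returned `GRanges` follows the
#' usual R convention (1-based, closed).  Intervals are returned sorted;
#' overlapping intervals are preserved (no merging).
#'
#' @param path Path to a BED file.
#' @param genome Optional genome (or named vector of sequence lengths)
#'   used to validate interval bounds.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(GenomicRanges::width(gr) < 1L)) {
    stop("BED interval with start >= end in ", path)
  }
  gr <- GenomicRanges::sort(gr)
  if (!is.null(genome)) {
    len <- if (is.numeric(genome)) genome else genome_lengths(genome)
    if (is.null(names(len))) stop("sequence lengths must be named")
    chr <- as.character(GenomicRanges::seqnames(gr))
    if (!all(chr %in% names(len))) {
      stop("BED sequence names absent from genome: ",
           paste(setdiff(chr, names(len)), collapse = ", "))
    }
    if (any(GenomicRanges::end(gr) > len[chr])) {
      stop("BED interval beyond sequence end")
    }
    GenomeInfoDb::seqlengths(gr) <- len[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Write genomic intervals to BED
#'
#' @param gr A `GRanges` (or a target selection from [select_fragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  if (inherits(gr, "target_selection")) gr <- gr$regions
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
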