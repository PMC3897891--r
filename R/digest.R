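#' Define a blunt-end restriction enzyme
#'
#' Only palindromic blunt-end cutters are modelled: the cut position is the
#' same on both strands, so a single forward-strand scan enumerates all cut
#' sites.  Recognition sites with IUPAC ambiguity codes are rejected.
#'
#' @param name Enzyme name, e.g. `"HaeIII"`.
#' @param site Recognition site (4-6 bp, A/C/G/T only, palindromic).
#' @param cut_offset Integer in `[0, nchar(site)]`: the cut falls after this
#'   many bases of the site on the forward strand (HaeIII `GG^CC` has
#'   offset 2).
#' @return An object of class `restriction_enzyme`.
#' @examples
#' haeIII <- restriction_enzyme("HaeIII", "GGCC", 2)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) {
    stop("unsupported enzyme '", name,
         "': recognition sites with ambiguity codes are not supported")
  }
  m <- nchar(site)
  if (m < 4L || m > 6L) {
    stop("recognition site must be 4-6 bp, got ", m, " bp")
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(site, "")[[1]]), collapse = ""))
  if (rc != site) {
    stop("recognition site '", site, "' is not palindromic; ",
         "only blunt-end palindromic cutters are supported")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > m) {
    stop("cut_offset must lie in [0, ", m, "]")
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cut <- paste0(substr(x$site, 1, x$cut_offset), "^",
                substr(x$site, x$cut_offset + 1, nchar(x$site)))
  cat("<restriction_enzyme> ", x$name, " (", cut, ")\n", sep = "")
  invisible(x)
}

#' Catalogue of common blunt-end cutters
#'
#' A small built-in table of commercially available Type II blunt-end
#' enzymes with 4-6 bp palindromic recognition sites.
#'
#' @return A data.frame with columns `name`, `site`, `cut_offset`.
#' @seealso [get_enzyme()]
#' @export
enzyme_catalogue <- function() {
  data.frame(
    name = c("HaeIII", "AluI", "RsaI", "DraI", "EcoRV", "SspI",
             "ScaI", "HpaI", "StuI", "PvuII", "SmaI", "NruI"),
    site = c("GGCC", "AGCT", "GTAC", "TTTAAA", "GATATC", "AATATT",
             "AGTACT", "GTTAAC", "AGGCCT", "CAGCTG", "CCCGGG", "TCGCGA"),
    cut_offset = c(2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Look up an enzyme from the built-in catalogue
#'
#' @param name Enzyme name as listed by [enzyme_catalogue()].
#' @return A `restriction_enzyme`.
#' @export
get_enzyme <- function(name) {
  cat_ <- enzyme_catalogue()
  i <- match(name, cat_$name)
  if (is.na(i)) {
    stop("unknown enzyme '", name, "'; see enzyme_catalogue()")
  }
  restriction_enzyme(cat_$name[i], cat_$site[i], cat_$cut_offset[i])
}

#' In-silico digestion of a genome
#'
#' Finds every forward-strand occurrence of the recognition site
#' (case-insensitively; overlapping occurrences all cut) and splits each
#' sequence at `occurrence start + cut_offset`.  Runs of `N` are
#' cut-opaque: a site never matches across an ambiguous base.  The
#' fragments tile each sequence exactly.
#'
#' @param genome A genome (see [as_genome()]).
#' @param enzyme A [restriction_enzyme()].
#' @return A `GRanges` of fragments with `seqlengths` set and metadata
#'   columns `n_frac` (fraction of N bases) and `masked_frac` (fraction of
#'   soft-masked, lowercase bases).
#' @examples
#' fr <- digest(c(chr1 = "AAGGCCTTGGCCAA"), get_enzyme("HaeIII"))
#' GenomicRanges::width(fr)  # 4 6 4
#' @export
digest <- function(genome, enzyme) {
  genome <- as_genome(genome)
  if (!inherits(enzyme, "restriction_enzyme")) {
    stop("enzyme must be a restriction_enzyme object")
  }
  pat <- Biostrings::DNAString(enzyme$site)
  lens <- genome_lengths(genome)
  per_seq <- lapply(names(genome), function(nm) {
    s <- genome[[nm]]
    len <- nchar(s)
    subj <- Biostrings::DNAString(toupper(s))
    hits <- Biostrings::matchPattern(pat, subj, fixed = TRUE)
    cuts <- sort(unique(BiocGenerics::start(hits) - 1L + enzyme$cut_offset))
    cuts <- cuts[cuts > 0L & cuts < len]
    bounds <- c(0L, cuts, len)
    ir <- IRanges::IRanges(start = bounds[-length(bounds)] + 1L,
                           end = bounds[-1])
    bsub <- Biostrings::BString(s)
    v <- Biostrings::Views(bsub, ir)
    low <- rowSums(Biostrings::letterFrequency(v, c("a", "c", "g", "t", "n")))
    nn <- rowSums(Biostrings::letterFrequency(v, c("N", "n")))
    gr <- GenomicRanges::GRanges(nm, ir)
    S4Vectors::mcols(gr)$n_frac <- nn / IRanges::width(ir)
    S4Vectors::mcols(gr)$masked_frac <- low / IRanges::width(ir)
    gr
  })
  gr <- suppressWarnings(do.call(c, per_seq))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- unname(lens)
  S4Vectors::metadata(gr)$enzyme <- enzyme
  gr
}

#' Select fragments by length for a reduced-representation library
#'
#' Retains the fragments whose length lies in `[min_len, max_len]` (both
#' bounds inclusive) and reports the genome fraction they represent.  The
#' denominator is the total sequence length including N bases.
#'
#' @param fragments A fragment `GRanges` from [digest()].
#' @param min_len,max_len Inclusive length window in bp.
#' @return An object of class `target_selection`: a list with `regions`
#'   (`GRanges`), `n_fragments`, `total_bp`, `genome_fraction`, `min_len`,
#'   `max_len`.
#' @export
select_fragments <- function(fragments, min_len, max_len) {
  stopifnot(methods::is(fragments, "GRanges"))
  min_len <- as.numeric(min_len)
  max_len <- as.numeric(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len < 1 || min_len > max_len) {
    stop("need 1 <= min_len <= max_len")
  }
  sl <- GenomeInfoDb::seqlengths(fragments)
  if (any(is.na(sl))) {
    stop("fragments must carry seqlengths (use digest())")
  }
  w <- GenomicRanges::width(fragments)
  keep <- fragments[w >= min_len & w <= max_len]
  structure(list(
    regions = keep,
    n_fragments = length(keep),
    total_bp = sum(as.numeric(GenomicRanges::width(keep))),
    genome_fraction = sum(as.numeric(GenomicRanges::width(keep))) /
      sum(as.numeric(sl)),
    min_len = min_len,
    max_len = max_len
  ), class = "target_selection")
}

#' @export
print.target_selection <- function(x, ...) {
  cat("<target_selection> ", x$n_fragments, " fragments of ",
      x$min_len, "-", x$max_len, " bp; ",
      format(x$total_bp, big.mark = ","), " bp (",
      sprintf("%.2f%%", 100 * x$genome_fraction), " of the genome)\n",
      sep = "")
  invisible(x)
}

#' Fragment length-distribution profile
#'
#' Tallies fragments by length: the count, the count multiplied by the
#' length (total bp per length class, the quantity plotted when choosing a
#' size window), and the mean soft-masked fraction per class as a
#' repetitive-content proxy.
#'
#' @param fragments A fragment `GRanges` from [digest()].
#' @param max_plot_len Largest length to report (default all).
#' @return A data.frame with columns `length`, `n`, `bp`, `masked_frac`.
#' @export
fragment_profile <- function(fragments, max_plot_len = Inf) {
  stopifnot(methods::is(fragments, "GRanges"))
  w <- GenomicRanges::width(fragments)
  keep <- w <= max_plot_len
  w <- w[keep]
  if (length(w) == 0L) {
    return(data.frame(length = integer(), n = integer(),
                      bp = numeric(), masked_frac = numeric()))
  }
  mf <- S4Vectors::mcols(fragments)$masked_frac[keep]
  if (is.null(mf)) mf <- rep(NA_real_, length(w))
  lens <- sort(unique(w))
  n <- as.integer(table(factor(w, levels = lens)))
  masked <- as.numeric(tapply(mf, factor(w, levels = lens), mean))
  data.frame(length = lens, n = n, bp = as.numeric(n) * lens,
             masked_frac = masked)
}

#' Sensitivity of the selected genome fraction to the size window
#'
#' Recomputes the target selection for a base window and a set of shifted
#' or widened windows, reporting relative changes; used to judge how
#' precisely fragments must be excised for homologous libraries.
#'
#' @param fragments A fragment `GRanges` from [digest()].
#' @param base_window Numeric `c(min, max)` window in bp.
#' @param shifts List of alternative `c(min, max)` windows.
#' @return A data.frame with one row per window (base first): `min_len`,
#'   `max_len`, `n_fragments`, `total_bp`, `genome_fraction`,
#'   `bp_change_pct`, `fraction_change_pct` (relative to the base window).
#' @export
window_sensitivity <- function(fragments, base_window, shifts = list()) {
  windows <- c(list(base_window), shifts)
  rows <- lapply(windows, function(wn) {
    sel <- select_fragments(fragments, wn[1], wn[2])
    data.frame(min_len = wn[1], max_len = wn[2],
               n_fragments = sel$n_fragments,
               total_bp = sel$total_bp,
               genome_fraction = sel$genome_fraction)
  })
  out <- do.call(rbind, rows)
  base_bp <- out$total_bp[1]
  base_fr <- out$genome_fraction[1]
  out$bp_change_pct <- if (base_bp > 0) 100 * (out$total_bp - base_bp) / base_bp else NA_real_
  out$fraction_change_pct <- if (base_fr > 0) 100 * (out$genome_fraction - base_fr) / base_fr else NA_real_
  rownames(out) <- NULL
  out
}
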