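## Population-genomic summary statistics and the sliding-window
## differentiation scan.

#' Observed site heterozygosity
#'
#' The number of individuals carrying both alleles divided by the total
#' number of called genotypes in the population, per site.
#'
#' @param snps A `snp_table` from [population_filter()].
#' @param pop Population label.
#' @return Numeric vector in `[0, 1]` (NA where no genotype was called).
#' @export
site_heterozygosity <- function(snps, pop) {
  stopifnot(inherits(snps, "snp_table"))
  if (!pop %in% attr(snps, "populations")) stop("unknown population '", pop, "'")
  n_called <- snps[[paste0("n_called_", pop)]]
  n_het <- snps[[paste0("n_het_", pop)]]
  ifelse(n_called > 0, n_het / n_called, NA_real_)
}

#' Allele-frequency differential D
#'
#' `D = (|p1 - p2| + |q1 - q2|) / 2` with `q = 1 - p`; for a biallelic
#' site this equals `|p1 - p2|`.  Ranges from 0 (identical frequencies)
#' to 1 (alternatively fixed alleles).
#'
#' @param p1,p2 Alternative-allele frequencies in `[0, 1]` (vectorised).
#' @return Numeric vector of differentials.
#' @examples
#' allele_freq_differential(0.6, 0.1)  # 0.5
#' @export
allele_freq_differential <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  (abs(p1 - p2) + abs((1 - p1) - (1 - p2))) / 2
}

#' Sliding-window differentiation scan
#'
#' Tiles each sequence with windows anchored at position 1 and advancing
#' by `step` (trailing partial windows included), averages the
#' allele-frequency differential D of the SNPs inside each window, and
#' flags outlier windows: mean D above `threshold` with at least
#' `min_snps` SNPs.
#'
#' @param snps A `snp_table` from [population_filter()] with exactly two
#'   populations.
#' @param seqlengths Named vector of sequence lengths in bp.
#' @param window,step Window and step size in bp.
#' @param threshold Outlier threshold on mean D.
#' @param min_snps Minimum SNPs for a window to qualify as an outlier.
#' @param exclude Optional regular expression; matching sequence names are
#'   excluded from the scan (e.g. unplaced `"_random$"` scaffolds).
#' @return A data.frame of class `window_scan`: `chrom`, `start`, `end`,
#'   `n_snps`, `mean_d` (NA for empty windows), `outlier`.  Attributes
#'   record the grid parameters.
#' @export
sliding_window_scan <- function(snps, seqlengths, window = 100000L,
                                step = 25000L, threshold = 0.95,
                                min_snps = 2L, exclude = NULL) {
  stopifnot(inherits(snps, "snp_table"))
  pops <- attr(snps, "populations")
  if (length(pops) != 2L) stop("the scan needs exactly two populations")
  if (is.null(names(seqlengths))) stop("seqlengths must be named")
  if (window < 1 || step < 1) stop("window and step must be positive")
  if (!is.null(exclude)) {
    seqlengths <- seqlengths[!grepl(exclude, names(seqlengths))]
  }
  d <- allele_freq_differential(snps[[paste0("p_", pops[1])]],
                                snps[[paste0("p_", pops[2])]])
  grids <- lapply(names(seqlengths), function(chrom) {
    len <- seqlengths[[chrom]]
    starts <- seq(1L, len, by = step)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + window - 1, len))
  })
  out <- do.call(rbind, grids)
  win <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$start, out$end))
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(win, snp_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  out$n_snps <- as.integer(tabulate(qh, nbins = nrow(out)))
  sums <- rep(0, nrow(out))
  agg <- tapply(d[S4Vectors::subjectHits(hits)], qh, sum)
  sums[as.integer(names(agg))] <- agg
  out$mean_d <- ifelse(out$n_snps > 0, sums / out$n_snps, NA_real_)
  out$outlier <- out$n_snps >= min_snps & !is.na(out$mean_d) &
    out$mean_d > threshold
  rownames(out) <- NULL
  attr(out, "window") <- as.integer(window)
  attr(out, "step") <- as.integer(step)
  attr(out, "threshold") <- threshold
  attr(out, "min_snps") <- as.integer(min_snps)
  class(out) <- c("window_scan", "data.frame")
  out
}

#' Singleton and private-SNP flags
#'
#' A singleton carries exactly one alternative-allele copy among the
#' called genotypes of the chosen scope (the whole dataset, or one
#' population).  A private SNP is polymorphic in one population and
#' monomorphic in the other.  Per-population singleton percentages use
#' the number of sites polymorphic within that population as the
#' denominator, so that private-SNP counts stay meaningful.
#'
#' @param snps A `snp_table` from [population_filter()].
#' @param scope `"overall"` or `"population"` for the singleton
#'   definition.
#' @return A list: `flags` (data.frame with `singleton` (scope-dependent;
#'   per-population scope yields one column per population) and
#'   `private_P` columns), `summary` (data.frame `scope`, `n_sites`,
#'   `n_singletons`, `pct_singletons`, plus `n_private` per population).
#' @export
singleton_and_private <- function(snps, scope = c("overall", "population")) {
  stopifnot(inherits(snps, "snp_table"))
  scope <- match.arg(scope)
  pops <- attr(snps, "populations")
  alt_total <- Reduce(`+`, lapply(pops, function(p)
    snps[[paste0("alt_copies_", p)]]))
  flags <- data.frame(row.names = seq_len(nrow(snps)))
  summary_rows <- list()
  if (scope == "overall") {
    flags$singleton <- alt_total == 1L
    summary_rows[["overall"]] <- data.frame(
      scope = "overall", n_sites = nrow(snps),
      n_singletons = sum(flags$singleton),
      pct_singletons = if (nrow(snps) > 0)
        100 * sum(flags$singleton) / nrow(snps) else NA_real_)
  } else {
    for (p in pops) {
      poly <- snps[[paste0("poly_", p)]]
      s <- snps[[paste0("alt_copies_", p)]] == 1L & poly
      flags[[paste0("singleton_", p)]] <- s
      summary_rows[[p]] <- data.frame(
        scope = p, n_sites = sum(poly), n_singletons = sum(s),
        pct_singletons = if (sum(poly) > 0) 100 * sum(s) / sum(poly)
        else NA_real_)
    }
  }
  summary <- do.call(rbind, summary_rows)
  if (length(pops) == 2L) {
    for (i in 1:2) {
      p <- pops[i]; q <- pops[3 - i]
      priv <- snps[[paste0("poly_", p)]] & !snps[[paste0("poly_", q)]]
      flags[[paste0("private_", p)]] <- priv
      summary[[paste0("n_private_", p)]] <- sum(priv)
    }
  }
  rownames(summary) <- NULL
  list(flags = flags, summary = summary)
}

#' Minor-allele-frequency spectrum
#'
#' Per-site minor-allele frequency of a population (the folded
#' alternative-allele frequency, `min(p, 1 - p)`), optionally with a
#' Gaussian kernel density on `[0, 0.5]` using Silverman's bandwidth for
#' plotting.
#'
#' @param snps A `snp_table` from [population_filter()].
#' @param pop Population label.
#' @param kde Compute the kernel density?
#' @param n_grid Grid size of the density.
#' @return A list: `maf` (numeric vector), `density` (data.frame `x`,
#'   `y`, or NULL).
#' @export
maf_spectrum <- function(snps, pop, kde = TRUE, n_grid = 512L) {
  stopifnot(inherits(snps, "snp_table"))
  p <- snps[[paste0("p_", pop)]]
  if (is.null(p)) stop("unknown population '", pop, "'")
  maf <- pmin(p, 1 - p)
  dens <- NULL
  if (kde && sum(!is.na(maf)) >= 2L) {
    d <- stats::density(maf[!is.na(maf)], bw = "nrd0", n = n_grid,
                        from = 0, to = 0.5)
    dens <- data.frame(x = d$x, y = d$y)
  }
  list(maf = maf, density = dens)
}
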