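## Population-based SNP filtering and target-efficiency accounting.

as_pop_assignment <- function(pops) {
  if (is.data.frame(pops)) {
    stopifnot(all(c("individual", "population") %in% names(pops)))
    pops <- stats::setNames(as.character(pops$population),
                            as.character(pops$individual))
  }
  if (is.null(names(pops)) || any(!nzchar(names(pops)))) {
    stop("population assignment must map individual ids to population labels")
  }
  if (anyDuplicated(names(pops))) stop("individual assigned twice")
  pops
}

#' Population-based SNP filter
#'
#' Applies the population filter to a call set: drops non-variant and
#' multi-allelic sites, then drops any site for which some population has
#' fewer than `min_individuals` non-missing genotypes, and computes the
#' per-population alternative-allele frequency from the called genotypes
#' (allele copies / 2 x called individuals; missing individuals are
#' excluded from the denominator).
#'
#' @param callset A [callset()].
#' @param pops Population assignment: a named character vector
#'   (individual -> population) or a data.frame with columns `individual`,
#'   `population`.  Every call-set individual must be assigned.
#' @param min_individuals Minimum called individuals per population
#'   (default 8, i.e. at least 16 chromosomes).
#' @return A data.frame of class `snp_table`: one row per retained site
#'   with columns `chrom`, `pos`, `ref`, `alt` and, per population `P`,
#'   `n_called_P`, `n_het_P`, `alt_copies_P`, `p_P` and a logical
#'   `poly_P` (both alleles observed within `P`).  Attribute
#'   `populations` lists the population labels.
#' @export
population_filter <- function(callset, pops, min_individuals = 8L) {
  stopifnot(inherits(callset, "callset"))
  pops <- as_pop_assignment(pops)
  missing_ind <- setdiff(callset$individuals, names(pops))
  if (length(missing_ind)) {
    stop("individuals without population assignment: ",
         paste(missing_ind, collapse = ", "))
  }
  pop_of <- pops[callset$individuals]
  labels <- unique(unname(pop_of))
  keep <- callset$sites$variant & !callset$sites$multiallelic
  out <- callset$sites[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no variant biallelic sites to filter")
  }
  g <- callset$geno[keep, , drop = FALSE]
  ok <- rep(TRUE, nrow(out))
  for (p in labels) {
    gp <- g[, pop_of == p, drop = FALSE]
    n_called <- rowSums(!is.na(gp))
    n_het <- rowSums(gp == 1L, na.rm = TRUE)
    alt_copies <- rowSums(gp, na.rm = TRUE)
    pfreq <- ifelse(n_called > 0, alt_copies / (2 * n_called), NA_real_)
    out[[paste0("n_called_", p)]] <- n_called
    out[[paste0("n_het_", p)]] <- n_het
    out[[paste0("alt_copies_", p)]] <- alt_copies
    out[[paste0("p_", p)]] <- pfreq
    out[[paste0("poly_", p)]] <- alt_copies > 0 & alt_copies < 2 * n_called
    ok <- ok & n_called >= min_individuals
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "populations") <- labels
  attr(out, "min_individuals") <- as.integer(min_individuals)
  class(out) <- c("snp_table", "data.frame")
  out
}

#' High-quality positions of each individual from read counts
#'
#' Builds the per-individual set of high-quality base positions from a
#' counts table: positions whose depth meets `min_depth` (base and
#' mapping quality are treated as already filtered upstream of the count
#' table).
#'
#' @param counts A [site_counts()].
#' @param min_depth Minimum depth (default 10).
#' @return A named list of `GRanges`, one per individual, of 1-bp
#'   positions.
#' @export
hiqual_positions <- function(counts, min_depth = 10L) {
  stopifnot(inherits(counts, "site_counts"))
  dp <- counts$ref + counts$alt
  out <- lapply(seq_along(counts$individuals), function(j) {
    i <- which(dp[, j] >= min_depth)
    GenomicRanges::GRanges(counts$sites$chrom[i],
                           IRanges::IRanges(counts$sites$pos[i], width = 1L))
  })
  names(out) <- counts$individuals
  out
}

#' Target efficiency of a reduced-representation library
#'
#' The percentage of an individual's high-quality positions that fall
#' inside the in-silico-predicted target regions; the headline measure of
#' how reproducibly the library sampled the intended genome fraction.
#'
#' @param hiqual Named list of per-individual `GRanges` of high-quality
#'   positions (see [hiqual_positions()] or [read_bed()]).
#' @param targets Target regions: a `GRanges` or a `target_selection`.
#' @param pops Optional population assignment; adds a per-population
#'   median attribute.
#' @return A data.frame with columns `individual`, `bp_hiqual`,
#'   `bp_on_target`, `efficiency_pct` (NA with a warning for individuals
#'   without high-quality positions).  When `pops` is given, attribute
#'   `median_by_population` holds the per-population medians.
#' @export
target_efficiency <- function(hiqual, targets, pops = NULL) {
  if (inherits(targets, "target_selection")) targets <- targets$regions
  stopifnot(methods::is(targets, "GRanges"), is.list(hiqual))
  if (is.null(names(hiqual))) stop("hiqual must be a named list")
  tgt <- GenomicRanges::reduce(targets)
  rows <- lapply(names(hiqual), function(id) {
    hq <- GenomicRanges::reduce(hiqual[[id]])
    total <- sum(as.numeric(GenomicRanges::width(hq)))
    if (total == 0) {
      warning("individual '", id, "' has no high-quality positions")
      return(data.frame(individual = id, bp_hiqual = 0,
                        bp_on_target = 0, efficiency_pct = NA_real_))
    }
    on_t <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(hq, tgt, ignore.strand = TRUE))))
    data.frame(individual = id, bp_hiqual = total, bp_on_target = on_t,
               efficiency_pct = 100 * on_t / total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(pops)) {
    pops <- as_pop_assignment(pops)
    pop_of <- pops[out$individual]
    med <- tapply(out$efficiency_pct, pop_of, stats::median, na.rm = TRUE)
    attr(out, "median_by_population") <- med
  }
  out
}
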