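## Multi-caller overlap, genotype concordance, intersection and
## validation scoring.  Site identity is allele-aware: a site overlaps
## between call sets only when chrom, position and allele pair all match.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention of printed
#' percentage tables), unlike R's round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Venn overlap of SNP sites between call sets
#'
#' Counts the variant, biallelic SNP sites in every region of the Venn
#' partition of two or more call sets.  Site identity is
#' `chrom:pos_ref/alt`, genotype-agnostic.  Private percentages use each
#' caller's own SNP total as the denominator.
#'
#' @param callsets Named list of [callset()] objects (>= 2).
#' @return A list: `venn` (data.frame `pattern`, `count`), `private`
#'   (data.frame `caller`, `n_snps`, `n_private`, `pct_private`),
#'   `n_union`, `n_all` (size of the full intersection).
#' @export
site_overlap <- function(callsets) {
  stopifnot(is.list(callsets), length(callsets) >= 2L)
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    names(callsets) <- vapply(callsets, function(x) x$caller, character(1))
  }
  keys <- lapply(callsets, variant_sites)
  universe <- unique(unlist(keys))
  mem <- vapply(keys, function(k) universe %in% k,
                logical(length(universe)))
  mem <- matrix(mem, nrow = length(universe),
                dimnames = list(NULL, names(callsets)))
  pattern <- apply(mem, 1L, function(r)
    paste(colnames(mem)[r], collapse = "&"))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  private <- data.frame(
    caller = names(callsets),
    n_snps = vapply(keys, length, integer(1)),
    n_private = vapply(names(callsets), function(nm)
      sum(rowSums(mem) == 1L & mem[, nm]), integer(1)),
    row.names = NULL
  )
  private$pct_private <- 100 * private$n_private / private$n_snps
  list(venn = venn, private = private, n_union = length(universe),
       n_all = sum(rowSums(mem) == ncol(mem)))
}

#' Genotype concordance between two call sets
#'
#' Over the SNP sites variant in both call sets, compares for each shared
#' individual whether the two callers produced identical genotypes.
#' Entries missing in either set are excluded from the comparison.
#' Discordant pairs are classified as het-vs-hom (one caller heterozygous,
#' the other homozygous for either allele) or as opposite homozygotes, and
#' the het-direction bias reports which caller supplies the heterozygote
#' in het-vs-hom disagreements.
#'
#' @param a,b [callset()] objects sharing individuals.
#' @return An object of class `concordance_report`: `per_individual`
#'   (data.frame `individual`, `n_compared`, `n_identical`,
#'   `pct_identical`), `median_pct`, `totals` (list with `n_compared`,
#'   `n_identical`, `het_a_hom_b`, `hom_a_het_b`, `homref_homalt`,
#'   `other`), `pct_het_hom` (share of discordances that are het-vs-hom),
#'   `bias` (named shares of het-vs-hom discordances in which each caller
#'   is the heterozygote), `callers`.
#' @export
genotype_concordance <- function(a, b) {
  stopifnot(inherits(a, "callset"), inherits(b, "callset"))
  ind <- intersect(a$individuals, b$individuals)
  if (length(ind) == 0L) stop("no shared individuals")
  shared <- intersect(variant_sites(a), variant_sites(b))
  ga <- a$geno[match(shared, rownames(a$geno)), ind, drop = FALSE]
  gb <- b$geno[match(shared, rownames(b$geno)), ind, drop = FALSE]
  both <- !is.na(ga) & !is.na(gb)
  eq <- both & ga == gb
  per_ind <- data.frame(
    individual = ind,
    n_compared = colSums(both),
    n_identical = colSums(eq, na.rm = TRUE),
    row.names = NULL
  )
  per_ind$pct_identical <- ifelse(per_ind$n_compared > 0,
                                  100 * per_ind$n_identical / per_ind$n_compared,
                                  NA_real_)
  disc <- both & ga != gb
  het_a <- sum(disc & ga == 1L, na.rm = TRUE)
  het_b <- sum(disc & gb == 1L, na.rm = TRUE)
  opp_hom <- sum(disc & ga != 1L & gb != 1L, na.rm = TRUE)
  n_disc <- sum(disc, na.rm = TRUE)
  totals <- list(n_compared = sum(both), n_identical = sum(eq, na.rm = TRUE),
                 het_a_hom_b = het_a, hom_a_het_b = het_b,
                 homref_homalt = opp_hom,
                 other = n_disc - het_a - het_b - opp_hom)
  n_het_hom <- het_a + het_b
  structure(list(
    per_individual = per_ind,
    median_pct = stats::median(per_ind$pct_identical, na.rm = TRUE),
    totals = totals,
    pct_het_hom = if (n_disc > 0) 100 * n_het_hom / n_disc else NA_real_,
    bias = c(
      stats::setNames(if (n_het_hom > 0) 100 * het_a / n_het_hom else NA_real_,
                      a$caller),
      stats::setNames(if (n_het_hom > 0) 100 * het_b / n_het_hom else NA_real_,
                      b$caller)),
    callers = c(a$caller, b$caller)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$callers[1], " vs ", x$callers[2], ": ",
      sprintf("median %.2f%% identical", x$median_pct), " (",
      x$totals$n_compared, " genotype pairs, ",
      x$totals$n_compared - x$totals$n_identical, " discordant)\n", sep = "")
  invisible(x)
}

#' Intersect two call sets
#'
#' Keeps, per (site, individual), the genotype only when both callers
#' assigned it identically and neither is missing; everything else becomes
#' missing.  Sites are matched allele-aware.  Intersection happens before
#' population-based filtering, which is re-applied downstream.
#'
#' @param a,b [callset()] objects sharing individuals.
#' @param label Label of the intersect call set (default
#'   `"<a>-<b>_intersect"`).
#' @return A [callset()] over the shared sites and individuals; depth is
#'   the per-entry minimum of the parents, genotype quality the minimum
#'   where both carry one.
#' @export
intersect_callsets <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "callset"), inherits(b, "callset"))
  ind <- intersect(a$individuals, b$individuals)
  if (length(ind) == 0L) stop("no shared individuals")
  shared <- intersect(rownames(a$geno), rownames(b$geno))
  ia <- match(shared, rownames(a$geno))
  ib <- match(shared, rownames(b$geno))
  ga <- a$geno[ia, ind, drop = FALSE]
  gb <- b$geno[ib, ind, drop = FALSE]
  g <- ga
  g[is.na(ga) | is.na(gb) | ga != gb] <- NA_integer_
  dp <- if (!is.null(a$dp) && !is.null(b$dp)) {
    pmin(a$dp[ia, ind, drop = FALSE], b$dp[ib, ind, drop = FALSE])
  } else NULL
  gq <- if (!is.null(a$gq) && !is.null(b$gq)) {
    pmin(a$gq[ia, ind, drop = FALSE], b$gq[ib, ind, drop = FALSE])
  } else NULL
  sites <- a$sites[ia, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  sites$multiallelic <- a$sites$multiallelic[ia] | b$sites$multiallelic[ib]
  callset(sites, g, dp = dp, gq = gq,
          caller = if (is.null(label))
            paste0(a$caller, "-", b$caller, "_intersect") else label)
}

#' Build a genotype-validation table
#'
#' Categorised counts of independently validated genotypes at sites where
#' two callers disagreed (plus a concordant-call row), as produced by
#' re-typing a subset of SNPs with an independent assay.
#'
#' @param categories data.frame with columns `category`, `n_snps`,
#'   `n_genotypes`, `n_true_a`, `n_true_b`; per row
#'   `n_true_a + n_true_b` must equal `n_genotypes`.
#' @param concordant Numeric `c(n_genotypes, n_correct)` for the
#'   concordant-call row.
#' @param caller_a,caller_b Labels of the two callers (a's truth count is
#'   `n_true_a`).
#' @return An object of class `validation_table`.
#' @export
validation_table <- function(categories, concordant = NULL,
                             caller_a = "A", caller_b = "B") {
  need <- c("category", "n_snps", "n_genotypes", "n_true_a", "n_true_b")
  stopifnot(is.data.frame(categories), all(need %in% names(categories)))
  bad <- categories$n_true_a + categories$n_true_b != categories$n_genotypes
  if (any(bad)) {
    stop("n_true_a + n_true_b must equal n_genotypes (rows: ",
         paste(which(bad), collapse = ", "), ")")
  }
  if (!is.null(concordant)) {
    stopifnot(length(concordant) == 2L, concordant[2] <= concordant[1])
  }
  structure(list(categories = categories, concordant = concordant,
                 caller_a = caller_a, caller_b = caller_b),
            class = "validation_table")
}

#' Score a genotype-validation table
#'
#' Per-category and total percentages of validated discordant genotypes
#' that each caller got right, and the accuracy of concordant calls.
#' Percentages are undefined (NA) for empty rows.
#'
#' @param table A [validation_table()].
#' @return A list: `by_category` (data.frame with `pct_true_a`,
#'   `pct_true_b` appended), `total` (list `n_genotypes`, `n_true_a`,
#'   `n_true_b`, `pct_true_a`, `pct_true_b`), `concordant` (list
#'   `n_genotypes`, `n_correct`, `pct_correct`, or NULL).
#' @export
score_validation <- function(table) {
  stopifnot(inherits(table, "validation_table"))
  cat_ <- table$categories
  cat_$pct_true_a <- ifelse(cat_$n_genotypes > 0,
                            100 * cat_$n_true_a / cat_$n_genotypes, NA_real_)
  cat_$pct_true_b <- ifelse(cat_$n_genotypes > 0,
                            100 * cat_$n_true_b / cat_$n_genotypes, NA_real_)
  tot_g <- sum(cat_$n_genotypes)
  tot_a <- sum(cat_$n_true_a)
  tot_b <- sum(cat_$n_true_b)
  conc <- NULL
  if (!is.null(table$concordant)) {
    conc <- list(n_genotypes = table$concordant[1],
                 n_correct = table$concordant[2],
                 pct_correct = if (table$concordant[1] > 0)
                   100 * table$concordant[2] / table$concordant[1] else NA_real_)
  }
  list(by_category = cat_,
       total = list(n_genotypes = tot_g, n_true_a = tot_a, n_true_b = tot_b,
                    pct_true_a = if (tot_g > 0) 100 * tot_a / tot_g else NA_real_,
                    pct_true_b = if (tot_g > 0) 100 * tot_b / tot_g else NA_real_),
       concordant = conc)
}

#' Venn overlap of outlier windows between scans
#'
#' Counts outlier windows in every region of the Venn partition of two or
#' more sliding-window scans computed on an identical window grid, and the
#' percentage of outliers identical among all scans relative to the union.
#'
#' @param scans Named list of `window_scan` data.frames (see
#'   [sliding_window_scan()]).
#' @return A list: `venn` (data.frame `pattern`, `count`), `n_union`,
#'   `n_all`, `pct_identical` (`100 * n_all / n_union`).
#' @export
outlier_overlap <- function(scans) {
  stopifnot(is.list(scans), length(scans) >= 2L)
  if (is.null(names(scans)) || any(!nzchar(names(scans)))) {
    names(scans) <- paste0("scan", seq_along(scans))
  }
  grid <- lapply(scans, function(s) paste0(s$chrom, ":", s$start, "-", s$end))
  for (i in seq_along(grid)[-1]) {
    if (!identical(grid[[1]], grid[[i]])) {
      stop("window grids differ between scans")
    }
  }
  keys <- lapply(scans, function(s)
    paste0(s$chrom, ":", s$start, "-", s$end)[s$outlier])
  universe <- unique(unlist(keys))
  if (length(universe) == 0L) {
    return(list(venn = data.frame(pattern = character(), count = integer()),
                n_union = 0L, n_all = 0L, pct_identical = NA_real_))
  }
  mem <- vapply(keys, function(k) universe %in% k, logical(length(universe)))
  mem <- matrix(mem, nrow = length(universe),
                dimnames = list(NULL, names(scans)))
  pattern <- apply(mem, 1L, function(r) paste(colnames(mem)[r], collapse = "&"))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  n_all <- sum(rowSums(mem) == ncol(mem))
  list(venn = venn, n_union = length(universe), n_all = n_all,
       pct_identical = 100 * n_all / length(universe))
}
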