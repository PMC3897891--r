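## Genotype calling from allelic read counts.
## Two callers share the depth gates: a hard-filter caller that assigns
## genotypes from fixed alternative-allele-fraction bands (the common
## read-count cut-off practice), and a binomial genotype-likelihood caller
## with either single-sample genotype priors or an empirical per-site
## allele-frequency (Hardy-Weinberg) prior emulating multi-sample calling.

site_key <- function(sites) {
  paste0(sites$chrom, ":", sites$pos, "_", sites$ref, "/", sites$alt)
}

#' Caller thresholds
#'
#' Depth and quality gates shared by the callers, and the hard-filter
#' allele-balance bands.  The defaults mirror stringent practice:
#' depth 10-1000, genotype quality >= 10, homozygous-reference below 15%
#' alternative-allele fraction, heterozygous between 20% and 80%,
#' homozygous-alternative above 85%, with the borderline 15-20% and
#' 80-85% zones conservatively set to missing.
#'
#' @param min_depth,max_depth Accepted depth band (calls outside are
#'   missing).
#' @param min_gq Minimum phred-scaled genotype quality; applied to
#'   likelihood calls only (hard-filter calls carry no GQ).
#' @param homref_max,het_lower,het_upper,homalt_min Allele-fraction band
#'   edges; must be non-decreasing in `[0, 1]`.
#' @return An object of class `caller_thresholds`.
#' @export
caller_thresholds <- function(min_depth = 10L, max_depth = 1000L,
                              min_gq = 10L, homref_max = 0.15,
                              het_lower = 0.20, het_upper = 0.80,
                              homalt_min = 0.85) {
  bands <- c(0, homref_max, het_lower, het_upper, homalt_min, 1)
  if (any(diff(bands) < 0)) {
    stop("band edges must satisfy 0 <= homref_max <= het_lower <= ",
         "het_upper <= homalt_min <= 1")
  }
  if (min_depth < 0 || max_depth < min_depth) stop("invalid depth band")
  structure(list(min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth),
                 min_gq = as.integer(min_gq),
                 homref_max = homref_max, het_lower = het_lower,
                 het_upper = het_upper, homalt_min = homalt_min),
            class = "caller_thresholds")
}

#' Hard-filter genotype call from allele counts
#'
#' With `f = alt / (ref + alt)`: `f < homref_max` is homozygous reference
#' (0); `het_lower <= f <= het_upper` is heterozygous (1);
#' `f > homalt_min` is homozygous alternative (2); the borderline zones
#' `[homref_max, het_lower)` and `(het_upper, homalt_min]` are missing
#' (`NA`), as is any call whose depth falls outside the accepted band
#' (zero depth included).
#'
#' @param ref,alt Non-negative counts; vectors or matrices of identical
#'   shape.
#' @param thresholds A [caller_thresholds()].
#' @return Integer genotypes (0/1/2/`NA`) with the shape of the input.
#' @examples
#' hard_filter_call(18, 2)   # f = 0.10 -> 0 (homref)
#' hard_filter_call(10, 10)  # f = 0.50 -> 1 (het)
#' hard_filter_call(33, 7)   # f = 0.175 -> NA (borderline)
#' @export
hard_filter_call <- function(ref, alt, thresholds = caller_thresholds()) {
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    stop("negative read counts")
  }
  dp <- ref + alt
  f <- alt / dp
  g <- rep(NA_integer_, length(dp))
  ok <- !is.na(f)
  g[ok & f < thresholds$homref_max] <- 0L
  g[ok & f >= thresholds$het_lower & f <= thresholds$het_upper] <- 1L
  g[ok & f > thresholds$homalt_min] <- 2L
  g[dp < thresholds$min_depth | dp > thresholds$max_depth] <- NA_integer_
  if (!is.null(dim(ref))) dim(g) <- dim(ref)
  g
}

#' Binomial genotype-likelihood call from allele counts
#'
#' Diploid likelihoods are binomial in the alternative-read count:
#' `L(homref) = B(alt; depth, e)`, `L(het) = B(alt; depth, 1/2)`,
#' `L(homalt) = B(alt; depth, 1 - e)` with `e` the per-read error rate.
#' Priors are either the single-sample genotype prior
#' `{1 - t - t^2, t, t^2}` with `t = het_prior`, or, when an
#' alternative-allele frequency `af` is supplied, Hardy-Weinberg
#' proportions `{(1-af)^2, 2 af (1-af), af^2}` (the population prior used
#' in multi-sample calling).  The call is the maximum-posterior genotype;
#' GQ is the phred-scaled probability that the call is wrong, capped at
#' 99.  Calls with depth outside the band or GQ below `min_gq` are
#' missing.
#'
#' @param ref,alt Non-negative counts; vectors or matrices of identical
#'   shape.
#' @param error_rate Per-read error rate, `0 < e < 0.5`.
#' @param het_prior Single-sample heterozygosity prior, `0 < t < 0.5`.
#' @param af Optional alternative-allele frequency in `(0, 1)` (scalar or
#'   shaped like `ref`); switches on the Hardy-Weinberg population prior.
#' @param thresholds A [caller_thresholds()].
#' @return A list: `genotype` (0/1/2/`NA`, input shape), `gq` (integer,
#'   input shape, `NA` where missing), `posterior` (N x 3 matrix of
#'   genotype posteriors in input order).
#' @examples
#' likelihood_call(40, 0, error_rate = 0.001)$genotype  # 0, GQ 99
#' likelihood_call(20, 20, error_rate = 0.001)$genotype # 1
#' @export
likelihood_call <- function(ref, alt, error_rate = 0.001, het_prior = 0.001,
                            af = NULL, thresholds = caller_thresholds()) {
  if (error_rate <= 0 || error_rate >= 0.5) stop("error_rate must lie in (0, 0.5)")
  if (is.null(af) && (het_prior <= 0 || het_prior >= 0.5)) {
    stop("het_prior must lie in (0, 0.5)")
  }
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    stop("negative read counts")
  }
  dims <- dim(ref)
  dp <- as.vector(ref + alt)
  av <- as.vector(alt)
  n <- length(dp)
  ll <- cbind(dbinom(av, dp, error_rate, log = TRUE),
              dbinom(av, dp, 0.5, log = TRUE),
              dbinom(av, dp, 1 - error_rate, log = TRUE))
  if (is.null(af)) {
    lpri <- matrix(log(c(1 - het_prior - het_prior^2, het_prior,
                         het_prior^2)),
                   nrow = n, ncol = 3, byrow = TRUE)
  } else {
    if (any(af <= 0 | af >= 1)) stop("af must lie strictly in (0, 1)")
    afv <- rep_len(as.vector(af), n)
    lpri <- cbind(2 * log1p(-afv), log(2) + log(afv) + log1p(-afv),
                  2 * log(afv))
  }
  lp <- ll + lpri
  mx <- pmax(lp[, 1], lp[, 2], lp[, 3])
  post <- exp(lp - mx)
  post <- post / rowSums(post)
  colnames(post) <- c("homref", "het", "homalt")
  call <- max.col(post, ties.method = "first") - 1L
  pcall <- post[cbind(seq_len(n), call + 1L)]
  gq <- pmin(99L, as.integer(round(-10 * log10(pmax(1 - pcall, 1e-10)))))
  drop_ <- dp < thresholds$min_depth | dp > thresholds$max_depth |
    gq < thresholds$min_gq
  call[drop_] <- NA_integer_
  gq[drop_] <- NA_integer_
  if (!is.null(dims)) { dim(call) <- dims; dim(gq) <- dims }
  list(genotype = call, gq = gq, posterior = post)
}

#' Construct a call set
#'
#' A caller-labelled matrix of diploid genotype calls over sites x
#' individuals, with per-call depth and (optionally) genotype quality.
#' Sites are sorted by coordinate; duplicate sites are an error.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `multiallelic` (logical).
#' @param geno Integer matrix (0/1/2/`NA`), sites x individuals, with
#'   individual ids as column names.
#' @param dp Optional depth matrix, same shape.
#' @param gq Optional genotype-quality matrix, same shape (absent for
#'   hard-filter calls).
#' @param caller Caller label.
#' @return An object of class `callset` with elements `caller`, `sites`
#'   (including logical columns `multiallelic` and `variant`), `geno`,
#'   `dp`, `gq`, `individuals`.
#' @export
callset <- function(sites, geno, dp = NULL, gq = NULL, caller = "caller") {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites)) stop("one genotype row per site required")
  if (is.null(colnames(geno))) stop("geno needs individual ids as column names")
  key <- site_key(sites)
  if (anyDuplicated(key)) {
    stop("duplicate (site, individual) entries: duplicated site keys ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (anyDuplicated(paste0(sites$chrom, ":", sites$pos))) {
    stop("duplicate site coordinates with mismatched alleles")
  }
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("genotypes must be 0/1/2/NA")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  geno <- geno[o, , drop = FALSE]
  rownames(geno) <- site_key(sites)
  fix_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)[o, , drop = FALSE]
    if (!identical(dim(m), dim(geno))) stop("matrix dimensions differ from geno")
    dimnames(m) <- dimnames(geno)
    m
  }
  dp <- fix_mat(dp)
  gq <- fix_mat(gq)
  if (is.null(sites$multiallelic)) sites$multiallelic <- FALSE
  sites$variant <- rowSums(geno > 0L, na.rm = TRUE) > 0L
  structure(list(caller = caller, sites = sites, geno = geno, dp = dp,
                 gq = gq, individuals = colnames(geno)),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat("<callset> '", x$caller, "': ", nrow(x$sites), " sites (",
      sum(x$sites$variant), " variant) x ", length(x$individuals),
      " individuals\n", sep = "")
  invisible(x)
}

#' Variant sites of a call set
#'
#' A site is non-variant when every called individual is homozygous
#' reference; such sites are excluded from the variant set but retained in
#' the call set for genotype lookup (a missing entry cannot distinguish
#' "homozygous reference" from "not sequenced").
#'
#' @param x A [callset()].
#' @param drop_multiallelic Also drop sites flagged multi-allelic.
#' @return Character vector of site keys (`chrom:pos_ref/alt`).
#' @export
variant_sites <- function(x, drop_multiallelic = TRUE) {
  stopifnot(inherits(x, "callset"))
  keep <- x$sites$variant
  if (drop_multiallelic) keep <- keep & !x$sites$multiallelic
  site_key(x$sites)[keep]
}

#' Call genotypes for a whole cohort
#'
#' Applies the chosen per-genotype caller to every (site, individual) pair
#' of a [site_counts()] object.  For the likelihood caller the default
#' prior mode `"estimate"` emulates multi-sample calling: the per-site
#' alternative-allele frequency is estimated from the pooled counts
#' (with a half-read pseudocount) and fed in as a Hardy-Weinberg prior;
#' `"genotype"` uses the single-sample `het_prior` instead.  Sites whose
#' third-allele reads total at least `multiallelic_floor` are flagged
#' multi-allelic for downstream exclusion.
#'
#' @param counts A [site_counts()].
#' @param caller `"hard_filter"` or `"likelihood"`.
#' @param thresholds A [caller_thresholds()].
#' @param error_rate,het_prior Likelihood-caller model parameters.
#' @param af_prior `"estimate"` or `"genotype"` (likelihood caller only).
#' @param multiallelic_floor Minimum total third-allele reads to flag a
#'   site multi-allelic.
#' @param label Caller label stored in the call set (defaults to the
#'   caller name).
#' @return A [callset()].
#' @export
call_population <- function(counts, caller = c("hard_filter", "likelihood"),
                            thresholds = caller_thresholds(),
                            error_rate = 0.001, het_prior = 0.001,
                            af_prior = c("estimate", "genotype"),
                            multiallelic_floor = 2L, label = NULL) {
  stopifnot(inherits(counts, "site_counts"))
  caller <- match.arg(caller)
  af_prior <- match.arg(af_prior)
  dp <- counts$ref + counts$alt
  gq <- NULL
  if (caller == "hard_filter") {
    geno <- hard_filter_call(counts$ref, counts$alt, thresholds)
  } else {
    af <- NULL
    if (af_prior == "estimate") {
      af1 <- (rowSums(counts$alt) + 0.5) / (rowSums(dp) + 1)
      af <- matrix(af1, nrow = nrow(dp), ncol = ncol(dp))
    }
    lc <- likelihood_call(counts$ref, counts$alt, error_rate = error_rate,
                          het_prior = het_prior, af = af,
                          thresholds = thresholds)
    geno <- lc$genotype
    gq <- lc$gq
  }
  sites <- counts$sites
  sites$multiallelic <- if (is.null(counts$other)) {
    rep(FALSE, nrow(sites))
  } else {
    rowSums(counts$other) >= multiallelic_floor
  }
  dimnames(geno) <- dimnames(counts$ref)
  callset(sites, geno, dp = dp, gq = gq,
          caller = if (is.null(label)) caller else label)
}
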