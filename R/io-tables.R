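## Plain TSV readers/writers for count tables, population assignments and
## truth genotypes.  All round-trip exactly through the corresponding
## in-memory objects.

#' Write allelic read counts to TSV
#'
#' Long format: one row per (site, individual) with columns `chrom`,
#' `pos`, `ref`, `alt`, `individual`, `ref_count`, `alt_count`.
#'
#' @param counts A [site_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(counts, path) {
  stopifnot(inherits(counts, "site_counts"))
  ni <- length(counts$individuals)
  df <- data.frame(
    chrom = rep(counts$sites$chrom, ni),
    pos = rep(counts$sites$pos, ni),
    ref = rep(counts$sites$ref, ni),
    alt = rep(counts$sites$alt, ni),
    individual = rep(counts$individuals, each = nrow(counts$sites)),
    ref_count = as.vector(counts$ref),
    alt_count = as.vector(counts$alt),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allelic read counts from TSV
#'
#' @param path TSV written by [write_site_counts()] (or equivalent).
#' @return A [site_counts()].
#' @export
read_site_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "individual", "ref_count", "alt_count")
  if (!all(need %in% names(df))) {
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste0(df$chrom, ":", df$pos, "_", df$ref, "/", df$alt)
  sites <- df[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  skey <- unique(key)
  inds <- unique(df$individual)
  i <- match(key, skey)
  j <- match(df$individual, inds)
  if (anyDuplicated(cbind(i, j))) stop("duplicate (site, individual) rows")
  refm <- matrix(NA_integer_, length(skey), length(inds),
                 dimnames = list(skey, inds))
  altm <- refm
  refm[cbind(i, j)] <- df$ref_count
  altm[cbind(i, j)] <- df$alt_count
  if (anyNA(refm)) stop("counts TSV is not a complete sites x individuals grid")
  rownames(sites) <- NULL
  site_counts(sites, refm, altm)
}

#' Write a population assignment to TSV
#'
#' @param pops Named character vector or data.frame (`individual`,
#'   `population`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_assignment <- function(pops, path) {
  pops <- as_pop_assignment(pops)
  df <- data.frame(individual = names(pops), population = unname(pops),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population assignment from TSV
#'
#' @param path TSV with columns `individual`, `population`.
#' @return Named character vector (individual -> population).
#' @export
read_population_assignment <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_pop_assignment(df)
}

#' Write truth genotypes to TSV
#'
#' Long format: `chrom`, `pos`, `ref`, `alt`, `individual`, `genotype`
#' (0/1/2 alternative-allele copies).  Accepts a `truth_set` or any
#' call-set-like object with `sites` and `geno`.
#'
#' @param truth A `truth_set` from [simulate_genotypes()] (or a
#'   [callset()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_genotypes <- function(truth, path) {
  g <- truth$geno
  ni <- ncol(g)
  df <- data.frame(
    chrom = rep(truth$sites$chrom, ni),
    pos = rep(truth$sites$pos, ni),
    ref = rep(truth$sites$ref, ni),
    alt = rep(truth$sites$alt, ni),
    individual = rep(colnames(g), each = nrow(g)),
    genotype = as.vector(g),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read truth genotypes from TSV
#'
#' @param path TSV written by [write_truth_genotypes()].
#' @return A list with `sites` (data.frame) and `geno` (integer matrix,
#'   sites x individuals; `NA` allowed for missing truth).
#' @export
read_truth_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "individual", "genotype")
  if (!all(need %in% names(df))) {
    stop("truth TSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste0(df$chrom, ":", df$pos, "_", df$ref, "/", df$alt)
  sites <- df[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  skey <- unique(key)
  inds <- unique(df$individual)
  g <- matrix(NA_integer_, length(skey), length(inds),
              dimnames = list(skey, inds))
  g[cbind(match(key, skey), match(df$individual, inds))] <-
    as.integer(df$genotype)
  rownames(sites) <- NULL
  list(sites = sites, geno = g)
}
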