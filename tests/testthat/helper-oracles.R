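# Independent oracles and toy-object builders shared across tests.

# Naive position-by-position scanning digest: checks every start position
# for a literal (case-insensitive) site occurrence, cuts at start+offset,
# returns fragment lengths.  Ground truth for digest().
naive_digest_lengths <- function(seq, site, cut_offset) {
  s <- toupper(seq)
  site <- toupper(site)
  n <- nchar(s)
  m <- nchar(site)
  starts <- integer(0)
  if (n >= m) {
    from <- 1:(n - m + 1)
    starts <- from[substring(s, from, from + m - 1) == site]
  }
  cuts <- sort(unique(starts - 1L + cut_offset))
  cuts <- cuts[cuts > 0 & cuts < n]
  diff(c(0L, cuts, n))
}

# Rule-table oracle for the allele-balance hard filter, in exact integer
# arithmetic (100*alt compared against band-edge multiples of depth).
hard_filter_oracle <- function(ref, alt, min_dp = 10L, max_dp = 1000L) {
  d <- ref + alt
  if (d < min_dp || d > max_dp) return(NA_integer_)
  a <- 100L * alt
  if (a < 15L * d) return(0L)
  if (a < 20L * d) return(NA_integer_)
  if (a <= 80L * d) return(1L)
  if (a <= 85L * d) return(NA_integer_)
  2L
}

# Random palindromic blunt-end enzyme (4 or 6 bp site).
random_enzyme <- function() {
  k <- sample(2:3, 1)
  half <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
  rc <- chartr("ACGT", "TGCA", rev(half))
  site <- paste(c(half, rc), collapse = "")
  restriction_enzyme("rand", site, sample(0:(2 * k), 1))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small call set over evenly spaced sites; geno is a sites x individuals
# matrix (0/1/2/NA).
toy_callset <- function(geno, caller = "A", chrom = "chr1", dp = 30L) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("ind%02d", seq_len(ncol(geno)))
  }
  sites <- data.frame(chrom = chrom, pos = 100L + 10L * seq_len(nrow(geno)),
                      ref = "A", alt = "G", stringsAsFactors = FALSE)
  callset(sites, geno, dp = matrix(dp, nrow(geno), ncol(geno)),
          caller = caller)
}

# All-heterozygote truth panel: n_sites x n_ind, one population.
het_truth_panel <- function(n_sites, n_ind = 31L) {
  sites <- data.frame(chrom = "chr1", pos = 50L * seq_len(n_sites),
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  truth_set(sites, matrix(1L, n_sites, n_ind))
}
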