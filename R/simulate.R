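## Synthetic two-population diploid RRL data with known truth.
## The generator plants recognition sites into a random background so the
## digest output is known exactly, draws Hardy-Weinberg genotypes at chosen
## per-population allele frequencies, and emits quality-passing read counts
## with Poisson depth and a symmetric per-read allele-flip error.

site_starts <- function(seq, site) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                   Biostrings::DNAString(toupper(seq)),
                                   fixed = TRUE)
  BiocGenerics::start(hits)
}

# replace accidental occurrences of `site` until none remain
scrub_sites <- function(chars, site) {
  alph <- c("A", "C", "G", "T")
  others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))
  repeat {
    st <- site_starts(paste(chars, collapse = ""), site)
    if (length(st) == 0L) break
    j <- unique(st + 1L)  # mutate the second base of each occurrence
    chars[j] <- others[cbind(match(chars[j], alph),
                             sample.int(3L, length(j), replace = TRUE))]
  }
  chars
}

# plant `site` at each (1-based) start position in `pos`
plant_site <- function(chars, site, pos) {
  m <- nchar(site)
  idx <- rep(as.integer(pos), each = m) + rep(0:(m - 1L), length(pos))
  chars[idx] <- rep(strsplit(site, "")[[1]], times = length(pos))
  chars
}

#' Simulate a genome with planted restriction sites
#'
#' Generates a random A/C/G/T genome, removes accidental occurrences of the
#' enzyme's recognition site, then plants exactly `n_sites` copies at
#' random non-overlapping positions per chromosome.  The planted positions
#' are returned so digest output can be checked against known truth:
#' a chromosome with `n_sites` planted sites yields `n_sites + 1`
#' fragments (cut positions strictly inside the sequence).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_sites Number of recognition sites planted per chromosome
#'   (0 gives one fragment per chromosome).
#' @param enzyme A [restriction_enzyme()] (default HaeIII).
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A list of class `sim_genome`: `genome` (named character),
#'   `planted` (list of 1-based site start positions per chromosome),
#'   `enzyme`, `seed`.
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_len = 10000L, n_sites = 20L,
                            enzyme = get_enzyme("HaeIII"), seed = 1L) {
  stopifnot(n_chrom >= 1L, chrom_len >= 1L, n_sites >= 0L)
  m <- nchar(enzyme$site)
  if (n_sites > 0 && n_sites * m > chrom_len - m) {
    stop("site density too high: ", n_sites, " sites of ", m,
         " bp cannot be planted without overlap in ", chrom_len, " bp")
  }
  set.seed(seed)
  genome <- character(n_chrom)
  planted <- vector("list", n_chrom)
  names(genome) <- names(planted) <- sprintf("chr%d", seq_len(n_chrom))
  for (i in seq_len(n_chrom)) {
    for (attempt in 1:20) {
      chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
      chars <- scrub_sites(chars, enzyme$site)
      pos <- integer(0)
      if (n_sites > 0L) {
        ok <- FALSE
        for (draw in 1:100) {
          pos <- sort(sample.int(chrom_len - m + 1L, n_sites))
          if (n_sites == 1L || min(diff(pos)) >= m) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place ", n_sites,
                      " non-overlapping sites; lower the density")
        chars <- plant_site(chars, enzyme$site, pos)
      }
      s <- paste(chars, collapse = "")
      if (identical(site_starts(s, enzyme$site), as.integer(pos))) {
        genome[i] <- s
        planted[[i]] <- as.integer(pos)
        break
      }
      if (attempt == 20L) stop("site planting failed to converge")
    }
  }
  structure(list(genome = genome, planted = planted,
                 enzyme = enzyme, seed = seed),
            class = "sim_genome")
}

#' Simulate a genome whose digest yields evenly spaced in-window fragments
#'
#' Plants pairs of recognition sites `fragment_length` apart at regular
#' spacing, so that digestion followed by size selection recovers exactly
#' the planted target fragments; the long inter-pair fragments fall outside
#' any realistic size window.  This emulates the reduced-representation
#' design: sequencing targets tile the genome sparsely and evenly.
#'
#' @param chrom_len Chromosome length in bp.
#' @param spacing Distance between consecutive planted fragments in bp.
#' @param fragment_length Length of each planted fragment (distance between
#'   the two cut points), in bp.
#' @param enzyme A [restriction_enzyme()].
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @return A list of class `sim_genome` with an extra element
#'   `target_truth`: a `GRanges` of the planted fragment intervals.
#' @export
simulate_target_genome <- function(chrom_len = 2e6, spacing = 2000L,
                                   fragment_length = 110L,
                                   enzyme = get_enzyme("HaeIII"), seed = 1L,
                                   n_chrom = 1L) {
  m <- nchar(enzyme$site)
  if (spacing < fragment_length + 2L * m + 10L) {
    stop("spacing too small for the requested fragment length")
  }
  set.seed(seed)
  genome <- character(n_chrom)
  names(genome) <- sprintf("chr%d", seq_len(n_chrom))
  truth <- list()
  for (i in seq_len(n_chrom)) {
    chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    chars <- scrub_sites(chars, enzyme$site)
    b <- seq(from = 501L, by = spacing,
             to = chrom_len - fragment_length - m - 500L)
    chars <- plant_site(chars, enzyme$site, c(b, b + fragment_length))
    s <- paste(chars, collapse = "")
    expect <- sort(c(b, b + fragment_length))
    if (!identical(site_starts(s, enzyme$site), as.integer(expect))) {
      stop("site planting failed to converge")
    }
    genome[i] <- s
    # fragment between the two cuts: 1-based [b + offset, b + offset + L - 1]
    truth[[i]] <- GenomicRanges::GRanges(
      names(genome)[i],
      IRanges::IRanges(start = b + enzyme$cut_offset,
                       width = fragment_length))
  }
  gr <- suppressWarnings(do.call(c, truth))
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- rep(as.integer(chrom_len), n_chrom)
  structure(list(genome = genome, planted = NULL, enzyme = enzyme,
                 seed = seed, target_truth = gr),
            class = "sim_genome")
}

#' Build a two-population allele-frequency model
#'
#' Houses the per-site alternative-allele frequencies of each population
#' and the cohort composition.  Individuals are labelled
#' `<pop><index>` (e.g. `WA01`).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param freq Numeric vector (shared across populations) or matrix with
#'   one column per population, of alternative-allele frequencies in
#'   `[0, 1]`.
#' @param n_ind Named integer vector: individuals per population
#'   (default `c(WA = 15, SK = 16)`, a two-population cohort of 31).
#' @param seqlengths Optional named vector of chromosome lengths, used to
#'   validate sweep regions.
#' @return An object of class `population_model`.
#' @export
population_model <- function(sites, freq, n_ind = c(WA = 15L, SK = 16L),
                             seqlengths = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (is.null(names(n_ind)) || any(!nzchar(names(n_ind))) || any(n_ind < 1L)) {
    stop("n_ind must be a named vector with at least one individual per population")
  }
  if (is.vector(freq)) {
    freq <- matrix(rep(freq, length(n_ind)), ncol = length(n_ind))
  }
  freq <- as.matrix(freq)
  colnames(freq) <- names(n_ind)
  if (nrow(freq) != nrow(sites)) stop("freq must have one row per site")
  if (any(freq < 0 | freq > 1)) stop("allele frequencies must lie in [0, 1]")
  individuals <- data.frame(
    individual = unlist(lapply(names(n_ind), function(p)
      sprintf("%s%02d", p, seq_len(n_ind[[p]])))),
    population = rep(names(n_ind), n_ind),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(individuals$individual)) stop("individual ids must be unique")
  structure(list(sites = sites, freq = freq, n_ind = n_ind,
                 individuals = individuals, seqlengths = seqlengths),
            class = "population_model")
}

#' Plant a divergence sweep into a population model
#'
#' Sets the allele-frequency differential of every SNP inside `region` to
#' `differential`, by assigning frequencies `(1 + d)/2` and `(1 - d)/2` to
#' the two populations (`d = 1` fixes alternative alleles in opposite
#' populations).  A zero differential leaves the model untouched.
#'
#' @param model A [population_model()] with exactly two populations.
#' @param chrom,start,end Region (1-based, inclusive).
#' @param differential Target `|p1 - p2|` in `[0, 1]`.
#' @return The modified model.
#' @export
plant_sweep <- function(model, chrom, start, end, differential) {
  stopifnot(inherits(model, "population_model"))
  if (ncol(model$freq) != 2L) stop("plant_sweep needs exactly two populations")
  if (differential < 0 || differential > 1) stop("differential must lie in [0, 1]")
  if (!is.null(model$seqlengths)) {
    if (!chrom %in% names(model$seqlengths) ||
        start < 1 || end > model$seqlengths[[chrom]]) {
      stop("sweep region outside the genome")
    }
  }
  if (start > end) stop("sweep region with start > end")
  if (differential == 0) return(model)
  idx <- model$sites$chrom == chrom & model$sites$pos >= start &
    model$sites$pos <= end
  model$freq[idx, 1] <- (1 + differential) / 2
  model$freq[idx, 2] <- (1 - differential) / 2
  model
}

#' Draw true diploid genotypes under Hardy-Weinberg proportions
#'
#' Each individual's genotype at each site is the sum of two independent
#' Bernoulli(`p`) allele copies, with `p` the individual's population
#' frequency.
#'
#' @param model A [population_model()].
#' @param seed Integer seed.
#' @return An object of class `truth_set`: `sites`, `geno` (integer matrix
#'   sites x individuals with values 0/1/2 alternative-allele copies),
#'   `individuals` (assignment data.frame), `freq`.
#' @export
simulate_genotypes <- function(model, seed = 1L) {
  stopifnot(inherits(model, "population_model"))
  set.seed(seed)
  ns <- nrow(model$sites)
  cols <- lapply(colnames(model$freq), function(p) {
    n <- model$n_ind[[p]]
    pr <- model$freq[, p]
    matrix(rbinom(ns * n, 1L, pr) + rbinom(ns * n, 1L, pr), nrow = ns)
  })
  geno <- do.call(cbind, cols)
  dimnames(geno) <- list(site_key(model$sites), model$individuals$individual)
  structure(list(sites = model$sites, geno = geno,
                 individuals = model$individuals, freq = model$freq),
            class = "truth_set")
}

#' Construct a truth set directly
#'
#' Wraps an explicit genotype matrix as a `truth_set`, for experiments
#' that need a fixed genotype composition (e.g. all-heterozygote panels)
#' rather than Hardy-Weinberg draws.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param geno Integer matrix (0/1/2), sites x individuals, with
#'   individual ids as column names.
#' @param populations Optional named character vector
#'   (individual -> population); defaults to one population `"pop1"`.
#' @param freq Optional per-site frequency matrix.
#' @return An object of class `truth_set`.
#' @export
truth_set <- function(sites, geno, populations = NULL, freq = NULL) {
  geno <- as.matrix(geno)
  if (nrow(geno) != nrow(sites)) stop("one genotype row per site required")
  if (!all(geno %in% 0:2)) stop("truth genotypes must be 0/1/2")
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("ind%02d", seq_len(ncol(geno)))
  }
  if (is.null(populations)) {
    populations <- setNames(rep("pop1", ncol(geno)), colnames(geno))
  }
  individuals <- data.frame(individual = colnames(geno),
                            population = unname(populations[colnames(geno)]),
                            stringsAsFactors = FALSE)
  rownames(geno) <- site_key(sites)
  structure(list(sites = sites, geno = geno, individuals = individuals,
                 freq = freq),
            class = "truth_set")
}

#' Simulate quality-passing allelic read counts
#'
#' Per (site, individual): depth is Poisson(`mean_depth`); each read
#' reports the allele of a uniformly chosen chromosome copy, flipped with
#' probability `error_rate`.  Counts are quality-passing by construction
#' (base/mapping-quality filtering is modelled as already applied).
#'
#' @param truth A `truth_set` from [simulate_genotypes()].
#' @param mean_depth Mean per-site coverage (> 0).
#' @param error_rate Per-read allele-flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A [site_counts()] object.
#' @export
simulate_counts <- function(truth, mean_depth = 40, error_rate = 0.001,
                            seed = 1L) {
  stopifnot(inherits(truth, "truth_set"))
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must lie in [0, 0.5)")
  set.seed(seed)
  g <- truth$geno
  n <- length(g)
  dp <- matrix(rpois(n, mean_depth), nrow = nrow(g), dimnames = dimnames(g))
  palt <- (g / 2) * (1 - error_rate) + (1 - g / 2) * error_rate
  alt <- matrix(rbinom(n, dp, palt), nrow = nrow(g), dimnames = dimnames(g))
  site_counts(truth$sites, ref = dp - alt, alt = alt)
}

#' Per-individual, per-site allelic read counts
#'
#' The substrate of both genotype callers: quality-passing reference and
#' alternative read counts per (site, individual).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param ref,alt Non-negative integer matrices, sites x individuals, with
#'   identical dimensions and column names (individual ids).
#' @param other Optional matrix of third-allele read counts.
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(sites, ref, alt, other = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt))) stop("ref and alt dimensions differ")
  if (nrow(ref) != nrow(sites)) stop("one count row per site required")
  if (any(ref < 0) || any(alt < 0)) stop("negative read counts")
  if (is.null(colnames(ref)) && !is.null(colnames(alt))) colnames(ref) <- colnames(alt)
  if (is.null(colnames(ref))) {
    colnames(ref) <- colnames(alt) <- sprintf("ind%02d", seq_len(ncol(ref)))
  }
  colnames(alt) <- colnames(ref)
  key <- site_key(sites)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) sites")
  rownames(ref) <- rownames(alt) <- key
  if (!is.null(other)) {
    other <- as.matrix(other)
    if (!identical(dim(other), dim(ref))) stop("other counts dimensions differ")
    dimnames(other) <- dimnames(ref)
  }
  structure(list(sites = sites, ref = ref, alt = alt, other = other,
                 individuals = colnames(ref)),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat("<site_counts> ", nrow(x$sites), " sites x ", length(x$individuals),
      " individuals\n", sep = "")
  invisible(x)
}

#' Simulate a full RRL cohort with a planted divergence sweep
#'
#' End-to-end study generator: a genome whose digest yields evenly spaced
#' in-window target fragments, SNP sites placed only inside target regions,
#' a two-population frequency model with a sweep region at a fixed
#' frequency differential, Hardy-Weinberg truth genotypes and read counts.
#' Background SNPs are kept at least `margin` bp away from the sweep
#' region, so every scan window overlapping the sweep contains sweep SNPs
#' only.
#'
#' @param seed Integer seed driving the whole generator.
#' @param chrom_len,spacing,fragment_length,enzyme Passed to
#'   [simulate_target_genome()].
#' @param min_len,max_len Size-selection window in bp.
#' @param n_ind Named cohort composition.
#' @param n_background_snps Number of neutral SNPs (shared frequencies,
#'   drawn uniformly on `freq_range`).
#' @param sweep_start,sweep_width Sweep region (1-based start, width bp);
#'   set `sweep_width = 0` for no sweep.
#' @param n_sweep_snps SNPs planted inside the sweep region (one per
#'   target fragment).
#' @param margin Background-SNP exclusion margin around the sweep, bp.
#' @param mean_depth,error_rate Read-count model.
#' @param freq_range Range of background allele frequencies.
#' @param differential Sweep frequency differential.
#' @return A list: `genome` (`sim_genome`), `targets` (`target_selection`),
#'   `model`, `truth`, `counts`, `sweep` (`GRanges` or NULL), `seed`.
#' @export
simulate_rrl_cohort <- function(seed = 1L, chrom_len = 2e6, spacing = 2000L,
                                fragment_length = 110L,
                                enzyme = get_enzyme("HaeIII"),
                                min_len = 104L, max_len = 123L,
                                n_ind = c(WA = 15L, SK = 16L),
                                n_background_snps = 400L,
                                sweep_start = 1000001L, sweep_width = 1e5,
                                n_sweep_snps = 50L, margin = 1e5,
                                mean_depth = 40, error_rate = 0.001,
                                freq_range = c(0.05, 0.95),
                                differential = 1) {
  sim <- simulate_target_genome(chrom_len = chrom_len, spacing = spacing,
                                fragment_length = fragment_length,
                                enzyme = enzyme, seed = seed)
  targets <- select_fragments(digest(sim$genome, enzyme), min_len, max_len)
  tg <- targets$regions
  chrom <- names(sim$genome)[1]
  has_sweep <- sweep_width > 0 && n_sweep_snps > 0
  sweep <- NULL
  set.seed(seed + 1L)
  pick_pos <- function(regions, n, one_per_region = TRUE) {
    if (length(regions) < n) {
      stop("not enough target fragments to place ", n, " SNPs")
    }
    idx <- sort(sample.int(length(regions), n))
    st <- GenomicRanges::start(regions)[idx]
    en <- GenomicRanges::end(regions)[idx]
    st + floor(runif(n) * (en - st + 1))
  }
  pos <- integer(0); swept <- logical(0)
  if (has_sweep) {
    sweep_end <- sweep_start + sweep_width - 1
    sweep <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(sweep_start, sweep_end))
    in_sweep <- GenomicRanges::start(tg) >= sweep_start &
      GenomicRanges::end(tg) <= sweep_end
    in_margin <- GenomicRanges::end(tg) >= sweep_start - margin &
      GenomicRanges::start(tg) <= sweep_end + margin
    pos_sweep <- pick_pos(tg[in_sweep], n_sweep_snps)
    pos_bg <- pick_pos(tg[!in_margin], n_background_snps)
    pos <- c(pos_bg, pos_sweep)
    swept <- c(rep(FALSE, n_background_snps), rep(TRUE, n_sweep_snps))
  } else {
    pos <- pick_pos(tg, n_background_snps)
    swept <- rep(FALSE, n_background_snps)
  }
  o <- order(pos)
  pos <- pos[o]; swept <- swept[o]
  ref <- toupper(substring(sim$genome[[chrom]], pos, pos))
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1), USE.NAMES = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  p0 <- runif(nrow(sites), freq_range[1], freq_range[2])
  model <- population_model(sites, p0, n_ind = n_ind,
                            seqlengths = genome_lengths(sim$genome))
  if (has_sweep) {
    model <- plant_sweep(model, chrom, sweep_start,
                         sweep_start + sweep_width - 1, differential)
  }
  truth <- simulate_genotypes(model, seed = seed + 2L)
  counts <- simulate_counts(truth, mean_depth = mean_depth,
                            error_rate = error_rate, seed = seed + 3L)
  list(genome = sim, targets = targets, model = model, truth = truth,
       counts = counts, sweep = sweep, seed = seed)
}
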