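test_that("hard-filter bands assign genotypes by alternative-allele fraction", {
  expect_identical(hard_filter_call(18, 2), 0L)    # f = 0.10 -> homref
  expect_identical(hard_filter_call(10, 10), 1L)   # f = 0.50 -> het
  expect_identical(hard_filter_call(33, 7), NA_integer_)  # f = 0.175 borderline
  expect_identical(hard_filter_call(5, 4), NA_integer_)   # depth 9 < 10
  expect_identical(hard_filter_call(0, 0), NA_integer_)   # no data
  expect_identical(hard_filter_call(2, 38), 2L)    # f = 0.95 -> homalt
  expect_error(hard_filter_call(-1, 3), "negative")
})

test_that("hard filter matches the integer rule-table oracle on a grid", {
  set.seed(5)
  for (i in 1:300) {
    d <- sample(0:80, 1)
    a <- sample(0:d, 1)
    expect_identical(hard_filter_call(d - a, a), hard_filter_oracle(d - a, a),
                     info = sprintf("ref=%d alt=%d", d - a, a))
  }
})

test_that("likelihood caller behaves like a maximum-posterior genotyper", {
  r <- likelihood_call(40, 0, error_rate = 0.001)
  expect_identical(r$genotype, 0L)
  expect_identical(r$gq, 99L)  # capped

  expect_identical(likelihood_call(20, 20, error_rate = 0.001)$genotype, 1L)
  expect_identical(likelihood_call(0, 40, error_rate = 0.001)$genotype, 2L)
  expect_identical(likelihood_call(0, 0)$genotype, NA_integer_)

  expect_error(likelihood_call(5, 5, error_rate = 0.7), "error_rate")
  expect_error(likelihood_call(5, 5, het_prior = 0.9), "het_prior")
})

test_that("genotype posteriors sum to one", {
  set.seed(8)
  d <- sample(0:60, 200, replace = TRUE)
  a <- rbinom(200, d, runif(200))
  r <- likelihood_call(d - a, a, error_rate = 0.01)
  expect_true(all(abs(rowSums(r$posterior) - 1) < 1e-12))
  raf <- likelihood_call(d - a, a, error_rate = 0.01, af = 0.3)
  expect_true(all(abs(rowSums(raf$posterior) - 1) < 1e-12))
})

test_that("likelihood calls converge to truth at high depth", {
  n <- 500
  sites <- data.frame(chrom = "chr1", pos = 50L * seq_len(n),
                      ref = "A", alt = "C")
  set.seed(21)
  m <- population_model(sites, runif(n, 0.1, 0.9), n_ind = c(P = 10))
  truth <- simulate_genotypes(m, seed = 22)
  counts <- simulate_counts(truth, mean_depth = 40, error_rate = 0.001,
                            seed = 23)
  cs <- call_population(counts, "likelihood")
  called <- !is.na(cs$geno)
  expect_gte(mean(cs$geno[called] == truth$geno[called]), 0.99)
})

test_that("cohort calling flags non-variant sites and applies depth gates", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                      ref = "A", alt = "G")
  ref <- rbind(c(40, 40, 40), c(20, 20, 20), c(20, 4, 25))
  alt <- rbind(c(0, 0, 0), c(18, 21, 0), c(20, 4, 26))
  counts <- site_counts(sites, ref, alt)
  cs <- call_population(counts, "likelihood", error_rate = 0.001)
  expect_equal(cs$sites$variant, c(FALSE, TRUE, TRUE))
  expect_length(variant_sites(cs), 2L)
  # depth 8 below the minimum -> missing; others called
  expect_true(is.na(cs$geno[3, 2]))
  expect_false(anyNA(cs$geno[3, c(1, 3)]))
  # a single heterozygote among homrefs keeps the site variant
  expect_equal(sum(cs$geno[2, ] == 1L, na.rm = TRUE), 2L)

  dup <- sites[c(1, 1, 2), ]
  expect_error(site_counts(dup, ref, alt), "duplicate")
})

test_that("raising min_depth never increases the number of calls", {
  set.seed(44)
  d <- matrix(rpois(600, 12), 60, 10)
  a <- matrix(rbinom(600, as.vector(d), 0.5), 60, 10)
  n_prev <- Inf
  for (md in c(5, 10, 15, 20)) {
    g <- hard_filter_call(d - a, a, caller_thresholds(min_depth = md))
    expect_lte(sum(!is.na(g)), n_prev)
    n_prev <- sum(!is.na(g))
  }
})

test_that("sites with third-allele support are flagged multi-allelic", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "G")
  other <- rbind(c(1, 1), c(1, 0))  # site 1 has 2 third-allele reads
  counts <- site_counts(sites, matrix(10, 2, 2), matrix(10, 2, 2),
                        other = other)
  cs <- call_population(counts, "hard_filter")
  expect_equal(cs$sites$multiallelic, c(TRUE, FALSE))
  expect_length(variant_sites(cs), 1L)
})
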