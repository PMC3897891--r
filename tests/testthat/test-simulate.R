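test_that("planted recognition sites are recovered exactly by the digest", {
  sg <- simulate_genome(n_chrom = 1, chrom_len = 10000, n_sites = 20, seed = 3)
  fr <- digest(sg$genome, sg$enzyme)
  expect_equal(length(fr), 21L)  # 20 internal cuts -> 21 fragments

  sg0 <- simulate_genome(chrom_len = 2000, n_sites = 0, seed = 3)
  expect_equal(length(digest(sg0$genome, sg0$enzyme)), 1L)

  expect_error(simulate_genome(chrom_len = 50, n_sites = 40),
               "density too high")
})

test_that("the generator is fully deterministic under a fixed seed", {
  a <- simulate_genome(chrom_len = 3000, n_sites = 5, seed = 9)
  b <- simulate_genome(chrom_len = 3000, n_sites = 5, seed = 9)
  expect_identical(a$genome, b$genome)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(a$genome, f1); write_fasta(b$genome, f2)
  expect_identical(readLines(f1), readLines(f2))

  m <- population_model(data.frame(chrom = "chr1", pos = c(10, 20),
                                   ref = "A", alt = "C"), c(0.3, 0.7))
  c1 <- simulate_counts(simulate_genotypes(m, seed = 5), seed = 6)
  c2 <- simulate_counts(simulate_genotypes(m, seed = 5), seed = 6)
  expect_identical(c1$alt, c2$alt)
})

test_that("genotypes follow the population allele frequencies", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                      ref = "A", alt = "G")
  m0 <- population_model(sites, c(0, 0, 0), n_ind = c(P = 20))
  expect_true(all(simulate_genotypes(m0, 1)$geno == 0L))
  m1 <- population_model(sites, c(1, 1, 1), n_ind = c(P = 20))
  expect_true(all(simulate_genotypes(m1, 1)$geno == 2L))

  # Hardy-Weinberg: het fraction at p = 0.5 is 0.5 within 3 binomial s.e.
  big <- population_model(data.frame(chrom = "chr1", pos = 1, ref = "A",
                                     alt = "G"),
                          0.5, n_ind = c(P = 10000))
  het <- mean(simulate_genotypes(big, 2)$geno == 1L)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("read counts follow the depth and error model", {
  sites <- data.frame(chrom = "chr1", pos = 1:500 * 10, ref = "A", alt = "G")
  homref <- truth_set(sites, matrix(0L, 500, 4))

  # no sequencing error: homozygous reference never yields alt reads
  m <- population_model(sites, rep(0, 500), n_ind = c(P = 4))
  cz <- simulate_counts(homref, mean_depth = 30, error_rate = 0, seed = 1)
  expect_true(all(cz$alt == 0L))

  # true het at large depth: alt fraction near 1/2
  het <- truth_set(sites, matrix(1L, 500, 4))
  ch <- simulate_counts(het, mean_depth = 2000, error_rate = 0, seed = 2)
  f <- ch$alt / (ch$ref + ch$alt)
  expect_lt(abs(mean(f) - 0.5), 3 * sqrt(0.25 / sum(ch$ref + ch$alt)))

  # error rate sets the expected alt fraction for homref
  ce <- simulate_counts(homref, mean_depth = 40, error_rate = 0.01, seed = 3)
  expect_lt(abs(sum(ce$alt) / sum(ce$ref + ce$alt) - 0.01),
            3 * sqrt(0.01 * 0.99 / sum(ce$ref + ce$alt)))

  expect_error(simulate_counts(homref, mean_depth = -1), "positive")
  expect_error(simulate_counts(homref, error_rate = 0.6), "0.5")
})

test_that("plant_sweep fixes opposite alleles inside the region only", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 5000, 9000),
                      ref = "A", alt = "G")
  m <- population_model(sites, c(0.3, 0.3, 0.3),
                        seqlengths = c(chr1 = 10000))
  sw <- plant_sweep(m, "chr1", 4000, 8000, 1)
  expect_equal(sw$freq[2, ], c(WA = 1, SK = 0))
  expect_equal(sw$freq[c(1, 3), 1], c(0.3, 0.3))

  expect_identical(plant_sweep(m, "chr1", 4000, 8000, 0), m)
  expect_error(plant_sweep(m, "chr1", 9000, 20000, 1), "outside")
  expect_error(plant_sweep(m, "chr1", 1, 10, 1.5), "\\[0, 1\\]")
})

test_that("estimated allele frequencies recover the generator truth", {
  n <- 300
  sites <- data.frame(chrom = "chr1", pos = 50L * seq_len(n),
                      ref = "A", alt = "C")
  set.seed(31)
  p <- runif(n, 0.05, 0.95)
  m <- population_model(sites, p)
  truth <- simulate_genotypes(m, seed = 32)
  counts <- simulate_counts(truth, mean_depth = 40, error_rate = 0.001,
                            seed = 33)
  cs <- call_population(counts, "likelihood")
  n_called <- rowSums(!is.na(cs$geno))
  phat <- rowSums(cs$geno, na.rm = TRUE) / (2 * n_called)
  se <- sqrt(p * (1 - p) / (2 * n_called))
  expect_gte(mean(abs(phat - p) <= 3 * se), 0.99)
})
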