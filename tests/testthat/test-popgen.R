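# build a two-population snp_table directly
mk_snp_table <- function(df, pops = c("WA", "SK")) {
  attr(df, "populations") <- pops
  class(df) <- c("snp_table", "data.frame")
  df
}

toy_snps <- function(p_wa, p_sk, pos = NULL, n_called = 10L) {
  n <- length(p_wa)
  mk_snp_table(data.frame(
    chrom = "chr1",
    pos = if (is.null(pos)) 1000L * seq_len(n) else pos,
    ref = "A", alt = "G",
    n_called_WA = n_called, n_het_WA = 0L,
    alt_copies_WA = round(2 * n_called * p_wa), p_WA = p_wa,
    poly_WA = p_wa > 0 & p_wa < 1,
    n_called_SK = n_called, n_het_SK = 0L,
    alt_copies_SK = round(2 * n_called * p_sk), p_SK = p_sk,
    poly_SK = p_sk > 0 & p_sk < 1))
}

test_that("site heterozygosity is the called-het fraction", {
  tab <- toy_snps(c(0.2, 0.5, 0.5), c(0.2, 0.5, 0.5))
  tab$n_het_WA <- c(4L, 0L, 10L)
  expect_equal(site_heterozygosity(tab, "WA"), c(0.4, 0, 1))
  expect_error(site_heterozygosity(tab, "XX"), "unknown population")
})

test_that("the allele-frequency differential follows its definition", {
  expect_equal(allele_freq_differential(1, 0), 1)
  expect_equal(allele_freq_differential(0.4, 0.4), 0)
  expect_equal(allele_freq_differential(0.6, 0.1), 0.5)
  expect_error(allele_freq_differential(1.2, 0), "\\[0, 1\\]")

  # biallelic identity D == |p1 - p2|, symmetry, range, on a full grid
  grid <- expand.grid(p1 = seq(0, 1, 0.05), p2 = seq(0, 1, 0.05))
  d <- allele_freq_differential(grid$p1, grid$p2)
  expect_equal(d, abs(grid$p1 - grid$p2))
  expect_equal(d, allele_freq_differential(grid$p2, grid$p1))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("the sliding-window scan flags dense high-D windows only", {
  sl <- c(chr1 = 300000L)
  # two fixed differences close together: only the first window holds both
  tab <- toy_snps(c(1, 1), c(0, 0), pos = c(10000L, 20000L))
  sc <- sliding_window_scan(tab, sl)
  expect_equal(sc$start[sc$outlier], 1L)
  expect_equal(sc$n_snps[1], 2L)
  expect_equal(sc$mean_d[1], 1)

  # a single SNP with D = 1 never qualifies (min_snps = 2)
  one <- toy_snps(1, 0, pos = 10000L)
  expect_false(any(sliding_window_scan(one, sl)$outlier))

  # no differentiation, no outliers; empty windows have missing mean D
  flat <- toy_snps(c(0.5, 0.5), c(0.5, 0.5), pos = c(10000L, 20000L))
  sf <- sliding_window_scan(flat, sl)
  expect_false(any(sf$outlier))
  expect_true(all(is.na(sf$mean_d[sf$n_snps == 0])))
})

test_that("the window grid tiles from position 1 with trailing partials", {
  sl <- c(chr1 = 260000L)
  tab <- toy_snps(0.5, 0.5, pos = 130000L)
  sc <- sliding_window_scan(tab, sl)
  expect_equal(sc$start, seq(1L, 260000L, by = 25000L))
  expect_equal(sc$end[1], 100000L)
  expect_equal(max(sc$end), 260000L)  # partial window clipped at the end
  # an interior SNP is counted in window/step = 4 windows
  expect_equal(sum(sc$n_snps), 4L)
  # excluding unplaced scaffolds removes their windows
  sl2 <- c(chr1 = 260000L, chrXY_random = 100000L)
  sc2 <- sliding_window_scan(tab, sl2, exclude = "_random$")
  expect_equal(unique(sc2$chrom), "chr1")
})

test_that("singletons and private SNPs follow their definitions", {
  # site 1: one alt copy overall (singleton, private to WA)
  # site 2: polymorphic in both; site 3: fixed alt in SK, absent in WA
  tab <- toy_snps(c(0.05, 0.5, 0), c(0, 0.5, 1))
  tab$alt_copies_WA <- c(1L, 10L, 0L)
  tab$alt_copies_SK <- c(0L, 10L, 20L)
  ov <- singleton_and_private(tab, scope = "overall")
  expect_equal(ov$flags$singleton, c(TRUE, FALSE, FALSE))
  expect_equal(ov$summary$pct_singletons, 100 / 3)
  expect_equal(ov$flags$private_WA, c(TRUE, FALSE, FALSE))
  expect_equal(ov$flags$private_SK, c(FALSE, FALSE, FALSE))

  pp <- singleton_and_private(tab, scope = "population")
  expect_equal(pp$flags$singleton_WA, c(TRUE, FALSE, FALSE))
  expect_equal(pp$summary$n_sites, c(2L, 1L))  # polymorphic sites per pop
})

test_that("the MAF spectrum folds frequencies at one half", {
  tab <- toy_snps(c(0.9, 0.5, 0.1), c(0.5, 0.5, 0.5))
  sp <- maf_spectrum(tab, "WA")
  expect_equal(sp$maf, c(0.1, 0.5, 0.1))
  expect_true(all(sp$density$x >= 0 & sp$density$x <= 0.5))
})

test_that("median site heterozygosity approaches 2p(1-p) on truth genotypes", {
  n <- 400
  sites <- data.frame(chrom = "chr1", pos = 100L * seq_len(n),
                      ref = "A", alt = "C")
  m <- population_model(sites, rep(0.3, n), n_ind = c(WA = 100, SK = 100))
  truth <- simulate_genotypes(m, seed = 12)
  cs <- callset(sites, truth$geno, caller = "truth")
  pops <- setNames(truth$individuals$population, truth$individuals$individual)
  tab <- population_filter(cs, pops)
  h <- site_heterozygosity(tab, "WA")
  expect_lt(abs(median(h) - 2 * 0.3 * 0.7), 0.03)
})
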