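test_that("site overlap partitions the union of SNP sites", {
  g <- matrix(1L, 3, 2)
  a <- toy_callset(g, caller = "A")
  # identical call sets: everything in the full intersection
  ov <- site_overlap(list(A = a, B = toy_callset(g, caller = "B")))
  expect_equal(ov$n_all, 3L)
  expect_equal(ov$private$pct_private, c(0, 0))

  # A has sites 1,2 variant; B has 2,3: one private each, one shared
  ga <- matrix(c(1L, 1L, 0L), 3, 1)
  gb <- matrix(c(0L, 1L, 1L), 3, 1)
  ov2 <- site_overlap(list(A = toy_callset(ga, "A"), B = toy_callset(gb, "B")))
  expect_equal(ov2$n_union, 3L)
  expect_equal(ov2$n_all, 1L)
  expect_equal(sort(ov2$venn$count), c(1L, 1L, 1L))
  expect_equal(sum(ov2$venn$count), ov2$n_union)  # partition sums to union
  expect_equal(ov2$private$pct_private, c(50, 50))

  # disjoint site lists: 100% private each
  gc <- matrix(c(1L, 0L, 0L), 3, 1)
  gd <- matrix(c(0L, 0L, 1L), 3, 1)
  ov3 <- site_overlap(list(A = toy_callset(gc, "A"), B = toy_callset(gd, "B")))
  expect_equal(ov3$n_all, 0L)
  expect_equal(ov3$private$pct_private, c(100, 100))
})

test_that("genotype concordance counts and classifies discordances", {
  g <- matrix(1L, 4, 3)
  a <- toy_callset(g, "A")
  same <- genotype_concordance(a, toy_callset(g, "B"))
  expect_true(all(same$per_individual$pct_identical == 100))
  expect_equal(same$totals$n_compared - same$totals$n_identical, 0L)

  # 10 shared sites, individual 1 discordant at one site (A het, B homref);
  # individual 2 keeps every site variant in B
  ga <- matrix(1L, 10, 2)
  gb <- matrix(1L, 10, 2)
  gb[1, 1] <- 0L
  cr <- genotype_concordance(toy_callset(ga, "A"), toy_callset(gb, "B"))
  i1 <- cr$per_individual[1, ]
  expect_equal(i1$n_compared, 10L)
  expect_equal(i1$pct_identical, 90)
  expect_equal(cr$totals$het_a_hom_b, 1L)
  expect_equal(cr$totals$hom_a_het_b, 0L)
  expect_equal(unname(cr$bias["A"]), 100)

  # entries missing in either set are excluded from n_compared
  gb2 <- gb; gb2[2, 1] <- NA_integer_
  cr2 <- genotype_concordance(toy_callset(ga, "A"), toy_callset(gb2, "B"))
  expect_equal(cr2$per_individual$n_compared[1], 9L)

  # symmetry up to swapping the bias labels
  cr_rev <- genotype_concordance(toy_callset(gb, "B"), toy_callset(ga, "A"))
  expect_equal(cr_rev$totals$hom_a_het_b, cr$totals$het_a_hom_b)
  expect_equal(unname(cr_rev$bias["A"]), unname(cr$bias["A"]))
})

test_that("intersecting call sets keeps only identical non-missing calls", {
  set.seed(3)
  g <- matrix(sample(c(0:2, NA), 30, TRUE), 10, 3)
  a <- toy_callset(g, "A")
  ii <- intersect_callsets(a, a)
  expect_identical(unname(ii$geno), unname(g))  # self-intersection: identity

  # total conflict: everything missing, nothing survives a population filter
  gb <- (g + 1L) %% 3L
  conflict <- intersect_callsets(a, toy_callset(gb, "B"))
  expect_true(all(is.na(conflict$geno)))
  expect_length(variant_sites(conflict), 0L)

  # concordance of an intersect with a parent is 100% where compared
  gb2 <- g; gb2[1, 1] <- NA_integer_
  ab <- intersect_callsets(a, toy_callset(gb2, "B"))
  cr <- genotype_concordance(ab, a)
  expect_equal(cr$totals$n_identical, cr$totals$n_compared)
})

test_that("validation-table scoring reproduces printed percentage splits", {
  # a hard-filter-style caller (A) against a probabilistic pair (B)
  cats <- data.frame(
    category = c("singleton by B", "singleton by A",
                 "hom by B / het by A", "het by B / hom by A"),
    n_snps = c(8, 4, 23, 23),
    n_genotypes = c(8, 4, 28, 23),
    n_true_a = c(1, 0, 3, 7),
    n_true_b = c(7, 4, 25, 16))
  vt <- validation_table(cats, concordant = c(114, 110))
  sc <- score_validation(vt)
  expect_equal(round_half_up(sc$by_category$pct_true_a, 2),
               c(12.5, 0, 10.71, 30.43))
  expect_equal(round_half_up(sc$by_category$pct_true_b, 2),
               c(87.5, 100, 89.29, 69.57))
  expect_equal(sc$total$n_genotypes, 63)
  expect_equal(round_half_up(sc$total$pct_true_a, 2), 17.46)
  expect_equal(round_half_up(sc$concordant$pct_correct, 2), 96.49)

  # a row fully won by one caller
  one <- validation_table(data.frame(category = "x", n_snps = 3,
                                     n_genotypes = 3, n_true_a = 3,
                                     n_true_b = 0))
  sc1 <- score_validation(one)
  expect_equal(sc1$by_category$pct_true_a, 100)
  expect_equal(sc1$by_category$pct_true_b, 0)

  expect_error(validation_table(data.frame(category = "bad", n_snps = 1,
                                           n_genotypes = 3, n_true_a = 1,
                                           n_true_b = 1)),
               "must equal")
})

test_that("outlier-window overlap uses the shared window grid", {
  grid <- data.frame(chrom = "chr1",
                     start = c(1, 25001, 50001, 75001),
                     end = c(100000, 125000, 150000, 175000))
  mk <- function(outl) {
    s <- grid; s$n_snps <- 5L; s$mean_d <- 0.5; s$outlier <- outl
    class(s) <- c("window_scan", "data.frame"); s
  }
  A <- mk(c(TRUE, TRUE, FALSE, FALSE))   # w1, w2
  B <- mk(c(FALSE, TRUE, FALSE, FALSE))  # w2
  C <- mk(c(FALSE, TRUE, TRUE, FALSE))   # w2, w3
  ov <- outlier_overlap(list(A = A, B = B, C = C))
  expect_equal(ov$n_union, 3L)
  expect_equal(ov$n_all, 1L)
  expect_equal(ov$pct_identical, 100 / 3)
  expect_equal(sum(ov$venn$count), ov$n_union)

  identical_ov <- outlier_overlap(list(A = A, A2 = A))
  expect_equal(identical_ov$pct_identical, 100)

  bad <- mk(c(TRUE, FALSE, FALSE, FALSE)); bad$start[2] <- 30000
  expect_error(outlier_overlap(list(A = A, bad = bad)), "grids differ")
})
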