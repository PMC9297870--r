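test_that("missingness filter removes loci first, then individuals, strictly", {
  # 18 individuals x 11 loci; locus L01 missing in 2/18 = 11.1%
  set.seed(31)
  n <- 18; L <- 11
  a <- matrix(sample(c(100L, 105L), n * L, TRUE), n, L,
              dimnames = list(paste0("i", 1:n), sprintf("L%02d", 1:L)))
  b <- a
  a[1:2, 1] <- b[1:2, 1] <- NA
  gm <- genotype_matrix(a, b, rep("p", n))
  res <- filter_missing(gm)
  expect_equal(res$report$loci_removed, "L01")
  expect_equal(res$report$individuals_removed, character(0))

  # a locus at exactly 10% missing is kept
  a2 <- matrix(100L, 20, 2, dimnames = list(paste0("i", 1:20), c("La", "Lb")))
  b2 <- a2
  a2[1:2, 1] <- b2[1:2, 1] <- NA  # 2/20 = 10%
  res2 <- filter_missing(genotype_matrix(a2, b2, rep("p", 20)))
  expect_equal(res2$report$loci_removed, character(0))

  # individuals are judged on the reduced locus set
  a3 <- matrix(100L, 10, 5, dimnames = list(paste0("i", 1:10), paste0("L", 1:5)))
  b3 <- a3
  a3[, 1] <- b3[, 1] <- NA            # locus 1: 100% missing -> removed
  a3[1, 2] <- b3[1, 2] <- NA          # i1: 1/4 = 25% on the reduced set
  res3 <- filter_missing(genotype_matrix(a3, b3, rep("p", 10)))
  expect_equal(res3$report$loci_removed, "L1")
  expect_equal(res3$report$individuals_removed, "i1")

  # no missing data -> identity
  gm4 <- toy_gm()
  gm4$a1[is.na(gm4$a1)] <- 215L; gm4$a2[is.na(gm4$a2)] <- 215L
  res4 <- filter_missing(gm4)
  expect_equal(res4$gm$a1, gm4$a1)
})

test_that("HWE Monte Carlo p-value matches the enumeration oracle", {
  # n = 5, all heterozygotes AB: allele counts (5, 5)
  a1 <- matrix(rep(1L, 5)); a2 <- matrix(rep(2L, 5))
  gm <- genotype_matrix(a1, a2, rep("p", 5))
  p_exact <- hwe_exact_enum(rep(1L, 5), rep(2L, 5))
  r <- hwe_exact_test(gm, 1, n_perm = 20000, seed = 33)
  expect_equal(r$p_value, p_exact, tolerance = 0.02)

  # a second, asymmetric configuration
  g1 <- c(1L, 1L, 1L, 2L, 2L, 3L)
  g2 <- c(1L, 2L, 3L, 2L, 3L, 3L)
  gm2 <- genotype_matrix(matrix(g1), matrix(g2), rep("p", 6))
  p_exact2 <- hwe_exact_enum(g1, g2)
  r2 <- hwe_exact_test(gm2, 1, n_perm = 20000, seed = 34)
  expect_equal(r2$p_value, p_exact2, tolerance = 0.02)

  mono <- genotype_matrix(matrix(rep(1L, 4)), matrix(rep(1L, 4)), rep("p", 4))
  rm <- hwe_exact_test(mono, 1)
  expect_equal(rm$p_value, 1)
  expect_true(rm$degenerate)
})

test_that("LD exact test flags self-association and stays calibrated on null pairs", {
  # two populations, both with a clearly polymorphic locus paired with itself
  set.seed(35)
  g <- sample(rep(c(100L, 105L, 110L), each = 16))
  h <- sample(rep(c(100L, 105L, 110L), each = 16))
  gm <- genotype_matrix(cbind(L1 = pmin(g, h), L2 = pmin(g, h)),
                        cbind(L1 = pmax(g, h), L2 = pmax(g, h)),
                        rep(c("p1", "p2"), each = 24))
  r <- ld_exact_test(gm, "L1", "L2", n_perm = 999, seed = 36)
  expect_lt(r$p_value, 0.01)

  # independently simulated loci: empirical rejection near alpha
  set.seed(37)
  rej <- 0; npairs <- 60
  for (i in seq_len(npairs)) {
    x1 <- sample(c(100L, 105L), 80, TRUE); x2 <- sample(c(100L, 105L), 80, TRUE)
    y1 <- sample(c(100L, 105L), 80, TRUE); y2 <- sample(c(100L, 105L), 80, TRUE)
    gm0 <- genotype_matrix(cbind(A = pmin(x1, x2), B = pmin(y1, y2)),
                           cbind(A = pmax(x1, x2), B = pmax(y1, y2)),
                           rep("p", 80))
    p <- ld_exact_test(gm0, "A", "B", n_perm = 200)$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_lte(rej / npairs, 0.15)  # 3 binomial SEs above 0.05
})

test_that("Fisher's combined probability test matches its closed form", {
  expect_equal(fisher_combine(0.2)$p, 0.2, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1))$X2, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  fc <- fisher_combine(c(0.05, 0.05))
  expect_equal(fc$X2, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(fc$df, 4L)
  # chi-square upper tail at df 4 in closed form: exp(-x/2) (1 + x/2)
  x <- -4 * log(0.05)
  expect_equal(fc$p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_warning(fisher_combine(c(0, 0.5)), "clamped")
})

test_that("rarefied allele counts match exhaustive enumeration", {
  expect_equal(rarefied_allele_count(c(3, 1), 2), rarefy_enum(c(3, 1), 2))
  set.seed(39)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    counts <- as.vector(stats::rmultinom(1, sample(4:8, 1), rep(1 / k, k)))
    counts <- counts[counts > 0]
    if (length(counts) < 1) next
    g <- sample(seq_len(sum(counts)), 1)
    expect_equal(rarefied_allele_count(counts, g), rarefy_enum(counts, g),
                 tolerance = 1e-12)
  }
  # monotone non-decreasing in g; equals the observed count at g = N
  counts <- c(5, 3, 1, 1)
  vals <- vapply(1:10, function(g) rarefied_allele_count(counts, g), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[10], 4)
})

test_that("diversity summaries use unbiased H_E and ratio-of-means F_IS", {
  # one locus, p = (0.5, 0.5), n = 5 -> unbiased H_E = (10/9) * 0.5
  a1 <- matrix(c(100L, 100L, 100L, 105L, 105L))
  a2 <- matrix(c(100L, 105L, 105L, 105L, 100L))
  gm <- genotype_matrix(a1, a2, rep("p", 5))
  div <- diversity_summary(gm, n_boot = 0)
  expect_equal(div$H_E, (10 / 9) * 0.5, tolerance = 1e-12)
  expect_equal(div$H_O, 3 / 5)
  expect_equal(div$F_IS, 1 - (3 / 5) / ((10 / 9) * 0.5), tolerance = 1e-12)

  # a fixed locus contributes 0 to both heterozygosities
  gm2 <- genotype_matrix(cbind(a1, 200L), cbind(a2, 200L), rep("p", 5))
  div2 <- diversity_summary(gm2, n_boot = 0)
  expect_equal(div2$H_E, (10 / 9) * 0.5 / 2, tolerance = 1e-12)

  # all-monomorphic population -> F_IS reported missing
  gm3 <- genotype_matrix(matrix(rep(100L, 4)), matrix(rep(100L, 4)),
                         rep("p", 4))
  expect_true(is.na(diversity_summary(gm3, n_boot = 0)$F_IS))

  # allele relabeling leaves H_E untouched
  gm4 <- gm; gm4$a1[gm4$a1 == 100L] <- 300L; gm4$a2[gm4$a2 == 100L] <- 300L
  expect_equal(diversity_summary(gm4, n_boot = 0)$H_E, div$H_E)
})

test_that("bootstrap intervals are seed-reproducible and ordered", {
  cfg <- simulation_config(n_populations = 2, seed = 41)
  gm <- simulate_ssr_dataset(cfg)$truth
  d1 <- diversity_summary(gm, n_boot = 200, seed = 42)
  d2 <- diversity_summary(gm, n_boot = 200, seed = 42)
  expect_identical(d1, d2)
  expect_true(all(d1$F_IS_lo <= d1$F_IS_hi))
})
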