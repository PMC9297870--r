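make_freq_table <- function(freq, counts) {
  structure(list(populations = rownames(counts), loci = colnames(counts),
                 freq = freq, counts = counts),
            class = "allele_freq_table")
}

test_that("Prevosti distance matches hand computations and its bounds", {
  counts <- matrix(10, 2, 2, dimnames = list(c("x", "y"), c("L1", "L2")))
  freq <- list(
    L1 = rbind(x = c(0.5, 0.5), y = c(0.25, 0.75)),
    L2 = rbind(x = c(1, 0), y = c(0.5, 0.5)))
  d <- prevosti_dist(make_freq_table(freq, counts))
  expect_equal(d["x", "y"], (1 / 4) * (0.5 + 1.0))  # = 0.375

  # identical frequencies -> 0; fully disjoint alleles -> 1
  same <- list(L1 = rbind(x = c(0.3, 0.7), y = c(0.3, 0.7)))
  d0 <- prevosti_dist(make_freq_table(same, counts[, 1, drop = FALSE]))
  expect_equal(d0["x", "y"], 0)
  disjoint <- list(L1 = rbind(x = c(1, 0), y = c(0, 1)),
                   L2 = rbind(x = c(0, 1), y = c(1, 0)))
  d1 <- prevosti_dist(make_freq_table(disjoint, counts))
  expect_equal(d1["x", "y"], 1)
})

test_that("allele frequencies renormalize over typed copies", {
  gm <- toy_gm()
  f <- allele_freqs(gm)
  expect_equal(unname(rowSums(f$freq$L1)), c(1, 1))
  expect_equal(f$counts["popB", "L1"], 4)  # one missing cell in popB
  # popA at L1: alleles 215 x3, 220 x2, 225 x1 over 6 copies
  expect_equal(unname(f$freq$L1["popA", ]), c(3, 2, 1) / 6)
})

test_that("NJ recovers 3-taxon trees by the closed-form three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  cop <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(cop, d)
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(la, (3 + 4 - 5) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reconstructs additive matrices exactly (random-tree oracle)", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(rownames(d))]
    nj <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("equidistant taxa resolve deterministically via the tie-break rule", {
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- ape::write.tree(neighbor_joining(d))
  t2 <- ape::write.tree(neighbor_joining(d))
  expect_identical(t1, t2)
  # the first pair by index order (A, B) is joined first
  expect_true(ape::is.monophyletic(ape::root(neighbor_joining(d), "D"),
                                   c("A", "B")))
})

test_that("bootstrap supports behave at the degenerate and separable extremes", {
  # all loci identical copies of one locus -> every bipartition at 100
  counts <- matrix(20, 4, 3, dimnames = list(paste0("p", 1:4), paste0("L", 1:3)))
  base <- rbind(p1 = c(1, 0, 0, 0), p2 = c(0, 1, 0, 0),
                p3 = c(0, 0.2, 0.8, 0), p4 = c(0, 0, 0.1, 0.9))
  f <- make_freq_table(list(L1 = base, L2 = base, L3 = base), counts)
  tr <- bootstrap_tree(f, n_reps = 100, seed = 45)
  expect_true(all(attr(tr, "support") == 100, na.rm = TRUE))

  # fixed seed -> identical supports
  cfg <- simulation_config(n_populations = 6, fst = 0.25, missing_rate = 0,
                           seed = 47)
  fa <- allele_freqs(simulate_ssr_dataset(cfg)$truth)
  s1 <- attr(bootstrap_tree(fa, n_reps = 60, seed = 48), "support")
  s2 <- attr(bootstrap_tree(fa, n_reps = 60, seed = 48), "support")
  expect_identical(s1, s2)
})

test_that("two well-separated clusters get near-unanimous bootstrap support", {
  # two groups of populations drawn from two very distinct ancestral pools
  set.seed(49)
  n_loci <- 12
  freq <- list(); counts <- matrix(30, 4, n_loci,
                                   dimnames = list(paste0("p", 1:4),
                                                   paste0("L", 1:n_loci)))
  for (l in seq_len(n_loci)) {
    anc1 <- c(0.9, 0.1, 0, 0); anc2 <- c(0, 0, 0.1, 0.9)
    jitter <- function(p) { q <- pmax(p + stats::rnorm(4, 0, 0.03), 0); q / sum(q) }
    freq[[paste0("L", l)]] <- rbind(p1 = jitter(anc1), p2 = jitter(anc1),
                                    p3 = jitter(anc2), p4 = jitter(anc2))
  }
  f <- make_freq_table(freq, counts)
  tr <- bootstrap_tree(f, n_reps = 200, seed = 50)
  sup <- attr(tr, "support")
  expect_true(any(sup > 95, na.rm = TRUE))  # the cluster bipartition
})

test_that("PCA of allele counts has the stated variance structure", {
  # two mirror-image individuals -> PC1 explains everything
  a1 <- rbind(c(100L, 200L), c(105L, 205L))
  a2 <- a1
  gm <- genotype_matrix(a1, a2, c("p", "p"))
  pc <- pca_individuals(gm)
  expect_equal(pc$pct_variance[1], 100)
  expect_equal(sum(pc$pct_variance), 100)
  expect_error(pca_individuals(gm_subset(gm, 1)), "at least 2")

  # pct_variance sums to 100 with missing-data imputation in play
  cfg <- simulation_config(n_populations = 3, missing_rate = 0.05, seed = 51)
  gm2 <- simulate_ssr_dataset(cfg)$truth
  pc2 <- pca_individuals(gm2)
  expect_equal(sum(pc2$pct_variance), 100, tolerance = 1e-9)
})

test_that("PC1-2 separate simulated clusters (k-means agreement)", {
  set.seed(63)
  accs <- vapply(1:5, function(s) {
    cfg <- simulation_config(n_populations = 3,
                             individuals_per_population = c(20, 20),
                             n_loci = 20, fst = 0.15, fis = 0,
                             missing_rate = 0, seed = 40 + s)
    gm <- simulate_ssr_dataset(cfg)$truth
    pc <- pca_individuals(gm)
    km <- stats::kmeans(pc$scores[, 1:2], 3, nstart = 20)
    tab <- table(km$cluster, gm$pop)
    sum(apply(tab, 1, max)) / sum(tab)
  }, numeric(1))
  expect_gt(stats::median(accs), 0.9)
})
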