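# Shared fixture builders and independent oracles.  Everything is built in
# code at test time; no binary fixtures.

# A small hand-built genotype matrix: 2 populations x 3 individuals x 2 loci.
toy_gm <- function() {
  a1 <- rbind(c(215L, 101L), c(215L, 106L), c(220L, 101L),
              c(225L, 111L), c(220L, 106L), c(NA, 111L))
  a2 <- rbind(c(220L, 106L), c(215L, 106L), c(225L, 101L),
              c(225L, 116L), c(225L, 111L), c(NA, 116L))
  rownames(a1) <- rownames(a2) <- paste0("i", 1:6)
  colnames(a1) <- colnames(a2) <- c("L1", "L2")
  genotype_matrix(a1, a2, rep(c("popA", "popB"), each = 3))
}

write_temp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Exhaustive-enumeration oracle for the HWE exact test: all pairings of the
# allele multiset into n genotypes, scored by the Levene conditional
# probability; p = total probability of tables no more probable than the
# observed one.
hwe_exact_enum <- function(g1, g2) {
  alleles <- c(g1, g2)
  n <- length(g1)
  geno_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  obs_tab <- table(geno_key(g1, g2))
  tab_prob <- function(tab) {
    # Levene: n! 2^h prod(allele!) / (prod(geno!) (2n)!)
    h <- sum(tab[vapply(strsplit(names(tab), " "),
                        function(x) x[1] != x[2], logical(1))])
    ac <- table(alleles)
    exp(lfactorial(n) + h * log(2) + sum(lfactorial(ac)) -
          sum(lfactorial(tab)) - lfactorial(2 * n))
  }
  # enumerate all distinct genotype tables by recursive pairing
  tabs <- new.env()
  recurse <- function(rem, acc) {
    if (length(rem) == 0L) {
      key <- paste(sort(acc), collapse = "|")
      if (is.null(tabs[[key]])) tabs[[key]] <- table(acc)
      return(invisible())
    }
    first <- rem[1]
    rest <- rem[-1]
    for (j in seq_along(rest)) {
      recurse(rest[-j], c(acc, geno_key(first, rest[j])))
    }
  }
  recurse(alleles, character())
  all_tabs <- as.list(tabs)
  probs <- vapply(all_tabs, tab_prob, numeric(1))
  p_obs <- tab_prob(obs_tab)
  sum(probs[probs <= p_obs + 1e-12]) / sum(probs)
}

# Enumeration oracle for rarefied allelic richness: mean number of distinct
# alleles over all size-g subsets of the gene copies.
rarefy_enum <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}
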