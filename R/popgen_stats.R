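# Missing-data filtering, exact tests (Monte Carlo with seeded RNG),
# Fisher's combined probability, and per-population diversity summaries
# with rarefied allelic richness and bootstrap F_IS confidence intervals.

#' Filter loci and individuals by missingness
#'
#' Loci with strictly more than `locus_thresh` missing data are removed
#' first; individuals with strictly more than `indiv_thresh` missing data
#' on the reduced locus set are removed second.  The order matters and is
#' recorded in the report.
#'
#' @param gm a [genotype_matrix()]
#' @param locus_thresh maximal tolerated missing fraction per locus
#' @param indiv_thresh maximal tolerated missing fraction per individual
#' @return `list(gm = filtered matrix, report = filter_report)` where the
#'   report lists `loci_removed`, `individuals_removed` and the thresholds
#' @export
filter_missing <- function(gm, locus_thresh = 0.10, indiv_thresh = 0.20) {
  miss <- gm_missing(gm)
  locus_frac <- colMeans(miss)
  drop_loci <- names(locus_frac)[locus_frac > locus_thresh]
  keep_loci <- setdiff(colnames(gm$a1), drop_loci)
  if (length(keep_loci) == 0L) stop("all loci removed by the missingness filter")
  ind_frac <- rowMeans(miss[, keep_loci, drop = FALSE])
  drop_ind <- rownames(gm$a1)[ind_frac > indiv_thresh]
  keep_ind <- setdiff(rownames(gm$a1), drop_ind)
  if (length(keep_ind) == 0L) stop("all individuals removed by the missingness filter")
  report <- structure(list(loci_removed = drop_loci,
                           individuals_removed = drop_ind,
                           locus_thresh = locus_thresh,
                           indiv_thresh = indiv_thresh),
                      class = "filter_report")
  list(gm = gm_subset(gm, keep_ind, keep_loci), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: removed", length(x$loci_removed), "locus/loci (>",
      x$locus_thresh * 100, "% missing) then", length(x$individuals_removed),
      "individual(s) (>", x$indiv_thresh * 100, "% missing)\n")
  if (length(x$loci_removed)) cat("  loci:", paste(x$loci_removed, collapse = ", "), "\n")
  if (length(x$individuals_removed)) cat("  individuals:",
                                         paste(x$individuals_removed, collapse = ", "), "\n")
  invisible(x)
}

#' Hardy-Weinberg exact test for one locus in one population
#'
#' Monte Carlo version of the exact test: the statistic is the conditional
#' (Levene) probability of the observed single-locus genotype array given
#' its allele counts, and the p-value is the proportion of tables -- formed
#' by randomly re-pairing the observed alleles -- whose conditional
#' probability is less than or equal to the observed one, with the
#' `(count + 1)/(n_perm + 1)` correction.
#'
#' @param gm a [genotype_matrix()]
#' @param locus locus name or index
#' @param population population id; `NULL` pools all individuals
#' @param n_perm number of Monte Carlo permutations
#' @param seed optional RNG seed for reproducibility
#' @return a `test_result` list: `unit`, `statistic` (observed conditional
#'   probability), `p_value`, `n_permutations`, `method`, `degenerate`
#' @export
hwe_exact_test <- function(gm, locus, population = NULL, n_perm = 10000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sel <- if (is.null(population)) rep(TRUE, nrow(gm$a1)) else gm$pop == population
  a1 <- gm$a1[sel, locus]; a2 <- gm$a2[sel, locus]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  if (length(a1) < 2L) stop("need at least 2 typed individuals")
  unit <- paste0("locus=", locus,
                 if (!is.null(population)) paste0(", population=", population))
  labs <- sort(unique(c(a1, a2)))
  if (length(labs) < 2L) {
    return(structure(list(unit = unit, statistic = 1, p_value = 1,
                          n_permutations = 0L, method = "hwe_mc_exact",
                          degenerate = TRUE), class = "test_result"))
  }
  g1 <- match(a1, labs); g2 <- match(a2, labs)
  res <- hwe_mc_cpp(g1, g2, length(labs), as.integer(n_perm))
  structure(list(unit = unit, statistic = exp(res$log_prob_obs),
                 p_value = (res$count_leq + 1) / (n_perm + 1),
                 n_permutations = as.integer(n_perm),
                 method = "hwe_mc_exact", degenerate = FALSE),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "[", x$unit, "] statistic =", signif(x$statistic, 4),
      " p =", signif(x$p_value, 4),
      if (isTRUE(x$degenerate)) " (degenerate)", "\n")
  invisible(x)
}

g_statistic <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  keep <- tab > 0
  2 * sum(tab[keep] * log(tab[keep] / e[keep]))
}

#' Linkage-disequilibrium exact test for a pair of loci
#'
#' Within each population the two-locus contingency table of single-locus
#' genotypes is scored by the log-likelihood-ratio G statistic; the null is
#' generated by permuting one locus's genotypes among individuals, holding
#' the other fixed (which preserves both single-locus genotype arrays).
#' Per-population p-values carry the `(count + 1)/(n_perm + 1)` correction
#' and are combined across populations with [fisher_combine()].
#'
#' @param gm a [genotype_matrix()]
#' @param locus_a,locus_b locus names or indices
#' @param n_perm permutations per population
#' @param seed optional RNG seed
#' @return a `test_result` list with the combined `p_value`, the combined
#'   chi-square `statistic`, and `per_population` p-values
#' @export
ld_exact_test <- function(gm, locus_a, locus_b, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(gm$pop)
  p_pop <- c()
  for (p in pops) {
    sel <- gm$pop == p
    gA <- paste(gm$a1[sel, locus_a], gm$a2[sel, locus_a])
    gB <- paste(gm$a1[sel, locus_b], gm$a2[sel, locus_b])
    ok <- !is.na(gm$a1[sel, locus_a]) & !is.na(gm$a1[sel, locus_b])
    gA <- gA[ok]; gB <- gB[ok]
    if (length(gA) < 2L) next
    fA <- factor(gA); fB <- factor(gB)
    if (nlevels(fA) < 2L || nlevels(fB) < 2L) next  # no information
    obs <- g_statistic(table(fA, fB))
    count <- 0L
    for (r in seq_len(n_perm)) {
      gperm <- g_statistic(table(fA, sample(fB)))
      if (gperm >= obs - 1e-12) count <- count + 1L
    }
    p_pop[p] <- (count + 1) / (n_perm + 1)
  }
  if (length(p_pop) == 0L) stop("no population carries information for this locus pair")
  comb <- fisher_combine(p_pop)
  structure(list(unit = paste0("loci=", locus_a, "x", locus_b),
                 statistic = comb$X2, p_value = comb$p,
                 df = comb$df, per_population = p_pop,
                 n_permutations = as.integer(n_perm),
                 method = "ld_mc_exact_fisher", degenerate = FALSE),
            class = "test_result")
}

#' Fisher's combined probability test
#'
#' `X^2 = -2 sum(log p_i)` on `2k` degrees of freedom.  Zero p-values are
#' clamped to the smallest positive double with a warning.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`
#' @return `list(X2, df, p)`
#' @export
fisher_combine <- function(p_values) {
  stopifnot(length(p_values) >= 1L, all(p_values >= 0), all(p_values <= 1))
  if (any(p_values == 0)) {
    warning("zero p-value(s) clamped to the smallest positive double")
    p_values[p_values == 0] <- .Machine$double.xmin
  }
  X2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(X2 = X2, df = df, p = stats::pchisq(X2, df, lower.tail = FALSE))
}

#' Expected allele count in a rarefied subsample
#'
#' `E[A(g)] = sum_a [1 - choose(N - N_a, g) / choose(N, g)]` for allele
#' counts `N_a` summing to `N` gene copies, the standard rarefaction
#' formula for allelic richness.
#'
#' @param counts integer vector of allele copy counts at one locus in one
#'   population
#' @param g rarefaction size in gene copies, `1 <= g <= sum(counts)`
#' @return expected number of distinct alleles in a random subsample of `g`
#'   copies
#' @export
rarefied_allele_count <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  stopifnot(g >= 1, g <= N)
  # lchoose-based for numerical stability at large N
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

pop_locus_stats <- function(gm) {
  # per (population, locus): typed copies, allele counts, H_O, H_E parts
  loci <- colnames(gm$a1)
  pops <- unique(gm$pop)
  res <- list()
  for (l in loci) {
    per_pop <- lapply(pops, function(p) {
      sel <- gm$pop == p
      a1 <- gm$a1[sel, l]; a2 <- gm$a2[sel, l]
      typed <- !is.na(a1)
      counts <- table(c(a1[typed], a2[typed]))
      list(n_typed = sum(typed), counts = counts,
           het = if (sum(typed) > 0) mean(a1[typed] != a2[typed]) else NA_real_)
    })
    names(per_pop) <- pops
    res[[l]] <- per_pop
  }
  res
}

unbiased_gene_diversity <- function(counts) {
  N <- sum(counts)
  if (N < 2L) return(NA_real_)
  p <- counts / N
  (N / (N - 1)) * (1 - sum(p^2))
}

#' Table of per-population diversity summaries
#'
#' One row per population: number of individuals, percent missing data,
#' number of alleles observed (summed across loci), percent of the total
#' alleles in the dataset (averaged across loci), rarefied allelic richness
#' (averaged across loci; rarefaction size per locus is the minimum typed
#' gene-copy count across populations, so populations are comparable),
#' observed and unbiased expected heterozygosity (averaged across loci),
#' and multilocus `F_IS = 1 - mean(H_O)/mean(H_E)` with a percentile
#' bootstrap confidence interval over individuals.
#'
#' @param gm a [genotype_matrix()]
#' @param n_boot bootstrap replicates for the F_IS interval (0 disables)
#' @param conf confidence level
#' @param seed optional RNG seed
#' @param rarefaction_g optional fixed rarefaction size (gene copies)
#'   overriding the per-locus minimum
#' @return a `diversity_summary` data frame
#' @export
diversity_summary <- function(gm, n_boot = 1000, conf = 0.95, seed = NULL,
                              rarefaction_g = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- colnames(gm$a1)
  pops <- unique(gm$pop)
  stats_pl <- pop_locus_stats(gm)
  total_alleles <- vapply(loci, function(l) {
    length(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
  }, numeric(1))
  g_locus <- vapply(loci, function(l) {
    n <- vapply(stats_pl[[l]], function(s) 2 * s$n_typed, numeric(1))
    n <- n[n > 0]
    if (length(n) == 0L) return(NA_real_)
    if (is.null(rarefaction_g)) min(n) else rarefaction_g
  }, numeric(1))

  alpha <- (1 - conf) / 2
  rows <- lapply(pops, function(p) {
    sel <- gm$pop == p
    per_locus <- lapply(loci, function(l) stats_pl[[l]][[p]])
    names(per_locus) <- loci
    ho <- vapply(per_locus, function(s) s$het, numeric(1))
    he <- vapply(per_locus, function(s) unbiased_gene_diversity(s$counts),
                 numeric(1))
    n_alleles <- vapply(per_locus, function(s) sum(s$counts > 0), numeric(1))
    rich <- vapply(loci, function(l) {
      s <- per_locus[[l]]
      if (s$n_typed == 0L || is.na(g_locus[l]) ||
          2 * s$n_typed < g_locus[l]) return(NA_real_)
      rarefied_allele_count(as.numeric(s$counts), g_locus[l])
    }, numeric(1))
    mean_ho <- mean(ho, na.rm = TRUE)
    mean_he <- mean(he, na.rm = TRUE)
    fis <- if (is.finite(mean_he) && mean_he > 0) 1 - mean_ho / mean_he
           else NA_real_
    ci <- c(NA_real_, NA_real_)
    if (n_boot > 0 && !is.na(fis)) {
      boot <- fis_bootstrap(gm, which(sel), n_boot)
      boot <- boot[!is.na(boot)]
      if (length(boot) > 0) ci <- stats::quantile(boot, c(alpha, 1 - alpha),
                                                  names = FALSE)
    }
    data.frame(population_id = p,
               n_genotyped = sum(sel),
               pct_missing = 100 * mean(is.na(gm$a1[sel, , drop = FALSE])),
               n_alleles_observed = sum(n_alleles),
               pct_total_alleles = 100 * mean(n_alleles / total_alleles),
               allelic_richness = mean(rich, na.rm = TRUE),
               H_O = mean_ho, H_E = mean_he,
               F_IS = fis, F_IS_lo = ci[1], F_IS_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_summary", "data.frame")
  out
}

# Multilocus F_IS recomputed on bootstrap resamples of individuals.
fis_bootstrap <- function(gm, rows, n_boot) {
  a1 <- gm$a1[rows, , drop = FALSE]
  a2 <- gm$a2[rows, , drop = FALSE]
  n <- length(rows); L <- ncol(a1)
  het <- a1 != a2
  vapply(seq_len(n_boot), function(b) {
    take <- sample.int(n, n, replace = TRUE)
    ho <- colMeans(het[take, , drop = FALSE], na.rm = TRUE)
    he <- vapply(seq_len(L), function(l) {
      al <- c(a1[take, l], a2[take, l])
      unbiased_gene_diversity(table(al[!is.na(al)]))
    }, numeric(1))
    mh <- mean(ho, na.rm = TRUE); mhe <- mean(he, na.rm = TRUE)
    if (is.finite(mhe) && mhe > 0) 1 - mh / mhe else NA_real_
  }, numeric(1))
}
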