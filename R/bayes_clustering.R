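# Simplified admixture-model Gibbs sampler (a desk-scale stand-in for the
# structure program, without the LOCPRIOR model), greedy label alignment
# across runs, and Evanno delta-K model choice.

gm_to_coded <- function(gm) {
  loci <- colnames(gm$a1)
  n_alleles <- integer(length(loci))
  n <- nrow(gm$a1)
  alleles <- matrix(0L, n, 2L * length(loci))
  for (l in seq_along(loci)) {
    labs <- sort(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
    n_alleles[l] <- max(length(labs), 1L)
    c1 <- match(gm$a1[, l], labs); c2 <- match(gm$a2[, l], labs)
    c1[is.na(c1)] <- 0L; c2[is.na(c2)] <- 0L
    alleles[, 2L * l - 1L] <- c1
    alleles[, 2L * l] <- c2
  }
  list(alleles = alleles, n_alleles = n_alleles)
}

#' Run the admixture-model Gibbs sampler
#'
#' Each individual's genome is modelled as a mixture over `K`
#' cluster-specific allele-frequency profiles: allele-origin indicators
#' `z`, cluster frequencies `P ~ Dirichlet(lambda)` per locus, and
#' admixture proportions `Q_i ~ Dirichlet(alpha, ..., alpha)` are updated
#' by Gibbs sampling from their full conditionals; missing alleles are
#' skipped.  The run-level log-likelihood summary is
#' `L_estimate = mean(lnL) - var(lnL)/2` over the post-burn-in sweeps,
#' where `lnL` is the complete-data log-likelihood `log P(X | Z, P)` at
#' the sampled assignments -- the deviance-style "estimated ln probability
#' of data" the Evanno method is defined on.  The observed-data mixture
#' trace `log P(X | Q, P)` is also returned as `loglik_mix`.
#'
#' @param gm a filtered [genotype_matrix()]
#' @param K number of clusters (`1 <= K <=` number of individuals)
#' @param burn_in discarded initial sweeps
#' @param n_sweeps retained sweeps after burn-in
#' @param alpha initial symmetric Dirichlet parameter on admixture
#'   proportions
#' @param lambda Dirichlet prior on cluster allele frequencies
#' @param infer_alpha update `alpha` by Metropolis sampling under a uniform
#'   prior on `(0, alpha_max]` (the behaviour of the program this sampler
#'   stands in for); set `FALSE` to keep `alpha` fixed
#' @param alpha_max upper bound of the uniform prior on `alpha`
#' @param alpha_prop_sd standard deviation of the normal proposal
#' @param seed optional RNG seed (the whole trace is reproducible from it)
#' @return a `cluster_run` list: `K`, `Q` (individuals x K posterior mean
#'   admixture, rows summing to 1), `loglik` (full complete-data lnL
#'   trace), `loglik_mix`, `L_estimate`, `seed`, `burn_in`, `n_sweeps`
#' @export
run_admixture <- function(gm, K, burn_in = 5000, n_sweeps = 20000,
                          alpha = 1.0, lambda = 1.0, infer_alpha = TRUE,
                          alpha_max = 10.0, alpha_prop_sd = 0.05,
                          seed = NULL) {
  n <- nrow(gm$a1)
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("K exceeds the number of individuals")
  if (!is.null(seed)) set.seed(seed)
  coded <- gm_to_coded(gm)
  res <- admixture_gibbs_cpp(coded$alleles, coded$n_alleles, as.integer(K),
                             as.integer(burn_in), as.integer(n_sweeps),
                             alpha, lambda, isTRUE(infer_alpha),
                             alpha_max, alpha_prop_sd)
  Q <- res$Q
  rownames(Q) <- rownames(gm$a1)
  colnames(Q) <- paste0("cluster", seq_len(K))
  lnl <- res$loglik
  post <- lnl[(burn_in + 1L):length(lnl)]
  structure(list(K = as.integer(K), Q = Q, loglik = lnl,
                 loglik_mix = res$loglik_mix,
                 alpha_trace = res$alpha_trace,
                 L_estimate = mean(post) - stats::var(post) / 2,
                 seed = seed, burn_in = as.integer(burn_in),
                 n_sweeps = as.integer(n_sweeps),
                 pop = gm$pop),
            class = "cluster_run")
}

#' @export
print.cluster_run <- function(x, ...) {
  cat("cluster_run: K =", x$K, ",", nrow(x$Q), "individuals, L_estimate =",
      signif(x$L_estimate, 6), "\n")
  invisible(x)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

q_similarity <- function(qa, qb) {
  1 - norm(qa - qb, type = "F") / sqrt(2 * nrow(qa))
}

best_permutation <- function(q_ref, q) {
  K <- ncol(q_ref)
  if (K <= 8L) {
    best <- seq_len(K); best_s <- -Inf
    for (p in all_permutations(K)) {
      s <- q_similarity(q_ref, q[, p, drop = FALSE])
      if (s > best_s) { best_s <- s; best <- unlist(p) }
    }
    list(perm = best, similarity = best_s)
  } else {
    # greedy column matching for large K
    perm <- integer(K); used <- logical(K)
    for (k in seq_len(K)) {
      d <- vapply(seq_len(K), function(j) {
        if (used[j]) Inf else sum((q_ref[, k] - q[, j])^2)
      }, numeric(1))
      perm[k] <- which.min(d); used[perm[k]] <- TRUE
    }
    list(perm = perm, similarity = q_similarity(q_ref, q[, perm, drop = FALSE]))
  }
}

#' Align cluster labels across runs and average the Q matrices
#'
#' Cluster labels are arbitrary within a run; alignment searches label
#' permutations maximizing the pairwise similarity
#' `G' = 1 - ||Q_a - Q_b P||_F / sqrt(2n)` against the first run
#' (exhaustively for `K <= 8`, greedily beyond), then averages the aligned
#' matrices.
#'
#' @param runs list of `cluster_run` objects at equal `K`
#' @return list with `Q` (aligned mean, rows on the simplex),
#'   `permutations` (one per run) and `similarities`
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1L)
  Ks <- vapply(runs, function(r) r$K, integer(1))
  if (length(unique(Ks)) != 1L) stop("runs have differing K")
  q_ref <- runs[[1]]$Q
  perms <- vector("list", length(runs))
  sims <- numeric(length(runs))
  acc <- 0
  for (i in seq_along(runs)) {
    bp <- best_permutation(q_ref, runs[[i]]$Q)
    perms[[i]] <- bp$perm
    sims[i] <- bp$similarity
    acc <- acc + runs[[i]]$Q[, bp$perm, drop = FALSE]
  }
  Q <- acc / length(runs)
  colnames(Q) <- colnames(q_ref)
  list(Q = Q, permutations = perms, similarities = sims)
}

#' Evanno delta-K table
#'
#' Groups runs by `K` (which must form a contiguous range with >= 2 runs
#' each) and computes `L'(K) = mean_L(K) - mean_L(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|` and `delta_K = |L''(K)| / sd_L(K)`.
#' Endpoints of the K range have undefined (NA) second differences.
#'
#' @param runs list of `cluster_run` objects spanning >= 3 consecutive K
#' @return data frame with columns `K`, `n_runs`, `mean_L`, `sd_L`,
#'   `L_prime`, `L_double_prime_abs`, `delta_K`
#' @export
evanno <- function(runs) {
  Ks <- vapply(runs, function(r) r$K, integer(1))
  Ls <- vapply(runs, function(r) r$L_estimate, numeric(1))
  k_levels <- sort(unique(Ks))
  if (length(k_levels) < 3L) stop("need at least 3 distinct K values")
  if (!all(diff(k_levels) == 1L)) stop("K values must be consecutive")
  n_runs <- vapply(k_levels, function(k) sum(Ks == k), integer(1))
  if (any(n_runs < 2L)) stop("need >= 2 runs per K")
  mean_L <- vapply(k_levels, function(k) mean(Ls[Ks == k]), numeric(1))
  sd_L <- vapply(k_levels, function(k) stats::sd(Ls[Ks == k]), numeric(1))
  m <- length(k_levels)
  L_prime <- c(NA, diff(mean_L))
  L_dd <- rep(NA_real_, m)
  L_dd[2:(m - 1)] <- abs(diff(mean_L)[-1] - diff(mean_L)[-(m - 1)])
  delta_K <- L_dd / sd_L
  if (any(sd_L == 0 & !is.na(L_dd))) {
    warning("sd_L is zero for some K; delta_K reported as Inf")
  }
  data.frame(K = k_levels, n_runs = n_runs, mean_L = mean_L, sd_L = sd_L,
             L_prime = L_prime, L_double_prime_abs = L_dd, delta_K = delta_K)
}
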