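# Population-level Prevosti distances, neighbour-joining with locus
# bootstrap supports, and PCA of individual allele counts.

#' Population x locus x allele frequency table
#'
#' Frequencies are computed over typed gene copies only (per-locus
#' renormalization over non-missing data).
#'
#' @param gm a [genotype_matrix()]
#' @return an `allele_freq_table`: list with `populations`, `loci`,
#'   `freq` (per locus, a populations x alleles frequency matrix) and
#'   `counts` (populations x loci matrix of typed gene copies)
#' @export
allele_freqs <- function(gm) {
  loci <- colnames(gm$a1)
  pops <- unique(gm$pop)
  counts <- matrix(0, length(pops), length(loci),
                   dimnames = list(pops, loci))
  freq <- lapply(loci, function(l) {
    labs <- sort(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
    f <- matrix(0, length(pops), length(labs),
                dimnames = list(pops, as.character(labs)))
    for (p in pops) {
      sel <- gm$pop == p
      al <- c(gm$a1[sel, l], gm$a2[sel, l])
      al <- al[!is.na(al)]
      counts[p, l] <<- length(al)
      if (length(al) > 0) {
        tab <- table(factor(al, levels = labs))
        f[p, ] <- as.numeric(tab) / length(al)
      }
    }
    f
  })
  names(freq) <- loci
  structure(list(populations = pops, loci = loci, freq = freq,
                 counts = counts),
            class = "allele_freq_table")
}

#' Prevosti genetic distance between populations
#'
#' `d(x, y) = (1 / 2L) * sum over the L loci typed in both populations of
#' sum_a |p_xa - p_ya|`, lying in `[0, 1]`.  The per-pair locus set is the
#' loci with typed copies in both populations (pairwise deletion).
#'
#' @param f an [allele_freqs()] table
#' @return symmetric distance matrix with zero diagonal
#' @export
prevosti_dist <- function(f) {
  pops <- f$populations
  n <- length(pops)
  d <- matrix(0, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- f$loci[f$counts[i, ] > 0 & f$counts[j, ] > 0]
      if (length(shared) == 0L) {
        stop("populations ", pops[i], " and ", pops[j], " share no typed locus")
      }
      s <- sum(vapply(shared, function(l) {
        sum(abs(f$freq[[l]][i, ] - f$freq[[l]][j, ]))
      }, numeric(1)))
      d[i, j] <- d[j, i] <- s / (2 * length(shared))
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Ties in Q are
#' broken by the lowest pair of current node indices (row first), making
#' the output deterministic; negative branch lengths are clamped to zero.
#' On an additive distance matrix the generating tree is recovered exactly.
#'
#' @param d symmetric distance matrix (or `dist`) over >= 3 taxa with
#'   dimnames
#' @return an unrooted [ape::phylo] tree
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbour-joining needs at least 3 taxa")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # each active node is a newick fragment without trailing length
  frag <- labels
  repeat {
    n <- nrow(d)
    if (n == 3L) break
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index tie-break: scan column-major over upper triangle by (i, j)
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (q[i, j] < best_q - 1e-12) {
          best_q <- q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], "internal")
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                    frag[1], max(la, 0), frag[2], max(lb, 0),
                    frag[3], max(lc, 0))
  ape::read.tree(text = newick)
}

#' Neighbour-joining tree with locus-bootstrap supports
#'
#' Builds the main Prevosti + NJ tree, then resamples loci with
#' replacement `n_reps` times, rebuilding distances and tree each time.
#' The support of each internal bipartition is the percentage of replicate
#' trees containing it, stored in the `support` attribute (length
#' `Nnode`, `NA` for the root node of the unrooted representation).
#'
#' @param f an [allele_freqs()] table
#' @param n_reps bootstrap replicates
#' @param seed optional RNG seed
#' @return an [ape::phylo] tree with a numeric `support` attribute
#' @export
bootstrap_tree <- function(f, n_reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  main <- neighbor_joining(prevosti_dist(f))
  L <- length(f$loci)
  if (L == 1L) {
    warning("single locus: bootstrap supports are trivially 100")
  }
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    take <- sample.int(L, L, replace = TRUE)
    fb <- structure(list(populations = f$populations,
                         loci = paste0("L", seq_len(L)),
                         freq = stats::setNames(f$freq[take],
                                                paste0("L", seq_len(L))),
                         counts = f$counts[, take, drop = FALSE]),
                    class = "allele_freq_table")
    colnames(fb$counts) <- fb$loci
    boots[[b]] <- neighbor_joining(prevosti_dist(fb))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  support <- 100 * counts / n_reps
  attr(main, "support") <- support
  main
}

#' PCA of individual allele counts
#'
#' Builds the individuals x alleles 0/1/2 count matrix over every allele
#' observed in the dataset, imputes missing cells with the column mean,
#' centers columns (no unit-variance scaling, the dominant allele-count
#' convention), and eigendecomposes the covariance.
#'
#' @param gm a [genotype_matrix()] with >= 2 individuals
#' @return list with `scores` (individuals x axes), `pct_variance`
#'   (percent of total variance per axis, summing to 100), and `pop`
#' @export
pca_individuals <- function(gm) {
  n <- nrow(gm$a1)
  if (n < 2L) stop("PCA needs at least 2 individuals")
  blocks <- lapply(colnames(gm$a1), function(l) {
    labs <- sort(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
    m <- matrix(NA_real_, n, length(labs),
                dimnames = list(rownames(gm$a1), paste0(l, ".", labs)))
    typed <- !is.na(gm$a1[, l])
    for (k in seq_along(labs)) {
      m[typed, k] <- (gm$a1[typed, l] == labs[k]) + (gm$a2[typed, l] == labs[k])
    }
    m
  })
  x <- do.call(cbind, blocks)
  mu <- colMeans(x, na.rm = TRUE)
  for (k in seq_len(ncol(x))) x[is.na(x[, k]), k] <- mu[k]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, pct_variance = 100 * ev / sum(ev), pop = gm$pop)
}
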