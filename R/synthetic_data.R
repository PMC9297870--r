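# Synthetic-data generator.  Emulates (a) qPCR panels implied by true copy
# numbers per duplication-genotype class, including the susceptible MGE
# baseline of 4-6 copies per haploid genome and absent type I/II
# amplification in susceptibles, and (b) SSR genotypes for many populations
# under a Balding-Nichols island model with inbreeding and missing data.
# Everything is reproducible from (config, seed).

#' Default regional duplication-genotype mixture
#'
#' One row per region, columns A/B/C/S summing to one.  The defaults mirror
#' the surveyed epidemiological pattern: genotype A confined to the Central
#' Great Plains, B dominant in the Northern Plains, C most common in the
#' Pacific Northwest, with susceptibles everywhere.
#' @return a 3 x 4 numeric matrix
#' @export
default_region_genotype_mix <- function() {
  m <- rbind(`Central Great Plains` = c(A = 0.60, B = 0.10, C = 0.05, S = 0.25),
             `Northern Plains`      = c(A = 0.00, B = 0.55, C = 0.25, S = 0.20),
             `Pacific Northwest`    = c(A = 0.00, B = 0.00, C = 0.65, S = 0.35))
  m
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults emulate
#' the surveyed design: ~44 populations of 9-18 individuals genotyped at 10
#' pentanucleotide SSR loci, weak population structure, moderate inbreeding,
#' and low missingness.
#'
#' @param n_populations number of populations
#' @param individuals_per_population inclusive range (length-2 integer) the
#'   per-population sample size is drawn from
#' @param n_loci number of SSR loci
#' @param motif_length repeat-unit length in bp (pentanucleotide default)
#' @param n_alleles_range inclusive range of distinct repeat-count alleles
#'   segregating per locus
#' @param fst Balding-Nichols divergence of population allele frequencies
#'   from the ancestral pool, in (0, 1)
#' @param fis within-population inbreeding coefficient in `[0, 1)`:
#'   probability that a genotype is drawn autozygous
#' @param missing_rate i.i.d. probability that an individual-locus cell is
#'   missing
#' @param region_genotype_mix region x {A,B,C,S} mixture matrix, rows
#'   summing to one (see [default_region_genotype_mix()])
#' @param ct_noise_sd technical noise of marker Ct values, in Ct units
#' @param size_noise_sd capillary sizing noise, in bp
#' @param als_ct_mean,als_ct_sd distribution of the ALS normalizer Ct
#' @param n_replicates technical qPCR replicates per individual
#' @param seed optional integer; when set, `simulate_*` calls seed the RNG
#'   themselves and are fully reproducible from the config alone
#' @return a validated `sim_config` list
#' @export
simulation_config <- function(n_populations = 44,
                              individuals_per_population = c(9L, 18L),
                              n_loci = 10L,
                              motif_length = 5L,
                              n_alleles_range = c(4L, 8L),
                              fst = 0.05,
                              fis = 0.2,
                              missing_rate = 0.03,
                              region_genotype_mix = default_region_genotype_mix(),
                              ct_noise_sd = 0.15,
                              size_noise_sd = 0.3,
                              als_ct_mean = 22,
                              als_ct_sd = 0.5,
                              n_replicates = 2L,
                              seed = NULL) {
  cfg <- list(n_populations = as.integer(n_populations),
              individuals_per_population = as.integer(individuals_per_population),
              n_loci = as.integer(n_loci),
              motif_length = as.integer(motif_length),
              n_alleles_range = as.integer(n_alleles_range),
              fst = fst, fis = fis, missing_rate = missing_rate,
              region_genotype_mix = region_genotype_mix,
              ct_noise_sd = ct_noise_sd, size_noise_sd = size_noise_sd,
              als_ct_mean = als_ct_mean, als_ct_sd = als_ct_sd,
              n_replicates = as.integer(n_replicates),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$n_populations >= 1L,
            length(cfg$individuals_per_population) == 2L,
            all(cfg$individuals_per_population >= 1L),
            cfg$individuals_per_population[1] <= cfg$individuals_per_population[2],
            cfg$n_loci >= 1L, cfg$motif_length >= 2L,
            cfg$fst > 0, cfg$fst < 1,
            cfg$fis >= 0, cfg$fis < 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$ct_noise_sd >= 0, cfg$size_noise_sd >= 0,
            cfg$n_replicates >= 1L)
  mix <- cfg$region_genotype_mix
  if (!all(colnames(mix) == GENOTYPE_CLASSES)) {
    stop("region_genotype_mix columns must be A, B, C, S")
  }
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-9)) {
    stop("each region's genotype mixture must be non-negative and sum to 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate true copy numbers for a duplication-genotype class
#'
#' Draws per-individual true copies of EPSPS (`epsps`), the type I and II
#' repeat junctions (`type1`, `type2`) and the mobile genetic element
#' (`mge`), per haploid genome.  The class-conditional ranges are calibrated
#' to the surveyed population means: susceptibles carry exactly one EPSPS
#' copy, no repeat junctions and the 4-6 copy MGE background; class A draws
#' type I above type II; classes B and C lack both repeat junctions, with
#' MGE elevated (tracking EPSPS) in B and at background level in C.
#'
#' @param class one of `"A"`, `"B"`, `"C"`, `"S"` (recycled against `n`)
#' @param n number of draws
#' @return data frame with columns `genotype`, `epsps`, `type1`, `type2`,
#'   `mge`
#' @export
simulate_copy_numbers <- function(class, n = length(class)) {
  class <- rep_len(as.character(class), n)
  bad <- !(class %in% GENOTYPE_CLASSES)
  if (any(bad)) stop("unknown genotype class: ", paste(unique(class[bad]), collapse = ", "))
  e <- t1 <- t2 <- mge <- numeric(n)
  idx <- class == "A"
  if (any(idx)) {
    k <- sum(idx)
    e[idx] <- runif(k, 4, 12)
    t1[idx] <- e[idx] * runif(k, 0.9, 1.3)
    t2[idx] <- e[idx] * runif(k, 0.3, 0.5)
    mge[idx] <- 2 * e[idx] + runif(k, 4, 6)
  }
  idx <- class == "B"
  if (any(idx)) {
    k <- sum(idx)
    e[idx] <- runif(k, 4, 30)
    mge[idx] <- 1.5 * e[idx] + runif(k, 4, 6)
  }
  idx <- class == "C"
  if (any(idx)) {
    k <- sum(idx)
    e[idx] <- runif(k, 2, 8)
    mge[idx] <- runif(k, 4, 6)
  }
  idx <- class == "S"
  if (any(idx)) {
    e[idx] <- 1
    mge[idx] <- runif(sum(idx), 4, 6)
  }
  data.frame(genotype = class, epsps = e, type1 = t1, type2 = t2, mge = mge,
             stringsAsFactors = FALSE)
}

#' Convert true copy numbers to a qPCR panel table
#'
#' Inverts the delta-Ct transform: each replicate draws its own ALS
#' normalizer Ct from `Normal(als_ct_mean, als_ct_sd)`; a marker with true
#' copies `c > 0` gets `Ct = Ct_ALS - log2(c) + Normal(0, ct_noise_sd)`
#' within that replicate, and `c = 0` yields no amplification (`NA`).
#' Amplification efficiency is fixed at 2 (perfect doubling).
#'
#' @param state data frame with columns `individual_id`, `population_id`,
#'   `epsps`, `type1`, `type2`, `mge` (copies >= 0)
#' @param cfg a [simulation_config()]
#' @return a `panel_table` data frame (see [read_panel_table()])
#' @export
copy_numbers_to_ct <- function(state, cfg = simulation_config()) {
  stopifnot(all(c("individual_id", "population_id",
                  "epsps", "type1", "type2", "mge") %in% names(state)))
  copies <- as.matrix(state[, c("epsps", "type1", "type2", "mge")])
  if (any(copies < 0)) stop("copy numbers must be non-negative")
  marker_of <- c(epsps = "EPSPS", type1 = "TypeI", type2 = "TypeII",
                 mge = "MGE")
  n <- nrow(state)
  out <- vector("list", cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    ct_als <- rnorm(n, cfg$als_ct_mean, cfg$als_ct_sd)
    ct <- matrix(NA_real_, n, 4L)
    amp <- copies > 0
    noise <- matrix(rnorm(n * 4L, 0, cfg$ct_noise_sd), n, 4L)
    ct[amp] <- (ct_als - log2(copies) + noise)[amp]
    out[[r]] <- data.frame(
      individual_id = rep(state$individual_id, 5L),
      population_id = rep(state$population_id, 5L),
      marker = rep(c(unname(marker_of), "ALS"), each = n),
      ct = c(ct, ct_als),
      replicate = r,
      stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$individual_id, panel$replicate), ]
  rownames(panel) <- NULL
  class(panel) <- c("panel_table", "data.frame")
  panel
}

region_of_population <- function(cfg) {
  regions <- rownames(cfg$region_genotype_mix)
  regions[(seq_len(cfg$n_populations) - 1L) %% length(regions) + 1L]
}

sim_population_sizes <- function(cfg) {
  lo <- cfg$individuals_per_population[1]
  hi <- cfg$individuals_per_population[2]
  sample(lo:hi, cfg$n_populations, replace = TRUE)
}

#' Simulate a complete qPCR survey
#'
#' Assigns populations round-robin to the three regions, draws each
#' individual's duplication genotype from the regional mixture, its true
#' copy numbers from [simulate_copy_numbers()], and its Ct panel from
#' [copy_numbers_to_ct()].
#'
#' @param cfg a [simulation_config()]; if `cfg$seed` is set the RNG is
#'   seeded first, making the result a pure function of the config
#' @return `list(panel, truth, metadata)` where `truth` holds the true
#'   genotype class and copy numbers per individual
#' @export
simulate_qpcr_dataset <- function(cfg = simulation_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sizes <- sim_population_sizes(cfg)
  pops <- sprintf("P%02d", seq_len(cfg$n_populations))
  region <- region_of_population(cfg)
  pop_of_ind <- rep(pops, sizes)
  region_of_ind <- rep(region, sizes)
  ids <- paste0(pop_of_ind, "_", unlist(lapply(sizes, seq_len)))
  class <- vapply(region_of_ind, function(rg) {
    sample(GENOTYPE_CLASSES, 1L, prob = cfg$region_genotype_mix[rg, ])
  }, character(1))
  truth <- cbind(data.frame(individual_id = ids, population_id = pop_of_ind,
                            stringsAsFactors = FALSE),
                 simulate_copy_numbers(class))
  panel <- copy_numbers_to_ct(truth, cfg)
  metadata <- data.frame(population_id = pops, region = region,
                         latitude = NA_real_, longitude = NA_real_,
                         resistance_status = ifelse(
                           tapply(class, factor(pop_of_ind, levels = pops),
                                  function(g) any(g != "S")), "R", "S"),
                         stringsAsFactors = FALSE)
  class(metadata) <- c("population_metadata", "data.frame")
  list(panel = panel, truth = truth, metadata = metadata)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate guard
  g / sum(g)
}

#' Simulate an SSR fragment dataset under a Balding-Nichols island model
#'
#' Per locus: 4-8 consecutive repeat-count alleles with ancestral
#' frequencies drawn flat-Dirichlet; population frequencies drawn
#' `Dirichlet(theta * p_anc)` with `theta = (1 - F_ST)/F_ST`; genotypes
#' drawn with probability `fis` of an autozygous (single-draw, doubled)
#' genotype; cells set missing i.i.d. at `missing_rate`; fragment size =
#' `locus_offset + motif * repeat_count + Normal(0, size_noise_sd)` bp.
#' Locus offsets are integers, so the truth matrix's allele labels are the
#' exact noiseless integer sizes the binning stage should recover.
#'
#' @param cfg a [simulation_config()]; if `cfg$seed` is set the RNG is
#'   seeded first
#' @return `list(fragments, truth, metadata, loci)` with `fragments` a
#'   `fragment_table`, `truth` the noiseless [genotype_matrix()], and
#'   `loci` a data frame of per-locus offsets and allele repeat counts
#' @export
simulate_ssr_dataset <- function(cfg = simulation_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sizes <- sim_population_sizes(cfg)
  pops <- sprintf("P%02d", seq_len(cfg$n_populations))
  region <- region_of_population(cfg)
  n_ind <- sum(sizes)
  pop_of_ind <- rep(pops, sizes)
  ids <- paste0(pop_of_ind, "_", unlist(lapply(sizes, seq_len)))
  loci <- sprintf("SSR%02d", seq_len(cfg$n_loci))
  m <- cfg$motif_length
  theta <- (1 - cfg$fst) / cfg$fst

  offset <- sample(60:200, cfg$n_loci, replace = TRUE)
  n_alleles <- sample(cfg$n_alleles_range[1]:cfg$n_alleles_range[2],
                      cfg$n_loci, replace = TRUE)
  base_repeat <- sample(15:40, cfg$n_loci, replace = TRUE)

  a1 <- matrix(NA_integer_, n_ind, cfg$n_loci, dimnames = list(ids, loci))
  a2 <- a1
  locus_info <- vector("list", cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    repeats <- base_repeat[l] + seq_len(n_alleles[l]) - 1L
    labels <- offset[l] + m * repeats
    p_anc <- rdirichlet1(rep(1, n_alleles[l]))
    locus_info[[l]] <- data.frame(locus_id = loci[l], offset = offset[l],
                                  motif = m,
                                  repeat_count = repeats, label = labels,
                                  ancestral_freq = p_anc)
    for (pi in seq_along(pops)) {
      p_pop <- rdirichlet1(theta * p_anc)
      rows <- which(pop_of_ind == pops[pi])
      auto <- runif(length(rows)) < cfg$fis
      g1 <- sample.int(n_alleles[l], length(rows), replace = TRUE,
                       prob = p_pop)
      g2 <- sample.int(n_alleles[l], length(rows), replace = TRUE,
                       prob = p_pop)
      g2[auto] <- g1[auto]
      a1[rows, l] <- labels[pmin(g1, g2)]
      a2[rows, l] <- labels[pmax(g1, g2)]
    }
  }
  miss <- matrix(runif(n_ind * cfg$n_loci) < cfg$missing_rate,
                 n_ind, cfg$n_loci)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  truth <- genotype_matrix(a1, a2, pop_of_ind)

  typed <- !miss
  k <- sum(typed)
  frag <- data.frame(
    individual_id = rep(ids, times = cfg$n_loci)[typed],
    population_id = rep(pop_of_ind, times = cfg$n_loci)[typed],
    locus_id = rep(loci, each = n_ind)[typed],
    size1 = a1[typed] + rnorm(k, 0, cfg$size_noise_sd),
    size2 = a2[typed] + rnorm(k, 0, cfg$size_noise_sd),
    stringsAsFactors = FALSE)
  frag <- normalize_fragment_sizes(frag)
  metadata <- data.frame(population_id = pops, region = region,
                         latitude = NA_real_, longitude = NA_real_,
                         resistance_status = NA_character_,
                         stringsAsFactors = FALSE)
  class(metadata) <- c("population_metadata", "data.frame")
  list(fragments = frag, truth = truth, metadata = metadata,
       loci = do.call(rbind, locus_info))
}
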