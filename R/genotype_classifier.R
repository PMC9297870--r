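# Rule-based duplication-genotype classification (A/B/C/S) from the
# four-marker copy-number profile, with population and regional summaries.
# The decision cascade is total and deterministic over non-negative
# profiles:
#   (1) EPSPS <= epsps_increased            -> S  (single-copy susceptible)
#   (2) else type I > 0 AND type II > 0     -> A  (both repeat junctions)
#   (3) else MGE >= mge_increased           -> B  (no junctions, high MGE)
#   (4) else                                -> C  (no junctions, normal MGE)
# Repeat-junction presence deliberately takes precedence over the MGE rule:
# field surveys contain all-A populations whose MGE mean sits below the
# threshold, which step (2) classifies correctly and flags as atypical.

#' Classification thresholds
#'
#' @param epsps_increased EPSPS copies above which an individual counts as
#'   having increased EPSPS (strict inequality; default 1.4, against the
#'   wild-type single copy per haploid genome)
#' @param mge_increased MGE copies at or above which MGE counts as
#'   "increased" rather than the normal 4-6 copy background (default 10)
#' @param repeat_present copies above which a repeat-junction marker counts
#'   as present (strict inequality; default 0)
#' @return a `dup_thresholds` list
#' @export
dup_thresholds <- function(epsps_increased = 1.4, mge_increased = 10,
                           repeat_present = 0) {
  stopifnot(epsps_increased > 0, mge_increased > 0, repeat_present >= 0)
  structure(list(epsps_increased = epsps_increased,
                 mge_increased = mge_increased,
                 repeat_present = repeat_present),
            class = "dup_thresholds")
}

#' Classify copy-number profiles into duplication genotypes
#'
#' Applies the A/B/C/S cascade to each row of a `copy_number_profile` data
#' frame and attaches QC flags:
#' * `discordant_repeat_markers` -- exactly one of type I/II amplified
#'   (classification proceeds via the MGE rule, steps 3-4);
#' * `atypical_low_MGE_A` -- genotype A with MGE below the "increased"
#'   threshold;
#' * `high_MGE_susceptible` -- genotype S with MGE at or above it.
#'
#' @param profiles data frame with columns `individual_id`,
#'   `population_id`, `epsps_cn`, `type1_cn`, `type2_cn`, `mge_cn`
#'   (all non-negative)
#' @param thresholds a [dup_thresholds()]
#' @return a `duplication_call` data frame with columns `individual_id`,
#'   `population_id`, `genotype` (factor A/B/C/S) and `flags`
#'   (`;`-separated, `""` when clean)
#' @export
classify_profiles <- function(profiles, thresholds = dup_thresholds()) {
  need <- c("epsps_cn", "type1_cn", "type2_cn", "mge_cn")
  stopifnot(all(need %in% names(profiles)))
  cn <- as.matrix(profiles[, need])
  if (any(!is.finite(cn))) stop("profiles must be finite")
  if (any(cn < 0)) stop("negative copy numbers are not valid input")

  th <- thresholds
  t1p <- cn[, "type1_cn"] > th$repeat_present
  t2p <- cn[, "type2_cn"] > th$repeat_present
  mge_hi <- cn[, "mge_cn"] >= th$mge_increased
  genotype <- ifelse(cn[, "epsps_cn"] <= th$epsps_increased, "S",
              ifelse(t1p & t2p, "A",
              ifelse(mge_hi, "B", "C")))

  flags <- mapply(function(disc, lowA, hiS) {
    paste(c(if (disc) "discordant_repeat_markers",
            if (lowA) "atypical_low_MGE_A",
            if (hiS) "high_MGE_susceptible"), collapse = ";")
  }, xor(t1p, t2p), genotype == "A" & !mge_hi, genotype == "S" & mge_hi)

  out <- data.frame(individual_id = profiles$individual_id,
                    population_id = profiles$population_id,
                    genotype = factor(genotype, levels = GENOTYPE_CLASSES),
                    flags = unname(flags),
                    stringsAsFactors = FALSE)
  class(out) <- c("duplication_call", "data.frame")
  out
}

se_or_na <- function(x) {
  n <- length(x)
  if (n < 2L) NA_real_ else stats::sd(x) / sqrt(n)
}

#' Population-level genotype and copy-number summary
#'
#' One row per population: sample size, arithmetic mean and standard error
#' (sd/sqrt(n), n-1 denominator; `NA` for n = 1) of each marker, and the
#' A/B/C/S call proportions.  Proportions sum to one.
#'
#' @param profiles a `copy_number_profile` data frame
#' @param calls the matching [classify_profiles()] output
#' @param meta a `population_metadata` data frame covering every population
#' @return a `population_genotype_summary` data frame, columns ordered
#'   region, population, n, marker means/SEs, proportions
#' @export
summarize_populations <- function(profiles, calls, meta) {
  stopifnot(nrow(profiles) == nrow(calls),
            all(profiles$individual_id == calls$individual_id))
  pops <- unique(profiles$population_id)
  missing_meta <- setdiff(pops, meta$population_id)
  if (length(missing_meta) > 0L) {
    stop("population(s) absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  rows <- lapply(pops, function(p) {
    sel <- profiles$population_id == p
    g <- calls$genotype[sel]
    n <- sum(sel)
    marker_cols <- c("epsps_cn", "type1_cn", "type2_cn", "mge_cn")
    stats_row <- unlist(lapply(marker_cols, function(mc) {
      x <- profiles[[mc]][sel]
      c(mean(x), se_or_na(x))
    }))
    names(stats_row) <- as.vector(t(outer(
      c("epsps", "type1", "type2", "mge"), c("mean", "se"), paste, sep = "_")))
    props <- as.vector(table(g)) / n
    data.frame(region = meta$region[match(p, meta$population_id)],
               population_id = p, n = n, as.list(stats_row),
               p_A = props[1], p_B = props[2], p_C = props[3], p_S = props[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("population_genotype_summary", "data.frame")
  out
}

#' Pool population summaries to regional genotype proportions
#'
#' Pooling is weighted by population sample size; `present_*` records
#' whether any individual in the region received each call.
#'
#' @param pop_summary a [summarize_populations()] result
#' @return data frame with one row per region
#' @export
summarize_regions <- function(pop_summary) {
  rows <- lapply(unique(pop_summary$region), function(rg) {
    sel <- pop_summary$region == rg
    n <- sum(pop_summary$n[sel])
    props <- vapply(c("p_A", "p_B", "p_C", "p_S"), function(pc) {
      sum(pop_summary[[pc]][sel] * pop_summary$n[sel]) / n
    }, numeric(1))
    data.frame(region = rg, n_populations = sum(sel), n = n,
               p_A = props[1], p_B = props[2], p_C = props[3], p_S = props[4],
               present_A = props[1] > 0, present_B = props[2] > 0,
               present_C = props[3] > 0, present_S = props[4] > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
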