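# Delta-Ct quantification: Ct values -> relative copies per haploid genome,
# normalized against the single-copy ALS gene, with amplification efficiency
# fixed at 2 (no standard-curve correction).

#' Relative copy number from a single delta-Ct
#'
#' `copies = 2^(ct_reference - ct_target)`.  A no-amplification target
#' (`NA`) maps to exactly 0 copies -- a definite zero, not a missing value,
#' because the downstream classifier tests "type I and type II > 0".
#'
#' @param ct_target numeric vector of target Ct values; `NA` = no
#'   amplification
#' @param ct_reference numeric vector of reference (ALS) Ct values; must be
#'   finite
#' @return numeric vector of relative copy numbers
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_reference))) {
    stop("reference Ct failed to amplify; the run is invalid")
  }
  out <- 2^(ct_reference - ct_target)
  out[is.na(ct_target)] <- 0
  out
}

#' Quantify a qPCR panel into copy-number profiles
#'
#' Technical replicates are averaged on the Ct scale (the delta-Ct
#' convention) before transformation; replicates that failed to amplify are
#' dropped from the mean, and a marker whose replicates all failed is
#' assigned 0 copies.  Markers with no rows at all for an individual are
#' likewise treated as non-amplifying.  If calibrator individuals with known
#' copy numbers are supplied, estimates are rescaled marker-wise by
#' `known / estimated` (delta-delta-Ct); otherwise raw delta-Ct values are
#' returned.
#'
#' @param panel a `panel_table` (see [read_panel_table()])
#' @param calibrators optional data frame with columns `individual_id`,
#'   `marker`, `known_copies`
#' @return a `copy_number_profile` data frame with columns `individual_id`,
#'   `population_id`, `epsps_cn`, `type1_cn`, `type2_cn`, `mge_cn`
#' @export
quantify_panel <- function(panel, calibrators = NULL) {
  stopifnot(all(c("individual_id", "population_id", "marker", "ct")
                %in% names(panel)))
  ind <- unique(panel$individual_id)
  pop <- panel$population_id[match(ind, panel$individual_id)]

  # mean Ct per individual x marker, NA when nothing amplified
  key_ind <- factor(panel$individual_id, levels = ind)
  key_mrk <- factor(panel$marker, levels = PANEL_MARKERS)
  sums <- tapply(panel$ct, list(key_ind, key_mrk), function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else mean(x)
  })
  mean_ct <- matrix(unlist(sums), nrow = length(ind),
                    dimnames = dimnames(sums))

  no_als <- !is.finite(mean_ct[, "ALS"])
  if (any(no_als)) {
    stop("individual(s) without a usable ALS reference: ",
         paste(ind[no_als], collapse = ", "))
  }
  targets <- c(EPSPS = "epsps_cn", TypeI = "type1_cn", TypeII = "type2_cn",
               MGE = "mge_cn")
  cn <- sapply(names(targets), function(mk) delta_ct(mean_ct[, mk],
                                                     mean_ct[, "ALS"]))
  cn <- matrix(cn, nrow = length(ind),
               dimnames = list(ind, unname(targets)))

  if (!is.null(calibrators)) {
    stopifnot(all(c("individual_id", "marker", "known_copies")
                  %in% names(calibrators)))
    for (r in seq_len(nrow(calibrators))) {
      mk <- calibrators$marker[r]
      if (!mk %in% names(targets)) stop("calibrator marker must be one of ",
                                        paste(names(targets), collapse = ", "))
      i <- match(calibrators$individual_id[r], ind)
      if (is.na(i)) stop("calibrator individual ",
                         calibrators$individual_id[r], " not in panel")
      est <- cn[i, targets[[mk]]]
      k <- calibrators$known_copies[r]
      if (est == 0 && k > 0) {
        stop("calibrator ", calibrators$individual_id[r], " estimates 0 for ",
             mk, " but is declared to carry ", k, " copies")
      }
      if (k > 0) cn[, targets[[mk]]] <- cn[, targets[[mk]]] * (k / est)
    }
  }
  out <- data.frame(individual_id = ind, population_id = pop,
                    cn, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("copy_number_profile", "data.frame")
  out
}
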