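# Flexibin-style allele binning: continuous capillary fragment sizes are
# mapped onto a fixed-width ladder of repeat-count rungs.  Unlike the full
# algorithm (which relaxes per-bin width to accommodate imperfect repeats),
# rungs here sit at exact motif spacing -- sufficient for pentanucleotide
# loci where adjacent alleles are 5 bp apart.

#' Fit an allele-bin ladder to the observed sizes of one locus
#'
#' Chooses the offset `o*` on a grid of `grid_step` over `[0, motif)` that
#' minimizes the total squared residual of every size to its nearest rung
#' `o + k * motif`, then assigns each size to its nearest rung.  Sizes whose
#' residual exceeds `tolerance` are flagged off-ladder (they become missing
#' when genotypes are built).
#'
#' @param sizes numeric vector of fragment sizes in bp (`NA` ignored)
#' @param motif repeat-unit length in bp (>= 2)
#' @param grid_step offset grid resolution in bp
#' @param tolerance maximal |size - rung| in bp before a size is declared
#'   off-ladder
#' @param locus_id optional identifier stored in the result
#' @return an `allele_bin_map` entry: list with `locus_id`, `offset`,
#'   `motif`, `tolerance`, and `bins`, a data frame of
#'   `(repeat_index, label, n)` with strictly increasing integer bp labels
#' @export
fit_bins <- function(sizes, motif, grid_step = 0.1, tolerance = 1.0,
                     locus_id = NA_character_) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0L) stop("no sizes to bin")
  stopifnot(motif >= 2, grid_step > 0, tolerance > 0)
  offsets <- seq(0, motif - grid_step, by = grid_step)
  cost <- vapply(offsets, function(o) {
    k <- round((sizes - o) / motif)
    sum((sizes - (o + k * motif))^2)
  }, numeric(1))
  o_star <- offsets[which.min(cost)]  # first minimum: deterministic
  k <- round((sizes - o_star) / motif)
  resid <- sizes - (o_star + k * motif)
  on_ladder <- abs(resid) <= tolerance
  if (!any(on_ladder)) {
    stop("all sizes are off-ladder at tolerance ", tolerance,
         if (!is.na(locus_id)) paste0(" for locus ", locus_id))
  }
  kk <- sort(unique(k[on_ladder]))
  bins <- data.frame(repeat_index = kk,
                     label = as.integer(round(o_star + kk * motif)),
                     n = as.integer(table(factor(k[on_ladder], levels = kk))))
  structure(list(locus_id = locus_id, offset = o_star, motif = motif,
                 tolerance = tolerance, bins = bins,
                 n_off_ladder = sum(!on_ladder)),
            class = "allele_bin_map")
}

#' Fit bin ladders for every locus of a fragment table
#'
#' @param frag a `fragment_table` data frame
#' @param motif repeat-unit length in bp (single value or named vector per
#'   locus)
#' @inheritParams fit_bins
#' @return named list of [fit_bins()] entries, one per locus
#' @export
fit_bin_maps <- function(frag, motif, grid_step = 0.1, tolerance = 1.0) {
  loci <- unique(frag$locus_id)
  motifs <- if (length(motif) == 1L)
    stats::setNames(rep(motif, length(loci)), loci) else motif
  out <- lapply(loci, function(l) {
    sel <- frag$locus_id == l
    fit_bins(c(frag$size1[sel], frag$size2[sel]), motifs[[l]],
             grid_step, tolerance, locus_id = l)
  })
  stats::setNames(out, loci)
}

#' Assign sizes to the bins of a fitted ladder
#'
#' @param map an [fit_bins()] entry
#' @param sizes numeric vector in bp
#' @return integer vector of bin labels, `NA` for missing or off-ladder
#'   sizes
#' @export
assign_bins <- function(map, sizes) {
  k <- round((sizes - map$offset) / map$motif)
  resid <- sizes - (map$offset + k * map$motif)
  lab <- as.integer(round(map$offset + k * map$motif))
  lab[is.na(sizes) | abs(resid) > map$tolerance] <- NA_integer_
  lab
}

#' Build a genotype matrix from a fragment table and fitted bin maps
#'
#' Each individual-locus cell becomes a pair of bin labels.  A cell with
#' one usable size (the other missing or off-ladder) is treated as a
#' homozygote for the present allele by default -- the common
#' fragment-analysis convention -- or set missing with
#' `single_peak = "missing"`.  Cells with no usable size are missing.
#'
#' @param frag a `fragment_table` data frame
#' @param bin_maps a [fit_bin_maps()] result covering every locus in `frag`
#' @param single_peak `"homozygote"` or `"missing"`
#' @return a [genotype_matrix()]
#' @export
build_genotype_matrix <- function(frag, bin_maps,
                                  single_peak = c("homozygote", "missing")) {
  single_peak <- match.arg(single_peak)
  loci <- unique(frag$locus_id)
  missing_maps <- setdiff(loci, names(bin_maps))
  if (length(missing_maps) > 0L) {
    stop("no bin map for locus/loci: ", paste(missing_maps, collapse = ", "))
  }
  ids <- unique(frag$individual_id)
  pop <- frag$population_id[match(ids, frag$individual_id)]
  multi_pop <- tapply(frag$population_id, frag$individual_id,
                      function(p) length(unique(p)) > 1L)
  if (any(multi_pop)) {
    stop("individual(s) assigned to multiple populations: ",
         paste(names(multi_pop)[multi_pop], collapse = ", "))
  }
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  for (l in loci) {
    sel <- which(frag$locus_id == l)
    map <- bin_maps[[l]]
    l1 <- assign_bins(map, frag$size1[sel])
    l2 <- assign_bins(map, frag$size2[sel])
    one <- xor(is.na(l1), is.na(l2))
    if (single_peak == "homozygote") {
      present <- ifelse(is.na(l1), l2, l1)
      l1[one] <- present[one]; l2[one] <- present[one]
    } else {
      l1[one] <- NA_integer_; l2[one] <- NA_integer_
    }
    rows <- match(frag$individual_id[sel], ids)
    a1[rows, l] <- pmin(l1, l2)
    a2[rows, l] <- pmax(l1, l2)
  }
  genotype_matrix(a1, a2, pop)
}
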