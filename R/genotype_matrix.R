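# The genotype matrix is the substrate of all SSR analyses: individuals x
# loci, with two binned allele labels per cell.  A cell is missing when both
# alleles are NA; single-NA cells are rejected (single-peak handling is the
# binning module's job, before construction).

#' Construct a genotype matrix
#'
#' @param a1,a2 numeric matrices (individuals x loci) of allele labels with
#'   identical dimnames; `NA` in both marks a missing cell.  Cells are
#'   normalized so `a1 <= a2`; homozygotes carry the same label twice.
#' @param pop character vector of population ids, one per individual
#' @return an object of class `genotype_matrix` with elements `a1`, `a2`,
#'   `pop`
#' @export
genotype_matrix <- function(a1, a2, pop) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(identical(dim(a1), dim(a2)), length(pop) == nrow(a1))
  if (is.null(rownames(a1))) rownames(a1) <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(colnames(a1))) colnames(a1) <- paste0("locus", seq_len(ncol(a1)))
  dimnames(a2) <- dimnames(a1)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    stop("cells with exactly one missing allele are not allowed; ",
         "resolve single peaks during binning (",
         sum(half), " offending cell(s))")
  }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  structure(list(a1 = a1, a2 = a2, pop = as.character(pop)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$a1), "individuals x", ncol(x$a1), "loci,",
      length(unique(x$pop)), "populations;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Logical matrix of missing cells
#' @param gm a [genotype_matrix()]
#' @return individuals x loci logical matrix
#' @export
gm_missing <- function(gm) is.na(gm$a1)

#' Subset a genotype matrix
#' @param gm a [genotype_matrix()]
#' @param individuals,loci index vectors (logical, integer or names);
#'   `NULL` keeps everything
#' @return a [genotype_matrix()]
#' @export
gm_subset <- function(gm, individuals = NULL, loci = NULL) {
  i <- individuals %||% seq_len(nrow(gm$a1))
  l <- loci %||% seq_len(ncol(gm$a1))
  if (is.character(i)) i <- match(i, rownames(gm$a1))
  pop_idx <- seq_along(gm$pop)[i]
  genotype_matrix(gm$a1[i, l, drop = FALSE], gm$a2[i, l, drop = FALSE],
                  gm$pop[pop_idx])
}

#' Logical vector: is each typed cell heterozygous?
#' @keywords internal
gm_het <- function(gm) gm$a1 != gm$a2
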