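# Readers and writers for every external representation the pipeline touches.
# All delimited readers auto-detect comma vs tab only; anything else must be
# passed explicitly via `sep`.  Readers reject rows violating closed
# vocabularies instead of coercing.

#' Detect the field delimiter of a delimited text file
#'
#' Only comma and tab are auto-detected; silent mis-parsing of exotic
#' dialects is the dominant failure mode, so everything else must be
#' declared explicitly by the caller.
#' @param path file path
#' @return `","` or `"\t"`
#' @keywords internal
detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("empty file: ", path)
  if (grepl("\t", line)) "\t" else ","
}

read_delim_checked <- function(path, sep, required, optional = character()) {
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

num_or_na <- function(x, codes, what, path) {
  out <- rep(NA_real_, length(x))
  is_code <- x %in% codes | is.na(x)
  suppressWarnings(out[!is_code] <- as.numeric(x[!is_code]))
  bad <- !is_code & is.na(out)
  if (any(bad)) {
    stop("non-numeric ", what, " in ", path, " at data row(s) ",
         paste(which(bad), collapse = ", "))
  }
  out
}

#' Read a qPCR panel table
#'
#' The table must contain the columns `individual_id`, `population_id`,
#' `marker`, `ct` and (optionally) `replicate`.  `marker` is restricted to
#' the closed panel vocabulary `EPSPS`, `TypeI`, `TypeII`, `MGE`, `ALS`.
#' Ct values matching a no-amplification code are mapped to `NA`, the
#' internal NO_AMP sentinel.  Every `(individual, replicate)` block must
#' contain an `ALS` row, because ALS is the normalizer the delta-Ct method
#' divides by.
#'
#' @param path delimited text file (comma or tab auto-detected)
#' @param sep optional explicit field separator
#' @param no_amp_codes character vector of strings treated as
#'   no-amplification (default `""`, `"NA"`, `"Undetermined"`,
#'   `"no amplification"`)
#' @return a `panel_table` data frame with columns `individual_id`,
#'   `population_id`, `marker`, `ct` (numeric, `NA` = no amplification),
#'   `replicate`
#' @export
read_panel_table <- function(path, sep = NULL,
                             no_amp_codes = c("", "NA", "Undetermined",
                                              "no amplification")) {
  df <- read_delim_checked(path, sep,
                           c("individual_id", "population_id", "marker", "ct"))
  bad <- !(df$marker %in% PANEL_MARKERS)
  if (any(bad)) {
    stop("unknown marker name(s) ", paste(unique(df$marker[bad]), collapse = ", "),
         " at data row(s) ", paste(which(bad), collapse = ", "),
         "; allowed: ", paste(PANEL_MARKERS, collapse = ", "))
  }
  ct <- num_or_na(df$ct, no_amp_codes, "ct", path)
  if (any(ct < 0, na.rm = TRUE)) {
    stop("negative Ct value(s) at data row(s) ",
         paste(which(!is.na(ct) & ct < 0), collapse = ", "))
  }
  replicate <- if ("replicate" %in% names(df)) as.integer(df$replicate) else 1L
  out <- data.frame(individual_id = df$individual_id,
                    population_id = df$population_id,
                    marker = df$marker, ct = ct,
                    replicate = replicate,
                    stringsAsFactors = FALSE)
  validate_panel_table(out)
  class(out) <- c("panel_table", "data.frame")
  out
}

validate_panel_table <- function(panel) {
  block <- paste(panel$individual_id, panel$replicate, sep = "\r")
  has_als <- tapply(panel$marker == "ALS", block, any)
  if (!all(has_als)) {
    missing <- unique(sub("\r.*$", "", names(has_als)[!has_als]))
    stop("individual(s) without an ALS normalizer row: ",
         paste(missing, collapse = ", "))
  }
  invisible(panel)
}

#' Write a qPCR panel table
#'
#' Inverse of [read_panel_table()]; `NA` Ct values are written as `"NA"`.
#' @param panel a `panel_table` data frame
#' @param path output file
#' @param sep field separator (default comma)
#' @export
write_panel_table <- function(panel, path, sep = ",") {
  utils::write.table(panel, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an SSR fragment-size table
#'
#' Columns: `individual_id`, `population_id`, `locus_id`, `size1`, `size2`
#' (base pairs; missing codes map to `NA`).  Sizes must lie within the
#' 35--500 bp capillary sizing-ladder range.  Cells are normalized so the
#' present allele comes first and `size1 <= size2` when both are present.
#'
#' @inheritParams read_panel_table
#' @param missing_codes strings treated as a missing size
#' @return a `fragment_table` data frame
#' @export
read_fragment_table <- function(path, sep = NULL,
                                missing_codes = c("", "NA", "?")) {
  df <- read_delim_checked(path, sep,
                           c("individual_id", "population_id", "locus_id",
                             "size1", "size2"))
  s1 <- num_or_na(df$size1, missing_codes, "size1", path)
  s2 <- num_or_na(df$size2, missing_codes, "size2", path)
  rng <- range(c(s1, s2), na.rm = TRUE)
  sizes <- c(s1, s2)
  out_of_range <- !is.na(sizes) & (sizes < 35 | sizes > 500)
  if (any(out_of_range)) {
    stop("fragment size(s) outside the 35-500 bp sizing range at data row(s) ",
         paste(unique((which(out_of_range) - 1L) %% nrow(df) + 1L), collapse = ", "))
  }
  out <- data.frame(individual_id = df$individual_id,
                    population_id = df$population_id,
                    locus_id = df$locus_id,
                    size1 = s1, size2 = s2, stringsAsFactors = FALSE)
  normalize_fragment_sizes(out)
}

normalize_fragment_sizes <- function(frag) {
  swap <- (!is.na(frag$size1) & !is.na(frag$size2) & frag$size1 > frag$size2) |
    (is.na(frag$size1) & !is.na(frag$size2))
  if (any(swap)) {
    tmp <- frag$size1[swap]
    frag$size1[swap] <- frag$size2[swap]
    frag$size2[swap] <- tmp
  }
  class(frag) <- c("fragment_table", "data.frame")
  frag
}

#' Write an SSR fragment-size table
#' @param frag a `fragment_table` data frame
#' @param path output file
#' @param sep field separator
#' @export
write_fragment_table <- function(frag, path, sep = ",") {
  utils::write.table(frag, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a population metadata table
#'
#' Maps `population_id` to a geographical `region` (one of
#' `"Central Great Plains"`, `"Northern Plains"`, `"Pacific Northwest"`),
#' optional latitude/longitude, and a `resistance_status` of `R` or `S`.
#'
#' @inheritParams read_panel_table
#' @return a `population_metadata` data frame
#' @export
read_population_metadata <- function(path, sep = NULL) {
  df <- read_delim_checked(path, sep, c("population_id", "region"))
  bad <- !(df$region %in% REGIONS)
  if (any(bad)) {
    stop("unknown region(s) ", paste(unique(df$region[bad]), collapse = ", "),
         "; allowed: ", paste(REGIONS, collapse = ", "))
  }
  if (anyDuplicated(df$population_id)) {
    stop("duplicated population_id in metadata: ",
         paste(unique(df$population_id[duplicated(df$population_id)]),
               collapse = ", "))
  }
  out <- data.frame(population_id = df$population_id, region = df$region,
                    stringsAsFactors = FALSE)
  out$latitude <- if ("latitude" %in% names(df))
    num_or_na(df$latitude, c("", "NA"), "latitude", path) else NA_real_
  out$longitude <- if ("longitude" %in% names(df))
    num_or_na(df$longitude, c("", "NA"), "longitude", path) else NA_real_
  if ("resistance_status" %in% names(df)) {
    status <- df$resistance_status
    status[status %in% c("", "NA")] <- NA_character_
    if (!all(status %in% c("R", "S") | is.na(status))) {
      stop("resistance_status must be R, S or missing")
    }
    out$resistance_status <- status
  } else {
    out$resistance_status <- NA_character_
  }
  class(out) <- c("population_metadata", "data.frame")
  out
}

#' Write a population metadata table
#' @param meta a `population_metadata` data frame
#' @param path output file
#' @param sep field separator
#' @export
write_population_metadata <- function(meta, path, sep = ",") {
  utils::write.table(meta, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# GENEPOP

#' Write a genotype matrix in GENEPOP format
#'
#' Alleles are written as fixed 3-digit integers (the dominant community
#' dialect), `000000` for a missing cell.  Sample names are written as
#' `population:individual` so the population assignment round-trips.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file
#' @param title title line
#' @export
write_genepop <- function(gm, path, title = "dupepi GENEPOP export") {
  labels <- c(gm$a1, gm$a2)
  if (any(labels > 999, na.rm = TRUE) || any(labels < 0, na.rm = TRUE)) {
    stop("allele labels must be encodable as 3-digit integers (0-999)")
  }
  for (l in seq_len(ncol(gm$a1))) {
    n_alleles <- length(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
    if (n_alleles > 999) {
      stop("locus ", colnames(gm$a1)[l], " has more than 999 distinct alleles")
    }
  }
  enc <- function(a) ifelse(is.na(a), "000", sprintf("%03d", as.integer(a)))
  lines <- c(title, colnames(gm$a1))
  pops <- unique(gm$pop)
  for (p in pops) {
    lines <- c(lines, "Pop")
    for (i in which(gm$pop == p)) {
      geno <- paste0(enc(gm$a1[i, ]), enc(gm$a2[i, ]), collapse = " ")
      lines <- c(lines, paste0(p, ":", rownames(gm$a1)[i], " ,  ", geno))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GENEPOP file written by [write_genepop()]
#'
#' Understands the standard layout: title line, locus names (one per line or
#' comma-separated), `Pop` blocks with `name , genotype ...` sample lines.
#' @param path GENEPOP file
#' @return a [genotype_matrix()]
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first_pop <- which(toupper(trimws(lines)) == "POP")[1]
  if (is.na(first_pop)) stop("no Pop block found in ", path)
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  ids <- character(); pop <- character()
  a1 <- NULL; a2 <- NULL
  pop_idx <- 0L
  for (line in lines[first_pop:length(lines)]) {
    if (toupper(trimws(line)) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L) stop("malformed sample line: ", line)
    name <- trimws(parts[1])
    if (grepl(":", name, fixed = TRUE)) {
      nm <- strsplit(name, ":", fixed = TRUE)[[1]]
      this_pop <- nm[1]; this_id <- paste(nm[-1], collapse = ":")
    } else {
      this_pop <- paste0("pop", pop_idx); this_id <- name
    }
    tokens <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(tokens) != length(loci)) {
      stop("sample ", this_id, " has ", length(tokens), " genotypes for ",
           length(loci), " loci")
    }
    g1 <- as.integer(substr(tokens, 1, 3))
    g2 <- as.integer(substr(tokens, 4, 6))
    g1[g1 == 0L] <- NA_integer_; g2[g2 == 0L] <- NA_integer_
    ids <- c(ids, this_id); pop <- c(pop, this_pop)
    a1 <- rbind(a1, g1); a2 <- rbind(a2, g2)
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  genotype_matrix(a1, a2, pop)
}

# ---------------------------------------------------------------------------
# STRUCTURE

#' Write a genotype matrix in STRUCTURE one-allele-per-row format
#'
#' Two rows per individual, alleles integer-recoded per locus (dense codes
#' `1..A` in increasing label order), `-9` for missing.  A header row with
#' locus names is included.  Returns (invisibly) the per-locus recode maps,
#' each a named integer vector mapping original labels to codes.
#'
#' @param gm a [genotype_matrix()]
#' @param path output file
#' @param include_pop write an integer-coded population column
#' @return invisibly, `list(recode = <per-locus named integer vectors>,
#'   pop_levels = <character>)`
#' @export
write_structure_input <- function(gm, path, include_pop = TRUE) {
  loci <- colnames(gm$a1)
  recode <- lapply(seq_along(loci), function(l) {
    labs <- sort(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
    stats::setNames(seq_along(labs), labs)
  })
  names(recode) <- loci
  pop_levels <- unique(gm$pop)
  pop_int <- match(gm$pop, pop_levels)
  code <- function(a, l) {
    out <- unname(recode[[l]][as.character(a)])
    out[is.na(out)] <- -9L
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(loci, collapse = "\t"), con)
  for (i in seq_len(nrow(gm$a1))) {
    for (allele in c("a1", "a2")) {
      row <- vapply(seq_along(loci),
                    function(l) code(gm[[allele]][i, l], l), integer(1))
      lead <- if (include_pop) c(rownames(gm$a1)[i], pop_int[i]) else
        rownames(gm$a1)[i]
      writeLines(paste(c(lead, row), collapse = "\t"), con)
    }
  }
  invisible(list(recode = recode, pop_levels = pop_levels))
}

#' Read a STRUCTURE one-allele-per-row file written by
#' [write_structure_input()]
#'
#' Returns a genotype matrix whose allele labels are the integer recodes
#' (`-9` mapped back to missing).
#' @param path STRUCTURE-format file
#' @param has_pop whether a population column is present
#' @return a [genotype_matrix()]
#' @export
read_structure_input <- function(path, has_pop = TRUE) {
  lines <- readLines(path, warn = FALSE)
  loci <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(body) %% 2L != 0L) stop("odd number of data rows in ", path)
  n <- length(body) / 2L
  lead <- if (has_pop) 2L else 1L
  a1 <- matrix(NA_integer_, n, length(loci))
  a2 <- matrix(NA_integer_, n, length(loci))
  ids <- character(n); pop <- character(n)
  for (i in seq_len(n)) {
    r1 <- body[[2L * i - 1L]]; r2 <- body[[2L * i]]
    if (r1[1] != r2[1]) stop("row pair mismatch for individual ", r1[1])
    ids[i] <- r1[1]
    pop[i] <- if (has_pop) paste0("pop", r1[2]) else "pop1"
    a1[i, ] <- as.integer(r1[(lead + 1L):length(r1)])
    a2[i, ] <- as.integer(r2[(lead + 1L):length(r2)])
  }
  a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  genotype_matrix(a1, a2, pop)
}

# ---------------------------------------------------------------------------
# Newick

#' Write a tree with bootstrap supports to a Newick file
#'
#' Internal-node supports (the `support` attribute set by
#' [bootstrap_tree()], in percent) are written as node labels at the
#' configured precision.  All labels are written; filtering low supports is
#' a rendering concern, not a serialization one.
#'
#' @param tree an [ape::phylo] tree, optionally carrying a numeric
#'   `support` attribute (length `tree$Nnode`)
#' @param path output file
#' @param support_digits decimal digits used to print supports
#' @export
write_newick <- function(tree, path, support_digits = 1) {
  support <- attr(tree, "support")
  if (!is.null(support)) {
    tree$node.label <- ifelse(
      is.na(support), "",
      sub("\\.?0+$", "", sprintf(paste0("%.", support_digits, "f"), support)))
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree, recovering numeric node supports
#'
#' Inverse of [write_newick()]: numeric node labels are moved into the
#' `support` attribute.
#' @param path Newick file
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    attr(tree, "support") <- sup
  }
  tree
}
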