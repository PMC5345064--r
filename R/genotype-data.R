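#' Locus description table
#'
#' Build the per-locus metadata table that accompanies a genotype table.
#' Allele calls are stored as raw fragment sizes in base pairs; `repeat_unit`
#' and `size_offset` are what converts them to repeat units when a statistic
#' (the M-ratio, the mutation model) needs them:
#' `repeats = (size_bp - size_offset) / repeat_unit`.
#'
#' @param locus character vector of locus names (order is meaningful and is
#'   preserved through every read/write cycle).
#' @param repeat_unit integer vector (recycled), base pairs per repeat, >= 1.
#' @param size_offset integer vector (recycled), base pairs of flanking
#'   sequence included in the fragment size; 0 if alleles are already in
#'   repeat units.
#' @return A tibble with columns `locus`, `repeat_unit`, `size_offset`.
#' @export
#' @examples
#' locus_table(c("Ba01", "Ba02"), repeat_unit = c(2, 4), size_offset = c(100, 88))
locus_table <- function(locus, repeat_unit = 1L, size_offset = 0L) {
  locus <- as.character(locus)
  if (anyDuplicated(locus)) abort("locus names must be unique")
  repeat_unit <- as.integer(rep_len(repeat_unit, length(locus)))
  size_offset <- as.integer(rep_len(size_offset, length(locus)))
  if (any(repeat_unit < 1L)) abort("repeat_unit must be >= 1")
  if (any(size_offset < 0L)) abort("size_offset must be >= 0")
  tibble::tibble(locus = locus, repeat_unit = repeat_unit, size_offset = size_offset)
}

#' Tidy genotype table
#'
#' The universal input of the package: one row per individual x locus, with
#' the two allele fragment sizes (base pairs) in `allele_1`/`allele_2`. A
#' missing genotype is missing as a unit: both alleles `NA` (one-sided
#' missingness is rejected). The locus metadata (see [locus_table()]) ride
#' along as the `"loci"` attribute, and every downstream function accepts the
#' genotype table as its first argument.
#'
#' @param genotypes a data frame with columns `site`, `year`, `individual`,
#'   `locus`, `allele_1`, `allele_2`.
#' @param loci a [locus_table()]; defaults to repeat unit 1, offset 0 for the
#'   loci present.
#' @return A `genotype_tbl` (a tibble subclass).
#' @export
genotype_table <- function(genotypes, loci = NULL) {
  need <- c("site", "year", "individual", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(need, names(genotypes))
  if (length(missing_cols)) {
    abort(paste0("genotype table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(genotypes)[need]
  out$site <- as.character(out$site)
  out$year <- as.integer(out$year)
  out$individual <- as.character(out$individual)
  out$locus <- as.character(out$locus)
  out$allele_1 <- as.integer(out$allele_1)
  out$allele_2 <- as.integer(out$allele_2)

  one_sided <- xor(is.na(out$allele_1), is.na(out$allele_2))
  if (any(one_sided)) {
    abort(sprintf(
      "%d genotype cell(s) have exactly one missing allele; a cell must be missing as a unit",
      sum(one_sided)
    ))
  }

  if (is.null(loci)) {
    loci <- locus_table(unique(out$locus))
  } else {
    loci <- tibble::as_tibble(loci)
    extra <- setdiff(unique(out$locus), loci$locus)
    if (length(extra)) {
      abort(paste0("genotypes contain loci absent from `loci`: ", paste(extra, collapse = ", ")))
    }
  }
  out$locus <- factor(out$locus, levels = loci$locus)
  out <- dplyr::arrange(out, .data$site, .data$year, .data$locus, .data$individual)
  out$locus <- as.character(out$locus)
  new_genotype_tbl(out, loci)
}

new_genotype_tbl <- function(x, loci) {
  x <- tibble::as_tibble(x)
  attr(x, "loci") <- tibble::as_tibble(loci)
  class(x) <- c("genotype_tbl", class(tibble::tibble()))
  x
}

#' Locus metadata of a genotype table
#' @param x a `genotype_tbl`.
#' @return The `locus_table` attribute (tibble).
#' @export
loci <- function(x) {
  out <- attr(x, "loci", exact = TRUE)
  if (is.null(out)) locus_table(unique(as.character(x$locus))) else out
}

#' @export
print.genotype_tbl <- function(x, ...) {
  lt <- loci(x)
  keys <- dplyr::distinct(as_plain_tibble(x), .data$site, .data$year)
  cat(sprintf(
    "# Genotype table: %d loci, %d samples (site x year), %d genotype rows\n",
    nrow(lt), nrow(keys), nrow(x)
  ))
  NextMethod()
}

as_plain_tibble <- function(x) {
  class(x) <- class(tibble::tibble())
  attr(x, "loci") <- NULL
  x
}

#' Sample sizes per site and year
#'
#' @param geno a `genotype_tbl`.
#' @return A tibble with one row per (site, year) and the number of
#'   individuals `n`.
#' @export
sample_sizes <- function(geno) {
  as_plain_tibble(geno) |>
    dplyr::distinct(.data$site, .data$year, .data$individual) |>
    dplyr::count(.data$site, .data$year, name = "n")
}

#' Count gene copies per allele
#'
#' Tallies allele fragment sizes per (site, year, locus); each non-missing
#' genotype contributes two gene copies, missing cells contribute none, so
#' counts sum to twice the number of complete genotypes at each locus.
#'
#' @param geno a `genotype_tbl` (or any data frame with the same columns).
#' @return A tibble with columns `site`, `year`, `locus`, `allele`, `n_copies`.
#' @export
#' @examples
#' g <- genotype_table(tibble::tibble(
#'   site = "A", year = 2005, individual = c("i1", "i2"),
#'   locus = "L1", allele_1 = c(150L, 152L), allele_2 = c(150L, 154L)
#' ))
#' allele_counts(g)
allele_counts <- function(geno) {
  as_plain_tibble(tibble::as_tibble(geno)) |>
    tidyr::pivot_longer(c("allele_1", "allele_2"),
      names_to = NULL, values_to = "allele"
    ) |>
    dplyr::filter(!is.na(.data$allele)) |>
    dplyr::count(.data$site, .data$year, .data$locus, .data$allele,
      name = "n_copies"
    )
}

# Named integer vector of gene-copy counts for one (site, year, locus),
# the low-level currency of the diversity statistics.
count_vector <- function(geno, site, year, locus) {
  rows <- geno$site == site & geno$year == year & geno$locus == locus
  a <- c(geno$allele_1[rows], geno$allele_2[rows])
  a <- a[!is.na(a)]
  if (!length(a)) {
    return(setNames(integer(0), character(0)))
  }
  tab <- table(a)
  setNames(as.integer(tab), names(tab))
}

#' Check allele sizes against the locus repeat structure
#'
#' Verifies that, after subtracting `size_offset`, all allele sizes observed
#' at each locus are congruent modulo `repeat_unit`. Violations (e.g. an
#' imperfect repeat) are reported, never silently fixed.
#'
#' @param geno a `genotype_tbl`.
#' @return A tibble of violations (locus, offending alleles); zero rows when
#'   the panel is clean.
#' @export
check_repeat_structure <- function(geno) {
  lt <- loci(geno)
  ac <- allele_counts(geno)
  bad <- purrr::map_dfr(seq_len(nrow(lt)), function(i) {
    sizes <- sort(unique(ac$allele[ac$locus == lt$locus[i]]))
    if (length(sizes) < 2L) {
      return(NULL)
    }
    resid <- (sizes - lt$size_offset[i]) %% lt$repeat_unit[i]
    if (length(unique(resid)) == 1L) {
      return(NULL)
    }
    main <- as.integer(names(which.max(table(resid))))
    tibble::tibble(
      locus = lt$locus[i],
      offending_alleles = paste(sizes[resid != main], collapse = ",")
    )
  })
  if (nrow(bad)) {
    warn(paste0(
      "allele sizes not congruent modulo the repeat unit at: ",
      paste(bad$locus, collapse = ", ")
    ))
  }
  bad
}
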