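#' Unbiased expected heterozygosity
#'
#' Nei's unbiased gene diversity for a single locus,
#' `He = n/(n-1) * (1 - sum(p_i^2))`, where `n` is the number of gene copies
#' and `p_i` the sample allele frequencies.
#'
#' @param counts numeric vector of gene-copy counts per allele.
#' @return He in `[0, 1]`; 0 for a monomorphic locus.
#' @export
#' @examples
#' expected_heterozygosity(c(2, 2)) # (4/3) * (1 - 0.5)
expected_heterozygosity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) abort("expected heterozygosity is undefined for fewer than 2 gene copies")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Garza-Williamson M-ratio
#'
#' `M = k / (r + 1)` where `k` is the number of alleles and `r` the allelic
#' size range in repeat units, `(max - min) / repeat_unit`. Bottlenecks
#' knock alleles out of the interior of the size ladder faster than they
#' shrink its range, so M falls after a crash. Sizes must be congruent
#' modulo the repeat unit (after subtracting the flanking offset); an
#' imperfect repeat raises an error naming the offending alleles.
#'
#' @param sizes allele sizes present (bp), or a named count vector whose
#'   names are sizes.
#' @param repeat_unit bp per repeat.
#' @param size_offset bp of flanking sequence.
#' @return M in `(0, 1]`; 1 for a monomorphic locus or a full ladder.
#' @export
#' @examples
#' m_ratio(c(150, 152, 154, 158), repeat_unit = 2) # 4 alleles over 5 classes
m_ratio <- function(sizes, repeat_unit = 1L, size_offset = 0L) {
  if (!is.null(names(sizes))) sizes <- as.numeric(names(sizes)[sizes > 0])
  sizes <- sort(unique(sizes))
  if (!length(sizes)) abort("no alleles observed")
  resid <- (sizes - size_offset) %% repeat_unit
  if (length(unique(resid)) > 1L) {
    main <- as.numeric(names(which.max(table(resid))))
    abort(paste0(
      "allele sizes not congruent modulo the repeat unit (", repeat_unit,
      "): offending alleles ", paste(sizes[resid != main], collapse = ", ")
    ))
  }
  k <- length(sizes)
  r <- (max(sizes) - min(sizes)) / repeat_unit
  k / (r + 1)
}

#' Rarefied allelic richness, closed form
#'
#' Expected number of distinct alleles in a uniform without-replacement draw
#' of `g` gene copies, by the hurdle formula
#' `sum_i [1 - C(n - n_i, g) / C(n, g)]`.
#'
#' @param counts gene-copy counts per allele.
#' @param g rarefaction depth in gene copies, `1 <= g <= sum(counts)`.
#' @return Expected allele number (equals `k` at `g = n`).
#' @export
#' @examples
#' rarefied_richness_exact(c(A = 3, B = 1), g = 2) # 1.5
rarefied_richness_exact <- function(counts, g) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  g <- assert_count(g, "g")
  if (g > n) abort(sprintf("rarefaction depth g = %d exceeds the %d gene copies present", g, n))
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

#' Rarefied allelic richness, by resampling
#'
#' Monte-Carlo counterpart of [rarefied_richness_exact()]: repeatedly draw
#' `g` gene copies without replacement and count distinct alleles. The SD is
#' the empirical SD across iterations.
#'
#' @inheritParams rarefied_richness_exact
#' @param iterations number of resampling iterations.
#' @param seed integer seed.
#' @return A tibble with `mean`, `sd`, `iterations`.
#' @export
rarefied_richness_resample <- function(counts, g, iterations = 1000L, seed = 1L) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  g <- assert_count(g, "g")
  iterations <- assert_count(iterations, "iterations")
  if (g > n) abort(sprintf("rarefaction depth g = %d exceeds the %d gene copies present", g, n))
  pool <- rep.int(seq_along(counts), counts)
  draws <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      length(unique(pool[sample.int(n, g)]))
    }, numeric(1))
  })
  s <- stats::sd(draws)
  tibble::tibble(
    mean = mean(draws), sd = if (is.na(s)) 0 else s,
    iterations = iterations
  )
}

#' Per-sample, per-locus diversity table
#'
#' One row per (site, year, locus): gene copies `n_genes`, allele count `k`,
#' observed and unbiased expected heterozygosity, allelic size range `r`
#' (repeat units), M-ratio, and (optionally) rarefied allelic richness
#' `A_g` at depth `g` gene copies. Individuals missing a locus are dropped
#' for that locus (complete-case per locus); loci with fewer gene copies
#' than `g` get `NA` richness.
#'
#' @param geno a [genotype_table()].
#' @param g optional rarefaction depth in gene copies (e.g. `2 * 43` for a
#'   43-individual standard).
#' @return A tibble.
#' @export
diversity_table <- function(geno, g = NULL) {
  lt <- loci(geno)
  unit <- setNames(lt$repeat_unit, lt$locus)
  offset <- setNames(lt$size_offset, lt$locus)

  complete <- dplyr::filter(as_plain_tibble(geno), !is.na(.data$allele_1))
  ho <- complete |>
    dplyr::group_by(.data$site, .data$year, .data$locus) |>
    dplyr::summarise(
      n_genes = 2L * dplyr::n(),
      Ho = mean(.data$allele_1 != .data$allele_2),
      .groups = "drop"
    )

  per_locus <- allele_counts(geno) |>
    dplyr::group_by(.data$site, .data$year, .data$locus) |>
    dplyr::summarise(
      k = dplyr::n(),
      He = if (sum(.data$n_copies) >= 2) expected_heterozygosity(.data$n_copies) else NA_real_,
      r = (max(.data$allele) - min(.data$allele)) / unit[[.data$locus[1]]],
      M = m_ratio(setNames(.data$n_copies, .data$allele),
        repeat_unit = unit[[.data$locus[1]]],
        size_offset = offset[[.data$locus[1]]]
      ),
      A_g = if (!is.null(g) && sum(.data$n_copies) >= g) {
        rarefied_richness_exact(.data$n_copies, g)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  out <- dplyr::inner_join(ho, per_locus, by = c("site", "year", "locus"))
  out$locus <- factor(out$locus, levels = lt$locus)
  out <- dplyr::arrange(out, .data$site, .data$year, .data$locus)
  out$locus <- as.character(out$locus)
  if (is.null(g)) out$A_g <- NULL
  out
}
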