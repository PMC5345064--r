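# One-sample Wilcoxon signed-rank p-value with the classical treatment:
# zero differences dropped (empty set -> p = 1), ties share average ranks,
# exact null distribution when there are no ties and at most `exact_max`
# informative differences, normal approximation with continuity correction
# otherwise.
signed_rank_p <- function(d, alternative = c("greater", "less", "two.sided"),
                          exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(1)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    p_greater <- psignrank(v - 1, n, lower.tail = FALSE)
    p_less <- psignrank(v, n)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    p_greater <- pnorm((v - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    p_less <- pnorm((v - mu + 0.5) / sqrt(sigma2))
  }
  switch(alternative,
    greater = min(p_greater, 1),
    less = min(p_less, 1),
    two.sided = min(1, 2 * min(p_greater, p_less))
  )
}

#' Heterozygosity-excess bottleneck test
#'
#' For each sample (site x year) and each polymorphic locus, compares the
#' observed unbiased heterozygosity with the distribution of equilibrium
#' heterozygosity simulated conditional on the observed allele number under
#' the two-phase mutation model ([simulate_heq()]). A recently bottlenecked
#' population loses alleles faster than heterozygosity, so observed He sits
#' above the conditional equilibrium value. Loci are combined with a
#' one-tailed Wilcoxon signed-rank test on `He - mean(Heq)` (excess
#' direction by default; deficiency and two-sided variants behind
#' `alternative`).
#'
#' @param geno a [genotype_table()] (one or more samples).
#' @param mutation a [mutation_model()]; the default allows 10% multistep
#'   mutations.
#' @param reps retained equilibrium replicates per locus.
#' @param seed integer seed.
#' @param alternative `"excess"` (default), `"deficiency"`, or `"two.sided"`.
#' @param heq_cache optional environment used to memoise [simulate_heq()]
#'   calls across samples sharing (n, k); useful in simulation studies.
#' @return An object of class `heq_test` with elements `loci` (per-locus
#'   tibble: n_genes, k, He, mean/sd of Heq, standardized difference `DH`)
#'   and `samples` (per-sample tibble with the Wilcoxon p-value). Monomorphic
#'   loci are excluded (equilibrium He conditional on k = 1 is undefined).
#' @export
heterozygosity_excess_test <- function(geno, mutation = mutation_model(),
                                       reps = 1000L, seed = 1L,
                                       alternative = c("excess", "deficiency", "two.sided"),
                                       heq_cache = NULL) {
  alternative <- match.arg(alternative)
  wilcox_side <- switch(alternative,
    excess = "greater",
    deficiency = "less",
    two.sided = "two.sided"
  )

  div <- diversity_table(geno)
  poly <- dplyr::filter(div, .data$k >= 2L)
  if (!nrow(poly)) abort("all loci are monomorphic; the excess test is undefined")
  n_poly <- dplyr::count(poly, .data$site, .data$year)
  if (any(n_poly$n < 4L)) {
    warn("some samples have fewer than 4 polymorphic loci; the signed-rank test has little resolution there")
  }

  heq_for <- function(n_genes, k, stream) {
    key <- sprintf(
      "n%d_k%d_r%d_%.3g_%.3g_%.3g",
      n_genes, k, reps, mutation$rate, mutation$p_multistep, mutation$multistep_mean
    )
    if (!is.null(heq_cache) && !is.null(heq_cache[[key]])) {
      return(heq_cache[[key]])
    }
    out <- simulate_heq(n_genes, k, mutation,
      reps = reps,
      seed = child_seed(seed, stream)
    )
    if (!is.null(heq_cache)) heq_cache[[key]] <- out
    out
  }

  poly <- poly |>
    dplyr::mutate(.stream = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      heq = list(heq_for(.data$n_genes, .data$k, .data$.stream))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      Heq_mean = purrr::map_dbl(.data$heq, mean),
      Heq_sd = purrr::map_dbl(.data$heq, stats::sd),
      DH = (.data$He - .data$Heq_mean) / .data$Heq_sd,
      heq = NULL, .stream = NULL
    )

  samples <- poly |>
    dplyr::group_by(.data$site, .data$year) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      p_value = signed_rank_p(.data$He - .data$Heq_mean, alternative = wilcox_side),
      .groups = "drop"
    )

  structure(
    list(loci = poly, samples = samples, alternative = alternative, mutation = mutation),
    class = "heq_test"
  )
}

#' @export
print.heq_test <- function(x, ...) {
  cat(sprintf(
    "Heterozygosity-%s test (two-phase model, %g%% multistep)\n",
    x$alternative, 100 * x$mutation$p_multistep
  ))
  print(x$samples)
  invisible(x)
}

#' @export
tidy.heq_test <- function(x, ...) x$loci

#' @export
glance.heq_test <- function(x, ...) x$samples
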