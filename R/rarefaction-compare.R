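# Session registry used to flag seed reuse across different comparisons
# (re-using one seed for several sites pseudo-replicates the resampling).
.rarefy_seed_registry <- new.env(parent = emptyenv())

#' Before/after period design for hierarchical rarefaction
#'
#' Splits a site's yearly samples into a pre-disturbance and a
#' post-disturbance period and standardizes the comparison: samples smaller
#' than `n_individuals` are excluded up front (and logged), and the number
#' of yearly samples drawn per period (`years_per_block`) is the smaller
#' period's year count, so both periods contribute
#' `n_individuals x years_per_block` individuals per iteration.
#'
#' @param geno a [genotype_table()].
#' @param site site to compare.
#' @param tsunami_year disturbance year; before-years are `< tsunami_year`,
#'   after-years start the following calendar year.
#' @param n_individuals individuals drawn per yearly sample.
#' @param iterations resampling iterations.
#' @return A `period_design` object.
#' @export
build_period_design <- function(geno, site, tsunami_year = 2011L,
                                n_individuals = 43L, iterations = 1000L) {
  sizes <- sample_sizes(geno)
  sizes <- sizes[sizes$site == site, ]
  if (!nrow(sizes)) abort(sprintf("site '%s' not present in the dataset", site))
  n_individuals <- assert_count(n_individuals, "n_individuals")
  iterations <- assert_count(iterations, "iterations")

  excluded <- sizes[sizes$n < n_individuals, ]
  if (nrow(excluded)) {
    inform(sprintf(
      "excluding %d under-sized sample(s) at %s: %s",
      nrow(excluded), site,
      paste(sprintf("%d (n = %d)", excluded$year, excluded$n), collapse = ", ")
    ))
  }
  usable <- sizes[sizes$n >= n_individuals, ]
  before_years <- sort(usable$year[usable$year < tsunami_year])
  after_years <- sort(usable$year[usable$year >= tsunami_year + 1L])
  if (!length(before_years) || !length(after_years)) {
    abort(sprintf(
      "site '%s' lacks usable samples on one side of %d (before: %d, after: %d)",
      site, tsunami_year, length(before_years), length(after_years)
    ))
  }

  structure(
    list(
      site = site,
      before_years = before_years,
      after_years = after_years,
      years_per_block = min(length(before_years), length(after_years)),
      n_individuals = n_individuals,
      iterations = iterations,
      excluded = excluded
    ),
    class = "period_design"
  )
}

#' @export
print.period_design <- function(x, ...) {
  cat(sprintf(
    "Period design for %s: before {%s} | after {%s}; %d year(s) per block x %d individuals (%d in total per iteration)\n",
    x$site, paste(x$before_years, collapse = ", "),
    paste(x$after_years, collapse = ", "),
    x$years_per_block, x$n_individuals,
    2L * x$years_per_block * x$n_individuals
  ))
  invisible(x)
}

# Per-year allele matrices in repeat units (individuals x loci), the fast
# currency of the resampler.
repeat_unit_matrices <- function(geno, site, years) {
  lt <- loci(geno)
  setNames(lapply(years, function(y) {
    rows <- as_plain_tibble(geno)[geno$site == site & geno$year == y, ]
    wide1 <- tidyr::pivot_wider(rows,
      id_cols = "individual",
      names_from = "locus", values_from = "allele_1"
    )
    wide2 <- tidyr::pivot_wider(rows,
      id_cols = "individual",
      names_from = "locus", values_from = "allele_2"
    )
    a1 <- as.matrix(wide1[lt$locus])
    a2 <- as.matrix(wide2[lt$locus])
    for (j in seq_len(nrow(lt))) {
      a1[, j] <- (a1[, j] - lt$size_offset[j]) / lt$repeat_unit[j]
      a2[, j] <- (a2[, j] - lt$size_offset[j]) / lt$repeat_unit[j]
    }
    list(a1 = a1, a2 = a2, individuals = wide1$individual)
  }), as.character(years))
}

#' Hierarchically rarefied richness and M-ratio, before vs after
#'
#' The two-level resampling that standardizes both sampling effort levels:
#' each iteration draws `years_per_block` yearly samples without replacement
#' from each period, then `n_individuals` individuals without replacement
#' within each drawn sample, pools the draw, and computes the per-locus
#' allele number and M-ratio of the pool (pooled counts, pooled size range).
#' Across-locus means are recorded per iteration; period summaries are the
#' mean and empirical SD across iterations.
#'
#' @param geno a [genotype_table()].
#' @param design a [build_period_design()].
#' @param seed integer seed; reusing a seed for a different site in the same
#'   session triggers a pseudo-replication warning.
#' @param redraw_years if `TRUE` (default) the year subset is redrawn each
#'   iteration; if `FALSE` one subset is fixed for the whole run.
#' @return A `rarefaction_result`: per-iteration tibble, per-period
#'   summaries, per-locus mean differences (after - before), and sign-test
#'   p-values via [sign_test_change()].
#' @export
hierarchical_rarefy <- function(geno, design, seed = 1L, redraw_years = TRUE) {
  stopifnot(inherits(design, "period_design"))
  key <- as.character(seed)
  prev <- .rarefy_seed_registry[[key]]
  if (!is.null(prev) && !identical(prev, design$site)) {
    warn(sprintf(
      "seed %s was already used for site '%s'; reusing it for '%s' pseudo-replicates the resampling",
      key, prev, design$site
    ))
  }
  .rarefy_seed_registry[[key]] <- design$site

  lt <- loci(geno)
  L <- nrow(lt)
  years <- list(before = design$before_years, after = design$after_years)
  mats <- repeat_unit_matrices(geno, design$site, unlist(years))
  for (m in mats) {
    if (nrow(m$a1) < design$n_individuals) {
      abort("a period year has fewer individuals than the design requires")
    }
  }

  iters <- design$iterations
  nb <- design$years_per_block
  res <- with_seed(seed, {
    fixed_sets <- lapply(years, function(ys) {
      if (redraw_years || length(ys) == nb) ys[seq_len(nb)] else sample(ys, nb)
    })
    rich <- matrix(NA_real_, iters, 2L, dimnames = list(NULL, names(years)))
    mrat <- rich
    npool <- rich
    locus_rich <- matrix(0, L, 2L, dimnames = list(lt$locus, names(years)))
    locus_m <- locus_rich
    for (it in seq_len(iters)) {
      for (p in c("before", "after")) {
        ys <- if (redraw_years && length(years[[p]]) > nb) {
          sample(years[[p]], nb)
        } else {
          fixed_sets[[p]]
        }
        drawn <- lapply(as.character(ys), function(y) {
          m <- mats[[y]]
          idx <- sample.int(nrow(m$a1), design$n_individuals)
          list(
            a1 = m$a1[idx, , drop = FALSE],
            a2 = m$a2[idx, , drop = FALSE]
          )
        })
        pooled1 <- do.call(rbind, lapply(drawn, `[[`, "a1"))
        pooled2 <- do.call(rbind, lapply(drawn, `[[`, "a2"))
        kk <- numeric(L)
        mm <- numeric(L)
        for (l in seq_len(L)) {
          v <- c(pooled1[, l], pooled2[, l])
          v <- v[!is.na(v)]
          u <- unique(v)
          kk[l] <- length(u)
          mm[l] <- length(u) / (max(u) - min(u) + 1)
        }
        rich[it, p] <- mean(kk)
        mrat[it, p] <- mean(mm)
        npool[it, p] <- nrow(pooled1)
        locus_rich[, p] <- locus_rich[, p] + kk
        locus_m[, p] <- locus_m[, p] + mm
      }
    }
    list(
      rich = rich, mrat = mrat, npool = npool,
      locus_rich = locus_rich / iters, locus_m = locus_m / iters
    )
  })

  iterations_tbl <- tibble::tibble(
    iteration = rep(seq_len(iters), 2L),
    period = rep(c("before", "after"), each = iters),
    richness = c(res$rich[, "before"], res$rich[, "after"]),
    m_ratio = c(res$mrat[, "before"], res$mrat[, "after"]),
    n_pooled = as.integer(c(res$npool[, "before"], res$npool[, "after"]))
  )
  summary_tbl <- iterations_tbl |>
    tidyr::pivot_longer(c("richness", "m_ratio"), names_to = "index") |>
    dplyr::group_by(.data$period, .data$index) |>
    dplyr::summarise(
      mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    )
  locus_diff <- tibble::tibble(
    locus = lt$locus,
    d_richness = res$locus_rich[, "after"] - res$locus_rich[, "before"],
    d_m_ratio = res$locus_m[, "after"] - res$locus_m[, "before"]
  )

  structure(
    list(
      iterations = iterations_tbl,
      summary = summary_tbl,
      locus_diff = locus_diff,
      design = design,
      samples_total = 2L * nb * design$n_individuals
    ),
    class = "rarefaction_result"
  )
}

#' Sign test on the before/after change
#'
#' Reduces the per-locus mean (over iterations) after-minus-before
#' differences to signs and applies the exact two-tailed binomial sign test
#' per index (richness, M-ratio). Zero differences are dropped.
#'
#' @param result a [hierarchical_rarefy()] result.
#' @return A tibble with columns `index`, `n_positive`, `n_negative`,
#'   `p_value`.
#' @export
sign_test_change <- function(result) {
  stopifnot(inherits(result, "rarefaction_result"))
  purrr::map_dfr(
    c(richness = "d_richness", m_ratio = "d_m_ratio"),
    function(col) {
      d <- result$locus_diff[[col]]
      d <- d[d != 0]
      if (!length(d)) {
        warn("all per-locus differences are zero; sign test is uninformative")
        return(tibble::tibble(n_positive = 0L, n_negative = 0L, p_value = 1))
      }
      if (length(d) < 5L) {
        warn("fewer than 5 loci with nonzero differences; the sign test has little power")
      }
      pos <- sum(d > 0)
      tibble::tibble(
        n_positive = pos,
        n_negative = length(d) - pos,
        p_value = binom.test(pos, length(d), 0.5)$p.value
      )
    },
    .id = "index"
  )
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf(
    "Hierarchical rarefaction at %s: %d iterations, %d year(s) per block x %d individuals (%d samples in total)\n",
    x$design$site, x$design$iterations, x$design$years_per_block,
    x$design$n_individuals, x$samples_total
  ))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.rarefaction_result <- function(x, ...) x$iterations

#' @export
glance.rarefaction_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary,
    names_from = "period",
    values_from = c("mean", "sd")
  )
  dplyr::left_join(wide, sign_test_change(x), by = "index")
}
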