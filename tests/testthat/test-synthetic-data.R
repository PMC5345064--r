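test_that("the study design has seven sample years and the decided generation map", {
  des <- make_study_design()
  expect_identical(des$sample_years, c(2005L, 2006L, 2010L, 2012L, 2013L, 2014L, 2015L))
  expect_identical(des$generation_time, 3)
  # round((2015 - 2005)/3) = 3 generations before the newest sample
  expect_identical(generations_before_anchor(2005L, des), 3L)
  expect_identical(generations_before_anchor(2014L, des), 0L)

  small <- make_study_design(small_sample = list(site = "mangokuura", year = 2013L, n = 12L))
  expect_identical(snaildrift:::n_for_sample(small, "mangokuura", 2013L), 12L)
  expect_identical(snaildrift:::n_for_sample(small, "mangokuura", 2012L), 43L)
})

test_that("study scenarios carry the emulated crash magnitudes", {
  sc <- make_study_scenarios()
  rates <- vapply(sc, function(s) {
    rate_of_change(s$trajectory[1L], s$trajectory[length(s$trajectory)])
  }, numeric(1))
  expect_equal(unname(rates[c("nagatsuraura", "mangokuura")]), c(-60, -88))
  expect_lt(rates[["torinoumi"]], -98)
  expect_true(all(rates[c("katsugigaura", "sokanzan", "matsukawaura")] == 0))
  for (s in sc[c("katsugigaura", "sokanzan", "matsukawaura")]) {
    expect_identical(length(unique(s$trajectory)), 1L)
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  sc <- demography_scenario("s", rep(30L, 4L))
  des <- make_study_design(n_default = 10L)
  g1 <- simulate_site(sc, mutation_model(rate = 2e-3), n_loci = 3L, design = des, seed = 9)
  g2 <- simulate_site(sc, mutation_model(rate = 2e-3), n_loci = 3L, design = des, seed = 9)
  expect_identical(
    snaildrift:::as_plain_tibble(g1),
    snaildrift:::as_plain_tibble(g2)
  )
})

test_that("a vanishing mutation rate leaves every sample monomorphic", {
  sc <- demography_scenario("s", rep(10L, 4L))
  des <- make_study_design(n_default = 5L)
  g <- simulate_site(sc, mutation_model(rate = 1e-7), n_loci = 3L, design = des, seed = 3)
  d <- diversity_table(g)
  expect_true(all(d$k == 1L))
})

test_that("allele sizes never cross the reflection floor", {
  mm <- mutation_model(rate = 0.05, p_multistep = 0.5, reflection_floor = 5L)
  sc <- demography_scenario("s", rep(30L, 4L))
  des <- make_study_design(n_default = 10L)
  lt <- locus_table(c("A", "B"), repeat_unit = 1L, size_offset = 0L)
  g <- simulate_site(sc, mm, n_loci = 2L, design = des, seed = 13, loci = lt, founder_size = 7L)
  expect_gte(min(c(g$allele_1, g$allele_2)), 5L)
})

test_that("oversized sample requests and short trajectories are rejected", {
  des <- make_study_design(n_default = 50L)
  expect_error(
    simulate_site(demography_scenario("s", rep(20L, 4L)), mutation_model(),
      n_loci = 2L, design = des, seed = 1
    ),
    "exceeds the contemporaneous Ne"
  )
  expect_error(
    simulate_site(demography_scenario("s", rep(50L, 2L)), mutation_model(),
      n_loci = 2L, design = des, seed = 1
    ),
    "trajectory covers"
  )
  expect_error(demography_scenario("s", integer(0)), "empty")
  expect_error(demography_scenario("s", c(10L, 1L)), ">= 2")
})

test_that("equilibrium heterozygosity matches the stepwise-model closed form", {
  # strict SMM, constant Ne = 500, mu = 5e-4: He = 1 - 1/sqrt(1 + 8*Ne*mu)
  mm <- mutation_model(rate = 5e-4, p_multistep = 0)
  des <- sampling_design(2015L, n_default = 40L, anchor_year = 2015L)
  sc <- demography_scenario("eq", 500L)
  g <- simulate_site(sc, mm, n_loci = 200L, design = des, seed = 31)
  he <- diversity_table(g)$He
  theory <- 1 - 1 / sqrt(1 + 8 * 500 * 5e-4)
  se <- stats::sd(he) / sqrt(length(he))
  expect_lt(abs(mean(he) - theory), 3 * se)
})

test_that("a crash reduces allele number and the M-ratio, and drift tracks the trajectory", {
  des <- make_study_design(n_default = 25L)
  mm <- mutation_model(rate = 2e-3, p_multistep = 0)
  k_pre <- k_post <- m_pre <- m_post <- numeric(50)
  for (i in 1:50) {
    sc <- demography_scenario("crash", c(500L, 500L, 25L, 25L), crash_generation = 2L)
    g <- simulate_site(sc, mm, n_loci = 6L, design = des, seed = 700 + i)
    d <- diversity_table(g)
    # 2010 precedes the crash; by 2015 two bottleneck generations have passed
    k_pre[i] <- mean(d$k[d$year == 2010L])
    k_post[i] <- mean(d$k[d$year == 2015L])
    m_pre[i] <- mean(d$M[d$year == 2010L])
    m_post[i] <- mean(d$M[d$year == 2015L])
  }
  # one-sided over replicate seeds: post-crash allele number is reduced
  expect_lt(
    suppressWarnings(
      stats::wilcox.test(k_post, k_pre, alternative = "less", paired = TRUE)$p.value
    ),
    0.01
  )
  # under pure SMM the M-ratio concentrates high pre-crash vs post-crash
  expect_gt(stats::median(m_pre), stats::median(m_post))

  # temporal allele-frequency variance grows with cumulative drift; mutation
  # rates scale inversely with Ne so every scenario sits at theta = 2 and
  # only the drift differs
  sizes <- c(40L, 80L, 200L, 600L)
  drift_pred <- freq_var <- numeric(length(sizes))
  for (j in seq_along(sizes)) {
    sc <- demography_scenario("s", rep(sizes[j], 4L))
    mm2 <- mutation_model(rate = 2 / (4 * sizes[j]))
    g <- simulate_site(sc, mm2,
      n_loci = 12L,
      design = make_study_design(n_default = 30L), seed = 40 + j
    )
    fv <- allele_counts(g) |>
      dplyr::filter(year %in% c(2005L, 2015L)) |>
      tidyr::pivot_wider(names_from = year, values_from = n_copies, values_fill = 0L) |>
      dplyr::group_by(locus) |>
      dplyr::summarise(
        num = {
          p1 <- `2005` / sum(`2005`)
          p2 <- `2015` / sum(`2015`)
          sum((p1 - p2)^2)
        },
        den = {
          p1 <- `2005` / sum(`2005`)
          p2 <- `2015` / sum(`2015`)
          pb <- (p1 + p2) / 2
          sum(pb * (1 - pb))
        },
        .groups = "drop"
      )
    freq_var[j] <- sum(fv$num) / sum(fv$den)
    drift_pred[j] <- drift_accumulation(sizes[j], sizes[j], 3L)
  }
  expect_gt(stats::cor(drift_pred, freq_var, method = "spearman"), 0)
})

test_that("all six study scenarios simulate end-to-end into a valid dataset", {
  des <- make_study_design(n_default = 10L)
  sc <- make_study_scenarios(n_base = 100L, design = des)
  g <- simulate_dataset(sc, mutation_model(rate = 1e-3), n_loci = 3L, design = des, seed = 8)
  expect_s3_class(g, "genotype_tbl")
  expect_identical(nrow(sample_sizes(g)), 42L)
  expect_identical(nrow(check_repeat_structure(g)), 0L)
})
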