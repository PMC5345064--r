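test_that("cumulative drift follows the product formula and is time-reversible", {
  expect_identical(drift_accumulation(500, 500, 0L), 0)
  expect_equal(drift_accumulation(500, 500, 3L), 1 - (1 - 1 / 1000)^3, tolerance = 1e-12)
  # swapping the endpoints reverses the trajectory but not the total drift
  expect_equal(
    drift_accumulation(500, 50, 4L),
    drift_accumulation(50, 500, 4L),
    tolerance = 1e-12
  )
  # monotone in elapsed generations
  f <- drift_accumulation(300, 40, 0:5, total_span = 5L)
  expect_true(all(diff(f) > 0))
})

test_that("the temporal likelihood is additive over loci and monotone for identical samples", {
  m <- rbind(
    c(150L, 150L, 152L, 152L, 154L, 150L),
    c(152L, 150L, 154L, 152L, 150L, 150L)
  )
  # two identical loci: log-likelihood doubles
  rows1 <- tibble::tibble(
    site = "s", year = rep(c(2005L, 2015L), each = 6),
    individual = rep(sprintf("i%02d", 1:6), 2),
    locus = "L1",
    allele_1 = rep(m[1, ], 2), allele_2 = rep(m[2, ], 2)
  )
  rows2 <- dplyr::mutate(rows1, locus = "L2")
  cnt_one <- snaildrift:::temporal_counts(
    genotype_table(rows1, loci = locus_table("L1", 2L, 100L)), "s", make_study_design()
  )
  cnt_two <- snaildrift:::temporal_counts(
    genotype_table(dplyr::bind_rows(rows1, rows2), loci = locus_table(c("L1", "L2"), 2L, 100L)),
    "s", make_study_design()
  )
  expect_equal(
    temporal_log_likelihood(cnt_two, 120, 60),
    2 * temporal_log_likelihood(cnt_one, 120, 60),
    tolerance = 1e-10
  )

  # identical counts at both times: likelihood rises along the N_before = N_after ray
  lls <- vapply(c(5, 20, 100, 500, 2000, 5000), function(n) {
    temporal_log_likelihood(cnt_one, n, n)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("the drift predictive matches brute-force integration on a two-allele toy", {
  # (a) Dirichlet-multinomial compound identity, checked by Monte Carlo over
  # the drifted frequency
  alpha <- c(2.1, 0.9)
  x <- c(2, 2)
  analytic <- exp(snaildrift:::ddirmult_log(x, alpha))
  set.seed(123)
  q <- stats::rbeta(40000, alpha[1], alpha[2])
  vals <- stats::dbinom(x[1], sum(x), q)
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(analytic - mean(vals)), 3 * se)

  # (b) baseline integration: the filter's moment-matched predictive vs the
  # exact quadrature over the baseline posterior (4 baseline genes, 2 alleles)
  a <- c(3, 1) + 1
  f <- 0.15
  conc <- (1 - f) / f
  m <- a / sum(a)
  v <- 1 / (sum(a) + 1)
  v_pred <- v + (1 - v) * f
  A <- (1 - v_pred) / v_pred
  lbb <- function(x1, n, a1, a2) lchoose(n, x1) + lbeta(x1 + a1, n - x1 + a2) - lbeta(a1, a2)
  analytic <- exp(lbb(x[1], sum(x), m[1] * A, m[2] * A))
  exact <- stats::integrate(function(p) {
    stats::dbeta(p, a[1], a[2]) * exp(lbb(x[1], sum(x), conc * p, conc * (1 - p)))
  }, 0, 1, rel.tol = 1e-10)$value
  expect_lt(abs(analytic - exact) / exact, 0.05)
  # and the quadrature itself agrees with simulating the full hierarchy
  set.seed(321)
  p0 <- stats::rbeta(40000, a[1], a[2])
  qq <- stats::rbeta(40000, conc * p0, conc * (1 - p0))
  vals <- stats::dbinom(x[1], sum(x), qq)
  expect_lt(abs(exact - mean(vals)), 3 * stats::sd(vals) / sqrt(length(vals)))
})

test_that("the Metropolis sampler is reproducible and respects the prior bounds", {
  st <- mcmc_settings(iterations = 2000, n_runs = 2, thinning = 4, seed = 3, n_max = 500)
  p1 <- suppressWarnings(run_mcmc(NULL, st, log_likelihood = NULL))
  p2 <- suppressWarnings(run_mcmc(NULL, st, log_likelihood = NULL))
  expect_identical(p1$chains, p2$chains)
  draws <- snaildrift:::posterior_draws(p1)
  expect_true(all(draws >= 2 & draws <= 500))
  expect_identical(nrow(p1$chains[[1]]), 250L)
})

test_that("a simulated crash is recovered in the right direction", {
  des <- make_study_design()
  sc <- demography_scenario("crash", c(500L, 500L, 50L, 50L), crash_generation = 2L)
  g <- simulate_site(sc, make_study_mutation_model(), n_loci = 14L, design = des, seed = 40001)
  st <- mcmc_settings(iterations = 8000, n_runs = 3, thinning = 5, seed = 99)
  post <- estimate_temporal_ne(g, "crash", st)
  s <- tidy(post)
  expect_lt(s$median[s$parameter == "n_after"], s$median[s$parameter == "n_before"])
  expect_true(all(gelman_rubin(post)$r_hat < 1.2))
  gl <- glance(post)
  expect_identical(gl$site, "crash")
  expect_gt(gl$bayes_factor, 1)
})

test_that("Bayes factors follow the posterior draw ratio and the Jeffreys scale", {
  sym <- cbind(c(1:50, 51:100), c(51:100, 1:50))
  v <- bayes_factor(fake_posterior(sym, sym))
  expect_equal(v$bayes_factor, 1)
  expect_identical(v$category, "none")

  expect_identical(classify_bayes_factor(128.9), "strong")
  expect_identical(classify_bayes_factor(3.3), "substantial")
  expect_identical(classify_bayes_factor(2.4), "none")
  expect_identical(classify_bayes_factor(1), "none")
  expect_identical(classify_bayes_factor(0.2), "false_detection")

  # all draws declining: zero denominator reads as infinitely strong support
  dec <- cbind(rep(100, 40), rep(10, 40))
  v2 <- bayes_factor(fake_posterior(dec, dec))
  expect_identical(v2$bayes_factor, Inf)
  expect_identical(v2$category, "strong")
})

test_that("swapping the endpoint draws inverts the Bayes factor and mirrors the category", {
  set.seed(5)
  m1 <- cbind(exp(stats::rnorm(300, 6, 0.4)), exp(stats::rnorm(300, 3, 0.4)))
  m2 <- cbind(exp(stats::rnorm(300, 6, 0.4)), exp(stats::rnorm(300, 3, 0.4)))
  v <- bayes_factor(fake_posterior(m1, m2))
  v_swap <- bayes_factor(fake_posterior(m1[, 2:1], m2[, 2:1]))
  expect_equal(v_swap$bayes_factor, 1 / v$bayes_factor, tolerance = 1e-12)
  expect_identical(v$category, "strong")
  expect_identical(v_swap$category, "false_detection")

  near <- cbind(exp(stats::rnorm(400, 4, 0.5)), exp(stats::rnorm(400, 4, 0.5)))
  v3 <- bayes_factor(fake_posterior(near, near))
  v3s <- bayes_factor(fake_posterior(near[, 2:1], near[, 2:1]))
  expect_identical(v3$category, "none")
  expect_identical(v3s$category, "none")
})

test_that("highest-density intervals behave on uniform, degenerate, and nested cases", {
  set.seed(8)
  u <- stats::runif(20000)
  h <- hpd(u, mass_levels = 0.9)
  expect_lt(abs((h$upper - h$lower) - 0.9), 0.02)

  pt <- hpd(rep(3.3, 100), mass_levels = c(0.5, 0.9))
  expect_true(all(pt$upper - pt$lower == 0))

  x <- stats::rnorm(5000)
  hh <- hpd(x, mass_levels = c(0.5, 0.9))
  expect_lte(hh$lower[hh$mass == 0.9][1], hh$lower[hh$mass == 0.5][1])
  expect_gte(hh$upper[hh$mass == 0.9][1], hh$upper[hh$mass == 0.5][1])

  expect_error(hpd(x, mass_levels = 1.2), "strictly")
})

test_that("the convergence diagnostic matches a one-way ANOVA decomposition", {
  set.seed(9)
  a <- cbind(exp(stats::rnorm(200, 4, 0.3)), exp(stats::rnorm(200, 3, 0.3)))
  b <- cbind(exp(stats::rnorm(200, 4.4, 0.3)), exp(stats::rnorm(200, 3, 0.3)))
  post <- fake_posterior(a, b)
  gr <- gelman_rubin(post)

  # independent route: classical between/within decomposition via stats::aov
  for (par in c("n_before", "n_after")) {
    sims <- cbind(log(a[, ifelse(par == "n_before", 1, 2)]), log(b[, ifelse(par == "n_before", 1, 2)]))
    df <- data.frame(v = c(sims), chain = factor(rep(1:2, each = 200)))
    tab <- summary(stats::aov(v ~ chain, data = df))[[1]]
    w <- tab["Residuals", "Mean Sq"]
    b_over_n <- tab["chain", "Mean Sq"] / 200
    ref <- sqrt(max(1, (199 / 200 * w + b_over_n) / w))
    expect_equal(gr$r_hat[gr$parameter == par], ref, tolerance = 1e-6)
  }

  # identical chains: exactly 1
  same <- fake_posterior(a, a)
  expect_identical(unique(gelman_rubin(same)$r_hat), 1)
  # chains exploring disjoint ranges: far from converged
  lo <- cbind(rep(10, 100) + stats::runif(100), rep(10, 100) + stats::runif(100))
  hi <- cbind(rep(1000, 100) + stats::runif(100), rep(1000, 100) + stats::runif(100))
  expect_true(all(gelman_rubin(fake_posterior(lo, hi))$r_hat > 1.1))
  expect_error(gelman_rubin(fake_posterior(a)), "2 chains")
})

test_that("rate of change reproduces simple endpoints", {
  expect_identical(rate_of_change(10, 10), 0)
  expect_identical(rate_of_change(200, 100), -50)
  expect_error(rate_of_change(0, 5), "positive")
})
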