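# Coalescent sampler for one microsatellite locus under the two-phase
# model. Works backward in time on lineage leaf-sets: during the interval
# with k active lineages, mutations fall as Poisson(k * theta/2 * dt) and
# each adds a signed two-phase step to every leaf below its lineage. Only
# relative sizes matter here (allele identity drives k and He), so no
# reflection boundary is applied.
coalescent_locus <- function(n, theta, model) {
  values <- integer(n)
  members <- as.list(seq_len(n))
  k <- n
  while (k > 1L) {
    dt <- rexp(1L, rate = k * (k - 1L) / 2)
    n_mut <- rpois(1L, k * theta / 2 * dt)
    if (n_mut > 0L) {
      hit <- sample.int(k, n_mut, replace = TRUE)
      steps <- draw_steps(n_mut, model)
      for (m in seq_len(n_mut)) {
        idx <- members[[hit[m]]]
        values[idx] <- values[idx] + steps[m]
      }
    }
    pair <- sample.int(k, 2L)
    members[[pair[1L]]] <- c(members[[pair[1L]]], members[[pair[2L]]])
    members[[pair[2L]]] <- members[[k]]
    members[[k]] <- NULL
    k <- k - 1L
  }
  values
}

# Monte-Carlo expected allele count at (n, theta).
expected_k_mc <- function(n, theta, model, reps) {
  mean(vapply(seq_len(reps), function(i) {
    length(unique(coalescent_locus(n, theta, model)))
  }, numeric(1)))
}

#' Calibrate theta to an observed allele count
#'
#' Finds the scaled mutation rate `theta = 4*Ne*mu` at which the expected
#' allele count of a coalescent sample of `n_genes` gene copies equals
#' `k_obs` (within `tol` alleles), by bisection on `log(theta)` with a
#' Monte-Carlo estimate of the expectation at each probe. Deterministic for
#' a fixed seed.
#'
#' @param n_genes gene copies in the sample.
#' @param k_obs observed allele count, `2 <= k_obs <= n_genes`.
#' @param mutation a [mutation_model()].
#' @param seed integer seed.
#' @param tol calibration tolerance, alleles.
#' @param reps coalescent replicates per probe.
#' @return theta (scalar).
#' @export
calibrate_theta <- function(n_genes, k_obs, mutation = mutation_model(),
                            seed = 1L, tol = 0.25, reps = 400L) {
  n_genes <- assert_count(n_genes, "n_genes", min = 2L)
  k_obs <- assert_count(k_obs, "k_obs", min = 2L)
  if (k_obs > n_genes) abort("`k_obs` cannot exceed `n_genes`")

  eval_count <- 0L
  probe <- function(log_theta) {
    eval_count <<- eval_count + 1L
    with_seed(child_seed(seed, eval_count), {
      expected_k_mc(n_genes, exp(log_theta), mutation, reps) - k_obs
    })
  }

  lo <- log(0.01)
  hi <- log(50)
  f_lo <- probe(lo)
  f_hi <- probe(hi)
  tries <- 0L
  while (f_lo > 0 && tries < 6L) {
    lo <- lo - log(10)
    f_lo <- probe(lo)
    tries <- tries + 1L
  }
  tries <- 0L
  while (f_hi < 0 && tries < 6L) {
    hi <- hi + log(10)
    f_hi <- probe(hi)
    tries <- tries + 1L
  }
  if (f_lo > 0 || f_hi < 0) {
    abort(sprintf(
      "theta calibration cannot bracket k = %d at n = %d (expected allele count range [%.2f, %.2f])",
      k_obs, n_genes, f_lo + k_obs, f_hi + k_obs
    ))
  }

  for (i in seq_len(30L)) {
    mid <- (lo + hi) / 2
    f_mid <- probe(mid)
    if (abs(f_mid) <= tol) {
      return(exp(mid))
    }
    if (f_mid < 0) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Simulated equilibrium heterozygosity conditional on allele number
#'
#' The reference distribution of the heterozygosity-excess test: coalescent
#' samples of `n_genes` gene copies are simulated under the two-phase model
#' at a theta calibrated so the expected allele count equals `k_obs`, and
#' only replicates whose realized allele count equals `k_obs` are retained.
#' Heterozygosity is Nei's unbiased estimator.
#'
#' @inheritParams calibrate_theta
#' @param reps retained replicates required (>= 100 for a usable reference).
#' @param theta optional pre-calibrated theta (skips calibration).
#' @return Numeric vector of `reps` equilibrium He values; attributes
#'   `theta` and `retention` (acceptance rate of the conditioning).
#' @export
simulate_heq <- function(n_genes, k_obs, mutation = mutation_model(),
                         reps = 1000L, seed = 1L, theta = NULL) {
  reps <- assert_count(reps, "reps")
  if (is.null(theta)) {
    theta <- calibrate_theta(n_genes, k_obs, mutation, seed = child_seed(seed, 0L))
  }
  batch <- max(reps, 200L)
  kept <- numeric(0)
  attempts <- 0L
  warned <- FALSE
  with_seed(child_seed(seed, 1L), {
    while (length(kept) < reps) {
      he <- vapply(seq_len(batch), function(i) {
        v <- coalescent_locus(n_genes, theta, mutation)
        if (length(unique(v)) == k_obs) {
          expected_heterozygosity(table(v))
        } else {
          NA_real_
        }
      }, numeric(1))
      kept <- c(kept, he[!is.na(he)])
      attempts <- attempts + batch
      if (!warned && attempts >= 100L * reps && length(kept) < attempts / 100L) {
        warn(sprintf(
          "conditioning on k = %d retains %.2f%% of replicates at n = %d, theta = %.3g",
          k_obs, 100 * length(kept) / attempts, n_genes, theta
        ))
        warned <- TRUE
      }
      if (attempts > 2000L * reps) {
        abort(sprintf(
          "conditioning on k = %d failed: %d of %d replicates retained",
          k_obs, length(kept), attempts
        ))
      }
    }
  })
  structure(kept[seq_len(reps)],
    theta = theta,
    retention = length(kept) / attempts
  )
}
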