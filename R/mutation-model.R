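#' Two-phase microsatellite mutation model
#'
#' The mutation law shared by the forward simulator and the equilibrium
#' heterozygosity test. A mutation is a single-step change of +/-1 repeat
#' with probability `1 - p_multistep`; otherwise it is a multistep change
#' whose magnitude (in repeats) is geometric with mean `multistep_mean`,
#' with a symmetric random sign. `p_multistep = 0` gives the strict stepwise
#' model (SMM). Allele sizes reflect at `reflection_floor` repeats so they
#' can never walk below it.
#'
#' @param rate per-locus, per-generation, per-gene-copy mutation probability
#'   mu, in (0, 0.05]. May be a vector (one rate per locus): microsatellite
#'   panels show order-of-magnitude rate variation across loci, and a
#'   heterogeneous panel is what reproduces the wide spread of allele counts
#'   (roughly 4-23 per locus) seen in real multi-locus datasets.
#' @param p_multistep probability a mutation is multistep; the two-phase
#'   model used throughout defaults to 0.10.
#' @param multistep_mean mean magnitude (repeats) of a multistep change;
#'   geometric step law.
#' @param reflection_floor minimum allele size in repeat units.
#' @return A `mutation_model` object (a list).
#' @export
#' @examples
#' mutation_model()                    # two-phase model, 10% multistep
#' mutation_model(p_multistep = 0)     # strict stepwise model
mutation_model <- function(rate = 5e-4, p_multistep = 0.10,
                           multistep_mean = 2.8, reflection_floor = 5L) {
  if (!all(rate > 0 & rate <= 0.05)) abort("`rate` must be in (0, 0.05]")
  if (p_multistep < 0 || p_multistep > 1) abort("`p_multistep` must be in [0, 1]")
  if (multistep_mean < 1) abort("`multistep_mean` must be >= 1 repeat")
  structure(
    list(
      rate = rate,
      p_multistep = p_multistep,
      multistep_mean = multistep_mean,
      reflection_floor = as.integer(reflection_floor)
    ),
    class = "mutation_model"
  )
}

#' Heterogeneous study mutation panel
#'
#' A two-phase [mutation_model()] with per-locus rates log-spaced across
#' `rate_range`, giving scaled mutation rates `theta = 4*Ne*mu` from about
#' 0.5 to 40 at the default baseline Ne of 500. This spread reproduces the
#' wide range of per-locus allele counts (about 4-23 pooled over sites and
#' years) that multi-locus microsatellite panels typically show; a uniform
#' rate cannot.
#'
#' @param n_loci number of loci in the panel.
#' @param rate_range lower and upper per-locus mutation rates.
#' @param ... passed to [mutation_model()].
#' @return A [mutation_model()] with a vector `rate`.
#' @export
make_study_mutation_model <- function(n_loci = 14L, rate_range = c(2.5e-4, 0.02), ...) {
  n_loci <- assert_count(n_loci, "n_loci")
  mutation_model(
    rate = exp(seq(log(rate_range[1L]), log(rate_range[2L]), length.out = n_loci)),
    ...
  )
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf(
    "Two-phase mutation model: mu = %g, %g%% multistep (geometric, mean %g repeats), floor %d repeats\n",
    x$rate, 100 * x$p_multistep, x$multistep_mean, x$reflection_floor
  ))
  invisible(x)
}

# Draw n signed mutation step sizes (repeats) under the two-phase law.
draw_steps <- function(n, model) {
  if (n == 0L) {
    return(integer(0))
  }
  multi <- runif(n) < model$p_multistep
  size <- rep(1L, n)
  if (any(multi)) {
    # geometric on {1, 2, ...} with mean multistep_mean
    size[multi] <- 1L + rgeom(sum(multi), prob = 1 / model$multistep_mean)
  }
  sign <- sample(c(-1L, 1L), n, replace = TRUE)
  sign * size
}

# Apply steps to allele sizes (repeat units), reflecting at the floor.
mutate_alleles <- function(sizes, steps, model) {
  out <- sizes + steps
  below <- out < model$reflection_floor
  if (any(below)) {
    out[below] <- 2L * model$reflection_floor - out[below]
  }
  out
}
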