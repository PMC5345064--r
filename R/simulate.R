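#' Temporal sampling design
#'
#' Describes when and how deeply each site is sampled. Calendar years map to
#' discrete Wright-Fisher generations counted backward from the newest
#' sample: `generation = round((anchor_year - year) / generation_time)`;
#' years that round to the same index share a generation.
#'
#' @param sample_years calendar years with a sample.
#' @param n_default individuals drawn per site-year.
#' @param overrides optional tibble (`site`, `year`, `n`) of per-sample
#'   depths that differ from the default.
#' @param generation_time years per generation.
#' @param anchor_year calendar year of the newest sample (simulation end).
#' @return A `sampling_design` object.
#' @export
sampling_design <- function(sample_years, n_default = 43L, overrides = NULL,
                            generation_time = 3, anchor_year = max(sample_years)) {
  sample_years <- sort(unique(as.integer(sample_years)))
  if (any(sample_years > anchor_year)) {
    abort("sample years after `anchor_year` would map to negative generation indices")
  }
  structure(
    list(
      sample_years = sample_years,
      n_default = assert_count(n_default, "n_default"),
      overrides = if (is.null(overrides)) NULL else tibble::as_tibble(overrides),
      generation_time = generation_time,
      anchor_year = as.integer(anchor_year)
    ),
    class = "sampling_design"
  )
}

#' Generations before the newest sample
#'
#' @param year calendar year(s).
#' @param design a [sampling_design()].
#' @return Integer backward generation index (0 = the newest generation).
#' @export
generations_before_anchor <- function(year, design) {
  as.integer(round((design$anchor_year - year) / design$generation_time))
}

design_span <- function(design) {
  max(generations_before_anchor(design$sample_years, design))
}

n_for_sample <- function(design, site, year) {
  ov <- design$overrides
  if (!is.null(ov)) {
    hit <- ov$site == site & ov$year == year
    if (any(hit)) {
      return(as.integer(ov$n[hit][1L]))
    }
  }
  design$n_default
}

#' The seven-year, six-site study design
#'
#' The sampling frame the synthetic data emulate: yearly samples in 2005,
#' 2006, 2010, 2012, 2013, 2014 and 2015; 43 individuals per site-year; a
#' 3-year generation time. One override slot allows a deliberately small
#' sample (e.g. 12 individuals) to exercise the downstream exclusion rule
#' for under-sized samples.
#'
#' @param n_default individuals per site-year.
#' @param small_sample optional list or tibble row (`site`, `year`, `n`)
#'   marking one under-sized sample.
#' @return A [sampling_design()].
#' @export
#' @examples
#' make_study_design()
#' make_study_design(small_sample = list(site = "mangokuura", year = 2013, n = 12))
make_study_design <- function(n_default = 43L, small_sample = NULL) {
  overrides <- if (!is.null(small_sample)) tibble::as_tibble(small_sample)
  sampling_design(
    sample_years = c(2005L, 2006L, 2010L, 2012L, 2013L, 2014L, 2015L),
    n_default = n_default,
    overrides = overrides,
    generation_time = 3,
    anchor_year = 2015L
  )
}

#' Per-site effective-size trajectory
#'
#' A diploid Ne for every forward generation of the sampled span
#' (generation 0 = the oldest sampled generation), optionally with an
#' instantaneous crash.
#'
#' @param site site identifier.
#' @param trajectory integer vector of diploid Ne (>= 2) per forward
#'   generation, oldest first; must cover the full simulated span.
#' @param crash_generation optional forward generation index at which an
#'   instantaneous decline occurs (bookkeeping only; the trajectory itself
#'   carries the sizes).
#' @return A `demography_scenario` object.
#' @export
demography_scenario <- function(site, trajectory, crash_generation = NULL) {
  trajectory <- as.integer(trajectory)
  if (!length(trajectory)) abort("empty trajectory")
  if (any(trajectory < 2L)) abort("Ne must be >= 2 at every generation")
  structure(
    list(
      site = as.character(site),
      trajectory = trajectory,
      crash_generation = crash_generation
    ),
    class = "demography_scenario"
  )
}

#' Six-site disturbance scenarios
#'
#' The demographic truth behind the synthetic study data: three sites crash
#' instantaneously at the generation containing the disturbance year (2011)
#' by roughly 60%, 88% and 99%, and three stay constant. The severest site
#' starts from a higher baseline (multiplier 9.6, i.e. ~4800 at the default
#' baseline of 500, falling to ~60), mirroring the pattern that the largest
#' relative collapse was observed at a large population; it also keeps the
#' post-crash size above the 43-individual sampling depth, which a crash to
#' 1% of a 500 baseline could not support.
#'
#' @param n_base baseline diploid Ne.
#' @param crash_fractions named numeric vector: crash severity (fraction of
#'   Ne lost) for the crashing sites.
#' @param baseline_multipliers named numeric vector of per-site baseline
#'   multipliers (sites absent default to 1).
#' @param stable_sites names of the non-crashing sites.
#' @param design the [sampling_design()] whose span the trajectories cover.
#' @param crash_year calendar year of the disturbance.
#' @return A named list of [demography_scenario()] objects.
#' @export
#' @examples
#' sc <- make_study_scenarios(n_base = 100)
#' sc$torinoumi$trajectory
make_study_scenarios <- function(n_base = 500L,
                                 crash_fractions = c(
                                   nagatsuraura = 0.60,
                                   mangokuura = 0.88,
                                   torinoumi = 0.9875
                                 ),
                                 baseline_multipliers = c(torinoumi = 9.6),
                                 stable_sites = c(
                                   "katsugigaura", "sokanzan", "matsukawaura"
                                 ),
                                 design = make_study_design(),
                                 crash_year = 2011L) {
  span <- design_span(design)
  crash_fwd <- span - generations_before_anchor(crash_year, design)
  base <- rep(as.integer(n_base), span + 1L)

  crashed <- purrr::imap(crash_fractions, function(frac, site) {
    pre <- as.integer(round(n_base * (baseline_multipliers[site] %|na|% 1)))
    traj <- rep(pre, span + 1L)
    post <- max(2L, as.integer(round(pre * (1 - frac))))
    traj[seq.int(crash_fwd + 1L, span + 1L)] <- post
    demography_scenario(site, traj, crash_generation = crash_fwd)
  })
  stable <- setNames(
    purrr::map(stable_sites, function(site) demography_scenario(site, base)),
    stable_sites
  )
  c(crashed, stable)
}

# One Wright-Fisher reproduction step: each of the 2*N_next child gene
# copies at each locus picks a uniform random parent copy (independent
# inheritance per locus; no selfing bookkeeping).
wf_next_generation <- function(G, n_next) {
  n_copies <- 2L * n_next
  L <- ncol(G)
  idx <- sample.int(nrow(G), n_copies * L, replace = TRUE)
  dim_off <- rep.int((seq_len(L) - 1L) * nrow(G), rep.int(n_copies, L))
  matrix(G[idx + dim_off], n_copies, L)
}

# Binomially thinned per-copy mutation under the two-phase law; `model$rate`
# may carry one rate per locus (column).
apply_mutation <- function(G, model) {
  rates <- rep_len(model$rate, ncol(G))
  if (length(unique(rates)) == 1L) {
    len <- length(G)
    n_mut <- rbinom(1L, len, rates[1L])
    if (n_mut > 0L) {
      pos <- sample.int(len, n_mut)
      G[pos] <- mutate_alleles(G[pos], draw_steps(n_mut, model), model)
    }
    return(G)
  }
  nr <- nrow(G)
  for (l in seq_len(ncol(G))) {
    n_mut <- rbinom(1L, nr, rates[l])
    if (n_mut > 0L) {
      pos <- sample.int(nr, n_mut)
      G[pos, l] <- mutate_alleles(G[pos, l], draw_steps(n_mut, model), model)
    }
  }
  G
}

default_locus_panel <- function(n_loci) {
  locus_table(
    sprintf("Ba%02d", seq_len(n_loci)),
    repeat_unit = rep_len(c(2L, 3L, 4L), n_loci),
    size_offset = rep_len(c(96L, 105L, 120L), n_loci)
  )
}

#' Simulate one site's genotype time series
#'
#' Forward-time Wright-Fisher simulation of `n_loci` unlinked microsatellite
#' loci under the two-phase mutation model, along the scenario's Ne
#' trajectory, with temporal samples drawn non-destructively (individuals
#' are copied out, the population continues). A burn-in of
#' `burn_in_mult x max(Ne)` generations from a monomorphic start precedes
#' the sampled span so the population approaches mutation-drift equilibrium.
#'
#' @param scenario a [demography_scenario()]; its trajectory must cover the
#'   design's span (oldest to newest sampled generation).
#' @param mutation a [mutation_model()].
#' @param n_loci number of loci.
#' @param design a [sampling_design()].
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param loci optional [locus_table()] for the panel (defaults to a mixed
#'   di-/tri-/tetranucleotide panel).
#' @param burn_in_mult burn-in length in multiples of the maximum Ne.
#' @param founder_size founder allele size, repeat units.
#' @return A [genotype_table()] with one sample per design year.
#' @export
simulate_site <- function(scenario, mutation, n_loci = 14L, design = make_study_design(),
                          seed = 1L, loci = NULL, burn_in_mult = 10,
                          founder_size = 20L) {
  n_loci <- assert_count(n_loci, "n_loci")
  if (is.null(loci)) loci <- default_locus_panel(n_loci)
  if (nrow(loci) != n_loci) abort("`loci` must describe exactly `n_loci` loci")
  traj <- scenario$trajectory
  span <- design_span(design)
  if (length(traj) < span + 1L) {
    abort(sprintf(
      "trajectory covers %d generation(s) but the design spans %d",
      length(traj), span + 1L
    ))
  }

  back <- generations_before_anchor(design$sample_years, design)
  fwd <- span - back
  years_by_gen <- split(design$sample_years, fwd)

  for (y in design$sample_years) {
    g <- span - generations_before_anchor(y, design)
    n <- n_for_sample(design, scenario$site, y)
    if (n > traj[g + 1L]) {
      abort(sprintf(
        "sample of %d individuals in %d exceeds the contemporaneous Ne (%d) at %s",
        n, y, traj[g + 1L], scenario$site
      ))
    }
  }

  with_seed(seed, {
    G <- matrix(founder_size, nrow = 2L * traj[1L], ncol = n_loci)
    burn <- as.integer(ceiling(burn_in_mult * max(traj)))
    for (b in seq_len(burn)) {
      G <- apply_mutation(wf_next_generation(G, traj[1L]), mutation)
    }

    out <- vector("list", length(design$sample_years))
    k <- 0L
    for (g in 0:span) {
      if (g > 0L) {
        G <- apply_mutation(wf_next_generation(G, traj[g + 1L]), mutation)
      }
      yrs <- years_by_gen[[as.character(g)]]
      for (y in yrs %||% integer(0)) {
        n <- n_for_sample(design, scenario$site, y)
        ids <- sample.int(nrow(G) / 2L, n)
        a1 <- G[2L * ids - 1L, , drop = FALSE]
        a2 <- G[2L * ids, , drop = FALSE]
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          site = scenario$site,
          year = as.integer(y),
          individual = rep(sprintf("ind_%03d", seq_len(n)), times = n_loci),
          locus = rep(loci$locus, each = n),
          allele_1 = as.integer(loci$size_offset[rep(seq_len(n_loci), each = n)] +
            loci$repeat_unit[rep(seq_len(n_loci), each = n)] * as.vector(a1)),
          allele_2 = as.integer(loci$size_offset[rep(seq_len(n_loci), each = n)] +
            loci$repeat_unit[rep(seq_len(n_loci), each = n)] * as.vector(a2))
        )
      }
    }
    genotype_table(dplyr::bind_rows(out), loci = loci)
  })
}

#' Simulate a multi-site genotype dataset
#'
#' Runs [simulate_site()] independently for each scenario (sites are
#' demographically independent: the species is a direct developer with
#' negligible between-site gene flow) and binds the results into one
#' genotype table. The per-site seeds are derived deterministically from
#' `seed`.
#'
#' @param scenarios named list of [demography_scenario()] objects.
#' @param mutation a [mutation_model()]; defaults to the heterogeneous
#'   per-locus panel of [make_study_mutation_model()].
#' @param n_loci loci per site (the same panel is used at every site).
#' @param design a [sampling_design()].
#' @param seed integer seed.
#' @param ... passed on to [simulate_site()].
#' @return A [genotype_table()]; the attribute `"n_individuals"` records the
#'   generator's own tally of sampled individuals.
#' @export
simulate_dataset <- function(scenarios, mutation = make_study_mutation_model(n_loci),
                             n_loci = 14L, design = make_study_design(),
                             seed = 1L, ...) {
  loci_panel <- default_locus_panel(assert_count(n_loci, "n_loci"))
  parts <- purrr::imap(scenarios, function(sc, nm) {
    simulate_site(sc, mutation,
      n_loci = n_loci, design = design,
      seed = child_seed(seed, match(nm, names(scenarios))),
      loci = loci_panel, ...
    )
  })
  geno <- genotype_table(dplyr::bind_rows(purrr::map(parts, as_plain_tibble)),
    loci = loci_panel
  )
  attr(geno, "n_individuals") <- sum(sample_sizes(geno)$n)
  geno
}
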