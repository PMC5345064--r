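# Small fixtures built in code; no data files.

# Hand-written two-sample, two-locus genotype table with one missing cell.
tiny_genotypes <- function() {
  genotype_table(
    tibble::tibble(
      site = rep(c("kamoike", "kamoike", "oshima"), each = 2),
      year = rep(c(2005L, 2005L, 2012L), each = 2),
      individual = rep(c("i1", "i2", "i1"), each = 2),
      locus = rep(c("L1", "L2"), 3),
      allele_1 = c(150L, 210L, 152L, NA, 150L, 213L),
      allele_2 = c(152L, 213L, 152L, NA, 154L, 213L)
    ),
    loci = locus_table(c("L1", "L2"), repeat_unit = c(2L, 3L), size_offset = c(100L, 90L))
  )
}

# Equilibrium dataset drawn from the coalescent under the two-phase model:
# the exact null of the heterozygosity-excess test. `theta` may be a vector
# (one scaled mutation rate per locus).
equilibrium_dataset <- function(n_ind, n_loci, theta, model, seed,
                                site = "eq", year = 2012L) {
  set.seed(seed)
  theta <- rep_len(theta, n_loci)
  rows <- lapply(seq_len(n_loci), function(l) {
    v <- snaildrift:::coalescent_locus(2L * n_ind, theta[l], model)
    sz <- as.integer(130L + 2L * (v - min(v)))
    tibble::tibble(
      site = site, year = year,
      individual = sprintf("i%03d", seq_len(n_ind)),
      locus = sprintf("L%02d", l),
      allele_1 = sz[seq_len(n_ind)],
      allele_2 = sz[n_ind + seq_len(n_ind)]
    )
  })
  genotype_table(
    dplyr::bind_rows(rows),
    loci = locus_table(sprintf("L%02d", seq_len(n_loci)), repeat_unit = 2L, size_offset = 130L)
  )
}

# Random allele-count vector for property tests.
random_counts <- function(max_alleles = 8L, max_copies = 12L) {
  k <- sample(2:max_alleles, 1L)
  counts <- sample.int(max_copies, k, replace = TRUE)
  setNames(counts, seq(150L, by = 2L, length.out = k))
}

# A posterior object assembled from given draw matrices (for summary tests).
fake_posterior <- function(..., n_max = 5000) {
  chains <- lapply(list(...), function(m) {
    colnames(m) <- c("n_before", "n_after")
    m
  })
  structure(
    list(
      chains = chains,
      acceptance = rep(0.4, length(chains)),
      settings = mcmc_settings(iterations = 100, n_runs = length(chains), n_max = n_max)
    ),
    class = "ne_posterior"
  )
}
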