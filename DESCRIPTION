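Package: snaildrift
Title: Genetic Bottleneck Detection and Temporal Effective Population Size
    from Microsatellite Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the population-genetic impact of an abrupt
    demographic disturbance from multi-year microsatellite samples. Provides
    a Genepop reader/writer and tidy genotype tables; a forward-time
    Wright-Fisher simulator of diploid microsatellite genotypes under a
    two-phase mutation model with per-site effective-size trajectories;
    per-locus diversity statistics (observed and unbiased expected
    heterozygosity, Garza-Williamson M-ratio, rarefied allelic richness by
    resampling and by the closed-form hurdle formula); a BOTTLENECK-style
    heterozygosity-excess test that simulates equilibrium heterozygosity
    conditional on the observed allele number under the two-phase model and
    combines loci with a one-tailed Wilcoxon signed-rank test; hierarchical
    rarefaction of allelic richness and M-ratio before versus after a
    disturbance with a sign test; and Bayesian temporal estimation of
    effective population size under an exponential growth-or-decline
    trajectory, summarised by Bayes factors on the Jeffreys scale, highest
    posterior density intervals, and the Gelman-Rubin diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
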