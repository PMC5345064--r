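# snaildrift

Population-genetic impact assessment of an abrupt demographic disturbance
from multi-year microsatellite samples — built around the monitoring design
used for intertidal mud snails bracketing a major tsunami: six sites,
yearly samples over a decade, 14 microsatellite loci, ~43 diploid
individuals per site-year, a 3-year generation time.

For population geneticists and ecologists asking: *did the crash leave a
genetic scar?* The package answers with three complementary instruments:

1. **Bottleneck detection by heterozygosity excess.** After a bottleneck,
   allele number drops faster than gene diversity, so observed He exceeds
   the equilibrium He expected for the observed allele count k. The
   reference distribution Heq | (n, k) is simulated from coalescent
   genealogies under a two-phase mutation model (10% multistep mutations),
   with θ calibrated so E[k] matches the observation; loci combine through
   a one-tailed Wilcoxon signed-rank test.
2. **Standardized diversity comparison.** Garza–Williamson
   M-ratio, M = k/(r+1) with r the allelic size range in repeat units, and
   rarefied allelic richness (resampling and the closed-form hurdle formula
   Σᵢ [1 − C(n−nᵢ, g)/C(n, g)]), compared before vs after the disturbance
   by hierarchical rarefaction: equal numbers of yearly samples per period
   and 43 individuals per sample, drawn without replacement, 1,000
   iterations, significance by the exact sign test over loci.
3. **Temporal Ne estimation.** A Bayesian fit of the endpoint effective
   sizes (N_before, N_after) under exponential growth/decline, with drift
   accumulating as F(t) = 1 − Π(1 − 1/(2N(g))). The likelihood is a
   Dirichlet-multinomial drift pseudo-likelihood evaluated by an
   assumed-density filter; sampling is random-walk Metropolis on
   (ln N_before, ln N_after) with a uniform-in-log prior on [2, 5000].
   Results are summarised by the Bayes factor
   P(N_before > N_after) / P(N_before < N_after) on the Jeffreys scale
   (>10 strong, 3–10 substantial, 0.33–3 none, <0.33 false detection),
   10–90% HPD intervals, and the Gelman–Rubin diagnostic.

A forward-time Wright–Fisher simulator (two-phase mutation, per-site Ne
trajectories with configurable crashes, study-shaped temporal sampling)
generates the synthetic datasets every stage is validated against, and
Genepop / delimited-table I/O connects the package to standard tools.

## Worked example

Simulate one site that crashes by 88% (Ne 500 → 60) at the 2011 generation
under the study design, then ask all three instruments what happened:

```r
library(snaildrift)

des <- make_study_design()                       # 2005..2015, 43 per sample
sc  <- make_study_scenarios()["mangokuura"]      # 500 -> 60 at 2011
g   <- simulate_dataset(sc, n_loci = 14, design = des, seed = 2024)
g
#> # Genotype table: 14 loci, 7 samples (site x year), 4214 genotype rows

st   <- mcmc_settings(iterations = 12000, n_runs = 3, thinning = 5, seed = 7)
post <- estimate_temporal_ne(g, "mangokuura", st)
glance(post)
#> # A tibble: 1 x 8
#>   site       n_before n_after rate_of_change bayes_factor category max_r_hat
#>   <chr>         <dbl>   <dbl>          <dbl>        <dbl> <chr>        <dbl>
#> 1 mangokuura     215.    43.6          -79.8         28.0 strong        1.00

pd <- build_period_design(g, "mangokuura")       # 3 usable years per period
rr <- hierarchical_rarefy(g, pd, seed = 11)
glance(rr)
#> # A tibble: 2 x 8
#>   index  mean_after mean_before sd_after sd_before n_positive n_negative p_value
#> 1 m_rat…      0.898       0.936  0.00271         0          2          4   0.687
#> 2 richn…      8.57        8.79   0.0877          0          4          6   0.754
```

The temporal method recovers the decline (posterior mode 215 → 44, −79.8%
against a true −88%, Bayes factor 28 = strong support), while the rarefied
richness and M-ratio changes stay non-significant (sign-test p ≈ 0.7) —
the characteristic pattern for a severe but brief crash: effective size
collapses before measurable diversity is lost. `autoplot(post)` shows the
joint posterior against the N_before = N_after diagonal; `autoplot(rr)`
boxplots the rarefied indices per period; `tidy()` returns the underlying
per-draw / per-iteration tables.

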