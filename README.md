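# trophicnet

Eutrophication assessment and plankton–bacteria co-occurrence analysis for
river surveys, as one reproducible R pipeline.

River eutrophication restructures both phytoplankton and bacterial
communities: diatoms give way to cyanobacteria, bacterial diversity falls,
and the interaction network between the two kingdoms tightens and turns
antagonistic. `trophicnet` implements the quantitative chain behind that kind
of survey for water-quality scientists and microbial ecologists:

1. **Trophic state scoring.** The modified Carlson Trophic State Index for
   Chinese rivers. Component scores are log-linear in the measurements,

   ```
   TSI(Chl-a) = 10 (2.5   + 1.086 ln Chl-a)     [ug/L]
   TSI(TP)    = 10 (9.436 + 1.624 ln TP)        [mg/L]
   TSI(TN)    = 10 (5.453 + 1.694 ln TN)        [mg/L]
   TSI(SD)    = 10 (5.118 - 1.94  ln SD)        [m]
   ```

   and the composite is the weighted sum
   `TSI = 0.326 TSI(Chl-a) + 0.219 TSI(TN) + 0.230 TSI(TP) + 0.225 TSI(SD)`,
   classified as oligotrophic (< 30), mesotrophic ([30, 50]), slightly
   (50, 60], moderately (60, 70] or hyper-eutrophic (> 70); a site is
   *eutrophic* when TSI > 50.

2. **Community metrics.** Richness, Shannon entropy (`H = -sum p_i ln p_i`),
   seeded rarefaction of ASV tables to a common depth (default 27,000 reads),
   relative abundance and Bray–Curtis dissimilarity matrices for downstream
   ordination.

3. **Association statistics.** Tie-aware Spearman correlation over all taxon
   pairs with Benjamini–Hochberg FDR control (exact permutation p-values
   below 10 samples, t-approximation otherwise), Mantel and partial Mantel
   permutation tests, and a distance-based environment–community permutation
   correlation.

4. **Signed co-occurrence networks.** Per trophic group (L/M/H), taxa passing
   a strict 0.01% overall relative-abundance filter are correlated on
   per-kingdom relative abundances; an edge is kept only when
   `|rho| >= 0.6` **and** FDR-adjusted `p < 0.05`. Topology metrics follow
   the standard bundle: average degree, diameter and mean path length on the
   largest component, mean local clustering, Louvain modularity (best of 10
   seeded restarts), signed-edge percentages and cross-kingdom
   (bacteria–phytoplankton) edge composition, plus cross-group trend flags.

5. **Synthetic gradient generator.** `simulate_dataset()` builds complete
   surveys — chemistry back-solved from target TSIs, a logistic
   diatom-to-cyanobacteria turnover, Proteobacteria-dominated bacterial
   profiles whose evenness decays with trophic state, and a Gaussian copula
   planting signed correlation blocks within and across kingdoms — together
   with a truth sidecar, so that every stage of the pipeline can be validated
   by recovery of planted truth (`score_recovery()`).

## Worked example

```r
library(trophicnet)

chem <- tibble::tibble(
  site_id = c("HJ01", "HJ02", "HJ03"),
  tn = c(2.9, 1.4, 4.1), tp = c(0.09, 0.03, 0.16),
  chl_a = c(6.3, 1.2, 21.0), secchi = c(0.79, 2.1, 0.4)
)
assessment <- assess_sites(chem)
assessment
#> # Trophic assessment of 3 unit(s); 66.7% eutrophic
#> # A tibble: 3 × 8
#>   site_id tsi_chl tsi_tn tsi_tp tsi_sd   tsi label              eutrophic
#>   <chr>     <dbl>  <dbl>  <dbl>  <dbl> <dbl> <fct>              <lgl>
#> 1 HJ01       45.0   72.6   55.3   55.8  55.8 slightly_eutrophic TRUE
#> 2 HJ02       27.0   60.2   37.4   36.8  38.9 mesotrophic        FALSE
#> 3 HJ03       58.1   78.4   64.6   69.0  66.5 moderately_eutrop… TRUE
glance(assessment)$tsi_median
#> [1] 55.81128
```

HJ01 sits right at the slightly-eutrophic median of a typical summer survey;
HJ02's clear water (Secchi 2.1 m, Chl-a 1.2 ug/L) keeps it mesotrophic;
HJ03's nutrient load pushes it into the moderately eutrophic class.

A full synthetic survey, end to end:

```r
dataset <- simulate_dataset(gradient_scenario(), seed = 1)
analysis <- analyze_dataset(dataset, seed = 1)
analysis$topologies[, c("group", "n_edges", "modularity", "pct_negative_edges")]
#> # A tibble: 3 × 4
#>   group n_edges modularity pct_negative_edges
#> 1 L          77      0.810               1.30
#> 2 M         110      0.571              34.5
#> 3 H         183      0.288              39.3
score_recovery(analysis, dataset)$trends
#>      shannon_decreasing   modularity_decreasing pct_negative_increasing
#>                    TRUE                    TRUE                    TRUE
```

Modularity falls and the negative-edge share rises from the low to the high
trophic group — the planted signature of collapsing module boundaries and
intensifying antagonism under eutrophication — and the recovery report
confirms the pipeline found what the generator planted.

The same run is available from the shell:

```sh
Rscript inst/scripts/trophicnet run --scenario scenario.yml --seed 1 --out results/
```

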