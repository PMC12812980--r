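---
title: "Trophic state scoring and plankton-bacteria co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trophic state scoring and plankton-bacteria co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicnet)
```

`trophicnet` chains four analyses that river-eutrophication surveys routinely
combine: composite Trophic State Index (TSI) scoring, community diversity
metrics, permutation association tests, and signed co-occurrence network
construction with topology metrics. This vignette explains the models behind
each stage, the tunable parameters and their defaults, what the synthetic
gradient generator emulates (and what it does not), and the numerical choices
made where the design was genuinely open.

## The trophic state model

The composite TSI is a weighted sum of four log-linear component scores, one
per measurement. Each component has the form `10 * (a + b * ln(value))` with

| component | measurement, unit | a | b |
|---|---|---|---|
| `chl_a` | chlorophyll-a, ug/L | 2.5 | 1.086 |
| `tn` | total nitrogen, mg/L | 5.453 | 1.694 |
| `tp` | total phosphorus, mg/L | 9.436 | 1.624 |
| `sd` | Secchi depth, m | 5.118 | -1.94 |

and the composite weights are 0.326 (Chl-a), 0.219 (TN), 0.230 (TP), 0.225
(SD) — a calibration for Chinese rivers that damps the phosphorus term
relative to the classic index. Two conventions deserve emphasis because the
printed constants only make sense under them:

* **Natural logarithms.** The Carlson family is defined on `ln`; with
  `log10` the same constants would place ordinary rivers far off the 0-100
  scale.
* **Units are enforced, never converted.** Chl-a in ug/L but TN/TP in mg/L
  is easy to get wrong silently; the readers validate an optional units
  header row instead of guessing.

Classification follows the closed/open interval pattern of the scale:
oligotrophic strictly below 30, mesotrophic on the closed interval
[30, 50], then half-open intervals (50, 60], (60, 70] and above 70. The
*eutrophic* predicate is `TSI > 50`, which makes the three eutrophic classes
exactly partition the eutrophic range. Because the weights sum to 1, equal
component scores pass through unchanged — a property the tests exercise as an
exact invariant.

Two deliberate strictnesses: all four components are required (the index
definition has no missing-data rule; `renormalize = TRUE` is an explicit
opt-in extension that rescales the remaining weights), and non-positive
measurements are errors rather than being clamped to a detection limit —
substitution rules vary between laboratories and should be applied upstream,
consciously.

One survey-design note: a cohort summary treats one input row as one
classified unit. Surveys often measure several replicate containers per
physical site; whether to aggregate them first is left to the caller, and
the summary makes no assumption either way.

## Diversity and dissimilarity

Shannon entropy is computed in nats (`H = -sum p_i ln p_i`), the dominant
ecology convention and the one consistent with the `H <= ln S` bound used in
the tests. Rarefaction subsamples each sample's reads without replacement to
a common depth (default 27,000 reads, a typical choice for 16S surveys) and
**drops** samples that fall short, with a warning, rather than resampling
them with replacement — the conservative rule, at the cost of losing
samples. Rarefaction applies to read-count tables only (it is meaningless
for microscopy cell densities, which are instrument-scaled) and is used here
before alpha diversity; networks are built on relative abundances of the
unrarefied tables, so a dropped sample never silently changes the network
sample set. Bray-Curtis dissimilarity is available with or without the
relative-abundance transform; the choice is recorded in an attribute so that
exported matrices are self-describing.

## Association statistics

All correlation in the package is tie-aware Spearman: the Pearson
correlation of average ranks. Rank invariance is not a stylistic choice —
it is what makes phytoplankton cell densities (cells/L) and bacterial read
counts commensurable after per-kingdom relative-abundance transformation,
and it is why no Pearson edge statistic is offered for networks.

P-values for pairwise correlations use the t-distribution approximation for
10 or more samples and the exact two-sided permutation distribution below
that, where the approximation is unreliable and enumeration (at most 9! =
362,880 permutations, cached) is cheap. The Benjamini-Hochberg adjustment is
implemented as the literal step-up formula and applied once across the full
pair set of a correlation matrix — a single FDR gate, not per-taxon gates.

The Mantel test correlates upper triangles of two distance matrices and
permutes rows and columns of the second jointly; the p-value uses the
add-one formula `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`, one-tailed
(greater), with default `n_perm = 999`. The inner statistic is Spearman by
default with a Pearson flag. For small matrices an exhaustive mode
enumerates all `n!` relabelings, which the tests compare against a
brute-force oracle. The partial Mantel variant removes a control matrix by
least squares from both (ranked) triangles before correlating; ranking
commutes with joint relabeling, so permuted statistics reuse the ranked
matrices. The environment-community test standardizes one environmental
variable, converts it to Euclidean distances, and runs the Mantel machinery;
it is documented as a distance-based approximation of envfit-style Monte
Carlo vector fitting, not a reproduction of those coefficients.

All permutation machinery is seeded and bit-reproducible given
`(inputs, n_perm, seed)`; a constant input (zero-variance vector) yields a
flagged undefined result rather than a number.

## Signed co-occurrence networks

Per trophic group, the pipeline

1. filters taxa on the pooled table by overall relative abundance strictly
   above 0.01% (per kingdom), so the three group networks share one node
   set;
2. converts counts to per-kingdom relative abundances and computes all
   pairwise Spearman correlations across the group's samples;
3. keeps an edge only under the double gate `|rho| >= 0.6` **and**
   FDR-adjusted `p < 0.05`, the sign of the edge being the sign of rho.

Topology metrics are computed on the unsigned simple graph (the convention
of desktop network tools), with sign kept as an edge attribute used for the
signed percentages and the cross-kingdom composition: average degree is
`2E/N` over the full node set including isolates; diameter and average path
length are computed on the largest connected component (with the component
count reported); clustering is the mean of local clustering coefficients
with nodes of degree < 2 contributing 0; modularity is the best Newman Q of
Louvain (resolution 1) over 10 seeded restarts, which tames the heuristic's
stochasticity — the tests check it attains the exhaustive-search optimum on
all random graphs up to 8 nodes. Cross-kingdom composition classifies each
edge as bacteria-bacteria, phytoplankton-phytoplankton or
bacteria-phytoplankton, and reports fractions both of all edges and within
each sign class. `compare_topologies()` reduces per-group metric vectors to
weak-monotonicity flags (`decreasing` / `increasing` / `flat` /
`non-monotonic`) in low-to-high group order.

Networks export as GraphML and GEXF with kingdom/phylum node attributes and
rho/q/sign edge attributes, and as plain edge lists.

## The synthetic gradient generator

The generator exists so that recovery of *planted truth* — not agreement
with any one dataset — is the package's acceptance surface. A
`gradient_scenario()` fixes everything: 30 sites per trophic group (L
mesotrophic, targets in [30, 50]; M slightly eutrophic, (50, 60]; H
moderately eutrophic, (60, 70]), chemistry noise, community sizes (33
phytoplankton genera, 40 bacterial taxa), dominance parameters, the planted
correlation module structure, and the sequencing library size (30,000 reads
in expectation, negative-binomial size 10).

**Chemistry** is generated by drawing a target composite TSI per site
uniformly within its group's range and back-solving every component
(`value = exp((TSI/10 - a)/b)`), then jittering with multiplicative
lognormal noise (sd 0.05 by default, calibrated so classes remain ~96%
recoverable while measurements look realistically imprecise). At zero noise
the forward computation recovers the targets to 1e-9, an exact
forward-inverse invariant. Covariates (water temperature, dissolved oxygen,
COD) co-vary with the target TSI so the environment-community tests have
something real to find.

**Composition** responds to the gradient at the *group* level: phylum mixing
weights and evenness parameters are evaluated at the group's representative
TSI (the midpoint of its target range) rather than per site. This is a
deliberate identifiability choice: the within-group covariation budget
belongs entirely to the planted copula, so that a site-level compositional
trend cannot masquerade as (or attenuate) planted correlation inside a group
network. The consequences: the diatom-to-cyanobacteria turnover (logistic in
TSI, slope 0.15 per TSI unit, midpoint 55 — the minimal monotone choice, as
only the endpoint pattern is documented in field surveys) and the bacterial
diversity decline are step patterns across groups, not smooth per-site
gradients. Bacterial diversity declines through two coupled mechanisms: the
Proteobacteria share swells around its 0.6 baseline (0.45 at the L midpoint
to 0.70 at H, so the across-site mean stays at the baseline), and the
within-phylum power-law exponent of abundance ranks grows with TSI (0.025
per unit). Splitting the decline between the two keeps any single taxon from
dominating the library — important because the relative-abundance transform
shares each kingdom's denominator across all its taxa, and one dominant
noisy taxon would inject correlated noise into every relative abundance in
the kingdom.

**Planted correlation** uses a Gaussian copula over a factor model: each of
six blocks (two diatom/cyanobacterial/green-algal phytoplankton blocks of
6, 6 and 3 taxa; Proteobacteria/Bacteroidota/Actinobacteria bacterial blocks
of 6, 6 and 3) has one latent factor, members load `sqrt(0.9)` on it
(within-block latent correlation 0.9), and cross-kingdom couplings load a
block's members (with sign) on another block's factor, splitting the 0.9
budget so within-block correlation is preserved. Marginals are
negative-binomial via the quantile transform, so rank correlations are
controlled while counts stay overdispersed; the latent-to-observed
attenuation (copula nonlinearity, count discretization, and the
relative-abundance closure) is measured by the recovery tests, not assumed.
Two structural choices matter for the closure effect: block members sit at
the *tail* abundance ranks of their host phylum, and blocks are spread
across phyla, so no block carries a dominant share of its kingdom total —
a co-varying block that dominated its kingdom would partially cancel its own
signal through the shared denominator.

The coupling pattern across groups is the planted version of the
eutrophication story: a positive (mutualistic) green-algae-Actinobacteria
module in every group whose strength fades L to H (0.92/0.82/0.72, so the
positive cross-kingdom edge share declines); no antagonism in L; one
antagonistic coupling in M (B1 against the diatom factor, 0.88); and in H
two bacterial blocks coupled against the *same* diatom factor (0.94 and
0.92), which merges diatoms and both bacterial blocks into one dominant
mixed module (modularity falls sharply) and implies a positive B1-B2
association that is part of planted truth. Every pair with nonzero implied
latent correlation — direct or factor-shared — is emitted in the truth
sidecar, and `score_recovery()` scores edge recall, precision, sign accuracy
and the spurious-edge rate against it, plus the direction of the Shannon,
modularity and negative-edge-share trends.

What the generator does **not** emulate, and hence what passing tests do not
show about real data: taxon identities and real phylogenetic structure;
compositional count dependence beyond the closure of relative abundances (no
SparCC-style compositional effects are modelled or corrected); sequencing
artefacts (chimeras, contamination, variable primer efficiency);
within-group environmental gradients in community composition; temporal or
spatial autocorrelation between sites. Its effect sizes are free parameters
chosen for clear recoverability at 30 samples per group — they are a
benchmark, not field estimates.

## Numerical choices and degenerate inputs

* Classification boundaries are implemented exactly at 30/50/60/70 with the
  closed bounds stated above; the tests probe the boundaries bit-for-bit.
* Constant vectors give flagged `NA` correlations; all-zero samples are
  errors naming the sample; an empty network yields a zero topology row with
  an `empty` flag rather than NaNs.
* A single classified unit reports standard deviation 0 with
  `sd_defined = FALSE` instead of `NA`, so downstream tables stay numeric.
* Permutation p-values use the add-one convention and therefore can never
  be 0; exhaustive enumeration includes the identity relabeling.
* One run seed drives everything; each stage derives an independent
  substream from a hash of `(seed, stage)`, so adding a stage never perturbs
  the draws of earlier stages, and pipeline outputs are byte-identical
  across reruns of the same configuration.
* The abundance filter is strictly "above" its threshold: a taxon at exactly
  0.01% is removed.

## Problem sizes

The validation suite runs at deliberately moderate sizes chosen to exercise
the statistics well: oracle equivalence on graphs up to 8 nodes (exhaustive
partitions) and 50 nodes (Floyd-Warshall); calibration on 200-500 seeded
replicates; recovery on the default scenario of 90 sites and 73 taxa, with
the trend-direction check repeated over 50 seeds. These sizes are the
package's own benchmark definition and are stated here so they can be
reproduced exactly.

## Known limitations

Edge detection at `|rho| >= 0.6` with 30 samples per group sits deliberately
in the regime where strong planted correlations (latent 0.8-0.9) are
recovered and moderate ones (latent below ~0.65) often are not; the
benchmark's recall target refers to the strong structure it plants. The
environment-community statistic is a Mantel-type approximation and its
coefficient is not comparable to envfit-style correlation coefficients.
Modularity relies on a heuristic; restarts make it reliable at these sizes
but global optimality is only guaranteed where the tests enumerate. The
pipeline performs no compositional-data correction (no centered log-ratio,
no SparCC): with the strict 0.6 edge gate and minor-share blocks this is a
second-order effect in the benchmark, but on real data with strongly
dominant taxa it can both hide true associations and induce spurious
negative ones.
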