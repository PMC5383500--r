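---
title: "Functional neighborhoods, dark diversity, and establishment prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional neighborhoods, dark diversity, and establishment prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funneigh)
```

# The modelling framework

`funneigh` models community assembly as two sequential filters acting on a
regional species list, and turns the fitted filters into establishment
predictions for added species.

**Pool levels.** The regional list (all species within plausible dispersal
distance) is split into three levels. Species occurring in at least
`minSites` surveyed sites of the habitat type *and* present on the regional
list form the habitat-specific species pool; the occurrence-frequency rule
(default `minSites = 2`, i.e. single-site records are dropped) guards
against misidentifications and atypical records. Pool members absent from
the focal community are the dark diversity; the remainder of the regional
list is environmentally excluded. Species observed at the focal site are
always pool members even if they fail the frequency rule — they demonstrably
occur there, and the framework's partition requires observed ⊆ pool.

**Distances.** Traits are standardized to [0, 1] by range over the
*regional modelling set* (regional species with complete traits); heavily
right-skewed traits (height, SLA, seed weight) are natural-log-transformed
first. The log base is irrelevant after range standardization but is fixed
for reproducibility. The same affine map is applied to colonists, whose
standardized values may legitimately fall outside [0, 1]; they are reported,
not clipped. On this scale the single-trait Gower dissimilarity is the
absolute difference and the multivariate Gower distance is the mean over
traits. A precomputed square dissimilarity matrix (e.g. scaled cophenetic
phylogenetic distances) can be substituted and is treated as one "trait".

**Functional neighborhoods.** The distance from a focal species to a
reference set is summarized as the mean of the *k* smallest pairwise
distances. *k* is resolved from a proportion p of the reference-set size n
as k = ⌈p·n⌉ (always rounded up), over the grid {NN, 10%, ..., 100%}; NN
(k = 1) is the nearest-neighbor distance and 100% the mean pairwise
distance. When a pool member is its own reference (self-excluded, see
below) and p = 1 would give k = n > n − 1, the effective k is capped at the
available reference size — the only reading under which the MP identity
survives self-exclusion.

**Environmental filter.** One logistic regression over the regional
modelling set: pool membership (1 = pool member, 0 = environmentally
excluded) on per-trait neighborhood distances to the pool. Each trait gets
its own neighborhood under its own distance by default; a shared
multivariate neighborhood is available (`basis = "multivariate"`).

**Biotic filter.** One binomial mixed model over pool species × plots:
presence in the plot community on centered, abundance-weighted neighborhood
distances to that plot's residents, with a plot random intercept (Laplace
approximation via `lme4::glmer`). Each observed species j contributes
v_j = w_j (d_j − d̄), where w_j is its relative abundance in the plot and d̄
a per-trait centering constant; neighborhood membership is decided on the
v_j (ascending), and the value is the sum of the k smallest v_j divided by
the sum of their weights. The renormalization by included weight makes
values comparable across k and reduces exactly to the fully weighted
centered mean at k = all.

**Selection and prediction.** Models are fitted at every neighborhood size
and interaction scheme (none, all pairwise, backward-eliminated
"parsimonious") and ranked by AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1). Selection
is *not* by AICc alone: candidates carrying hard degeneracy flags
(separation, runaway estimates, insufficient distance variation, constant
predictor columns) are excluded first, because nearest-neighbor fits can
attain excellent AICc with coefficients orders of magnitude too large and
p-values near 1. Establishment probability for a colonist is
P(env) × mean over plots of P(biotic); the validation regresses observed
establishment proportions on the predictions (OLS, site factor when more
than one site), reporting the slope t statistic and adjusted R².

# Numerical and design choices

Several contracts are underdetermined by the framework itself; the choices
made here, and why:

* **Self-exclusion everywhere.** A species is never its own neighbor — in
  the environmental design for pool members, in the biotic design for
  observed species, and for colonists that happen to be recorded locally.
  A self-distance of zero would leak the response into the predictor and
  push the logistic fits toward separation.
* **Centering set for biotic distances.** d̄ per trait is the grand mean of
  distances between all habitat-pool species and all species observed
  anywhere at the site, excluding self-pairs. A site-level constant keeps
  centered values comparable across plots; a per-plot center would conflate
  plot richness with the similarity signal.
* **Within-plot neighborhood resolution.** Proportional sizes are resolved
  per plot against the available (self-excluded) observed richness,
  k = min(⌈p·n_obs⌉, n_obs), since only residents of that plot can be
  neighbors there.
* **Tie-breaking.** Neighborhood membership ties are broken by species id.
  The mean of the k smallest values is unaffected, but membership lists and
  the weighted biotic values become deterministic across platforms.
* **Standardization.** Predictors are z-scored with the sample sd (n − 1).
  Interaction columns are products of z-scored mains, then z-scored
  themselves; the constants are stored in the model and re-applied at
  prediction time, so predictions from raw distances and from
  pre-standardized inputs agree to numerical precision. Constant columns
  are flagged and zeroed rather than dropped, keeping term bookkeeping
  aligned.
* **Convergence and degeneracy.** Logistic fits use a log-likelihood
  tolerance of 1e−8 with at most 100 iterations. Separation is flagged when
  the fitter warns of fitted probabilities at 0/1 *and* a standardized
  coefficient exceeds 10. A biotic fit whose random-intercept variance
  collapses below 1e−8 is refitted as a plain logistic regression and
  flagged "zero RE variance"; this is a *soft* flag — the fallback is a
  valid limiting case and remains selectable, unlike the hard flags above.
* **Ordinal interactions.** Interactions among ordinal traits are excluded
  from environmental models by default (toggleable): at small neighborhood
  sizes ordinal distances take too few values for such products to vary,
  and the fits fail to converge.
* **Backward elimination.** Greedy single-term deletion on AICc over
  interaction terms only (main effects always stay), stopping at the first
  local minimum; an exhaustive subset search is available for up to six
  interaction terms. The greedy path is O(m²) refits and in the test
  fixtures tracks the exhaustive optimum.
* **Colonist random effects.** Biotic predictions for colonists use the
  estimated plot intercepts by default — the plots are known units, not new
  ones — with a population-level (zero-intercept) alternative behind
  `rePrediction = "population"`.
* **Validation scale.** The establishment validation is OLS on proportions,
  with adjusted R² as the headline statistic; a quasi-binomial GLM
  alternative is provided but non-default, matching the framework's use of
  linear validation on proportion data.

# What the simulator emulates

The simulator generates assemblies with known truth so that every stage of
the pipeline can be tested without field data. Its defaults are the study
conditions used throughout the test suite:

| parameter | default | rationale |
|---|---|---|
| `nRegional` | 600 | regional list of several hundred species, matching the scale of county-level floras |
| `nTraits` | 2 | the minimal setting in which clustering and dispersion can act on distinct traits |
| `envOptimum`, `envSd` | (0.5, 0.5), 0.15 | Gaussian admission kernel exp(−‖t−opt‖²/2σ²); σ = 0.15 yields a pool of roughly 80–100 of 600 species |
| `bioticMode` | weak phenotype exclusion per trait | Gaussian retention kernel; `limiting_similarity` and `neutral` per trait |
| `wpeOptimum`, `wpeSd` | 0.5, 0.08 | retention kernel narrower than the pool spread, so local clustering is a real signal beyond environmental filtering |
| `lsMinDistance` | 0.05 | iterative most-similar-pair removal until all nearest-neighbor gaps ≥ 0.05; yields ~20-species communities |
| `nPlots`, `plotRichnessMean` | 40, 15 | plot counts and richnesses of the order observed in species-rich grassland quadrats |
| `abundanceProb` | 0.3 | geometric (shifted to ≥ 1) counts: a log-series-like skewed abundance distribution |
| `nColonists`, `seedsAdded` | 25, 15 | a seed-addition experiment of realistic size |

Limiting similarity removes one member (uniformly at random) of the most
similar pair until the gap threshold holds, never reducing the community
below two species. The true establishment probability of a colonist is the
product of the generative kernels: the environmental admission kernel times,
per trait, the weak-phenotype retention kernel or — for limiting
similarity — the nearest-neighbor gap to the realized community scaled by
`lsMinDistance` and capped at one. Plot-level establishment is
Binomial(seeds, true P). Every stage draws from a seed derived
deterministically from the configuration seed, so assemblies are
reproducible bit for bit.

The simulator deliberately omits several features of real data: trait
measurement error and database gaps, spatial structure among plots,
dispersal limitation, temporal dynamics, ordinal trait scales, and
covariance between traits and abundance. Passing tests therefore show that
the estimators recover *their own generative model* under realistic sizes
and noise — not that field data meet these assumptions.

# Problem sizes in the tests

The replicated checks in the test suite and the acceptance script use: 100
assemblies of 600 regional species for the environmental sign recovery
(multivariate basis, sizes 30–100%); 100 dual-mode assemblies (one trait
clustered, one dispersed) fitted at NN and 30% for the biotic signs; 100
full-pipeline runs (25 colonists, 40 plots, matched mean-pairwise
neighborhoods, 1000-permutation null) for end-to-end recovery; and 100
two-cluster pools scanned over all eleven sizes for the selection behavior.
Distance-level properties (oracle equivalence, monotonicity in k, the Gower
metric axioms, the AICc closed form) are checked exhaustively on smaller
random fixtures at tolerances of 1e−12.

# Known limitations

* Pool construction implements only the occurrence-frequency rule;
  dispersal-probability and co-occurrence-based pool estimators are out of
  scope.
* Gower handling of categorical traits and pairwise missing-data weighting
  is not implemented; species with incomplete modelled traits are excluded
  from modelling sets (and reported).
* The biotic model's random structure is a plot intercept only; no random
  slopes, no spatial autocorrelation between plots.
* Phylogenetic information enters only as a precomputed distance matrix;
  tree parsing is out of scope.
* AICc-based selection across neighborhood sizes compares models fitted to
  *different predictor constructions* of the same data — the diagnostics
  exist precisely because such comparisons can favor degenerate fits, and
  the distribution of distances should be examined alongside any selection.
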