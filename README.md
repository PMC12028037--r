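# mycostab

Complexity and stability analysis of microbial co-occurrence networks, for
amplicon feature tables — motivated by the question of how soil fungal
communities differ between habitats (e.g. clay-loam vs sandy mangrove
soils) and what drives those differences.

Starting from a samples × taxa abundance table, sample metadata and an
environmental matrix, the package computes:

* **Diversity** — Shannon index, Bray–Curtis dissimilarity, principal
  coordinates analysis, ANOSIM and Mantel permutation tests (with
  exhaustive-enumeration modes), WGS84 geodesic distance matrices.
* **Co-occurrence networks** — signed Spearman networks with
  t-approximation p-values and Benjamini–Hochberg filtering, average degree
  `(1/n)Σkᵢ`, density `2l/(n(n−1))`, weighted Louvain modules, and
  module hubs by within-module degree z-score.
* **Complexity** — per-sample *cohesion*
  `C = Σᵢ abundanceᵢ × connectednessᵢ`, where a taxon's positive (negative)
  connectedness is the mean of its retained positive (negative)
  correlations; total cohesion is `positive + |negative|`.
* **Stability** — *robustness*: the proportion of species remaining after
  removing 50% of nodes at random (or the top module hubs) and propagating
  secondary extinctions, where species *i* goes extinct when
  `Σⱼ bⱼ sᵢⱼ / Σⱼ bⱼ ≤ 0` over its remaining neighbours (`bⱼ` relative
  abundance, `sᵢⱼ` Pearson association strength) or when it loses all its
  edges.
* **Drivers** — Spearman correlation tables (with significance stars)
  between environmental variables and diversity/complexity/stability, and
  simple linear regressions.
* **PLS path modeling** — a partial least squares path modeling engine
  (centroid scheme, mode A, bootstrap inference) with exact
  direct/indirect/total effect decomposition, for latent-variable models
  such as soil properties + nutrients + geographic distance + alpha/beta
  diversity → complexity and stability.
* **Synthetic data** — a seeded generator for two-group communities with
  known dominance structure, Gaussian-copula correlation blocks,
  negative-binomial counts, latent-path environmental variables and
  jittered site coordinates, so every stage is testable against ground
  truth.

All user-facing functions take a data frame (or feature table) first and
return tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()` figures.

## Worked example

```r
library(mycostab)

# simulate a two-soil-type fungal survey with known ground truth
study <- generate_community(community_spec(seed = 1))
ft   <- study$feature_table
meta <- study$metadata

# alpha diversity: the evener sandy community is more diverse
alpha <- alpha_diversity(ft)
tapply(alpha$shannon, meta$soil_type[match(alpha$sample_id, meta$sample_id)], mean)
#> clay_loam     sandy
#>  3.302122  3.890881

# beta diversity: the soil types separate completely
bc <- bray_curtis(to_relative_abundance(ft))
anosim_test(bc, meta$soil_type, n_perm = 999, seed = 1)
#>   statistic p_value n_perm  seed
#> 1         1   0.001    999     1

# co-occurrence network of the clay-loam group
clay <- subset_samples(ft, meta$sample_id[meta$soil_type == "clay_loam"])
net  <- filter_taxa(clay) |> build_network() |> detect_modules(seed = 1)
glance(net)
#>   n_nodes n_edges average_degree density modularity n_modules ...
#> 1      25     110            8.8   0.367     0.0732         6

# complexity: per-sample cohesion of the clay-loam samples
conn <- connectedness(filter_taxa(clay), net = net)
coh  <- cohesion(to_relative_abundance(filter_taxa(clay)), conn)
summary(coh$total_cohesion)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> 0.05589 0.23395 0.29939 0.30277 0.38563 0.48134

# stability: robustness under the two removal protocols
robustness(net, "random_fraction", 0.5, n_iterations = 499, seed = 1)
#> # Robustness (random_fraction, parameter = 0.5): 0.3985 remaining (499 iterations)
robustness(net, "targeted_hubs", 5, seed = 1)
#> # Robustness (targeted_hubs, parameter = 5): 0.7200 remaining (1 iteration)
```

Reading the numbers: the 25 clay-loam samples yield a 25-node network whose
cooperative block gives a mean total cohesion of 0.30; removing half its
nodes at random leaves on average 40% of species after secondary
extinctions, while removing its five module hubs leaves 72%.

The same analysis runs end-to-end from one seeded configuration file —
simulation, diversity, per-group networks, cohesion/robustness, driver
tables and PLS-PM, with a manifest of every default, seed and checksum:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "mycostab")
run_pipeline(cfg, output_dir = "demo_run")
```

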