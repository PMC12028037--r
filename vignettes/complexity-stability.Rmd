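---
title: "Complexity and stability of microbial co-occurrence networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and stability of microbial co-occurrence networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mycostab implements a complete analysis chain for asking how *complex* and
how *stable* a microbial community is, and which environmental factors drive
both — the kind of question asked of soil fungal communities across
contrasting habitats such as clay-loam and sandy mangrove soils. This
vignette is the package's own account of the statistics it computes, the
assumptions behind them, and the design choices made where the methodology
admits more than one defensible option.

## The two core statistics

**Cohesion (complexity).** Every pair of taxa that survives the
co-occurrence significance filter carries a signed Spearman correlation.
For taxon $i$, its *positive connectedness* is the mean of its retained
positive correlations and its *negative connectedness* the mean of its
retained negative ones (zero when none are retained). A sample's cohesion is
the abundance-weighted sum

$$C = \sum_{i=1}^{m} a_i \cdot \mathrm{conn}_i,$$

computed separately for the positive and negative components over the $m$
taxa with relative abundances $a_i$. Positive cohesion tracks how much of a
sample's biomass participates in cooperative (positively co-varying)
structure; negative cohesion tracks competitive structure; total cohesion is
`positive + |negative|`. Because abundances sum to one and $|\mathrm{conn}|
\le 1$, every component is bounded by 1.

Two constructions of the "retained" correlation set are offered:
`network_edges` (the default — exactly the edges of the thresholded
network) and `all_significant` (every pair passing the significance test,
ignoring the $|\rho|$ edge threshold). A taxon-shuffle null-model correction
(subtracting the mean correlation observed after permuting each taxon's
abundances across samples) is available behind `null_model = TRUE` but off
by default: the basic abundance-weighted definition is the primary target,
and the correction is offered as the canonical refinement for users who
want background correlation removed.

**Robustness (stability).** Starting from a group's network, a removal
protocol deletes either a random fraction of nodes (Monte Carlo, default
50%) or the top module hubs (deterministic, default 5). Secondary
extinctions then propagate: a remaining species $i$ goes extinct when it has
no remaining edges, or when its abundance-weighted mean association strength

$$\frac{\sum_{j \ne i} b_j s_{ij}}{\sum_{j \ne i} b_j} \le 0,$$

summed over its remaining neighbours $j$, is non-positive — here $b_j$ is
the relative abundance of species $j$ and $s_{ij}$ the *Pearson* correlation
of relative abundances (the association-strength convention for this
statistic, retained alongside the Spearman matrix that selected the edges).
Extinction is iterated to a fixed point; robustness is the proportion of the
initial species that remain, averaged over iterations for the random
protocol. Two closed forms anchor the implementation: a complete
positive-correlation network with equal abundances loses exactly the removed
fraction (no secondary extinctions), and a star network collapses to zero
when its hub is removed.

One contract subtlety: a removal fraction so small that
`floor(fraction * n) < 1` is an error for the group-level statistic (the
request is unsatisfiable), while the per-sample score described below
returns 1 for tiny induced subnetworks (nothing was removed, everything
remains). Both behaviours are deliberate and tested.

**Per-sample stability.** Group-level robustness is one number per network,
but driver screening and path modeling need a per-sample response. The
package defines it explicitly as the robustness of the subnetwork induced by
the taxa *present* (abundance > 0) in the sample, with $b_j$ taken from that
sample's own relative abundances rather than the group mean. This makes the
score a genuine function of the sample — two samples over the same node set
still differ through their abundance weights — at the cost of being a
package-defined convention rather than a community standard; it is isolated
in `sample_stability()` and recorded in every run manifest.

## Network construction

Pairwise Spearman correlations use midranks for ties; p-values use the
t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of
freedom, with $p = 0$ at $|\rho| = 1$ (below any representable threshold).
Zero-variance taxa cannot be ranked and are excluded with a message. An
edge is kept when $|\rho| \ge$ `rho_min` and the (optionally
Benjamini–Hochberg corrected) p-value is below `alpha`. The defaults —
$|\rho| \ge 0.6$, BH-corrected $p < 0.05$ — follow common practice in
microbiome co-occurrence work; they are parameters, not constants, and every
pipeline run records them. Construction is monotone: tightening either
threshold can only remove edges. Isolated nodes are dropped by default.

Networks are built per group (e.g. per soil type) on that group's samples
only, after a mild prevalence filter (default: present in ≥ 20% of samples)
— rank-correlation p-values are meaningless for near-absent taxa. Module
detection is weighted Louvain (on $|\rho|$) with a fixed seed and resolution
1; modularity follows the standard weighted definition. Module hubs are
ranked by within-module degree z-score $Z_i$, the standard module-hub
criterion in microbial network ecology, with ties broken by total degree and
then node id; size-1 modules get $Z = -\infty$, constant-degree modules
$Z = 0$. Both the number of modules and the modularity are always reported
— they answer different questions and conflating them invites confusion.

## Diversity and spatial statistics

The Shannon index uses the natural logarithm (the prevailing ecology
convention; a `base` argument exists). Bray–Curtis dissimilarity,
$d = \sum|x_i - y_i| / \sum(x_i + y_i)$, feeds principal coordinates
analysis: Gower double-centering of $-d^2/2$, eigendecomposition, and
coordinates scaled by the square roots of positive eigenvalues. Percent
explained is reported against the sum of *positive* eigenvalues, with no
correction by default (Lingoes behind a flag) — Bray–Curtis matrices are
generally non-Euclidean and silently "fixing" them changes the axis
percentages.

ANOSIM midranks all pairwise distances and computes
$R = (\bar r_{between} - \bar r_{within}) / (N(N-1)/4)$; the p-value is the
one-sided (large $R$) add-one permutation estimator
$(1 + \#\{R^* \ge R\})/(1 + n_{perm})$, which cannot return 0. The Mantel
test correlates upper triangles under joint row/column permutation and is
two-sided by default (a one-sided flag exists). Both tests offer exhaustive
enumeration of all label permutations for small $n$, which is how the test
suite pins them to brute-force oracles exactly. Geographic distances are
geodesics on the WGS84 ellipsoid, in meters.

## PLS path modeling

The inner model is a DAG of latent variables in declared causal order
(strictly lower-triangular adjacency by construction); each latent is
measured reflectively (mode A) by a block of manifests. Estimation is the
classical Lohmöller alternation: standardize manifests (population, $1/n$,
variance — so latent scores have population variance 1 and a single path
coefficient equals a latent correlation); start with equal outer weights;
alternate outer estimation, inner proxies (centroid scheme by default —
correlation *signs* of adjacent latents; factorial and path schemes behind
flags), and mode-A weight updates until the largest weight change falls
below `tol` (default 1e-7, `max_iter` 300, non-convergence is an error
carrying the last delta). Path coefficients are then OLS among latent
scores with a condition-number guard against collinear predecessors;
loadings are manifest–score correlations; $R^2$ per endogenous latent;
$\mathrm{GoF} = \sqrt{\overline{\mathrm{communality}} \times \overline{R^2}}$.

PLS scores are sign-indeterminate; each latent is oriented so its mean
loading is positive, which makes output reproducible and leaves all
|effects| invariant (a tested property). Effects decompose exactly:
direct = path coefficient, indirect = sum over all directed paths of length
≥ 2 of coefficient products, obtained from the finite series
$(I - B)^{-1} - I$; total = direct + indirect to machine precision.
Significance uses a nonparametric bootstrap (resample samples, refit,
percentile CI, two-sided percentile p against 0) with non-convergent
resamples dropped and counted (more than 20% dropped is an error).

A composite-based method carries attenuation: with loadings $\lambda$ and
$K$ manifests per block, a block composite correlates with its latent at
roughly $\lambda\sqrt{K}/\sqrt{1 + (K-1)\lambda^2}$, so estimated paths are
biased toward zero by the product of the two blocks' reliabilities. At
$\lambda = 0.8$ this factor is ≈ 0.93 for $K = 4$ and ≈ 0.97 for $K = 8$.
The package's parameter-recovery study therefore uses 8 manifests per
latent at $n = 500$ over 50 generator seeds, where the residual attenuation
(≈ 0.03 on a path of 0.5) sits comfortably inside the ±0.05 recovery band;
with few indicators per block a user should expect visibly shrunken
coefficients — that is the method, not a bug.

For the full study-shaped model (soil properties, nutrients, geographic
distance, alpha diversity, beta diversity → complexity and stability), the
per-sample manifests are: Shannon index for alpha diversity; scores on the
first two Bray–Curtis principal coordinates for beta diversity; mean
geodesic distance to all other samples for geographic distance; total
cohesion for complexity; and the per-sample stability score. None of these
reductions is canonical — they are explicit, configurable choices, and the
model is fitted per group.

## The synthetic community generator

`generate_community()` emulates the features of a two-soil-type amplicon
survey that the downstream statistics actually consume, with known ground
truth:

* **Group-specific dominance.** Per-group class weight profiles (e.g. a
  Dothideomycetes-dominated clay loam vs a more even sandy community) are
  split among class members and jittered by log-normal taxon effects. The
  more even profile automatically yields higher Shannon diversity, matching
  the intended contrast.
* **Correlation blocks.** Within each block, a Gaussian copula with an
  equicorrelated latent factor injects a target pairwise Spearman
  correlation (latent Pearson $r = 2\sin(\pi\rho_s/6)$), leaving the count
  marginals intact — exactly the quantity a Spearman network measures.
  Negative blocks split into two anti-correlated halves (pairwise negative
  equicorrelation beyond 2 taxa is infeasible). Blocks may be restricted to
  one group, which is what produces group-specific cohesion. Block taxa get
  a configurable abundance boost so the correlated guilds matter to the
  abundance-weighted statistics.
* **Counts.** Negative binomial per taxon (variance $\mu + \phi\mu^2$,
  shared dispersion $\phi = 0.5$ by default — overdispersion is the norm in
  amplicon counts) via quantile transform of the copula uniforms, at an
  expected depth of 20,000 reads; a multinomial fixed-depth alternative sits
  behind a flag (its block correlation is injected on the log-probability
  scale and is approximate).
* **Environment and space.** Environmental variables come from a latent
  path model generated recursively along a DAG with unit-variance latents,
  so declared path coefficients are latent correlations and recovery can be
  tested against hidden scores. Coordinates are site centers plus uniform
  disc jitter; geodesic distances then have known between-site structure.

Default study conditions mirror a three-site, two-soil-type design: 25
clay-loam samples at one site, 50 sandy samples across two sites, 120 taxa,
with a strong cooperative clay-loam block and weaker mixed sandy blocks.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: compositional closure effects (counts are
independent NB draws, not strictly sum-constrained, so spurious negative
correlation from closure is absent), taxonomic structure beyond opaque
class labels, spatial autocorrelation of environmental variables within
sites, sequencing error or chimeras, and any relationship between the
environment and the community (environmental drivers in the synthetic study
are null unless the user wires them in). Environmental variables are
generated on a standardized scale, not in physical units.

The directional end-to-end check — that a group carrying one dominant,
highly cohesive cooperative block (15 taxa, $\rho = 0.8$, 6× abundance
boost) beats a group with a weaker positive block and a low-abundance
competitive block on *both* mean total cohesion and robustness in ≥ 45 of 50
seeded replicates — is designed around mechanism: abundance weighting makes
the dominant block carry cohesion, while the competitive block's members
count equally in the species-proportion robustness score and are
extinction-prone. Balanced group sizes (30/30) keep network statistical
power comparable between groups.

## Numerical conventions and degenerate inputs

* Relative-abundance rows must sum to 1 within 1e-9; round-trips through
  TSV preserve reals to 1e-12.
* Ties: midranks everywhere (Spearman, ANOSIM).
* Add-one permutation p-values; exhaustive mode reports the exact
  proportion over all permutations (identity included).
* All-zero samples are an error for normalization and Bray–Curtis; an
  all-zero taxon is excluded from correlation work with a message.
* Empty networks are valid objects (with a warning) for export, but
  robustness and module detection refuse them.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state; the pipeline derives per-stage seeds from one top-level seed,
  and identical configurations produce byte-identical result tables.

## Validation problem sizes

The test suite pins every statistic to an independent oracle at small scale:
exhaustive permutations at $n \le 6$, all-bipartition modularity on 8-node
graphs, brute-force recomputation on random graphs up to 12 nodes, hand
dot-products for cohesion, fixed-point hand simulation for extinction
cascades. Calibration studies use 1000 null replicates (permutation tests
and bootstrap rejection rates at $\alpha = 0.05$), parameter recovery uses
$n = 500$ with 50 seeds, and the directional end-to-end study uses 50
seeded replicates of the two-group design above — sizes chosen to make
Monte-Carlo error small relative to the tolerances being asserted.

## Interfaces

The package is function-first: tibble-in/tibble-out stages that chain with
the pipe, `tidy()`/`glance()` methods on fitted objects, and `autoplot()`
methods for ordinations, driver tables and path models. Batch orchestration
goes through `validate_config()` and `run_pipeline()`, driven by one
YAML/JSON configuration with an explicit seed, unknown-key rejection and a
manifest recording every applied default, seed and output checksum; this
configuration surface is the package's scripting interface, and
`scripts/acceptance.R` in the source repository is a worked example of
driving a full study from code.

## Known limitations

Spearman co-occurrence networks are not compositionality-aware (no
SparCC/SPIEC-EASI); correlation is not interaction. The per-sample
stability score is a package convention (see above). PLS-PM is
composite-based and attenuated relative to a covariance SEM; only
reflective (mode A) blocks are supported. Rarefaction and phylogenetic
diversity are out of scope. The robustness statistic depends on the
network's significance thresholds; comparisons are meaningful within a
fixed threshold policy, which the run manifest records.
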