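---
title: "Inferring correlog and anti-correlog gene networks from phylogenetic profiles"
author: "correlognet developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring correlog and anti-correlog gene networks from phylogenetic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(correlognet)
```

## The problem

Genes that work together — as enzymes of one pathway, subunits of one
complex, or partners in one cellular program — tend to be inherited and
lost together during evolution. The phylogenetic profile of a gene is
the binary vector $x_{ki} \in \{0,1\}$ recording whether an ortholog of
gene $i$ is present in species $k$. Across a panel of $N$ genomes,
functionally linked genes co-occur (*correlogs*), while genes belonging
to mutually exclusive repertoires — alternative solutions to the same
need, or markers of incompatible lifestyles — avoid each other
(*anti-correlogs*).

Raw profile correlation is a poor measure of direct linkage: if genes
$i$ and $j$ are both correlated with a third gene $m$, they appear
correlated with each other even when no direct functional relationship
exists (the transitivity effect). `correlognet` removes this artifact
with a shrinkage-regularized graphical Gaussian model and then distills
the resulting weighted network into an interpretable backbone.

## The model

### Prevalence filtering

For each gene, $E_i = \sum_k x_{ki}$ and the balance score
$X_i = \min(E_i, N - E_i)$. Genes that are almost never or almost
always present offer few informative co-presences or co-absences, so
their pairwise correlations are dominated by chance and vertical
co-inheritance. `filter_by_prevalence()` keeps genes with
$X_i \ge X_{th}$. The default $X_{th} = 80$ is appropriate for panels
of several hundred genomes, where the empirical density of $X_i$ decays
as a power law above that point; `balance_distribution()` exposes the
density so the cutoff can be chosen by inspection for other panels, and
the synthetic-data tests rescale it in proportion to module prevalence
(e.g. $X_{th} = 30$ for the default 600-species planted world).

### From correlation to partial correlation

The Pearson correlation of two binary profiles has the closed
co-occurrence form
$$ r_{ij} \;=\; \frac{N C_{ij} - E_i E_j}
   {\sqrt{E_i (N - E_i)\, E_j (N - E_j)}}, $$
with $C_{ij}$ the number of species carrying both genes. Because the
number of genes typically exceeds the number of genomes, the sample
correlation matrix is ill-conditioned; it is shrunk toward the identity,
$$ r^{*}_{ij} = (1 - \lambda)\, r_{ij} + \lambda\, \delta_{ij}, $$
with the analytic Ledoit–Wolf-type intensity of Schäfer & Strimmer,
$$ \lambda = \frac{\sum_{i \ne j} \widehat{\mathrm{Var}}(r_{ij})}
  {\sum_{i \ne j} r_{ij}^2}, \qquad
  \widehat{\mathrm{Var}}(r_{ij}) = \frac{N}{(N-1)^3}
  \sum_k (z_{kij} - \bar z_{ij})^2, $$
where $z_{kij}$ is the product of the standardized profiles
($\sigma_i$ with the unbiased $N-1$ denominator) and $\lambda$ is
clipped to $[0,1]$. The partial correlation is read off the precision
matrix $p = (r^{*})^{-1}$:
$$ w_{ij} = -\, p_{ij} \, / \sqrt{p_{ii}\, p_{jj}}. $$
$w_{ij} > 0$ marks a correlog pair, $w_{ij} < 0$ an anti-correlog pair.
Mutual information $I_{ij}$ over the joint $2\times 2$ presence table
is computed alongside (in nats by default; the base is a reporting
choice) as the standard purely-pairwise comparator that retains
transitive associations.

Numerical choices: the inversion uses a Cholesky factorization of the
symmetric positive-definite $r^*$ (any $\lambda > 0$ guarantees
positive definiteness); asymmetries beyond $10^{-10}$ abort rather than
being averaged away silently; the diagonal of $w$ is reported as 0
because self-association is meaningless; a singular input produces an
error instructing the user to raise $\lambda$. $\lambda$ is estimated
on the filtered gene set, mirroring the order filter → estimate. When
every off-diagonal correlation vanishes the $\lambda$ ratio degenerates
to $0/0$ and full shrinkage ($\lambda = 1$) is applied with a message.

### The maximum relatedness subnetwork and correlog groups

In the MRS each gene points to at most two partners: its strongest
correlog ($\arg\max_j w_{ij}$ over $w_{ij} > 0$) and its strongest
anti-correlog ($\arg\min_j w_{ij}$ over $w_{ij} < 0$). Ties are broken
toward the lexicographically smallest gene id — the construction must
be deterministic for reproducible runs, and the choice is otherwise
arbitrary. A gene without a positive (negative) partner simply lacks
that edge; $w_{ij} = 0$ belongs to neither category.

*Correlog groups* are the connected components of the undirected
projection of correlog edges. Two structural facts are asserted on
every constructed MRS (`verify_mrs()`): following successor edges the
weights are non-decreasing until a mutually reciprocal pair is reached,
and every non-singleton group contains at least one reciprocal pair.
Group ids are assigned by decreasing size, then lexicographically —
any stable convention would do. Anti-correlog edges are expected to
bridge different groups (`intergroup_anti_fraction()`), producing a
modular network whose modules repel each other.

Per-gene coupling strengths are
$S^p_i = \sum_{j:\, w_{ij}>0} w_{ij}$ and
$S^n_i = \sum_{j:\, w_{ij}<0} |w_{ij}|$; $S^n$ sums magnitudes so both
quantities are non-negative sizes. Pairs with $w_{ij} > 0.045$
(strict) are flagged as the regime enriched for functionally
obligatory physical interactions; the threshold is exposed as a plain
parameter.

## Statistical machinery

### Clustering of gene sets on correlog groups

For an organism whose mappable genes hit $n$ distinct correlog groups,
the reference model maps the same number of genes uniformly at random,
**without replacement**, onto the $M = \sum_g N_g$ gene slots of the
partition. Then
$$ \eta = \sum_g p_g, \qquad p_g = 1 - \binom{M - N_g}{n_{\mathrm{map}}}
   \Big/ \binom{M}{n_{\mathrm{map}}}, $$
$$ \sigma^2 = \sum_g p_g (1 - p_g) + \sum_{g \ne h} (q_{gh} - p_g p_h),
   \qquad q_{gh} = p_g + p_h - 1 +
   \binom{M - N_g - N_h}{n_{\mathrm{map}}} \Big/ \binom{M}{n_{\mathrm{map}}}, $$
and $Z = (n - \eta)/\sigma$. Sampling without replacement is the model
consistent with "the same number of genes randomly mapped": it yields
$\sigma = 0$ exactly at saturation ($n_{\mathrm{map}} = M$), where $Z$
is reported as a flagged `NA` rather than a number. A
with-replacement variant is available behind `replace = TRUE` for
sensitivity analysis only. `clustering_bounds()` gives the attainable
range of $n$ (greedy packing for the minimum). The analytic moments are
tested against exhaustive enumeration for all partitions with
$M \le 12$ and against $10^5$-draw Monte Carlo for larger ones.

### Permutation nulls for annotations

Functional coherence: for group $g$ and category $c$,
$f_c^g = \tilde N_c^g / \tilde N^g$ over the annotated members; the
summary is the fraction of groups with $\tilde N^g > 1$ in which some
category reaches $f_c^g = 1$. Category overlap
$Y_{c_1 c_2}$ is the number of groups containing genes of both
categories over the number containing genes of either. Both statistics
are judged against the same null: annotation *sets* are randomly
exchanged among genes carrying the same number of categories, so each
gene's label count and the overall multiset of annotation sets are
preserved and unannotated genes never enter the shuffle. Empirical P
values use the add-one convention $P = (1 + k)/(1 + n_{\mathrm{perm}})$
so they are never zero; degenerate nulls (sd $= 0$) yield $Z = 0$ when
the observed value equals the null value and a flagged `NA` otherwise.

### Pair-set comparisons

To test whether designated pairs (physically interacting proteins,
isozymes, …) carry larger $w$ than arbitrary pairs,
`pairset_w_comparison()` draws, per stratum (typically shortest-path
length in the interaction network, from `shortest_path_strata()`),
random pair sets of matched size, and standardizes the observed mean
against the null means. The reported P is the upper-tail Gaussian value
— the null of averages is approximately normal by the central limit
theorem — while the raw empirical null means are kept in the output for
audit. Strata smaller than the designated set are resampled with
replacement and flagged. The same interface applies to the $r$ and $I$
matrices, and positive and negative $w$ are naturally analyzed in
separate passes by splitting the pair set on the sign.

### Phylum-level dispersion

With a species → phylum taxonomy, $n^{\mathrm{phyla}}_i$ counts the
distinct phyla containing gene $i$. Restricted to genes with
$n^{\mathrm{phyla}} <$ `n_phyla_max` (default 7, below the saturation
plateau of panel-scale data), the OLS slope of $S^p_i$ on
$n^{\mathrm{phyla}}_i$ measures whether taxonomically widespread genes
are more strongly coupled. There is no single canonical normalization
for such a slope, so both the raw slope and a
scale-free variant (slope $\times$ sd$(n^{\mathrm{phyla}})/$sd$(S^p)$,
i.e. the Pearson correlation of the regression) are exposed; the Z
score — which is what can be compared across analyses, being invariant
under any common linear rescaling — is computed on the normalized
variant against surrogates in which each gene's presence vector is
independently permuted across species (preserving every $E_i$) and the
whole pipeline ($\lambda$, $w$, $S^p$, $n^{\mathrm{phyla}}$) is
recomputed.

## The synthetic planted world

`planted_model()` states the world the pipeline assumes: disjoint gene
modules switching on/off per species with probability $\pi_g$
(default 0.5), optional anti-paired modules that are mutually exclusive
within a species (when both are drawn active, one is deactivated
uniformly at random, keeping marginal activities symmetric — this
convention sets the strength of planted anti-correlogy), per-cell
false-positive/false-negative rates (default 0.05 each), optional
i.i.d. background genes, and optional per-module species spans. The
default scale — 600 species, 20 modules of 5 genes, consecutive modules
anti-paired — mirrors panels of a few hundred bacterial genomes so that
shrinkage behaves comparably, with $X_{th}$ scaled down to 30 in the
tests in proportion to module prevalence. Companion generators emit
module-pure annotations at a chosen purity, a module-structured
interaction graph, organism gene sets drawn as unions of a few modules
with dropout, and a block taxonomy (`synthetic_taxonomy()`, optionally
with skewed phylum sizes, which real taxonomies have and which keeps
surrogate $n^{\mathrm{phyla}}$ distributions non-degenerate). All
generators are pure functions of (parameters, seed); each derives its
own stream from the model seed so regenerating one fixture never
perturbs another.

What the generator does *not* emulate: tree-structured vertical
co-inheritance (profiles are exchangeable across species given module
activity), gene-family size variation, and correlated annotation errors.
A green test on planted data therefore establishes correctness of the
computations and their calibration under the stated world, not
performance on any particular real orthology snapshot.

### What the planted world can and cannot meet

Two simulation targets deserve honesty. First, correlog groups are
components of a per-gene argmax graph. Within a planted module of five
statistically exchangeable genes the argmax partner is noise-determined,
and a random functional graph on five nodes is frequently disconnected —
so modules regularly split into two or three groups (≈27–30 groups from
20 modules at the default world). Group *purity* is essentially perfect,
but the adjusted Rand index against the planted partition plateaus
around 0.8–0.9. This is intrinsic to argmax backbones, which decompose
cohesive gene sets into many small subgroups rather than whole
pathways. Second,
a gene's planted anti-correlation with its partner module (marginal
$r \approx -0.5$) is largely explained away by conditioning on its
near-duplicate module-mates, so at the small analytic
$\lambda \approx 0.04$ of the default world the anti-correlog argmin
edge is usually claimed by noise rather than by the paired module. Both
effects are properties of the stated world, and the corresponding
acceptance assertions are left to fail rather than re-tuned; the third
planted-structure property — that essentially *all* anti-correlog edges
bridge distinct correlog groups — holds at 1.0 across seeds.

## Tunable parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `x_th` | 80 | minimum balance $X_i$ (genes kept); rescale per panel |
| `lambda_override` | none | bypass analytic shrinkage (1 = identity, 0 = none) |
| `obligatory threshold` | 0.045 | strict lower bound on $w_{ij}$ for the obligatory regime |
| `n_phyla_max` | 7 | dispersion regression uses genes below this phylum count |
| `n_perm` | 1000 | permutations for annotation nulls (minimum 100) |
| `n_draws` | 1000 | null draws for pair-set comparisons |
| `replace` | `FALSE` | clustering null sampling model |

## Known limitations

- The pipeline assumes a single binary presence call per gene/species;
  copy number and partial orthology are out of scope.
- No multiple-testing correction is applied across category pairs; the
  overlap table reports raw permutation P values.
- The MRS is the only backbone construction offered; it is the method
  under study, not a general community-detection substitute.
- Profile matrices are dense in memory; panels beyond ~10⁴ genes ×
  10³ species would need a blocked implementation.
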