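# correlognet

Correlog and anti-correlog gene networks from phylogenetic profiles.

## What problem this solves

Across hundreds of sequenced genomes, genes that function together tend
to be present together: the binary *phylogenetic profile*
`x_ki ∈ {0,1}` (gene *i* present in species *k*) carries a strong
signal of functional linkage. But raw profile correlation is inflated
by transitivity — two genes both correlated with a third look
correlated with each other. `correlognet` is for comparative genomicists
and systems biologists who want *direct* co-occurrence relationships:

1. **Association** — from a gene × species 0/1 matrix it computes the
   binary Pearson correlation
   `r_ij = (N·C_ij − E_i·E_j) / √(E_i(N−E_i)·E_j(N−E_j))`, shrinks it
   toward the identity with the analytic Schäfer–Strimmer intensity λ
   (`r*_ij = (1−λ)r_ij + λδ_ij`), and reads partial correlations off
   the precision matrix: `w_ij = −p_ij/√(p_ii·p_jj)`. `w_ij > 0` is a
   **correlog** (direct co-occurrence), `w_ij < 0` an **anti-correlog**
   (mutual avoidance). Mutual information `I_ij` is computed alongside
   for comparison.
2. **Network** — the *maximum relatedness subnetwork* (MRS): each gene
   points to its single strongest correlog and strongest anti-correlog
   partner. Connected components of the correlog edges are **correlog
   groups** (gene repertoires that travel together); anti-correlog
   edges bridge the groups. Per-gene coupling strengths `S_i^p`, `S_i^n`
   and the obligatory-interaction flag (`w_ij > 0.045`) complete the
   picture.
3. **Statistics** — analytic mean/variance for the number of distinct
   groups hit by a gene set (clustering Z of an organism's repertoire),
   permutation nulls for functional coherence `f_c^g` and category
   overlap `Y_c1,c2`, shortest-path-stratified pair-set comparisons
   against interaction networks, and the phylum-dispersion regression
   of `S_i^p`.
4. **Synthetic data** — a planted-module generator (correlog modules,
   mutually exclusive anti-paired modules, noise, spans, annotations,
   interaction graphs, organism sets) so the whole pipeline is testable
   without any database download.

## Worked example

```r
library(correlognet)

model  <- planted_model(n_species = 600, n_modules = 20,
                        genes_per_module = 5, seed = 1)
gp     <- generate_profiles(model)
gp$profile
#> profile_matrix: 100 genes x 600 species; fill 0.386

assoc  <- association_pipeline(gp$profile, x_th = 30)
assoc
#> association_result: 100 genes, lambda = 0.0409, 2502 correlog / 2448 anti-correlog pairs

mrs    <- build_mrs(assoc$w)
groups <- correlog_groups(mrs)
mrs; groups
#> mrs_graph: 100 nodes, 100 correlog edges, 100 anti-correlog edges
#> correlog_group_set: 30 groups over 100 genes (largest N_g = 5)

intergroup_anti_fraction(mrs, groups)$fraction
#> [1] 1

org <- generate_organism_sets(model, n_organisms = 1,
                              modules_per_organism = 3, dropout = 0.1)[[1]]
clustering_z(groups, org)
#> cluster_stat: n = 5 groups hit by 13 genes; eta = 10.980, sigma = 1.107, Z = -5.403
```

Reading the output: the analytic shrinkage is mild (λ ≈ 0.04, 600
species for 100 genes), the 20 planted five-gene modules are recovered
as 30 pure correlog groups (argmax components are finer than modules),
*every* anti-correlog edge bridges two different groups, and a
synthetic organism built from 3 modules hits far fewer groups (n = 5)
than random mapping of 13 genes would (η ≈ 11.0), i.e. its repertoire
is strongly clustered on correlog groups (Z ≈ −5.4).

## Command line

```sh
Rscript -e 'correlognet::correlognet_main()' simulate --outdir sim --seed 7
Rscript -e 'correlognet::correlognet_main()' infer --input sim/profiles.tsv \
    --outdir run --x-th 30
Rscript -e 'correlognet::correlognet_main()' mrs --input sim/profiles.tsv \
    --outdir run --x-th 30
```

(or use the launcher installed at `exec/correlognet` inside the package
library). Subcommands `infer`, `mrs`, `stats`
(`--stats-subcommand cluster|coherence|overlap|pairset|phylum`) and
`simulate` take a JSON `--config` plus per-flag overrides; every run
writes a metadata JSON with version, parameters, seeds and input
checksums. Exit status is 0 on success, 2 on validation errors.

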