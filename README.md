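# topoddg

Topological featurization and prediction machinery for mutation-induced
protein–protein binding free energy changes (ΔΔG), with an evaluation
pipeline for predicted complex structures.

## What problem this addresses, and for whom

A point mutation at a protein–protein interface shifts the binding free
energy by ΔΔG = ΔG(mutant) − ΔG(wild-type) (kcal/mol; by the dissociation
constant convention, ΔΔG = RT ln(K_d,mut / K_d,wt)). Structure-based ΔΔG
predictors in the topological deep learning family encode the interface
through **persistent Laplacian spectra**: element/site-specific atom
subsets become filtered simplicial complexes, and the spectra of their
combinatorial Laplacians

    L_k = B_{k+1} B_{k+1}ᵀ + B_kᵀ B_k        (L_0 = B_1 B_1ᵀ)

are tracked along the filtration. The multiplicity of the zero eigenvalue
of L_k equals the Betti number β_k (components, loops, cavities for
k = 0, 1, 2; combinatorial Hodge theorem), while the non-zero spectrum adds
geometric shape information that Betti numbers miss. The p-persistent
variant couples nested snapshots K_t ⊆ K_{t+p} and recovers persistent
homology in its harmonic space.

The package is for structural bioinformaticians who want to (a) build
these spectral features for mutation datasets in the SKEMPI convention and
regress ΔΔG with cross-validated Pearson correlation (Rp) and RMSE, and
(b) audit predicted complexes (e.g. from modern structure predictors)
against experimental references: Kabsch superposition RMSD, per-residue
backbone RMSD joined with crystallographic B-factors, and ipTM/pTM
confidence summaries with the standard bands (ipTM ≥ 0.8 confident,
< 0.6 likely wrong; pTM ≥ 0.5 acceptable).

Everything is testable offline: a synthetic module generates toy
two-chain complexes with controlled interface contacts, controlled
per-residue displacement ("predicted copy" error), and mutation datasets
whose ΔΔG is a known function of the features.

## Structure of the package

| Area | Functions |
|---|---|
| I/O | `parse_structure` (PDB/mmCIF), `write_structure`, `parse_confidence`, `parse_mutation_code`, `ddg_from_affinities`, `parse_skempi` |
| Atom subsets | `select_mutation_site`, `select_neighborhood`, `select_binding_site`, `filter_by_element`, `site_subsets`, `pairwise_distances` (Euclidean or cross-group "mod" with ∞ for same-group pairs) |
| Topology | `build_rips`, `build_alpha`, `prune_cross_only`, `snapshot`, `boundary_matrix` |
| Spectra | `combinatorial_laplacian`, `persistent_laplacian`, `spectrum`, `betti_from_spectrum`, `betti_by_rank` (independent rank oracle) |
| Features | `spectral_statistics`, `feature_config`, `filtration_features`, `build_mutant`, `assemble_features` |
| Regression | `train_model` (gradient-boosted trees; linear reference), `cross_validate`, `pearson_r`, `rmse` |
| Structure evaluation | `map_chains`, `kabsch_superpose`, `superpose_structures`, `per_residue_rmsd`, `bfactor_rmsd_table`, `summarize_and_rank`, `evaluate_manifest` |
| Synthetic data | `make_toy_dimer`, `perturb_structure`, `synth_mutation_dataset`, `make_fixtures` |

Thin command-line wrappers live in `inst/cli/` (`parse-skempi.R`,
`train.R`, `evaluate.R`, `make-fixtures.R`).

## Worked example

```r
library(topoddg)

# a toy two-chain complex: 16 residues per chain, 3 interface contacts
s <- make_toy_dimer(residues_per_chain = 16, interface_contacts = 3,
                    seed = 2)
s
#> Structure TOY - 159 atoms, 2 chain(s)
#>   P1 : A
#>   P2 : B

# features for a mutation at chain A residue 8 (Ile -> Gly), using the
# truncated-side-chain fallback mutant and a small filtration grid
mut <- parse_mutation_code("IA8G")
fv <- assemble_features(s, build_mutant(s, mut), mut,
                        feature_config(grid0 = seq(0, 8, 2),
                                       grid12 = seq(0, 6, 2)))
length(fv)
#> [1] 5616
round(fv[c("wt_binding_CC_k0_t4_n_harmonic",
           "mut_binding_CC_k0_t4_n_harmonic",
           "diff_binding_CC_k0_t4_n_harmonic")], 3)
#>   wt_binding_CC_k0_t4_n_harmonic  mut_binding_CC_k0_t4_n_harmonic
#>                               67                               66
#> diff_binding_CC_k0_t4_n_harmonic
#>                               -1
```

The harmonic multiplicity of the dimension-0 Laplacian at filtration
scale 4 Å counts connected components of the cross-partner carbon–carbon
contact graph; removing the side chain deletes one component, and the
difference block hands that −1 straight to the regressor.

```r
# cross-validated recovery of a known sparse linear ddG model
ds <- synth_mutation_dataset(n = 500, seed = 42)
cross_validate(ds$features, ds$records$ddg, k_folds = 10, seed = 42)
#> 10-fold CV (record grouping): Rp = 0.963, RMSE = 0.791 kcal/mol

# predicted-complex evaluation: flexible regions carry the model error
b <- tapply(s$atoms$b_factor, paste(s$atoms$chain, s$atoms$res_seq), mean)
pred <- perturb_structure(s, 0.05 * as.numeric(
          b[unique(paste(s$atoms$chain, s$atoms$res_seq))]),
          seed = 2, rigid = TRUE)
al <- superpose_structures(pred, s)
sprintf("alignment RMSD: %.3f A over %d residues", al$rmsd,
        nrow(al$per_residue))
#> [1] "alignment RMSD: 1.167 A over 32 residues"
tab <- bfactor_rmsd_table(s, al$per_residue)
cor(tab$b_factor, tab$rmsd, method = "spearman")
#> [1] 0.922
```

Here the synthetic "prediction" displaces each residue proportionally to
its B-factor; the Spearman correlation of 0.92 between reference
flexibility and per-residue backbone RMSD is the mechanism by which
flexible regions dominate predicted-structure error.

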