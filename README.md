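# barcodediv

Diversification inference for clades known mainly through a short, slowly
evolving barcode marker — the situation of arbuscular mycorrhizal fungi
(Glomeromycotina), whose global diversity is sampled almost entirely as
~520-bp SSU rRNA amplicons. When species-like units must be delineated from
such a marker, two artefacts threaten any inferred speciation-rate decline:
incomplete sampling of global diversity, and *lumping* of recently diverged
species that the slow marker cannot separate. `barcodediv` implements the
full analysis chain and, centrally, the simulation study that quantifies
the lumping artefact.

## What it does

* **Unit delineation** (`pairwise_similarity`, `delineate_eus`): traverses a
  haplotype tree from the root toward the tips and collapses every
  monophyletic clade whose mean pairwise sequence dissimilarity is strictly
  below `1 - tau` into one evolutionary unit (EU); `tau = 0.99` gives the
  "EU99" delineation.
* **Sampling completeness** (`rarefaction_curve`, `chao2_richness`,
  `sampling_fraction`): accession-level rarefaction, Chao2 incidence
  richness with the `(R-1)/R` correction, and observed/estimated fractions
  reported to the percent.
* **Birth–death fitting** (`fit_bd`, `fit_env`, `aicc_compare`,
  `slice_tree`, `decline_statistic`): constant, time-exponential
  (λ(t) = λ₀e^{αt}) and environment-driven (λ(t) = b·e^{a·env(t)})
  speciation with zero/constant/pinned extinction and incomplete sampling
  f, via the E(t) ordinary differential equation of the reconstructed
  birth–death likelihood, crown-survival conditioning, and AICc selection
  (support = all rivals ≥ 2 units worse).
* **Correlates** (`tajima_pi`, `niche_pca`, `rate_correlation`): per-unit
  nucleotide diversity θπ, niche-width PCA with a fixed sign convention
  (PC1 = generalism), and ordinary / phylogenetic-GLS / latitude-jackknife
  regressions.
* **Simulation workbench** (`sim_config`, `simulate_species_tree`,
  `graft_intraspecific`, `simulate_alignment`, `collapse_haplotypes`,
  `run_lumping_experiment`): crown-conditioned species trees (505 Myr),
  grafted within-species coalescents (2–15 individuals, roots within
  30 Myr), slow 520-bp alignments (25% variable sites, 0.001
  substitutions/site/Myr), and the end-to-end lumping-bias experiment.

The numbered scripts under `analysis/` run the workflow as a narrative:
`01_simulate.R` → `06_lumping_experiment.R`, writing tables under
`results/`.

## Worked example

```r
library(barcodediv)

cfg <- sim_config_scenario("pb", r = 0.010, crown_age = 505)
set.seed(7)
tree    <- simulate_species_tree(cfg)      # 324 species
grafted <- graft_intraspecific(tree, cfg)  # 2661 individuals
aln     <- simulate_alignment(grafted, cfg)
hap     <- collapse_haplotypes(aln)        # 1032 haplotypes
htree   <- haplotype_tree(grafted, hap$members)
part    <- delineate_eus(htree, pairwise_similarity(hap$alignment), 0.99)
part
#> EU partition at tau = 0.99: 281 units over 1032 tips
100 * (1 - length(part$blocks) / ape::Ntip(tree))
#> [1] 13.2716
```

281 EU99 units for 324 true species: the slow marker lumps ~13% of species
away. The full experiment repeats this over replicates:

```r
rep_tab <- run_lumping_experiment("pb", r = 0.010, n_reps = 10, tau = 0.99,
                                  seed = 1, fit_models = FALSE)
rep_tab
#> Lumping experiment [pb, r = 0.01, tau = 0.99]: 10 replicates
#>   median species = 300, median units = 264, median deficit = 13.1%
```

The median deficit sits in the 10–20% band, and (with `fit_models = TRUE`)
the decline statistics λ̂(0) − λ̂(150/100/50 Myr) it induces are far
smaller in magnitude than those of trees simulated with a genuinely
declining speciation rate — the basis for arguing that an observed strong
slowdown is not a pure delineation artefact.

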