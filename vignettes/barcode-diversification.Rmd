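---
title: "Diversification inference from short-marker molecular units: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversification inference from short-marker molecular units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodediv)
```

## The problem

For many microbial clades — arbuscular mycorrhizal fungi (Glomeromycotina)
are the motivating example — diversity is known almost entirely through a
short, slowly evolving barcode such as the ~520-bp variable region of the
SSU rRNA gene. Macroevolutionary questions (has speciation slowed down? do
environmental drivers such as global temperature modulate speciation? are
generalist lineages speciating faster?) must then be answered from
species-like units delineated on that marker, with two specific worries:

1. **Sampling completeness** — missing global diversity deflates recent
   branching and mimics a slowdown; and
2. **Lumping bias** — a slow marker cannot separate recently diverged
   species, so unit counts undershoot true species counts and recent nodes
   are censored, again mimicking a slowdown.

`barcodediv` implements the full analysis chain: unit delineation,
completeness estimation, time- and environment-dependent birth–death
fitting, trait correlates, and — centrally — a simulation workbench that
measures how large the lumping artefact actually is under the study
conditions.

## Unit delineation

Units ("evolutionary units", EUs) are delineated on a rooted haplotype tree
with a similarity matrix computed from the alignment
(`pairwise_similarity()`: p-distances over unambiguous bases with pairwise
deletion). `delineate_eus()` traverses the tree from the root toward the
tips; at each node it computes the mean pairwise dissimilarity over all
tip pairs descending from the node, and collapses the clade into one unit
when that mean is *strictly* below `1 - tau` ("lower than" the threshold;
exact ties therefore split). Each unit is monophyletic by construction.

Design choices worth noting:

* The per-node mean is computed over haplotypes *unweighted* by their
  sequence abundance; whether the original procedure weighted by abundance
  is not documented, and unweighted means match a haplotype-tree reading of
  "all sequences descending from the node". `partition_summary()` reports
  abundance via the haplotype membership map instead.
* The traversal is order-independent: the collapse decision at a node
  depends only on the tip set below it.
* Two useful invariants follow directly: partitions at a higher threshold
  refine partitions at a lower one, and unit counts are non-decreasing in
  the threshold. Both are property-tested, and the traversal is tested for
  exact agreement with a brute-force clade enumeration on hundreds of small
  random instances.
* Two memory-frugal routes exist for large haplotype sets, both
  property-tested for exact agreement with the full-matrix path:
  `pairwise_similarity(..., as_dist = TRUE)` keeps only the lower
  triangle, and `delineate_eus_aln()` skips pairwise storage entirely for
  gap-free alignments — the per-node mean dissimilarity is computed from
  per-column base counts accumulated post-order (the sum of mismatching
  pairs per column is $\binom{n_v}{2}-\sum_b \binom{c_b}{2}$), linear in
  alignment size. The simulation workbench uses the counting route, which
  is what makes the EU99-scale replicates (thousands of species, tens of
  thousands of sequences) tractable.
* In the simulation pipeline, delineation runs on the *true* simulated
  haplotype tree rather than a re-estimated one. The measured deficit is
  therefore attributable to marker slowness and lumping alone, not to
  tree-estimation error — a deliberate isolation of one error source.

## Sampling completeness

`rarefaction_curve()` rarefies *accessions* (sequence records, not
haplotypes), matching how occurrence databases are sampled; it uses nested
prefixes of random permutations, which makes every replicate curve — and
hence the reported median — monotone. `chao2_richness()` is the
incidence-based Chao2 estimator with the classic `(R-1)/R` correction and
the bias-corrected branch when no duplicates exist; it replaces a Bayesian
abundance-distribution estimator used in the original empirical tables
(whose machinery is out of scope here), and all outputs label the
estimator. `sampling_fraction()` reports observed/estimated richness to
the percent, the convention of completeness tables. Downstream robustness
sweeps re-fit the diversification models at assumed fractions of 90% down
to 50%.

## Birth–death models

All fits operate on ultrametric trees with ages in Myr before present
(present = 0). With speciation rate $\lambda(t)$, extinction rate $\mu(t)$
and sampling fraction $f$, the probability $E(t)$ that a lineage alive at
age $t$ leaves no sampled descendant solves

$$\frac{dE}{dt} = \mu(t) - (\lambda(t)+\mu(t))\,E + \lambda(t)\,E^2,
\qquad E(0) = 1-f,$$

integrated from the present into the past together with the cumulative
branch integrand $\Phi(t)=\int_0^t (\lambda+\mu-2\lambda E)\,du$
(adaptive solver, relative tolerance $10^{-8}$). The log-likelihood of the
reconstructed tree sums $\log\lambda(t_i)$ over branchings, $-\Delta\Phi$
over branches, $\log f$ per tip, and conditions on the survival of both
crown lineages via $-2\log(1-E(T))$. Parameter-free constants (topology
orderings) are omitted identically across all models, so AICc differences
are unaffected. With $f=1,\mu=0$ the machinery reduces exactly to the
closed-form Yule likelihood, which is the main numerical oracle in the
tests (agreement to $10^{-6}$).

Three speciation forms are provided: constant $\lambda_0$; exponential
$\lambda_0 e^{\alpha t}$ (ages grow into the past, so $\alpha>0$ means a
decline toward the present); and environmental $b\,e^{a\,env(t)}$, where a
positive $a$ means the environmental variable raises speciation.
Extinction is zero, constant, or pinned at a user-supplied value — the
robustness mode for "what if extinction were actually high?". Optimisation
is multi-start Nelder–Mead (Brent for one-parameter models) on
log-transformed positive parameters, 10 starts by default, convergence
tolerance $10^{-8}$ on the log-likelihood; non-convergence is flagged,
never silent. AICc uses $n$ = number of internal nodes (branching times),
reported in every fit, and a model is called "supported" only when all
rivals are at least 2 AICc units worse.

Environmental curves are tabulated series smoothed by a cubic spline with
33 degrees of freedom by default (the conventional smoothing for
Phanerozoic temperature series); evaluation outside the tabulated range is
linear extrapolation with a warning. A constant curve makes $(a,b)$
non-identifiable and is rejected.

`slice_tree()` cuts the tree at an age (400 and 200 Myr in the empirical
workflow, where younger environmental series begin) and returns the crown
clades below the slice. The stem piece between the slice age and each
clade's root is reported (`stem_length`) but excluded from fitting; only
subtrees with more than 50 tips are flagged as retained.

`decline_statistic()` is $\hat\lambda(0)-\hat\lambda(t_{ref})$ at
reference ages 150/100/50 Myr, negative when speciation declines toward
the present. In the original study this comparison used posterior mean
rates from a Bayesian lineage-heterogeneous model; here the statistic is
evaluated on the fitted parametric $\lambda(t)$ — a method substitution
that trades rate heterogeneity for a transparent two-parameter trend, and
is labelled as such wherever reports are produced.

## Correlates

`tajima_pi()` is the mean pairwise per-site difference over all member
sequences of a unit (pairwise deletion), computed on the full sample so
haplotype abundance weights the estimate, with the conventional minimum of
10 sequences per unit (15 and 20 as robustness). `niche_pca()`
standardises the ten niche-width variables and fixes signs so PC1
correlates positively with the number of occupied continents (PC1 =
generalism). `rate_correlation()` offers ordinary least squares,
phylogenetic GLS under Brownian covariance (which equals OLS exactly on a
star tree — an identity used as a test), and a latitude jackknife that
resamples 1,000 records per 20° band to correct uneven latitudinal
sampling. The original study used Bayesian phylogenetic mixed models for
the phylogenetic control; PGLS substitutes for them here and output
metadata says so. Speciation rates are positive and right-skewed, so the
analysis scripts log them before regression (`log_response = TRUE`); the
function default is `FALSE` because valid responses such as $\theta_\pi$
can be zero.

## The simulation workbench

`run_lumping_experiment()` chains the generators and the delineation:

1. `simulate_species_tree()` — a crown-conditioned birth–death tree with
   crown age exactly 505 Myr. Both crown lineages are conditioned on
   survival (matching the likelihood conditioning), with a retry cap of
   1,000 attempts per lineage. Two scenarios: pure birth, and birth–death
   at a given turnover. The net rates 0.010 and 0.015 events/lineage/Myr
   reproduce extant richness of the order of the empirical unit counts
   (pure birth expects $2e^{rT}\approx 312$ species at $r=0.010$).
   The turnover of the birth–death scenario is not documented in the
   original design; the default here is 0.5, configurable and echoed in
   every report.
2. `graft_intraspecific()` — each species tip is replaced by a coalescent
   subtree of 2–15 individuals. The subtree root age is uniform on
   $[0, \min(\text{pendant branch}, 30\,\text{Myr})]$: individuals must
   coalesce after the species' last speciation event, read as the pendant
   branch's origin (the last event involving that tip), and the min() rule
   is applied literally even for very short pendants. Topologies and
   relative times come from the standard exchangeable coalescent rescaled
   to the drawn root age — only the age constraint is specified by the
   study design, not the within-species process, so the neutral coalescent
   is the natural default.
3. `simulate_alignment()` — 520 bp with exactly 130 variable columns
   (25%), evolving Jukes–Cantor at 0.001 substitutions/site/Myr, uniform
   base frequencies, no rate heterogeneity and no indels. The original
   simulator's substitution model is not printed; Jukes–Cantor on a
   variable fraction is the minimal model consistent with "25% variable
   sites", and the Monte-Carlo tests verify the implied JC divergence
   expectation.
4. `collapse_haplotypes()` + `delineate_eus()` at $\tau = 0.99$ on the
   true grafted tree pruned to haplotype representatives, then the unit
   deficit $100(1-\text{units}/\text{species})$; optionally constant and
   exponential fits on the unit tree (complete sampling at unit level) and
   decline statistics from the AICc-best model.

Per-replicate seeds derive from the master seed, so reports are
bit-reproducible. Stage failures are caught per replicate and recorded
without aborting the run.

Under these defaults the experiment reproduces the headline result: the
99%-threshold delineation under-counts species by roughly 10–20% (median
around 13% across seeds in our runs), and the induced artefactual decline
statistics are much closer to zero than those measured on trees generated
with a genuinely declining $\lambda(t)$ — the logic by which the empirical
slowdown is argued not to be a pure delineation artefact.

### What the generator does and does not emulate

It emulates: the joint depth scales of inter- and intra-specific
divergence, the marker's information content (130 variable sites, slow
clock), haplotype sharing across species, uneven individuals-per-species,
and richness of the right order. It does not emulate: tree-estimation
error (delineation sees the true tree), rate heterogeneity across sites or
lineages, indels/ambiguities, chimeras, geographic sampling structure, or
abundance-biased sequencing. Passing tests therefore bound the lumping
artefact under idealised data; on real data the artefact combines with
reconstruction error, which this package deliberately does not model.

## Numerical choices and degenerate inputs

* Ultrametricity is checked to $10^{-6}$ relative tolerance; node ages are
  snapped to the nanoMyr to keep near-duplicate float ages from producing
  pathological ODE output grids. Generated trees satisfy ultrametricity to
  $10^{-8}$ Myr.
* Rate functions are screened before integration (finite, positive,
  below 1000 events/Myr over the tree span); violations yield
  $-\infty$ log-likelihood rather than solver failures. $E(t)$ leaving
  $[0,1]$ beyond $10^{-6}$ aborts with diagnostics.
* Similarity pairs with zero comparable sites get similarity 0 with a
  warning; a zero-length pendant branch yields a degenerate age-0
  coalescent with a warning; constant niche variables are dropped from the
  PCA with a warning.
* Ties: exact equality of mean dissimilarity with $1-\tau$ splits (strict
  inequality); representative ties go to the lexicographically smallest
  name.
* Problem sizes in the test-suite property checks are scaled to what the
  statistical claim needs: 100 random instances for the delineation
  oracle, 50 trees for each parameter-recovery check (crown ages 120–505
  Myr chosen so trees carry tens to hundreds of tips), 10 full-scale
  replicates for the lumping experiment.

## Known limitations

* The decline statistic uses the parametric $\lambda(t)$, not a
  lineage-heterogeneous posterior mean; strong among-lineage rate
  variation is thus summarised, not modelled.
* Chao2 is an incidence-based lower-bound estimator; it replaces (and will
  generally be more conservative than) parametric abundance-model
  richness estimates.
* The environment-dependent model inherits the usual caveat that any
  monotone long-term trend correlates with any other; support over the
  time-exponential model, not over "no trend", is the meaningful contrast.
* PGLS assumes Brownian covariance and a single rate; the Bayesian mixed
  models it replaces also handled within-unit replication of occurrence
  records.
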