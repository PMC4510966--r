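---
title: "Modelling the evolution of hand proportions with multi-regime OU processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of hand proportions with multi-regime OU processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handevo)
```

## The question and the data

Comparative claims about hand evolution — for instance, that the long human
thumb is largely an ancestral retention while chimpanzee and orangutan digital
elongation is convergent — are claims about which *model of trait evolution*
best explains measurements at the tips of a phylogeny. `handevo` implements
the chain of analyses such a claim rests on, from specimen tables to fitted
evolutionary hypotheses.

The measurement unit is a specimen with six hand-bone lengths (thumb
metacarpal MC1, proximal phalanx PP1, distal phalanx DP1; fourth-ray
metacarpal MC4, proximal phalanx PP4, intermediate phalanx IP4, all mm),
optionally a body mass (kg) and a femoral head diameter (mm). Two shape
summaries are computed per specimen:

* **IHP** (intrinsic hand proportions): (MC1+PP1+DP1)/(MC4+PP4+IP4), a
  dimensionless thumb-to-digit ratio and a functional proxy for thumb
  opposability. The fourth distal phalanx is excluded because it is rarely
  preserved in associated fossil hands.
* **EHP** (extrinsic hand proportions): each length divided by BM^(1/3)
  (mm·kg^(-1/3)). The cube root of mass is the standard linear proxy for body
  size, so these are size-standardized shape ratios. Ratios are used instead
  of regression residuals because residuals are sample-dependent, a ratio is a
  property of the individual.

Both are computed **per specimen and then averaged within taxa** (mean of
ratios, not ratio of means); the ordering matters and is asserted by the test
suite. Body masses missing from the records can be filled from femoral head
diameter via per-taxon log10–log10 least-squares regressions — the allometric
convention, which also guarantees positive predictions. Two reference
regressions (e.g. a quadrupedal and a bipedal training sample for a fossil of
contested locomotion) can be averaged.

Species-mean EHP vectors are summarized by PCA **on the covariance matrix**
(not the correlation matrix: the traits share units, and their unequal
variances are signal). Eigenvector signs are fixed by making each axis's
largest-magnitude loading positive, so results are deterministic across
linear-algebra backends.

## Evolutionary models

### Brownian motion

The baseline model: a trait changes along each branch with mean zero and
variance σ²·t. Tip values are then jointly normal with covariance σ²·C, where
C holds shared root-to-MRCA path lengths. `fit_bm()` estimates the root state
as the GLS phylogenetic mean and σ² by maximum likelihood; the likelihood is
evaluated by the pruning (contrasts) algorithm in O(n), never by inverting C —
the dense-matrix route is reserved for the independent oracles in the tests.

### The multi-regime Ornstein–Uhlenbeck (Hansen) model

Adaptive hypotheses are expressed as a **regime painting**: an assignment of
every branch to a selective regime r with its own optimum θ_r. Within a
branch the trait follows

dX = α(θ_r − X)dt + σ dB,

where α is the pull toward the optimum (per Myr; ln 2/α is the phylogenetic
half-life) and σ² the stochastic rate. The expected tip values are W·θ, with
W the matrix of exponentially discounted times each root-to-tip path spent in
each regime; the tip covariance has the standard closed form, valid for
non-ultrametric trees (fossil tips at positive age are ordinary tips
throughout the package). The root state is fixed at the root regime's optimum
— the usual Hansen convention, which removes the one parameter that is
unidentifiable on ultrametric trees.

`fit_hansen()` reduces the fit to a 1-D search over log α on
[1e-8/height, 1e3/height]: at each α, θ is the GLS estimate and σ² is
profiled analytically from the residual quadratic form. Ties resolve toward
smaller α, and a fit stuck at the lower bound is flagged `bm_like`. Below
α = 1e-8/height the covariance switches to a second-order series to avoid
0/0, making the model numerically continuous with Brownian motion (the test
suite checks |ΔlogL| < 1e-4 at the seam). Parameter count is 2 + #regimes
per trait.

### Multivariate fits and hypothesis comparison

Traits (in practice, the two leading PC axes of species-mean EHP) are treated
as independent given the painting: the joint log-likelihood is the sum of
per-trait fits sharing one painting, each trait with its own α, σ², θ. Joint
AICc uses total logL, total parameter count and n = tips × traits — a single
consistent convention; only AICc *differences* within a comparison matter, and
those are convention-stable. `compare_models()` reports ΔAICc and Akaike
weights exp(−Δ/2)/Σexp(−Δ/2). Absolute AICc values are not comparable across
packages with different parameter-count conventions.

## Detecting regimes without naming them

`surface_search()` implements the stepwise search. The **forward phase**
starts from a single-peak OU model and repeatedly evaluates placing one new
shift on every branch (a shift relabels the branch and its descendants until
overridden — "sticky" inheritance); the best candidate is accepted while it
improves joint AICc by more than `min_improvement`. The **backward phase**
then evaluates merging every pair of non-root regimes into one shared label
and accepts improving merges; a retained merged label spanning disjoint clades
is the signature of convergent evolution. The search is deterministic: ties go
to the branch with the older parent node, then to the lexicographically
smallest subtended tip set, under a 1e-7 AICc tie window (a shift on a
root-child branch and one on its complement induce the same tip partition and
match in AICc only to float noise).

Design notes, decided here:

* `min_improvement` defaults to 0 (any improvement accepted). This is the
  permissive convention that lets moderate true shifts — the 3–18 AICc-unit
  improvements typical of realistic clade contrasts — be found, and it is
  what the convergence-detection use case needs. The cost is a known one:
  with ~2n candidate branches per step, the best spurious candidate on pure
  null data captures roughly the largest of ~n squared whitened residuals
  (≈ 6–9 units), which exceeds the ≈ 2.3-unit AICc penalty for one extra
  optimum. **Stepwise forward search therefore overfits null data**, and the
  backward phase does not remove the excess, since regimes never merge back
  into the root regime. Users wanting family-wise control should raise
  `min_improvement` toward 2·log(#branches); the suite documents the
  operating characteristics at the default.
* The root carries no shift (the root regime is the baseline); every branch,
  including terminal branches to fossils, is otherwise eligible.
* α and σ² are re-optimized for every candidate painting — correctness over
  speed at the package's design scale (≤ ~50 tips, ≤ ~60 branches, ≤ 3
  traits; a full search on the packaged 20-taxon dataset takes seconds).

## Ancestral states and the phylomorphospace

Under Brownian motion the ML estimates of internal states solve the
branch-length-weighted harmonic system (each node the 1/branch-length-weighted
average of its neighbours) — identical to squared-change parsimony weighted by
branch length. `ml_ancestral_states()` solves that linear system; variances
are the conditional variances of internal states given the tips, scaled by
the ML σ̂², and 95% CIs are estimate ± 1.96·√variance. Because the
reconstruction is linear in the data, reconstructing PC scores directly
equals reconstructing traits and projecting afterwards;
`build_phylomorphospace()` therefore works on the score matrix, placing tips
at their scores and internal nodes at reconstructions, with the tree's edges
connecting them. The chimpanzee–human LCA (or any tip pair's MRCA) is
retrievable with its CIs. Plugging σ̂² into the variances ignores the
uncertainty of σ² itself; at the package's design scale (dozens of tips) the
effect is a ~1–2% understatement of CI width, and simulation puts root-CI
coverage within the nominal band (93–97% over 1000 Brownian replicates in the
suite).

## Phylogenetic signal

Blomberg's K compares the mean squared tip deviation from the phylogenetic
mean (MSE0) with the GLS mean squared error through the tree (MSE), and
divides the observed MSE0/MSE by its Brownian expectation
(tr C − n/Σ(C⁻¹))/(n−1). K ≈ 1 is Brownian-like; K < 1 concentrates variance
within clades (homoplasy-like); K > 1 among clades. On an equal-branch star
tree K is identically 1 — there is no tree structure to deviate from.

The permutation test shuffles tip values and reports
p = (1 + #{K_perm ≥ K_obs})/(1 + n_perm): shuffled data carry no signal and
give small K, so a small p means signal is *present*, whichever side of 1 the
observed K falls on — a K of 0.5 can still be wildly non-random. The add-one
estimator never returns 0 (minimum 1/1001 at the default 1000 permutations),
and the direction of departure from 1 is recorded separately for
interpretation. The package applies K to species-mean PC scores and notes
that choice in its output metadata.

## The synthetic study generator

Real specimen measurements of this kind live in museum records; the generator
produces datasets with the statistical structure the methods assume, so the
whole pipeline can be exercised and validated end to end:

* **Tree**: a fixed 16-taxon anthropoid chronogram (hominoid species, monkey
  genera, hylobatids pooled), node ages rounded from literature-standard
  divergence dates and documented as fixture constants in the tree file
  header. Four fossil tips (4.4, 2, 18 and 9.6 Myr) are grafted with 1-Myr
  ghost lineages; the 9.6-Myr great ape defaults to the orangutan stem, with
  `make_hispanopithecus_trees()` providing the stem-great-ape and
  stem-hominine alternatives (the stem-great-ape variant attaches 1 Myr above
  the crown great-ape node, since that stem is everywhere older than
  10.6 Myr).
* **Taxon means**: the six log shape ratios evolve under a painted
  five-regime OU model (background; convergent Cebus+Alouatta;
  Papio+Theropithecus; hylobatids; convergent Pan+Pongo) with α = 0.1/Myr
  (half-life ≈ 7 Myr) and σ² = 0.001 — a stationary SD of ≈ 0.07 on log
  ratios, against regime contrasts of 0.15–0.5, i.e. ≈ 2–7 stationary SDs.
* **Specimens**: per-taxon counts match the study design being emulated
  (Homo 40, Pan troglodytes 34, Papio 50, ..., fossils n = 1); body masses
  are lognormal around taxon means (CV 0.15); element lengths are
  exp(taxon log ratio + N(0, 0.05²))·BM^(1/3), so within-taxon scatter is
  multiplicative, lengths are always positive, and recomputing EHP cancels
  the individual mass draw exactly. Femoral head diameters consistent with a
  slope-2.5 log-log allometry are attached so the mass-estimation path can be
  exercised.
* Simulation is in log space and exponentiated; all generators are
  bit-reproducible given their seed.

What passing tests on these data do **not** show: robustness to real
missing-data patterns (the optional mask is uniform-at-random), to
measurement covariance between elements, to sexual dimorphism, or to
phylogenetic uncertainty — the tree is treated as known.

## Numerical choices and degenerate inputs

* Zero-length branches are rejected at parse time (OU weights divide by path
  segments); polytomies are rejected by the Newick reader but supported by
  the in-memory machinery, so star-tree analyses work.
* A constant trait yields a flagged degenerate BM fit (σ̂² = 0) and an error
  from K (the statistic is undefined).
* AICc requires n > p + 1; fits on smaller samples report their estimates
  with an `NA` score rather than failing.
* Candidate paintings whose likelihood is non-finite are skipped and logged
  during the search, never silently accepted; unreachable regimes (a label
  with no weight on any tip path) are reported by name.
* Problem sizes used by the validation suite: 8–10-tip trees for oracle
  equivalence, 64 tips for search operating characteristics, K calibration
  and CI coverage, 128 tips for OU parameter recovery (200 replicates), and
  the 20-taxon packaged dataset for end-to-end runs.

## Known limitations

* Traits are independent given the painting (diagonal trait covariance); a
  full multivariate OU with trait correlations is out of scope.
* No measurement-error variance at the tips, and no multiple-rate (σ² shift)
  Brownian variants.
* The forward search's null behaviour at the default threshold is permissive
  by design (see above); simulation-based null distributions for shift counts
  are not implemented.
* OU-based ancestral reconstruction is not provided — phylomorphospace
  internals are Brownian ML estimates, as is conventional.
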