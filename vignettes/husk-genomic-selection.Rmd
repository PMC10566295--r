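---
title: "Genomic selection for husk tightness: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for husk tightness: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Husk tightness (HTI) controls how fast maize ears lose moisture at
maturity, and so the feasibility of mechanical grain harvesting in
temperate production zones. HTI is a polygenic trait of moderate
heritability, which makes marker-assisted selection ineffective and
genomic selection (GS) the method of choice: a prediction model trained
on a genotyped, phenotyped panel assigns genomic estimated breeding
values (GEBVs) to selection candidates from their markers alone.

Whether GS pays off depends on design factors the breeder controls:
the statistical model, the marker density (and so the genotyping cost),
the relative sizes of training and testing populations, and how the
training set is placed relative to the panel's subgroup structure
(stiff-stalk, non-stiff-stalk, tropical–subtropical and admixed
germplasm). This package implements the full evaluation loop for these
factors: trait statistics, multi-environment BLUP, marker QC and LD
pruning, six whole-genome regression models, Monte-Carlo
cross-validation schemes, and a synthetic panel generator so the whole
pipeline is testable without access to any particular data set.

## Trait statistics

Husk tightness is measured from the loose and tightened husk
perimeters (cm):

$$\mathrm{HTI} = \frac{\text{loose} - \text{tight}}{\text{loose}}
  \times 100\%$$

so larger values mean a looser husk. `compute_hti()` checks the
physical constraint tight ≤ loose and averages measurement repeats.

Kernel dry-down is summarised by the area under the dry-down curve
(AUDDC): the trapezoidal integral of moisture-meter readings
$\gamma_i$ over measurement days $t_i$ (by default 34, 40, 46, 52 and
58 days after pollination):

$$\mathrm{AUDDC} = \sum_{i=1}^{n-1}
  \frac{\gamma_i + \gamma_{i+1}}{2}\,(t_{i+1} - t_i).$$

A lower AUDDC means faster dry-down. `compute_auddc()` is linear in
the readings and additive over sub-intervals — both properties are
exercised by the test suite.

## Multi-environment BLUP and heritability

Phenotypes from a multi-environment trial follow

$$y_{ijk} = \mu + e_i + r(e)_{ij} + f_k + (f \times e)_{ik} +
  \epsilon_{ijk}$$

with environments $e_i$ and replicates-within-environment $r(e)_{ij}$
treated as fixed, and line $f_k$, line-by-environment and residual as
random. `fit_environment_blup()` fits this by REML (through `lme4`)
and reports per-line BLUPs as the overall mean plus the predicted line
effect, so predictions shrink toward the mean as the genotypic signal
weakens. The fixed/random split mirrors the heritability denominator:
only $\sigma^2_g$, $\sigma^2_{ge}$ and $\sigma^2_e$ appear in

$$h^2 = \frac{\sigma^2_g}
  {\sigma^2_g + \sigma^2_{ge}/e + \sigma^2_e/(re)}$$

for $e$ environments and $r$ replicates (`estimate_heritability()`).
REML already truncates negative variance estimates at zero. Two
degenerate designs are handled explicitly: a single environment drops
the GxE term with a warning, and a single observation per line (where
line and residual variance are not separable) returns the observations
themselves as BLUPs with a warning — the zero-residual limit.

## The six prediction models

All models regress the phenotype (usually the multi-environment BLUP)
on all markers at once, differing only in the prior on marker effects.
Dosages are coded 0/1/2 (count of the alternate allele, the VCF
convention) and centred by their training means; effects are
per-allele, with no variance standardisation. Fixed effects are
restricted to an intercept.

**rrBLUP** (`fit_rrblup()`) assumes one normal prior variance shared by
all markers. The variance ratio $\lambda = \sigma^2_e/\sigma^2_u$ is
estimated by REML: the restricted likelihood is profiled through the
spectral decomposition of the marker cross-product projected off the
intercept, and maximised over $\log\lambda \in [-10, 10]$ by bounded
scalar optimisation (tolerance 1e-8). Effects are the ridge solution
$\hat u = Z'(ZZ' + \hat\lambda I)^{-1}(y - \hat\mu)$. The test suite
verifies the closed form at fixed $\lambda$, that the optimum beats a
50-point grid, and that GEBVs agree (r ≥ 0.999) with an independent
gBLUP oracle that solves the kinship mixed-model equations with
determinant-based REML — the two formulations are equivalent.

**BayesA / BayesB / BayesC / Bayesian LASSO (BL) / Bayesian ridge
(BRR)** (`fit_bayes()`) are fitted by single-site Gibbs sampling
(compiled code, but all randomness through R's RNG so chains are
reproducible from `set.seed()`). Priors: BayesA — scaled-inverse-χ²
variance per marker (marginal scaled-t effects); BayesB — point mass at
zero with probability π plus the BayesA slab; BayesC — point mass plus
a common-variance normal slab; BL — double-exponential through its
exponential scale mixture with a Gamma hyperprior on the squared
regularisation parameter; BRR — common-variance normal.

Hyperpriors are weakly informative: 5 degrees of freedom and scales
set from the phenotypic variance, splitting it equally between markers
and residual a priori (`R2 = 0.5`); π gets a Beta(1, 1) prior and is
estimated unless fixed. Default chain: 5000 iterations, 1000 burn-in,
thinning 5 (tests and sweeps use shorter chains of 1500–3000
iterations, which the equivalence checks show is sufficient at these
panel sizes). A split-chain scale-reduction diagnostic on the residual
variance warns above 1.2. Prior-collapse identities anchor the
samplers: BRR tracks rrBLUP (GEBV r ≥ 0.98) and BayesC with π = 0
reduces to BRR (r ≥ 0.99).

## Marker QC and LD pruning

`filter_markers()` retains markers with MAF ≥ 0.05 and missing rate
≤ 0.2 (inclusive thresholds; MAF from non-missing calls only), with
removal reasons attributed MAF-first so report counts are disjoint.
The QC convention for a processed panel is filter → impute → filter:
simple marker-mean or marker-mode imputation stands in for
haplotype-based methods, and the refilter removes markers whose MAF
was shifted across the boundary by imputation. `prune_by_ld()`
implements greedy indep-pairwise-style pruning — windows of 50
markers advancing by 5, removing the member of an offending pair with
the higher mean r² to the rest of the window (ties to the later
position) — per chromosome. The window/step defaults are the common
pruning convention; exact kept counts therefore depend on them and are
not expected to reproduce any particular external tool bit-for-bit. A
threshold of 1.0 keeps everything (full density), and kept-set size is
non-decreasing in the threshold; the windowed result equals an
exhaustive no-window greedy oracle on small instances.

## Cross-validation design

`run_cv()` implements repeated random splits (Monte-Carlo CV): each
repeat draws a testing set of size round(test_fraction × n), fits on
the complement and scores prediction ability as the Pearson
correlation between GEBV and the observed value (or the true breeding
value, in simulation, via the `truth` argument). This matches the
described procedure of random resampling repeated 100 times, rather
than literal k-fold partitioning. Rounding is half-away-from-zero.
Per-repeat seeds are derived by mixing the scheme seed with the cell
identifier and repeat index, so a factorial sweep (`factorial_run()`)
is reproducible and independent of execution order; sampling is done
on the id-sorted frame, so results are invariant to input line order.
`run_subgroup_cv()` places the training set inside one focal subgroup
and tests either the subgroup remainder (within) or the remainder plus
all other subgroups (across). Group comparisons use Duncan's multiple
range test (`duncan_grouping()`) for fidelity to common agronomy
practice, with pairwise Welch tests reported alongside as a robustness
check — Duncan's protection levels imply an inflated family-wise error
(about 0.19 for the full range of five means at α = 0.05), which is a
known property of the procedure, not a defect of the implementation.

## The synthetic panel generator

`simulate_structured_genotypes()` emulates the statistical features
the evaluation depends on, not any real genome:

* **Structure.** Default subgroup sizes 121 NSS, 30 SS, 186 TST and
  101 MIXED (438 lines). Pure subgroups draw block-level allele
  frequencies from a Balding–Nichols model around ancestral
  frequencies uniform on [0.05, 0.95]; the default divergence
  `fst = 0.1` is a moderate value typical of maize germplasm groups.
  MIXED lines each draw a random convex mixture of the three pure
  frequency vectors (a highly diverse, admixed structure).
* **Linkage disequilibrium.** Markers come in blocks (default 5
  markers) sharing one frequency. Haplotypes copy a block-level latent
  uniform with probability `within_block_r2^(1/4)` — two markers both
  copy with the square of that, giving within-block allele r² equal to
  the target in expectation and exactly 1 at a target of 1. Block
  latents follow a Markov copy chain along each chromosome, so
  inter-block LD decays geometrically; the chain's copy probability is
  calibrated with a frequency-mismatch attenuation factor (~0.55 for
  Balding–Nichols draws) to hit `between_block_r2` (default 0.04)
  between adjacent blocks. The latent-uniform construction keeps
  marginal frequencies exact, so realized Fst matches the divergence
  target (verified by a Hudson-type estimator over 20 seeds).
* **Inbreeding.** With probability 0.95 a line's second haplotype is a
  copy of its first; heterozygotes remain possible, as the models must
  tolerate them.
* **Trait.** `simulate_trait()` standardises genetic values to unit
  variance and scales GxE (default 0.3 of genetic variance, a moderate
  level appropriate for an environment-sensitive trait; lacking a
  mechanistic model, GxE is independent Gaussian noise per line ×
  environment) and residual variance so the expected broad-sense
  heritability equals the target (default 0.41 over 3 environments × 2
  replicates). True breeding values are recorded before noise;
  `h2_target = 0` omits the genetic term entirely. Oligogenic
  architectures draw few large effects (default 10, at most 20);
  polygenic ones give half the markers small Gaussian effects.
* **Dry-down.** `simulate_moisture_series()` builds declining reading
  curves whose AUDDC correlates with supplied HTI values at a
  per-subgroup target (e.g. −0.5 in temperate subgroups, 0 in TST),
  by mixing a standardised HTI score into the curve's latent starting
  level; measurement noise (sd 0.3) is small against the level spread,
  so the target correlation is realized up to sampling error.

What the generator does **not** emulate: recombination maps and
realistic LD decay shapes, allele-frequency spectra from real
ascertainment, selection, pedigree relatedness, or genotyping error.
Passing tests therefore demonstrate the correctness and calibration of
the machinery on data with the assumed covariance structure, not
performance on any real panel.

## Problem sizes used by the tests and the acceptance script

Checks are run at desk scale, chosen so every stochastic bound sits
well inside its sampling error: heritability recovery uses 30 panels
of 438 lines (3 × 2 design); the rrBLUP/gBLUP equivalence a 300-line ×
1000-marker panel; the Bayesian equivalences 240 lines × 500 markers
with 3000-iteration chains; the training-fraction trend 200 lines ×
600 markers with 50 repeats at each of nine fractions; the
marker-density contrast 200 lines × 3000 markers (dense enough that
the r² = 0.1 pruned set retains the kinship information, the regime a
genotyping chip operates in); the architecture comparison 200 lines ×
300 markers with 30 repeats per model. The null-calibration check
spreads its 50 CV repeats over 5 independent null panels, because
repeats sharing one simulated phenotype share its sampling error — a
single-panel mean ability does not converge to zero with more repeats.
The acceptance script (`scripts/acceptance.R`) re-runs the pipeline at
the 438-line panel scale with 2000 markers and 100-repeat
cross-validation.

## Known limitations

* The REML engine for the trial model is `lme4`; heavily unbalanced
  designs are supported but the heritability denominator uses the mean
  replicate count per environment.
* Duncan's test is provided for fidelity to agronomy reporting
  conventions; its family-wise error under the null exceeds α by
  construction. Use the bundled Welch p-values when conservatism
  matters.
* Gibbs chains at the default lengths are adequate for GEBV ranking;
  posterior variance components for BayesB/C mixtures mix more slowly
  and may need longer chains.
* The dosage model is additive; dominance and epistasis are out of
  scope, as are phased haplotypes, indels and multiallelic sites.
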