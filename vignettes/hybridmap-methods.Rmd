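---
title: "Mapping gut-microbiome traits in a hybrid mouse intercross: models and methods"
author: "hybridmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gut-microbiome traits in a hybrid mouse intercross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hybridmap` implements, as a tested and reusable pipeline, the statistical
machinery needed to map host genetic control of gut microbial abundances in
a multi-line hybrid mouse intercross: heritability estimation with
relatedness and maternal structure, a per-SNP mixed-model association scan
with explicit additive and dominance terms, genomic control, effective-test
multiple-testing thresholds, dominance-architecture classification,
percent-variance-explained, LD-defined significant regions, and
permutation-based overlap and gene-set enrichment tests.  Because the
original animal cohort cannot be redistributed, the package ships a
first-class forward simulator that reproduces the statistical structure the
analysis assumes, with a truth record for parameter-recovery testing.

# The intercross simulator

## Design

The emulated design is a two-subspecies hybrid-zone intercross: eight
partially inbred founder lines (two per breeding stock, four predominantly
*Mus musculus domesticus*, four predominantly *M. m. musculus*), eight G1
line crosses in which every line appears once as dam and once as sire, and
eight G2 sub-crosses of 40 males each (320 individuals), arranged so each
G2 individual has one grandparent from each of the four stocks.  Each
sub-cross draws offspring from five distinct G1 mating pairs, so the
pedigree carries a mating-pair label nested within sub-cross — the grouping
structure the heritability model needs.

Key generator defaults and why:

* `inbreeding = 0.9` — the founder lines emulated were inbred past 82%;
  0.9 is a round value in that regime.
* `diagnosticFraction = 0.14` — the fraction of markers fixed between
  subspecies on the genotyping array used for this cross type (8775 fixed
  differences among 64103 quality-filtered SNPs is ~0.14).
* `subspeciesWeights = rep(c(0.2, 0.8), each = 4)` — hybrid-zone-derived
  lines are predominantly but not purely one subspecies; 0.2/0.8 places
  the two sides symmetrically about the 50% hybrid-index boundary used to
  classify them.
* 1 cM = 1 Mb when no genetic map is supplied — the standard rough mouse
  scaling; the genetic map is an explicit input because the original study
  does not state one.

Meiosis follows Haldane's model: crossover counts are Poisson with mean
equal to the chromosome's genetic length in Morgans, positions uniform on
the genetic map, no interference.  The X chromosome is not simulated: the
mapping cohort is male (hemizygous) and the emulated study found no X
associations, so a dosage-compensation model would be unconstrained
guesswork.

## Trait generation

For each taxon the generator builds a latent Gaussian trait

\[ \ell = \mu + \sum_{c} (a_c X^a_c + d_c X^d_c) + u_{pair} + u_{subcross}
   + u_{poly} + e, \]

with \(u_{pair}\sim N(0,\sigma^2_m)\), \(u_{subcross}\sim N(0,\sigma^2_s)\),
\(u_{poly}\sim MVN(0,\sigma^2_g K)\) for a supplied GRM \(K\), and
\(e\sim N(0,\sigma^2_e)\).  \(X^a\) is \(\pm1/0\) dosage coding (so
homozygote latent means differ by \(2a\), the heterozygote sits at the
midpoint plus \(d\)).  Latent vectors are pushed through a per-sample
softmax to a composition and counts drawn multinomially at the sequencing
depth.  This reproduces relative-abundance structure without modelling
absolute bacterial load — deliberately, since compositionality is a stated
limitation of this family of studies, not something the analysis resolves.

The truth record defines heritability on the latent scale,
\(h^2 = \sigma^2_g / (\sigma^2_g+\sigma^2_m+\sigma^2_s+\sigma^2_e)\).
Recovery tests therefore run on the latent traits: the softmax/multinomial
observation layer attenuates variance components on the count scale, which
is a property of compositional measurement, not of the estimator.  Passing
recovery tests consequently show the estimator is unbiased for the latent
model; they do not bound the attenuation real count data would add.

# Genotype QC and ancestry

QC follows the conventional order — individuals (call rate ≥ 0.90) before
markers (biallelic, missingness ≤ 0.10, MAF ≥ 0.05, Hardy–Weinberg exact
p ≥ 1e-10).  The HWE test is the exact conditional enumeration with the
standard (not mid-) p-value.  After filtering, dosages are re-oriented to
count the within-cohort minor allele.

LD pruning uses a window of 5 SNPs, step 1, r² > 0.9, with r² the squared
Pearson correlation of dosages over pairwise-complete individuals.  The
published description fixes window/step/threshold but not the tie rules, so
the package makes them explicit and deterministic: the lower-MAF member of
the worst pair is dropped (tie: the later position), windows slide over
*retained* markers, and passes repeat until a fixed point, which guarantees
the advertised invariant that no surviving within-window pair exceeds the
threshold (a single pass does not: a removal can shift a distant marker
into an already-visited window).

Ancestry-informative markers require ≥ 10 calls per subspecies panel, a
major-allele difference, and an allele-frequency difference > 0.3; the
hybrid index of an individual is the fraction of its non-missing AIM allele
copies that are *musculus*.

# Relatedness

Both GRM flavours follow the estimator on dosage columns \(x_i\):
centred \(K = \frac1p \sum_i (x_i-\bar x_i 1)(x_i-\bar x_i 1)^T\), and
standardised with each term divided by the marker variance.  The variance
uses the biased (1/n) convention; the formula's denominator is not further
specified at the source, and 1/n makes trace(K) = n an exact algebraic
identity, which the tests assert.  Zero-variance markers are excluded from
the standardised sum with p adjusted; missing dosages are mean-imputed
before centring.  Leave-one-chromosome-out matrices simply drop the focal
chromosome's markers.

# The REML engine

All variance-component models reduce to
\(V = \sum_k \sigma^2_k K_k + \sigma^2_e I\) with kernels (GRMs) and
grouping factors (expanded to \(ZZ^T\)).  The restricted likelihood is
evaluated by dense Cholesky factorisation; the components are optimised on
the log scale (hence never negative) by L-BFGS-B with the analytic gradient
\(-\tfrac12[\mathrm{tr}(PK_k) - y^TPK_kPy]\), from three fixed starts
(equal split, residual-dominant, genetic-dominant), keeping the best.
Models with exactly one kernel and no grouping terms use an exact spectral
path: after eigen-rotation the profile restricted likelihood is a
one-dimensional function of the variance ratio, scanned on a coarse grid
and polished with Brent search.  Components whose estimate collapses below
1e-8 of the trait variance are reported as 0 with a boundary flag.

Fixed-effect tests use ordinary ML fits (restricted likelihoods are not
comparable across fixed designs); variance-component tests use a
simulation-based restricted likelihood ratio test: the null model is
fitted, `nSim` traits are simulated from it, both models are refitted to
each, and \(p = (1+\#\{\text{sim} \ge \text{obs}\})/(n_{sim}+1)\).  The
target null distribution is the same one the spectral "exact" RLRT
algorithms sample; the parametric bootstrap was chosen because it is easy
to verify and extends unchanged to nuisance random terms.  In the
single-kernel case the bootstrap evaluates the profile likelihood on a
fixed 92-point variance-ratio grid for the observed and simulated traits
alike, so any grid bias cancels from the comparison.

# Heritability

Narrow-sense heritability fits random effects {centred GRM, mating pair
nested within sub-cross, sub-cross, residual} and reports
\(h^2=\sigma^2_g/(\sigma^2_g+\sigma^2_m+\sigma^2_s+\sigma^2_e)\); chip
heritability is the same model with the standardised GRM.  A genetic
component pinned at zero reports \(h^2=0\) with RLRT p = 1.  The
cospeciation comparison matches genera on exact name strings (the original
cross-study matching rule is unstated), computes a Spearman correlation,
and fits an ordinary least-squares regression of \(h^2\) on cospeciation
rate and median relative abundance to show the correlation is not an
abundance artefact.

# Association scan

Per marker the full model is \(y = \mu + aX_a + dX_d + u_{pair} +
u_{kinship} + e\) with the LOCO centred GRM for the marker's chromosome,
against the null \(y=\mu+u_{pair}+u_{kinship}+e\); \(X_a \in \{1,0,-1\}\)
for major-homozygote/het/minor-homozygote and \(X_d \in \{0,1\}\).  The
total p is the 2-df likelihood ratio; per-term additive and dominance p
values are 1-df drop-one LRTs (the original report does not say whether
Wald or LRT was used per term; LRT keeps one consistent framework).
Markers missing a genotype class fall back to a 1-df additive test with
the dominance estimate NA.

Two modes are offered.  `exact` refits the variance components by ML for
every marker and sub-model.  `approximate` (default) fits the null once
per chromosome, freezes its covariance, whitens, and reduces every marker
to nested least squares — the standard EMMAX/GRAMMAR-style approximation.
The two agree closely at moderate signal (tested: within one order of
magnitude around p ≈ 1e-4); at extreme signal the approximation is
conservative because the null fit absorbs QTL variance.

Genomic control converts the total p values to 1-df chi-squares ("assuming
one degree of freedom", as the original analysis states, even for the 2-df
test), takes \(\lambda_{GC} = \mathrm{median}(\chi^2)/0.4549\), and rescales
only when \(\lambda_{GC} > 1.05\).  Calibration is asserted under the
global null (pure-noise traits): traits that carry a polygenic component
are *deflated* by LOCO kinship correction in an admixed intercross, because
ancestry at any marker is correlated genome-wide — a property of the design
worth knowing when reading real scans.

The effective number of traits uses the eigenvalue-variance estimator,
\(M_{eff} = 1 + (M-1)(1 - \mathrm{Var}(\lambda)/M)\) on the trait
correlation matrix (sample variance, denominator M−1), clipped to
\([1, M]\).  Thresholds: genome-wide = \(\alpha/\#\)markers (0.05/32625
= 1.53e-6 at the emulated study's marker count); study-wide = genome-wide
/ \(M_{eff}\).

# Dominance architecture and effect sizes

The dominance ratio is reported as \(d/|a|\), oriented so +1 means complete
dominance of the higher-abundance allele (re-labelling alleles flips the
sign of \(a\) but not \(d\), so orientation by the higher-abundance
homozygote makes the ratio interpretable without ancestry information).
Bins: underdominant < −1.25; recessive [−1.25, −0.75]; partially recessive
(−0.75, −0.25); additive [−0.25, 0.25]; partially dominant (0.25, 0.75);
dominant [0.75, 1.25]; overdominant > 1.25.  \(a = 0\) with \(d \ne 0\) is
classified from the sign of \(d\) with a warning.

Transgressive heterozygotes are called by two Welch tests (heterozygote
versus each homozygote) at α = 0.05 each, with no correction — the source
analysis states "significantly lower/higher" without naming a test, so the
simplest defensible reading is documented and its joint false-positive rate
(≈ α²) is verified by simulation.

PVE is the marginal R² of the mixed model: the variance of the fixed-effect
predictions over that variance plus all random-component variances plus
residual, with fixed effects the intercept plus the requested marker
additive (and optionally dominance) codings; collinear marker columns are
dropped deterministically in position order.

# Regions, overlap, enrichment

Coordinates are 1-based inclusive internally; BED is converted from
0-based half-open at the boundary.  A significant SNP's region spans the
most distant same-chromosome markers with r² > 0.9 to it in the full
pre-pruning genotype set (no partner: a 1-bp interval).  Regions with a
gap (bases strictly between) below 10 Mb are merged transitively.  Overlap
with external interval sets counts overlapping interval pairs (the original
statistic is not specified at that granularity; pair counting is
implemented and stated); the null re-places each query interval uniformly
within its own chromosome with length preserved, which keeps the
chromosome-length confounder.  Gene-set enrichment permutes draws of
\(|hit|\) genes from the universe and also reports Fisher's exact p.
Regions longer than 10 Mb can be excluded before cross-study comparisons
via `maxRegionBp`.

# Numerical choices and problem sizes

Tolerances: optimiser relative tolerance ~1e-8 on the restricted
log-likelihood; GRM symmetry enforced to 1e-10; PSD enforced at −1e-8 on
the smallest eigenvalue.  Ties in LD pruning and collinearity drops are
resolved by genomic position so outputs are reproducible.  All randomness
flows from explicit seeds; one master seed is split into fixed per-stage
substreams so stages are independently reproducible.

The test suite exercises the full study geometry (320 G2s from the 8-line
cross) with 2000 markers on 19 autosomes, 100 replicate traits per
heritability level, 500 calibration replicates with 200 bootstrap samples
for the RLRT, and 50 replicates per power scenario — sizes chosen to give
Monte-Carlo standard errors comfortably inside the asserted bands while
keeping a full run on a single CPU practical.

# Known limitations

* Compositional observation: mapping operates on relative abundances; the
  simulator and estimators do not model absolute bacterial load.
* The inverse-logistic transform is applied to proportions exactly as the
  emulated analysis states; its image on [0,1] inputs is [0.5, 0.731], so
  it is a monotone rescaling rather than a variance-stabilising logit.
  The package follows the stated procedure rather than guessing an
  implicit logit of proportions.
* No epistasis, parent-of-origin, or X-chromosome models.
* The approximate scan reuses null variance components per chromosome;
  p-values at very strong signals are conservative relative to exact
  refits.
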