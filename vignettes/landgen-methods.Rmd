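---
title: "Methods: consensus genome scans and dissimilarity modelling of allelic turnover"
author: "landgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus genome scans and dissimilarity modelling of allelic turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`landgen` implements a comparative landscape-genomics workflow for paired
species sampled on a shared landscape — the motivating design is a
host plant and its specialist hemiparasite (a mistletoe), genotyped with a
reduced-representation method that yields biallelic SNPs with per-locus
technical reproducibility scores. The workflow:

1. quality-control filtering of the SNP table;
2. assembly and collinearity pruning of candidate climate predictors;
3. three genome scans — a PCA-outlier population-differentiation test, a
   latent-factor ridge environment association, and a Bayesian
   allele-frequency-covariance environment association;
4. a consensus partition of loci into putatively adaptive (flagged by two
   or more methods), putatively neutral (flagged by none) and excluded
   single-method sets;
5. Weir–Cockerham FST on each set, min–max scaled as the dissimilarity
   response;
6. generalized dissimilarity models (GDMs) with monotone I-splines,
   permutation-based backward elimination, predictor importance and
   deviance partitioning into geographic, temperature and precipitation
   components;
7. projection of fitted GDMs over climate grids as genetic-composition
   maps, compared between locus sets by Procrustes residuals and between
   species by jointly scaled residuals.

A synthetic-data generator stands in for the field data so that every stage
can be validated against known truth.

# The synthetic generator

The generator emulates the study design rather than any particular
organism's demography: around ten populations of 10–16 individuals on a
shared landscape, thousands of neutral loci, a handful of adaptive loci,
and DArT-style artefacts.

**Neutral structure.** Each neutral locus draws an ancestral frequency
$p \sim U(0.1, 0.9)$; population frequencies follow the Balding–Nichols
beta distribution $\mathrm{Beta}\!\left(p\frac{1-F}{F},
(1-p)\frac{1-F}{F}\right)$, whose expected FST equals the single parameter
$F$. We chose this one-parameter model because the comparison of interest
is a global differentiation contrast between species (the parasite more
differentiated than its host); defaults are $F = 0.30$ for the parasite
and $F = 0.08$ for the host, chosen to bracket the kind of neutral-set
contrast reported for host–mistletoe pairs.

**Adaptive loci.** An adaptive locus driven by climate variable $v$ has
population frequency $\mathrm{logit}^{-1}(\beta z_v)$ where $z_v$ is the
population-mean driver standardized across populations and $\beta = 3$ by
default (per standardized climate unit). A logistic cline is the natural
monotone counterpart of the GDM's monotone splines; $\beta = 3$ puts
extreme-site frequencies beyond 0.1/0.9, a strong but not fixed cline. The
parasite's drivers default to temperature variables and the host's to
precipitation variables, so the end-to-end analysis has an unambiguous
ground truth to recover.

**Artefacts.** Genotypes are $\mathrm{Binomial}(2, \text{freq})$;
calls go missing independently at rate 0.012 (matching the ~1% global
missingness typical of filtered DArT data sets); loci sit in consecutive
fragments of size 1–3 with probabilities (0.6, 0.3, 0.1), giving ~1.5 SNPs
per fragment as in DArT exports; reproducibility scores are uniform on
[0.98, 1] except for a 2% tail drawn below 0.98 to exercise the QC filter.
The generator deliberately omits linkage disequilibrium beyond fragment
co-membership, coalescent noise, and isolation-by-distance in the neutral
structure; passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
feature of real data (real neutral structure is itself spatially
autocorrelated, which is why the scans' inflation-factor calibration
matters in practice).

**Climate.** Synthetic climate grids are planar gradients plus smooth
seeded noise on a 50×50 grid of 0.1° cells; the temperature and
precipitation gradients are 90° apart so the two driver groups are
statistically distinguishable. Grids are read and written as ESRI ASCII
(`.asc`) text rasters.

# Quality control

Filters run in a fixed, documented order with strict inequalities: loci
with missing fraction < 0.05, then reproducibility > 0.98, then minor
allele frequency > 0.05 (computed over non-missing calls); then individuals
with missing fraction < 0.20; finally one SNP per fragment retained
uniformly at random under the run seed. The order matters only marginally
for the counts, but fixing it makes every downstream number reproducible.

# The three genome scans

**PCA-outlier test.** Genotypes are mean-imputed, centred and scaled by the
binomial standard deviation $\sqrt{2\hat p(1-\hat p)}$. With $K$ top
principal components (chosen by the scree elbow: the largest $K$ whose
eigenvalue drop exceeds 5% of the spectrum spread, minimum 1), each locus
gets the $K$-vector of its regression slopes on the unit-variance scores.
The squared Mahalanobis distance $D^2$ of these vectors uses a
median/MAD-based pairwise (Gnanadesikan–Kettenring) robust scatter —
deterministic and dependency-light, where subsampling-based robust
estimators would inject extra randomness. $D^2$ is calibrated by the
genomic inflation factor $\lambda = \mathrm{median}(D^2) /
\mathrm{median}(\chi^2_K)$ and referred to $\chi^2_K$; Storey q-values
control FDR at 0.05.

**Latent-factor ridge association.** Missing data are imputed by iterative
rank-$K$ SVD reconstruction (initialized at locus means, tolerance 1e-4,
at most 50 iterations, clamped into [0, 2] — kept continuous because the
association model uses dosages, not hard genotype calls). For each
climate variable scaled to unit standard deviation, the variable is
regressed out, $K$ latent factors are taken from the residual SVD, and
each locus is refit on [variable, factors]; squared z-scores are
recalibrated by $\lambda = \mathrm{median}(z^2)/\mathrm{median}(\chi^2_1)$
with per-variable Benjamini–Hochberg control at 0.05. With $K = 0$ the
scan degenerates exactly to per-locus simple regression, which is the
closed-form oracle used in the tests.

**Bayesian covariance model.** Population allele counts follow
$y_{ij} \sim \mathrm{Bin}(n_{ij}, \alpha_{ij})$ with
$\alpha_j \sim N(\pi_j \mathbf{1}, \pi_j(1-\pi_j)\Omega)$ truncated to
[0, 1], $\pi_j \sim \mathrm{Beta}(1,1)$ and an inverse-Wishart prior on
the population covariance $\Omega$. The sampler is Metropolis-within-Gibbs:
random-walk updates for $\alpha$ and $\pi$ with step sizes adapted during
pilot runs, and a conjugate inverse-Wishart step for $\Omega$ on the
standardized residuals. The conjugate step ignores the [0, 1] truncation;
with ancestral frequencies away from the boundary (as here) the truncation
almost never binds, and the parameter-recovery test (known diagonal
$\Omega$) bounds the resulting bias. XtX — the $\Omega$-corrected
standardized variance of a locus's population frequencies — is averaged
over posterior draws and over independent chains. Significance thresholds
come from a pseudo-observed data set simulated from the fitted model and
re-scored under the same fixed $\Omega$: the empirical 3%/97% XtX quantiles
flag balancing- and directional-selection outliers. Removing those
outliers and refitting gives the neutral covariance matrix under which the
environment-association run computes, per locus and covariate, an
importance-sampling Bayes factor for a linear effect on the standardized
frequencies, with a uniform grid prior on the effect size
($\beta \in [-0.3, 0.3]$, 41 points). Bayes factors are averaged over
chains and reported in decibans ($10\log_{10}\mathrm{BF}$); 20 dB
(BF = 100, "decisive") flags an association. Importance sampling over
posterior draws was chosen over reversible-jump model search because it is
reproducible at desk scale and uses the same posterior machinery as the
core model.

**Chain lengths.** Package defaults are 10,000 total sweeps with 5,000
burn-in, 15 pilot runs of 500 sweeps, thinning 10, and 4 chains;
`bp_settings(paper_scale = TRUE)` restores reference-scale settings
(100,000 kept sweeps, 50,000 burn-in, 30 pilots of 5,000). The bundled
tests and the acceptance script use desk-scale chains (2,500 total sweeps,
1,250 burn-in, 6 pilots of 250, 2 chains) — the XtX ranking and deciban
calls they feed are rank statistics that stabilize quickly, and the
calibration tests verify the desk-scale behaviour directly.

# Consensus, FST and the dissimilarity response

A locus counts for an environment-association method once, however many
variables flag it. Loci flagged by ≥ 2 methods form the putatively
adaptive set; loci flagged by none form the putatively neutral set;
single-method detections are excluded from both. Weir–Cockerham (1984)
variance-components $\theta$ is computed per set, globally and pairwise;
monomorphic loci contribute zero components, and negative pairwise values
are retained (clamping would distort ranks). The pairwise matrix is
min–max scaled to [0, 1] for the GDM response ("scaled between zero and
one" admits min–max or divide-by-max; both are provided, min–max is the
default because it uses the full unit interval).

# Generalized dissimilarity modelling

The GDM linear predictor is
$\eta_{ij} = a_0 + \sum_p \sum_{k=1}^{3} \beta_{pk}
\left| I_{pk}(x_{pi}) - I_{pk}(x_{pj}) \right|$
with fitted dissimilarity $\hat d = 1 - e^{-\eta}$ and all coefficients
non-negative. The three basis functions per predictor are order-2
I-splines with knots at the 0/50/100th percentiles of the site values —
the conventional default when "three splines" are requested; they are the
integrals of the order-2 M-splines on the knot sequence
$\{t_1, t_1, t_2, t_3, t_3\}$ and are verified against numerical
integration in the tests. Geographic distance (great-circle Haversine
between population centroids, km) enters as its own spline-transformed
predictor. Fitting minimizes the binomial-type deviance by iteratively
reweighted non-negative least squares (Lawson–Hanson NNLS inside IRLS,
step-halving on the deviance, convergence at |ΔD| < 1e-6, fitted values
clamped away from {0, 1}); percent deviance explained is relative to the
intercept-only null.

**Backward elimination.** Each predictor's p-value is the fraction of
site-level permutations of its values (pair table rebuilt, model refit)
whose percent explained reaches the observed model's, with the +1
small-sample correction. Site-level (not pair-level) permutation respects
the dependence structure of the pair table. While any retained predictor
exceeds α = 0.05, the non-significant predictor with the smallest summed
coefficients is dropped (ties by input order) and the model refit.
A force-retain list mirrors the common practice of keeping a marginal
predictor for comparability across models. The package default is 500
permutations; the bundled desk-scale runs use 200, which resolves
p-values to 1/201 — ample for a 0.05 threshold.

**Importance and deviance partitioning.** A predictor's importance is its
summed spline coefficients (also the maximum height of its turnover
curve). Deviance partitioning fits GDMs on every non-empty subset of the
predictor groups {geographic, temperature, precipitation} and decomposes
explained deviance by inclusion–exclusion into unique and joint
components, expressed as percentages of the full model's explained
deviance. The identity (components sum to 100%) is exact by construction;
small negative components (> −1 point) are clamped to zero with a
message — they arise because deviance is not additive across correlated
predictor groups — and larger negatives are reported as-is, since hiding
them would misrepresent genuine suppression.

# Spatial projection and Procrustes comparison

Each climate predictor retained in a model transforms its grid cell-wise
through the fitted turnover function $f_p(x) = \sum_k \beta_{pk}
I_{pk}(x)$ (clamped to the training range). The transformed surfaces are
reduced by PCA to three components composited as RGB (channels min–max
scaled to 0–255); similar colours mean similar predicted genetic
composition. Neutral- and adaptive-set maps are compared by least-squares
Procrustes superimposition of the cell × 3 PC configurations
(translation, rotation, uniform scaling; reflections permitted because PC
signs are arbitrary); configurations use the raw PC scores rather than
the RGB-scaled channels so residuals are unit-consistent. Cross-species
comparison scales both species' residual sets by the pooled minimum and
maximum. The adaptive-onto-neutral orientation is fixed so residual maps
are comparable across species.

# Numerical choices and degenerate inputs

- Scree rule: largest $K$ with eigenvalue drop > 5% of the spread; flat
  spectra return $K = 1$ with a warning.
- Spearman pruning drops the variable with the largest mean absolute
  within-group correlation, ties broken toward the later variable in
  input order — deterministic where the drop rule is otherwise
  unidentified; a fixed retained-variable list can be supplied instead.
- Nearest-cell raster extraction with half-open cell intervals; boundary
  points belong to the cell to their north-east.
- All-equal off-diagonal FST values, constant covariates, empty locus
  sets, and fully-missing loci raise errors rather than propagating NaN.
- One user seed drives every stage through fixed-offset sub-seeds; the
  MCMC uses R's RNG so `set.seed` reproduces chains bit-for-bit.

# Desk-scale problem sizes

The bundled tests and `scripts/acceptance.R` run the full pipeline on the
generator defaults (2 species × 10 populations × 15 individuals, 2,000
neutral + 10 adaptive loci) over five seeds, with the desk-scale chain
lengths and 200 permutations noted above; smaller fixtures are used for
unit-level oracles. Scan power is measured among planted loci that
survive QC: one-SNP-per-fragment thinning can legitimately discard a
planted SNP before any scan sees it, and that attrition is a property of
the sampling design, not of the scans.

# Known limitations

- The Balding–Nichols model has no spatial autocorrelation in neutral
  structure, so geographic distance competes with climate only through
  the planted clines and sampling noise.
- The Bayesian sampler's conjugate $\Omega$ step ignores frequency
  truncation (bias negligible away from fixation, unquantified near it).
- The GDM permutation test permutes one predictor at a time against the
  full model; strongly collinear retained predictors share significance.
- Composition maps require at least one retained climate predictor; a
  model retaining only geographic distance has no map, and the Procrustes
  comparison is then skipped with a note.
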