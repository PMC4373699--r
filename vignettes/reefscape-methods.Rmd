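---
title: "Methods: intra-reef landscape genetics with reefscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-reef landscape genetics with reefscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefscape)
```

## The problem

Sessile marine invertebrates such as brooding corals disperse as planktonic
larvae that actively choose settlement sites. On a single patch reef a few
tens of metres across, environmental gradients — depth above all — may
therefore structure *individual-level* genetic variation, either through
larval habitat selection or through post-settlement selective mortality.
`reefscape` implements the full analysis chain needed to ask that question
for an exhaustively mapped reef: every colony genotyped at 6 microsatellite
loci, with planar coordinates, tide-standardized depth, planar surface area,
and a grid of temperature loggers.

The chain is: (1) depth-independent thermal indices from the logger grid;
(2) ordinary kriging of depth and the indices onto colony positions;
(3) pairwise Moran's-I coefficients of relationship from the genotypes;
(4) simple and partial Mantel permutation tests linking relatedness to
space, depth and temperature; (5) AIC multi-model inference over all 15
subsets of the four pairwise-distance predictors; (6) equal-count
autocorrelograms defining a neighbour threshold; (7) spatial PCA over
neighbour networks with Moran's-eigenvector-map randomization tests; and
(8) pairwise AMOVA F~ST~ between colony size classes after clone removal.

## Thermal indices

Two station-level summaries are designed to be independent of depth:

* **Relative Hotspots** — the fraction of time a station is at least 1 SD
  hotter than the reef-wide reference. We compute the reference *per
  timestamp* (cross-station mean and SD at each reading), which removes the
  seasonal and diurnal cycles shared by all stations and isolates persistent
  spatial anomalies. A scalar two-year baseline is available via
  `baseline = "scalar"`; the per-timestamp version is the default because
  only it is structurally depth-independent when daily range varies with
  depth.
* **Relative Hothours** — the fraction of eligible readings at least 1 SD
  hotter than the station's *own* trailing 12-hour mean. The trailing window
  excludes the current reading; the first 12 h enter no denominator. The
  index is strictly local to a station.

Both thresholds are inclusive (`>=`). Timestamps or windows with zero
variance contribute no hot flags.

## Kriging

The empirical semivariogram uses the Matheron estimator on (default) 12
equal-width lag bins up to half the maximum station separation. Model
fitting (spherical by default; exponential and gaussian available) minimizes
Cressie-weighted least squares (`N(h)/h^2`) with bounded L-BFGS-B from three
starting points. Ordinary kriging solves the usual constrained system; the
covariance is `nugget + psill - gamma(h)`, weights sum to 1 by the Lagrange
construction, and exactly co-located stations are value-averaged first so
the system stays non-singular. With a zero nugget the predictor interpolates
exactly and the kriging variance vanishes at stations — both identities are
tested to 1e-10.

A caveat worth stating: kriging a *noisy* station variable onto thousands of
colonies manufactures a smooth surface whose large-scale features are
sampling artefacts of the finite grid. Any downstream pairwise test will
treat those features as real. This matters for the thermal indices (below).

## Pairwise relationship

For colony i with half-dosage `x_ila` of allele a at locus l (0, 0.5, 1) and
reference frequency `p_la`,

$$ r_{ij} = \frac{\sum_{l,a} (x_{ila} - p_{la})(x_{jla} - p_{la})}
                 {\sum_{l,a} p_{la}(1-p_{la})} . $$

Reference frequencies include clonal ramets by default (an exhaustively
mapped reef is a census, not a sample of genets); `dedup = TRUE` recomputes
them on unique multi-locus genotypes for sensitivity analysis. Two exact
identities are tested: the sum of numerators over ordered pairs equals
`-sum((x - p)^2)` when `p` are the sample means, and clonemates attain the
dataset maximum. Under panmixia the mean off-diagonal value is
`-1/(2(n-1))`: the individual variance under Hardy–Weinberg is half the
heterozygosity sum that standardizes the coefficient.

## Mantel machinery

All Mantel statistics are Spearman analogues: off-diagonal vectors are
rank-transformed (average ties) before correlating, because pairwise
distances on a disc-shaped reef are strongly right-skewed. The partial test
regresses the ranks of A and of B on the ranks of C and correlates the
residuals. The null permutes the rows/columns of **A** — the response
(relatedness) matrix — and repeats the residual procedure; permuting the
response is the scheme least damaged by autocorrelated covariates, and the
choice is recorded in every result object. P-values carry the +1 correction,
`p = (hits + 1)/(n_perm + 1)`, two-sided by default with the tail
configurable; defaults are 9999 permutations for Mantel, sPCA and AMOVA
tests and 200 for autocorrelogram envelopes. For n ≤ 8 both tests can
enumerate all n! relabelings (`exact = TRUE`), which the test suite checks
against an independent brute-force oracle at n = 5.

Known limitation: when the response is strongly structured by one smooth
surface (e.g. a saturated depth cline) and a covariate matrix is itself a
smooth random surface (e.g. a kriged index), the label-permutation null is
too narrow and small spurious associations reach significance. This is a
documented property of partial Mantel tests under nuisance autocorrelation,
not an implementation artefact; it is why the packaged demonstrations use a
weak cline when showing that thermal indices stay clean after the space
control, and why practitioners screen environmental layers for
depth-independence before including them.

## Size classes and AMOVA

Colonies below 10 cm² form the recruit bin; "large" bins (> 30, 40, 60,
90 cm²) deliberately overlap because age variance grows with size. Per bin,
partial Mantel tests run for depth, Hotspots and Hothours (controlling
space) and for space (controlling depth); bins under 10 members are skipped.
Pairwise F~ST~ between the small and each large bin comes from a two-level
AMOVA (among groups / individuals within groups) on allele-mismatch counts
(infinite-allele model), after removing repeated multi-locus genotypes
*within* each bin — a genet spanning two overlapping bins legitimately
appears once in each. Significance is one-tailed by permuting individuals
between groups; the permutation comparison uses the raw (possibly negative)
F~ST~ on both sides, because clamping at zero piles ties at p = 1 and
destroys the uniform null distribution. Both raw and clamped estimates are
reported.

## Spatial PCA and randomization tests

Neighbour networks connect colonies within a distance threshold — the mean
distance of the farthest autocorrelogram bin showing significant positive
autocorrelation (`neighbor_threshold()`); the same constructor serves the
2-D spatial network and the 1-D depth network, which are analysed
separately (depth-driven site selection and distance-limited dispersal are
distinct hypotheses; no 3-D analysis is attempted). With row-standardized
weights W and the column-centred individual allele matrix X, sPCA
eigen-decomposes `H = X'(W + W')X / (2n)`. Every axis satisfies
`lambda = var(s) * I(s)` with `var(s) = s's/n` and `I(s) = s'Ws/s's`
(verified to 1e-8, along with the trace identity), positive eigenvalues
being clines and negative ones patches. Lagged scores `W s` are the
neighbour-mean map; isolated nodes keep their own score and are flagged.

Global/local tests project each centred allele column onto the global
(positive-eigenvalue) or local (negative) Moran's eigenvector maps of the
doubly-centred adjacency; the statistic is the mean column R² (`"max"`
available behind the `stat` argument), and the null permutes the rows of X
with the network fixed. Binary versus row-standardized weights for the sPCA
term is likewise a config choice, with row-standardized the default.

## The synthetic reef

The generator's defaults *are* the study conditions: 2352 colonies uniform
on a 20 m-radius disc; a radial depth bowl from 0.5 m (centre) to 5 m (rim)
with exponent 2 plus smooth harmonic noise (SD 0.15 m); a 4 m logger grid
(~80 stations inside the disc) recording two years at a 3 h step (seasonal
plus diurnal sinusoids, iid reading noise of 0.15 °C, optional
depth-independent warm patch); lognormal areas with `meanlog = log 12`,
`sdlog = 1.2` — chosen once so the size-class proportions match field-typical
values (~46% under 10 cm², ~22% over 30 cm², ~5% over 90 cm²) — with 5.2%
of areas missing.

Genetic structure enters through three dials. The depth cline tilts each
locus' focal-allele frequency logistically,
`logit p(d) = logit p0 + s (d - d_center)` with `p0 = 0.4` and `d_center`
the disc-average depth; this is a statistical shorthand for
viability/selection, not a mechanistic larval model — the analyses only see
the resulting signature. Isolation by distance places each sexual recruit's
first allele copy from a parent drawn with kernel `exp(-d / ibd_scale)`
(default 5 m, matching short-range autocorrelation in brooding corals);
clonality copies a whole genotype from a colony within `clone_dispersal`
(default 2 m) with probability 0.2. Defaults for the structure dials when a
scenario does not set them: weak cline `s = 0.3`. All randomness flows
through one seeded stream and the `truth` record keeps every realized
parameter, so parameter recovery (e.g. the logistic slope via binomial GLM)
is testable.

What the generator does **not** emulate: genotyping error and null alleles,
linkage, selfing/inbreeding structure, depth-dependent temperature
statistics, fragmentation/fusion of colonies, and temporally varying
recruitment. Passing tests therefore show the machinery is correct and
calibrated under a clean model, not that field data will behave this way.

## Problem sizes, tolerances and numerical choices

The shipped fixtures use 200 colonies and ~30 loggers over 60 days; the
calibration studies use 500 null reefs and 100 strong-cline reefs of 150
colonies with 99-permutation tests (the smallest count that can reject at
alpha = 0.05), and the worked landscape table uses 300 colonies with 999
permutations — sizes chosen so a complete validation run takes minutes on a
laptop while keeping every statistical check exact or binomially calibrated.
Exact identities are asserted at 1e-10 (kriging, relatedness) and 1e-8
(sPCA); variogram simulation-recovery at 25% relative error, reflecting the
sampling noise of a single Gaussian-field realization. Spearman ties take
average ranks; zero-variance timestamps/windows are never "hot"; duplicate
stations are averaged; near-zero MEM eigenvalues are dropped at
`1e-10 * max|eigenvalue|`; a zero-residual regression floors its
log-likelihood with a warning rather than returning +Inf.

Open design points resolved here (the source material leaves them open):
the Hotspots baseline is per-timestamp (scalar behind a switch); Mantel
tails are two-sided by default; the intercept-only model is excluded from
the 15-model set (switchable), and Akaike weights are normalized over the
*full* set, consistent with published tables whose displayed weights sum to
slightly less than 1; AIC rather than AICc, the two being numerically
indistinguishable at pairwise sample sizes; the sPCA test statistic is the
mean column R² with the max variant behind a flag.
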