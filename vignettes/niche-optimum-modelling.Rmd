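---
title: "Niche-optimum modelling along environmental gradients: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche-optimum modelling along environmental gradients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheoptima)
library(dplyr)
```

## The problem

Soil microbial communities harbour enormous taxonomic diversity whose
ecological basis is mostly invisible: the vast majority of taxa have never
been cultivated, so their environmental preferences cannot be measured in
the laboratory. `nicheoptima` implements a culture-independent alternative.
If a taxon's *activity* (the relative abundance of its 16S rRNA
transcripts) is surveyed across many sites that span broad environmental
gradients, the shape of its response along each gradient can be modelled,
and the gradient position where activity peaks read off as that taxon's
**niche optimum** for the variable. Collecting the optima over many
variables gives each taxon a quantitative, multivariate description of its
realised niche, which can then be related to phylogeny, to the niches of
close relatives, and to the measured physiology of the few cultivated
representatives.

The package covers the full chain: read-to-reference assignment, gradient
preparation, hierarchical logistic response modelling, niche-space
analytics (distances, correlation networks, ordination), phylogenetic
signal, divergence-versus-relatedness regressions, and trait--niche
concordance tests, together with a synthetic-data module that generates
every input with known ground truth.

## Response models and the niche optimum

Per taxon and per environmental variable we model the per-site transcript
counts $y_i$ out of the per-site read totals $n_i$ as binomial with
success probability $p(x_i)$, where $x$ is the gradient rescaled to
$[1, 100]$. The response shapes are the five hierarchical logistic (HOF)
forms, written with $u = (x - 50.5)/99 \in [-0.5, 0.5]$ for optimiser
conditioning:

| model | shape | $p(u)$ | shape coefficients |
|---|---|---|---|
| I   | flat              | $1/(1+e^{a})$ | 1 |
| II  | monotone sigmoid  | $1/(1+e^{a+bu})$ | 2 |
| III | sigmoid + plateau | $1/[(1+e^{a+bu})(1+e^{c})]$ | 3 |
| IV  | symmetric unimodal| $1/[(1+e^{a+bu})(1+e^{c-bu})]$ | 3 |
| V   | skewed unimodal   | $1/[(1+e^{a+bu})(1+e^{c+du})]$ | 4 |

The maximum attainable response is fixed at 1 because the responses are
proportions. The bimodal extensions of the hierarchy are deliberately not
fitted. Fitting maximises the binomial log-likelihood under box
constraints (L-BFGS-B) with analytic gradients, from a deterministic grid
of starting positions and widths; the centred internal scale makes the
symmetric model peak at the gradient midpoint when $a = c$.

The niche optimum is extracted per the selected shape: undefined for model
I (a flat responder has no optimum), the favoured gradient end for II and
III, the closed form $(c-a)/(2b)$ for IV, and a golden-section argmax
(tolerance $10^{-6}$ internal units) for V, cross-checked in the tests
against a fine grid scan. Optima falling outside $[1, 100]$ are clamped
and flagged. The **inner niche width** is the gradient interval where the
predicted response stays above a fraction of its peak; the fraction is a
parameter with default $e^{-1/2}$, chosen because for a Gaussian-like
niche it corresponds to one standard deviation on either side of the
optimum.

### Model selection

All five shapes are fitted and ranked by AICc (the small-sample correction
is immaterial at 150 sites but costs nothing). Selection applies a
parsimony band: the simplest model within 2 AICc units of the best wins,
following the standard convention that models within 2 information-
criterion units are equally well supported. Without the band, a strict
lowest-AICc rule assigns a spurious non-flat shape to roughly a fifth of
truly flat responders (the penalty for one extra coefficient, 2 units,
is exceeded by chance with probability $\approx 0.15$); with it, the
flat-truth false-positive rate drops to well under 10% while recovery of
genuine unimodal responders is unaffected, as the acceptance checks
verify. `aicc_tol = 0` restores the strict rule.

The choice is then stabilised by bootstrapping: the sites are resampled 50
times, all five models refitted (warm-started from the full-data
estimates), and if the modal bootstrap choice differs from the full-data
choice the modal choice wins. Bootstrap ties resolve by lower full-data
AICc, then fewer coefficients. The reported `bootstrap_support` is the
fraction of resamples choosing the final model. Taxa whose optimisation
fails in more than half the resamples are flagged unmodelable.

### Error model

The binomial family with per-site totals as trials is an assumption: the
field data are relative transcript abundances whose sampling distribution
is not stated by any convention. Binomial counts are the natural model for
reads-out-of-total and make the likelihood well defined at zero counts.
Overdispersion beyond binomial (e.g. compositional competition between
taxa) is emulated in the generator via a Dirichlet-multinomial option, and
the recovery tests show the optimum estimates are robust to the per-site
renormalisation that multinomial sampling introduces.

## Gradient preparation

Variables measured in wildly different units are made comparable by the
affine map $x' = 1 + 99\,(x - \min)/(\max - \min)$ using the observed
minimum and maximum across sites (so a pH of 7.2 on an observed 4.6--7.5
range lands at 89.76, printed as 90). Rescaling with observed extremes is
what makes a single optimum scale meaningful across all 41 variables;
missing raw values stay missing. Land-use intensity is the square root of
the sum of mowing, grazing and fertilisation each standardised by its
overall mean; a management type absent from every plot contributes zero
by convention. A collinearity screen reports all pairwise Pearson
correlations (820 pairs for 41 variables) with the mean absolute value
and the count above 0.7 -- collinearity is tolerable here because the
variables are modelled marginally, never jointly in one regression.

## Read assignment

Amplicon reads are matched to full-length reference sequences at a 99%
identity cutoff (the platform's maximum error rate), identity being
matches over all aligned columns, gaps included, of the best global-local
alignment (full read against the best region of the reference; match +1,
mismatch -1, linear gap -2, via Biostrings). The cutoff is inclusive: a
100-bp read with one mismatch is kept. A read matching $k$ references
contributes $1/k$ of a read to each -- fractionated counting conserves
total matched read mass. Taxa observed in fewer than 25 of the 150 sites
are dropped before modelling; occurrence means any positive fractional
count, since the data carry no meaningful minimum-count threshold.

## Niche space

Ecological divergence between two taxa is the Euclidean distance between
their optimum vectors; across 41 variables on the common scale the
theoretical maximum is $99\sqrt{41} \approx 634$. Groups of ecologically
similar taxa come from a Spearman correlation network: an edge joins two
taxa whose optimum vectors correlate at or above a cutoff (0.85 by
default, with a sweep utility over the grid used to pick it), and
multi-level (Louvain) modularity optimisation finds the groups.
Singleton communities are not counted as groups. Correlations use
pairwise-complete variables; taxa with fewer than three usable optima are
excluded with a warning. PCA operates on the mean-imputed matrix --- the
same imputation rule the trait module uses, preferred over row deletion
because flat responses are informative missingness only for single
variables, not whole taxa.

## Phylogenetic signal

Blomberg's K compares the observed resemblance of relatives to the
Brownian-motion expectation, using the GLS root estimate and the ratio of
ordinary to covariance-weighted mean squared errors, normalised so that
K = 1 under Brownian motion on the given tree. The linear algebra goes
through Cholesky solves, never an explicit inverse. Significance comes
from permuting tip values and comparing the variance of phylogenetically
independent contrasts (lower variance than permutations = signal), with
the +1-corrected p-value; the contrast-variance statistic is the
convention of the standard implementation, and the test is exposed so a
K-based permutation could be swapped in.

The PSR curve regresses the trait on successive phylogenetic eigenvectors
and plots cumulative $R^2$ against the cumulative eigenvalue fraction;
the signed area between curve and diagonal is negative for traits
evolving faster than Brownian motion. The eigenvectors are taken from
Gower double-centring of $-D/2$, where $D$ is the patristic distance
matrix. This choice is deliberate: on an ultrametric tree, the
double-centred $-D/2$ *equals* the centred phylogenetic covariance
matrix, so its eigenbasis diagonalises the Brownian-motion covariance and
the expected $R^2$ gain of each eigenvector is exactly proportional to
its eigenvalue -- the PSR curve's Brownian expectation is exactly the
45-degree line, which is the property the area statistic is built on.
(Principal coordinates of the *squared* distances do not have this
property; in simulation their Brownian mean area on a 100-tip tree is
around -0.16 rather than 0.) Eigenvalues below $10^{-10}$ of the largest
are truncated.

## Divergence versus relatedness

Terminal-clade pairs (cherries; within a polytomy, every tip pair,
flagged) whose sequence dissimilarity is at most 5% form the unit of
analysis: each pair contributes its 16S dissimilarity and the ecological
divergence of its two members. Two ordinary least-squares models are
compared -- common slope with per-subdivision intercepts versus
per-subdivision slopes -- by the F-test on the interaction terms and by
AIC. Dissimilarity is conventionally expressed in percent so the slope
reads as divergence per percent sequence change. Pairwise intercept
contrasts use the single-step max-|t| adjustment over the joint
multivariate-t distribution (Holm available). Prediction bands draw 50
dissimilarity values per subdivision uniformly over that subdivision's
observed range and report the pointwise 95% confidence band of the
common-slope fit.

## Trait--niche concordance

Trait matrices from taxonomic descriptions are sparse; species with under
70% of traits and traits known for under half the species are removed
iteratively (rows first each round -- the order matters and is fixed for
determinism). Coded traits use 1/2/3 for negative/weak/positive (oxygen
relation aerobic = 3, microaerophilic = 2, anaerobic = 1); complex traits
are numeric, with ranges replaced by the midpoint. Optimum tables for the
comparison drop species missing more than two variables and mean-impute
the rest. Bray-Curtis dissimilarities omit, per pair, any trait missing in
either member; columns are not standardised before the computation
(raw codes carry the intended weighting; a flag could change this).
Ordinations use NMDS (Kruskal stress-1, multiple random starts) in six
dimensions by default, and ordination agreement uses the symmetric
Procrustes correlation $\sqrt{1 - m^2}$ with a row-permutation test.
Because a 999-permutation p-value is itself a random variable, the test
is repeated 100 times and the mean p reported, which stabilises borderline
calls.

## The synthetic-data module

Every pipeline input can be generated with known truth:

* **Gradients** -- one row per site, each variable uniform over its
  declared range (defaults mirror the 41 observed grassland ranges, e.g.
  pH 4.6--7.5). Uniform sampling maximises gradient coverage for testing;
  real soils are correlated and unevenly sampled, which the generator
  does not emulate.
* **Responses and reads** -- per-taxon HOF truth (shape, coefficients,
  true optimum), evaluated at the sites and sampled as multinomial reads
  of a fixed depth per site (Dirichlet-multinomial overdispersion
  optional). The per-site renormalisation means each taxon's realised
  proportion is distorted by the other taxa -- exactly the compositional
  noise real amplicon data carry.
* **Trees and traits** -- pure-birth trees rescaled to unit height;
  Brownian, Ornstein-Uhlenbeck or white-noise tip traits.
* **Planted structure** -- optimum tables with group centres plus
  Gaussian scatter (for the network stage), coupled 1/2/3 trait matrices
  sharing group labels (for the concordance stage), and linear
  divergence-pair data with per-subdivision intercepts (defaults 76, 150,
  149, 236 and slope 22.6 per percent, representative magnitudes for the
  system; residual SD 60, a realistic scatter given divergences up to
  ~520 on a 0--634 scale).

Everything is deterministic under a seed. Passing recovery tests on these
fixtures demonstrates the estimators are correct and calibrated under the
stated generative assumptions; it does not certify behaviour under
spatial autocorrelation, microscale soil heterogeneity, or measurement
error in the gradients, none of which are simulated.

## Problem sizes and numerical choices

The validation suite runs at deliberately chosen sizes: 150 sites and
read depth $10^4$ for response-model recovery (200 unimodal taxa; median
absolute optimum error well under 3 scaled units), 100 flat datasets for
the false-positive control, 200 Brownian replicates on 100-tip trees for
the K and PSR calibrations, 200 taxa in 4 planted groups for network
recovery, 500--1000 replicates for the size of the interaction F-test and
the protest null. Tolerances: likelihood optimisation runs to optimiser
convergence with bounds wide enough for near-degenerate sigmoids;
golden-section and bisection use $10^{-6}$--$10^{-8}$; eigenvalue
truncation $10^{-10}$ relative. Degenerate inputs (constant gradients,
all-zero counts, constant traits, empty networks, rank-deficient designs)
raise informative errors rather than propagating NaNs.

## Known limitations

* The HOF likelihood is binomial; a Gaussian-on-proportions fallback is
  not currently exposed, and genuinely overdispersed counts will show
  overconfident bootstrap support.
* Model III's plateau parameterisation follows the original HOF
  formulation; other parameterisations exist and give equivalent fits
  but differently scaled coefficients.
* Community detection depends on the seed through Louvain's sweep order;
  runs are comparable only at fixed seed, and modularity is reported so
  different runs can be compared.
* The read matcher aligns every read against every reference; it is meant
  for the package's analysis scale, not for hundreds of millions of raw
  reads.
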