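---
title: "Model-based morphometric delimitation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based morphometric delimitation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodelim)
```

## The problem

Taxonomists routinely ask whether continuous measurements (head length,
limb length, eye diameter, ...) support treating two or more operational
taxonomic units (OTUs) — putative species, populations, morphotypes — as
distinct. The traditional toolkit answers with univariate significance
tests and ordination plots. morphodelim adds a model-comparison layer:
competing *delimitation schemes* (assignments of every specimen to a
group) are treated as statistical models for the same data and ranked by
how well each explains the observed multivariate variation. Morphometric
structure is one line of evidence among several; the package quantifies
that evidence, it does not by itself delimit species.

## The mixture model and its covariance families

Size-corrected characters for each group are modelled as multivariate
Gaussian. Component covariances are parameterized by the
eigen-decomposition

$$\Sigma_k = \lambda_k D_k A_k D_k^{\mathsf T},$$

with volume $\lambda_k > 0$, diagonal shape $A_k$ ($\det A_k = 1$) and
orthogonal orientation $D_k$. Constraining each factor to be **E**qual
across components, **V**ariable, or the **I**dentity yields the 14
standard families `EII` ... `VVV` (`gmm_families()`). Smaller families
spend fewer parameters; which trade-off wins is decided by BIC in the
maximize form

$$\mathrm{BIC} = 2\,\ell - k \log n,$$

where $\ell$ is the log-likelihood and $k$ the free-parameter count from
the standard enumeration (`gmm_n_params()`; e.g. `VVV` spends
$G\,d(d{+}1)/2$ covariance parameters, `EII` spends one).

Three estimation modes share this machinery:

* **Unsupervised** (`fit_gmm()`, `unsupervised_cluster()`): labels
  unknown, EM over memberships; every $(G, \text{family})$ cell is
  fitted for $G = 1 \dots G_{\max}$ and the BIC-best cell gives the
  inferred number of morphological clusters. Cross-tabulating the best
  classification against OTU labels (`classify_correspondence()`)
  diagnoses *perfect correspondence*, *mixed clusters* or *split OTUs*.
* **Supervised / EDDA** (`fit_edda()`): labels known, so means and
  scatters are plain groupwise ML values; only constrained covariance
  estimation iterates. The log-likelihood is the complete-data value
  $\sum_i \log[\pi_{z_i}\phi(x_i \mid \mu_{z_i}, \Sigma_{z_i})]$ with
  group frequencies as proportions, counted as $K-1$ parameters. (The
  reference mixture implementation reports the *marginal* mixture
  likelihood for its discriminant models — same fitted parameters,
  different number; we use the complete-data convention throughout so
  supervised and unsupervised BICs share one definition.)
* **Scheme comparison** (`merge_path()`, `compare_schemes()`): each
  delimitation scheme is scored by its best-over-families EDDA BIC.
  `merge_path()` starts from the original OTUs, tries every pairwise
  merge, commits the one with the highest BIC, and repeats until all
  groups are lumped — a greedy path from maximum splitting to maximum
  lumping. `compare_schemes()` scores arbitrary user schemes (which may
  also *split* OTUs). Both share one code path, so identical hypotheses
  get identical scores.

Evidence between schemes is summarized by `rank_schemes()`:
$\Delta\mathrm{BIC}_i = \mathrm{BIC}_{best} - \mathrm{BIC}_i$, Bayes
factor $BF_i = \exp(\Delta\mathrm{BIC}_i/2)$ against scheme $i$, and
flat-prior posterior model probabilities
$PP_i \propto \exp(-\Delta\mathrm{BIC}_i/2)$. Bayes factors are kept in
log space internally and formatted in scientific notation above $10^6$,
so astronomically decisive comparisons remain printable.

## Allometric size correction

Raw distances grow with body size; between-OTU size differences would
otherwise masquerade as shape differences. `thorpe_correct()` adjusts
every character on the base-10 log scale:

$$X_{adj} = \log_{10} X - \beta\,(\log_{10}\mathrm{SVL} -
\overline{\log_{10}\mathrm{SVL}}),$$

with the grand mean log-size as the common reference. The slope $\beta$
is, by default, the pooled within-group OLS slope computed from
group-mean-centered data — the multispecies variant, which uses only
within-OTU covariation and is therefore invariant to relabeling. A
per-OTU slope mode exists for heterogeneous allometries, and a "none"
mode that log-transforms without any slope term (a raw passthrough is a
separate flag, since downstream Gaussian modelling is better behaved on
the log scale). After pooled correction the pooled within-group slope of
every corrected character is zero to numerical precision — a property
the tests assert at 1e-10. Degenerate inputs: if every specimen shares
one body size the correction term vanishes identically and the log data
are returned; if size is constant within but not between OTUs the pooled
slope is undefined and the function refuses with advice to use "none".

## Diagnostic characters and univariate tests

`boruta_select()` implements the shadow-feature wrapper around a random
forest: each run appends one shuffled copy ("shadow") of every
still-undecided character, trains a forest (`ranger`, out-of-bag
permutation importance, single-threaded for reproducibility), and scores
a *hit* for characters beating the best shadow. One-sided binomial tests
on hit counts (success probability 0.5, Bonferroni-corrected across the
characters still in play) promote to Confirmed or demote to Rejected;
rejected characters leave the game together with their shadows. Defaults
— 500 trees, at most 100 runs, decision level 0.01 — are the selection
algorithm's conventional settings. Confirmed means *discriminatory*, not
*different in mean*: `univariate_tests()` (Welch's t by default, with
Student's t and one-way ANOVA available, and none/Bonferroni/Holm/BH
adjustment across characters) supplies the mean-difference view, and
`diagnostic_report()` crosses the two, labelling the concordant and
discordant cells explicitly.

## Ordination and permutation tests

`morpho_pca()` is covariance (or correlation) PCA with a deterministic
sign convention (largest-magnitude loading positive per axis).
`morpho_dapc()` reduces to a retained number of principal components —
`"auto"` keeps the smallest set explaining 90% of variance, capped at
$n/3$ — then fits linear discriminant axes; retaining fewer components
than $n - K$ is enforced as an overfitting guard. `permanova()` computes
the one-way Euclidean pseudo-F directly from sums of squares,
$F = [SS_b/(K-1)]/[SS_w/(n-K)]$, with $R^2 = SS_b/SS_{tot}$, and a
seeded label-permutation p-value under the add-one convention
$p = (b+1)/(P+1)$, whose floor at $P = 50{,}000$ permutations is
$1/50001 \approx 0.000020$. Euclidean distances on all PCA scores equal
Euclidean distances on the input, so the test may be run on either.
Rows are sorted by specimen id before permuting, making the seeded
result invariant to input order. `pairwise_permanova()` tests every
group pair and adjusts across the $K(K-1)/2$ comparisons (Bonferroni by
default). Non-Euclidean dissimilarities and dispersion (PERMDISP) tests
are out of scope.

## Numerical choices

* **EM**: relative log-likelihood tolerance 1e-8, at most 500
  iterations; monotonicity is asserted in the tests at every iteration.
* **Initialization**: deterministic Ward agglomeration on standardized
  data cut at $G$ (so model-selection tables are bit-reproducible);
  random responsibility starts, and restarts after degeneracy, are
  seeded.
* **Iterative covariance families**: `VEI`/`VEE`/`VEV` alternate
  closed-form volume and shape updates; `EVE`/`VVE` additionally update
  the shared orientation by a linear majorize-minimize step over the
  orthogonal group (one guarded step per sweep), warm-started from the
  previous EM iteration — a generalized-EM M-step that keeps the
  likelihood monotone. Inner tolerance 1e-8, at most 100 sweeps.
* **Degeneracy**: components whose covariance falls below an eigenvalue
  floor of 1e-10 times the mean diagonal of the total covariance abort
  the fit; `fit_gmm()` retries from seeded random starts, and grid cells
  that still fail are recorded as missing and excluded from model
  selection (never as $-\infty$).
* **Tie-breaks** in any BIC comparison: higher BIC, then fewer
  parameters, then fewer components, then alphabetical family code.
  Equal-BIC merges break lexicographically; merged groups are named
  `"A-B"` in lexicographic order.

## What the synthetic generators emulate — and what they do not

`simulate_allometric()` draws body size uniformly on a log10 range and
builds characters as $\log_{10} X = a + b \log_{10}\mathrm{SVL} +
\varepsilon$: group structure lives in the intercepts (size-independent
shape), exactly the signal the Thorpe correction is designed to expose.
`desmognathus_mimic()` instantiates the three-OTU benchmark scenario —
69, 21 and 26 specimens, 17 characters, the second and third OTU drawn
from one distribution and the first separated by Mahalanobis distance 6
along the first discriminant direction, with near-isometric slopes
(0.75–1.15) and adult sizes 35–65 mm.

Residuals in the mimic are independent across characters with
heterogeneous scales (sd 0.02–0.04 log10 units). This is a deliberate
idealization: real morphometric residuals correlate, but at this scale
(n = 116, d = 17) a strongly correlated within-group covariance is not
identifiable by BIC — the correlated families cost up to
$d(d{+}1)/2 = 153$ parameters against $\log(116) \approx 4.75$ per
parameter, so mixtures of simple components would absorb the correlation
by splitting clusters. Passing recovery tests on this generator
therefore demonstrates correct engine behavior under the model's
assumptions; it does not certify cluster-count recovery on small, highly
correlated empirical datasets, where the same mechanism can inflate the
inferred number of clusters. The same caveat applies to the Gaussian
assumption itself: meristic or categorical characters are out of scope.

## Problem sizes used by the test suite

The delimitation-recovery check runs the mimic over 100 seeds with
$G_{\max} = 3$ and all 14 families — the lumping scenario only
distinguishes one to three clusters, and this grid keeps the full sweep
to a few minutes on one core. Engine identities (closed-form G = 1,
independent-EM oracle, family nesting) use 20 two-cluster fixtures of
n = 85, d = 3. The permutation-test calibration uses 200 null datasets
of n = 40 with 999 permutations each; the selection-stability check uses
20 replicates of two 50-specimen groups with 3 informative and 5 noise
characters. The greedy merge path is compared against exhaustive
enumeration of all merge-reachable partitions for four OTUs over 50
replicates (greedy is not guaranteed optimal; agreement is required in
at least 90% of replicates and observed well above that).

## Known limitations

* The shadow-feature selector measures *in-sample* relevance. Even when
  labels are generated independently of every character, a modest
  fraction of finite datasets contain a character whose chance
  association with the labels is real in that sample (over 10 characters
  at n = 60, the largest chance correlation is around 0.3), and the
  selector legitimately confirms it. Expect occasional single
  confirmations on null data rather than a guaranteed empty Confirmed
  set; the binomial decisions are Bonferroni-corrected over the full
  character set to keep this rare.
* BIC ranks the candidate schemes; it does not certify that any of them
  is adequate. A decisive posterior probability may simply mark the
  least wrong model.
* The EDDA layer requires at least two specimens per group, and families
  with per-group full covariances need group sizes exceeding the number
  of characters to be estimable; non-estimable cells are skipped with a
  note rather than silently substituted.
* The greedy merge path explores one trajectory; use `compare_schemes()`
  with explicit hypotheses (including splits) for decisions between
  specific alternatives.
* Exact numerical agreement with the reference GUI implementation's
  hierarchical initialization is not promised; its SVD-based
  agglomeration variant is undocumented, and Ward linkage is used here
  instead. Fitted log-likelihoods agree with the reference mixture
  engine to about 1e-4 on shared fixtures.
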