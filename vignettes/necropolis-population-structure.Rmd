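---
title: "Methods: biocultural population structure of a necropolis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biocultural population structure of a necropolis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necropop)
```

This vignette documents the models and numerical choices behind the three
analysis strands of `necropop`, and what the synthetic generator does and
does not emulate.

## Strontium isotope provenance

Tooth enamel does not remodel after crown mineralization, so its
^87^Sr/^86^Sr ratio fixes the bioavailable strontium of the region where
the individual lived while that crown formed. Bone remodels throughout
life and approximates the (local) residence at death, which also makes it
more vulnerable to diagenetic overprint. The pipeline therefore:

1. summarizes local baseline material with `summarize_ratios()` (mean and
   2 sample standard deviations, the conventional 2-sigma reporting);
2. builds the local range as the **union span** of one or more baseline
   intervals with `estimate_local_range()`. Using the broadest interval
   across tissues (e.g. human bone and published faunal enamel) is the
   conservative choice: it can only reduce the number of non-local calls.
   The packaged default range is `[0.7086, 0.7090]`;
3. classifies each individual from the **earliest-mineralizing** sampled
   tooth (`classify_provenance()`), under the crown chronology
   dm2 < M1 < P4 < M2 < M3. The chronology is a fixed table
   (`tooth_rank()`); side and arch never affect it;
4. types mobility from the earliest/latest tooth pair
   (`infer_mobility()`).

Two conventions matter and are deliberate:

* **Bounds are inclusive and comparisons unrounded.** A ratio of exactly
  0.7090 is local; a ratio of 0.709070 is not. Classification at the
  full printed precision of the input is what makes borderline calls
  reproducible.
* **Mobility categories are containment-driven.** The category follows
  from where the early and late ratio each fall relative to the local
  range (both within: stable local; both above: stable non-local; above
  then within: arrived during childhood; within then above: outbound
  plus return, since burial is local; early below the range: a distinct
  third origin). The configurable `delta_threshold` (default `1e-4`, the
  dispersion of the local baseline) is *reported* as a flag
  (`delta_exceeds`) rather than used as a gate: two teeth can differ by
  twice the analytical threshold while both sit comfortably inside the
  local range, and such movement between isotopically similar regions is
  not resolvable by a range test. Gating the stable categories on the
  delta would leave exactly those pairs unclassifiable.

A single-tooth individual is still classified for provenance (the call is
flagged `single_tooth`, and is weaker when the only tooth is a
late-mineralizing M3), but never typed for mobility.

## Dental biodistance

Non-metric crown and root traits are scored on ASUDAS ordinal scales,
dichotomized at published breakpoints (`dichotomize()`, left side
preferred, antimere substituted), and summarized per group as presence
counts `k` out of `n` scored individuals. Divergence between groups uses
the Mean Measure of Divergence over `r` traits:

$$\mathrm{MMD} = \frac{1}{r}\sum_i\left[(\theta_{Ai}-\theta_{Bi})^2 -
\left(\tfrac{1}{n_{Ai}+0.5}+\tfrac{1}{n_{Bi}+0.5}\right)\right],\qquad
\mathrm{SD} = \sqrt{\frac{2}{r^2}\sum_i\left(\tfrac{1}{n_{Ai}}+
\tfrac{1}{n_{Bi}}\right)^2}$$

with significance conventionally declared at MMD > 2 SD (about
p < 0.025). MMD can be legitimately negative for very similar groups —
the subtracted term is the expectation of the squared angular difference
under identical underlying frequencies.

**Choice of the angular transform.** The literature attaches the label
"Freeman–Tukey correction" to at least three related arcsine transforms.
All three are implemented in `ft_theta()`; the default is the
Freeman–Tukey double arcsine
$\theta = \pi/2 - \arcsin\sqrt{k/(n+1)} - \arcsin\sqrt{(k+1)/(n+1)}$,
with $1/(n+0.5)$ in the MMD bias correction but $1/n$ inside the SD. This
exact combination was pinned empirically: recomputing a published 19-group
divergence matrix from its published percent/n table reproduces all 51
printed MMD values of the three focal rows to at most 0.0024, every
printed SD to 0.0005, and the full printed significance pattern, while
the plausible alternatives (mean-arcsine form, Anscombe form, $1/(n+0.5)$
in the SD) miss by up to two orders of magnitude more. The alternatives
remain available behind `variant=` for comparisons with software that
uses them.

**Counts from percentages.** Published tables print rounded percentages;
`counts_from_percentages()` recovers `k = round(percent * n / 100)` and
warns when the recovered count cannot reproduce the printed percentage
within half a unit in the last digit (three entries of the packaged table
have this property; they are transcribed as printed).

**Trait screening.** Traits observed fewer than 5 times are excluded
before anything else (their frequencies are unstable), then pairs with
pairwise-complete association $|\phi| > 0.5$ (the signed
$\sqrt{\chi^2/N}$ of the 2x2 table) are resolved by iteratively removing
the trait involved in the most offending pairs, ties broken by fewer
observations and then column order (`correlation_screen()`).

**Ordination and clustering.** Because the reported MMD matrix may hold
negative entries, those are clamped to zero *only* on the way into
classical MDS (`classical_mds()`, Torgerson double centering via
`stats::cmdscale`) and Ward clustering (`ward_dendrogram()`,
`hclust` method `ward.D2`, i.e. Ward's criterion on dissimilarities). The
reported matrix itself keeps its negatives.

## Mortuary structure

Grave goods are coded as a binary individual-by-good matrix. Structure by
sex, age and isotopic origin is assessed by:

* **Jaccard distances** (`jaccard_matrix()`): `1 - |intersection|/|union|`
  over the good sets; two empty profiles get distance 0 (identity of
  empty sets), a convention needed because cremations or poor graves can
  be goodless.
* **Complete-linkage clustering** (`complete_linkage()`), a qualitative
  view of the same structure.
* **Chi-square on occurrence counts** (`goods_by_group_chisq()`): the
  goods-by-group table counts one occurrence per individual per good
  possessed, so 65 goods across two sexes give df = 64. Goods never
  observed are dropped (with a warning) before df is computed.
* **Distance-matrix AMOVA** (`amova()`): one-level decomposition with
  squared distances in the sums of squares (the standard convention even
  though Jaccard is not Euclidean), variance components via the weighted
  average group size, and a permutation p-value
  `(1 + #{perm >= obs}) / (1 + B)` with `B = 9999` by default — enough
  for stable p-values at the 0.001 level. Negative Phi_ST is reported as
  computed; it simply means groups are no more distinct than random sets.
  Individuals with a missing label (origin code 1, unknown-sex
  cremations) are excluded per test, never imputed.
* **Correspondence analysis** (`correspondence_analysis()`): SVD of the
  standardized Pearson residual matrix; per-axis inertia partitions
  chi-square / N.
* **Random-Forest importance** (`random_forest_importance()`, via the
  `randomForest` package): 500 trees, `floor(sqrt(p))` predictors per
  split, bootstrap per tree; mean Gini-impurity decrease ranks the goods,
  OOB votes give the error estimate. Goods with Gini importance above
  0.1 are treated as sex-linked and removed before any origin model.
* **Stepwise VIF** (`vif_stepwise()`): VIF = 1/(1-R^2) of each variable
  on the other retained ones; the largest VIF above 5 is removed
  repeatedly, perfect collinearity (infinite VIF) first, ties by column
  order.

## The synthetic necropolis

`synthetic_config()` fixes the study conditions: 38 individuals with 4
cremations; origin mixture 0.52/0.44/0.04 (local/non-local/outlier);
enamel sources Normal(0.70880, 6e-5), Normal(0.70930, 1.5e-4) and
Normal(0.70853, 3e-5), chosen to span the observed local
(0.7086–0.7090), non-local (0.7090–0.7096) and low outlier clusters, with
measurement noise at 2SE = 6e-6; two teeth per individual (dm2 + M1 for
children, M1 + M2/M3 for adults) with late-childhood arrival injected in
40% of non-locals and outbound-return in 17% of locals (the proportions
observed in the motivating assemblage); trait presence probabilities
taken from the packaged local/non-local frequency columns; and a 65-good
catalogue with 15 male-linked, 15 female-linked and 35 neutral goods
(linked probability 0.45 vs 0.05 at full strength, neutral 0.20,
subadults at half rate). Scenario `"A"` is origin-neutral, `"B"` adds an
origin-linked block for power analysis, `"null"` removes all structure.

What it does **not** emulate: diagenesis, geological gradients or
non-Gaussian source mixtures; ordinal trait grades (generation is binary
because only dichotomized data enter the analysis and no grade-level
distributions are published); correlated goods (inclusions are
conditionally independent given sex/age/origin); spatial grave layout and
chronology. Passing tests on synthetic data therefore demonstrate that
the estimators recover the structure they target under idealized
sampling, not that real assemblages meet those ideals.

## Numerical conventions and problem sizes

* All RNG-dependent functions accept a seed and are reproducible; the
  pipeline writes its configuration next to its outputs.
* Tests exercise the property suites at deliberately small sizes (AMOVA
  oracle equality on 100 random instances with n <= 12, a 1000-individual
  mixture-recovery check, permutation counts of 99–9999), which keeps the
  default suite within half a minute on one core while the Monte-Carlo
  error of each stochastic check stays inside its asserted bound.
* Newick export writes branch lengths as parent-minus-child merge
  heights, so leaf depth equals the root merge height and a two-leaf tree
  at height *h* reads `(A:h,B:h);`.

## Known limitations

* Provenance cannot separate regions with similar bioavailable strontium,
  and imported food biases individual signatures; these are limits of the
  isotope method itself, not of the implementation.
* MMD rests on trait independence after screening and on the angular
  variance stabilisation; groups with very small per-trait n (< 5) are
  excluded rather than modelled.
* The AMOVA permutation test permutes individuals as exchangeable units;
  it does not model spatial or temporal autocorrelation between graves.
* With more goods than individuals the VIF step necessarily removes
  variables until the regression is determined; the removal order within
  perfectly collinear sets follows column order and is a convention.
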