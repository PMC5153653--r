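---
title: "Methods: DMR inference and multivariate phenotype integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMR inference and multivariate phenotype integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open.

## The study system

The cohort is 36 Holstein cattle spanning four groups: perinatal animals
(foetuses and neonatal calves) and adults, each either cloned by
somatic-cell nuclear transfer or conventionally bred (AI). Pathological
perinatal clones share donor genotypes with clinically normal adult clones,
so phenotypic and epigenetic contrasts between the groups cannot be
explained by DNA sequence. Liver DNA methylation is assayed by MeDIP on a
promoter tiling array; the analysed signal is a binary per-probe,
per-animal enrichment call. The phenotypes are graded histological lesion
scores, histomorphometric measurements on hepatocytes and their nuclei,
and fatty-acid composition of the phospholipid and neutral-lipid
fractions.

## Binary enrichment calls and regions of interest

`call_enriched_probes()` declares a probe enriched in a sample when the
mean of its available replicate log2(MeDIP/input) values reaches a
threshold. The default threshold of 1 corresponds to a two-fold signal
over input — a transparent, configurable rule in a place where published
pipelines typically rely on array-specific scoring. `min_replicates`
(default 1) controls when a call is attempted at all; with fewer finite
replicates the call is missing rather than 0, so absence of evidence does
not count as evidence of non-enrichment.

`condition_level_calls()` pools calls within each of the four
age-by-cloning groups: a probe is enriched in a condition when strictly
more than half (default) of its non-missing calls are 1. The strictness
resolves ties deterministically: 2 of 4 is not a majority.

`anchor_extend()` builds regions from qualifying ("anchor") probes:
within a chromosome, consecutive anchors at most `max_gap` apart (next
start minus previous end) extend one region; runs shorter than
`min_probes` are discarded. Defaults — `max_gap = 500` bp,
`min_probes = 3` — follow common tiling-array practice of bridging one or
two missing probes at typical promoter-array spacing while refusing
single-probe "regions". Coordinates are 0-based half-open throughout,
matching BED conventions.

## DMR inference by nested binomial models

For each region, the calls of all probes and animals are modelled with a
Bernoulli working likelihood:

$$\mathrm{logit}\, P(\text{call}=1) = \beta_0 + \beta_{age}\,
\mathbf{1}[\text{adult}] + \beta_{clone}\, \mathbf{1}[\text{clone}].$$

No interaction term is fitted: with 26 animals, a two-parameter contrast
is the most that can be estimated robustly, and the two reduced models
(age only, cloning only) make the nested comparisons well defined.
Dropping the cloning term and comparing likelihoods by
$2\Delta\ell \sim \chi^2_1$ tests for a cloning effect; dropping the age
term tests for an age effect. Because both covariates are constant within
an animal, the per-probe likelihood collapses to per-animal binomial
counts, which is how `fit_region_models()` evaluates it.

Three numerical decisions:

* **Constant regions.** A region whose non-missing calls are all 0 or all
  1 carries no information about either contrast and invites separation
  pathologies; it is declared untestable with p = 1 rather than fitted.
* **Independence working likelihood.** Probes within a region are treated
  as independent given the group. Spatial correlation between neighbouring
  probes would make the tests anticonservative on real arrays; this is a
  known limitation, and the per-family FDR control shown in the tests
  holds under the generator's independence assumption, not necessarily on
  real data.
* **Missing calls** are excluded from the likelihood, but count as "not
  enriched" in the enrichment percentages below while the probe total
  stays fixed, keeping percentages comparable across animals
  (`rescale_missing = TRUE` divides by the observed probe count instead).

`adjust_and_classify()` applies Benjamini–Hochberg separately to the age
and cloning p-value families — the two families test different contrasts
over the same regions, and pooling them would let a strong age signal
loosen the cloning threshold. Classification uses adjusted p < 0.05.

Per-individual summaries are percentages of enriched probes,
$P_{ri} = 100\,E_{ri}/T_r$, and their means over the age-related and
cloning-related DMR sets ($Pi_{age}$, $Pi_{cloning}$), computed by
`compute_pi()`.

## The synthetic generator

`simulate_enrichment()` inverts the inference model: it plants regions on
one synthetic chromosome (probes every 100 bp, regions separated by ten
times the default gap so anchor extension recovers them exactly), assigns
a fraction of regions to each DMR class, and draws Bernoulli calls with
logit probability `baseline + age_effect·adult + clone_effect·clone`,
effects zeroed outside the planted class. The defaults are the cohort's
design: 26 animals (4 perinatal AI, 7 perinatal clones, 8 adult AI, 7
adult clones), 500 regions of 20 probes, baseline log-odds −1 (≈ 27%
enrichment), age effect +2 and cloning effect −2 (opposite signs, as DMRs
can be hyper- or hypomethylated), 10% of regions per DMR class, classes
drawn independently so overlap is possible — the real DMR classes overlap
too. One seed drives a single RNG stream, so identical configurations are
bit-identical.

What the generator does **not** emulate: raw two-colour intensities and
dye effects, CpG-density-dependent MeDIP affinity, spatial correlation of
calls along a region, and array-specific probe spacing. Passing the
recovery tests therefore demonstrates correctness of the inference chain
under its own assumptions, not performance on any particular array.

`simulate_phenotypes()` adds group-structured quantitative variables with
optional linear coupling to $Pi_{age}$ or $Pi_{cloning}$ and Gaussian
noise; fatty-acid percentage variables are renormalized to sum to 100
within each lipid fraction, as compositional data must.

The packaged lesion-score fixture (`load_lesion_fixture()`) transcribes
the cohort's graded histopathology: 36 animals, of which 30 carry complete
seven-variable scores, using the ordered severity codes of
`lesion_vocabulary()`.

## Multiple correspondence analysis and category merging

`mca()` is correspondence analysis of the complete disjunctive (indicator)
matrix: total inertia $J/Q - 1$ for $J$ observed categories over $Q$
variables, variance percentages as raw eigenvalue shares. Adjusted
(Benzécri-type) inertia corrections are deliberately not applied; raw
shares are what common MCA implementations report by default and what the
packaged cohort's 35% first-dimension figure corresponds to.

Categories observed in fewer than four individuals would dominate axes
through their rarity, so `merge_rare_categories()` merges them first. The
merge direction was a genuinely open choice. The rule adopted here: a rare
category joins its **next-higher** observed severity neighbour, falling
back to the next-lower one only at the top of the scale, iterating until
all observed categories have at least `min_count` individuals. This keeps
rare pathological grades together (focal + diffuse steatosis become
"S1S2"; anisocytosis grades become "C1C2") instead of diluting them into
the "absent" baseline, and it reproduces the merged category labels under
which the cohort's MCA is interpretable. Unobserved categories contribute
no indicator column — correspondence analysis is defined on observed
categories — so a merge list naming an unobserved grade is a no-op. A
variable that collapses to a single category is dropped with a warning.

## Rank PCA and multiple factor analysis

`rank_pca()` converts each variable to average-tie ranks and runs PCA on
the correlation matrix. Rank conversion homogenizes the skewed
distributions of fatty-acid percentages and makes the result invariant
under any strictly monotone transform of an input column — a property the
tests check directly. The standard fatty-acid input is built by
`fa_pca_variables()`: 13 core fatty acids × 2 lipid fractions, minus four
variables nearly collinear with retained partners, leaving 22.

`mfa()` implements multiple factor analysis: (1) centre and unit-scale
every variable; (2) separate PCA per set giving first eigenvalues
$\lambda_1^j$; (3) weight each variable of set $j$ by $1/\lambda_1^j$, so
every set's leading direction carries unit variance and no set dominates;
(4) global PCA of the weighted concatenation; (5) per-variable Pearson
correlations with the global dimensions; (6) the active-set coordinate on
dimension $s$ is $(1/\lambda_1^j) \sum_{k \in j} \mathrm{cor}^2(x_k, F_s)$
— these coordinates sum to $\lambda_s$ across sets and are bounded by 1;
(7) a categorical illustrative variable (the animal group) is projected as
$\eta^2$, the squared correlation ratio of the dimension scores against
its categories. $\eta^2$ was adopted as the contract for the illustrative
coordinate because it is bounded in [0, 1], equals 1 exactly when the
dimension separates the groups perfectly, and reduces to the squared
correlation for a two-level group — matching how "a coordinate close to 1"
is read on such plots. The `fa_mfa_variables()` builder assembles the
48-variable fatty-acid set (13 acids + 5 family totals + 6 ratios per
fraction).

Complete cases are taken per analysis, not globally, since each analysis
uses a different variable set and discarding an animal for one analysis
should not shrink another.

All ordinations orient each axis so its largest-magnitude loading (or
category coordinate) is positive, making output deterministic across
linear-algebra backends. Eigenvalues below `1e-12` relative to the leading
one are treated as numerical zeros.

`dim_correlations()` screens variables against a dimension with Pearson
correlation and an uncorrected two-sided t-test at α = 0.05 — axis scores
are continuous constructs, and the screen is descriptive, feeding
gene-list interpretation rather than confirmatory claims. Phenotype
against methylation-summary correlations use `spearman_corr()` (rank-based
with average ties and a t-approximation on n − 2 df), the appropriate
choice for small, non-Gaussian phenotype panels.

`group_ellipses()` returns 95% confidence ellipses of group **means**:
centroid, covariance divided by group size, scaled by the χ²(2) quantile.
They describe uncertainty of the centroid, not the spread of individuals.

## Permutation tests

`perm_test()` uses the difference of group means — the standard two-sample
permutation statistic, equivalent to the group-sum statistic — two-sided.
With at most `exact_limit` (default 200,000) label assignments the null
distribution is enumerated exhaustively and the p-value is exact;
otherwise Monte-Carlo sampling (default 100,000 permutations) with the
add-one estimator $(1 + \#\{|t^*| \ge |t|\})/(B + 1)$, which never returns
zero. Comparisons use a small relative tolerance so that exact ties in
the permutation distribution count as extreme, which keeps the test valid
(slightly conservative) under ties. `stratified_perm_test()` permutes
labels only within strata (e.g. pre/postnatal stage), preserving stratum
margins; with one stratum it reduces exactly to the plain test, and with
per-stratum enumeration feasible it combines the per-stratum assignment
sums exhaustively.

## Problem sizes used in the validation suite

The test suite and the end-to-end pipeline run at the cohort's own scale:
26 animals, 500 regions of 20 probes for recovery checks (sensitivity ≥
0.8 and false-discovery proportion ≤ 0.1 per class at BH α = 0.05), 2,000
simulated null datasets of 6 + 6 for permutation calibration, and the
packaged 30-animal lesion table for the MCA. These sizes were chosen to
match the study design; the region count is far below a full promoter
array (which has tens of thousands of regions) because the statistical
behaviour being verified — per-region tests and per-family FDR — is
invariant to the number of regions beyond Monte-Carlo noise.

## Known limitations

* The probe-independence working likelihood ignores spatial correlation;
  on real arrays an overdispersion correction would be prudent.
* Enrichment calling from replicate log-ratios is a thresholded mean, not
  a re-implementation of any array vendor's scoring.
* No adjusted MCA inertia, no MFA partial-individual representations, and
  no plotting: results are coordinates, eigenvalues and ellipse
  parameters.
* The generator's defaults are plausible for a promoter tiling design but
  are not calibrated to any specific array layout.
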