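---
title: "Methods: familial clustering inference in population genealogies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: familial clustering inference in population genealogies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`famclust` implements a familial-clustering inference stack for rare
phenotypes in multigenerational genealogies: exact Malécot kinship, the
Genealogical Index of Familiality (GIF) with matched-control resampling,
cohort-rate relative risks in first- to third-degree relatives, and a
founder-pedigree excess-case scan. This vignette records the models, the
tunable parameters, the numerical choices, and the design decisions taken
where the methodology left genuine latitude — together with what the
synthetic-data calibration does and does not demonstrate.

```{r setup}
library(famclust)
```

## The genealogy model

A genealogy is a directed acyclic parent-link graph. Each individual
carries id, optional father/mother ids, sex (`M`/`F`), an integer birth
year, a categorical birth place and an affection flag. Validation
enforces unique ids, resolvable parent links, male fathers and female
mothers, children born strictly after both parents, and acyclicity.
Sex is required rather than imputed because control matching needs it; a
row with unknown sex is a parse error, not a guess.

**Genealogical informativeness.** Analyses of rare phenotypes in linked
genealogies conventionally restrict to cases embedded in at least three
generations of data. We operationalize this with a *complete ancestral
depth*: depth 0 means no (or only one) recorded parent, and depth
$k$ means both parents are recorded and each has depth $\ge k-1$. A
single recorded parent terminates the lineage — the paper trail is
incomplete, so the generation does not count as fully recorded. "Three
generations" counts the individual's own generation (self + parents +
grandparents, i.e. depth $\ge 2$), the usual genealogical reading;
`informative_cases(g, min_generations, count_self = FALSE)` selects the
stricter purely-ancestral reading instead.

## Kinship and genetic distance

Kinship is computed two independent ways that cross-check each other in
the test suite:

* a memoized pairwise recursion, recursing on the individual with the
  larger generation number (which can never be an ancestor of the other),
  and
* a vectorized full-matrix recurrence in parents-before-children order
  (each row is the half-sum of the parental rows), $O(n^2)$ time and
  memory, used by the batch and resampling paths.

Both handle inbreeding loops exactly — self-kinship exceeds $1/2$ for
inbred individuals — which is the conservative superset of behaviours a
population genealogy can require. A third, implementation-independent
oracle, `gene_drop_kinship()`, transmits uniquely labelled founder
alleles down the pedigree and estimates $\varphi$ as an identity-by-descent
frequency; the suite requires agreement within three binomial standard
errors on randomized pedigrees.

Genetic distance is the minimum meiosis count over valid genealogical
paths (ascend from each individual to a common ancestor); paths through
spouses or shared descendants do not relate individuals. Unrelated pairs
get an explicit `Inf`, never a sentinel integer. The batch form uses the
recurrence $D_{i\cdot} = \min(D_{f_i\cdot}, D_{m_i\cdot}) + 1$ in
parents-before-children order, which the suite checks against a pairwise
ancestor-map search.

## The GIF test

The GIF of a case set is $10^5$ times the mean pairwise kinship over all
unordered case pairs. The $10^5$ scale is the convention in the
genealogy literature (population-scale values land around 1–10); it is
exposed as the `scale` argument so raw mean kinship is recoverable.

Significance is purely empirical, as in the GIF literature — no
asymptotic null is attempted. Control sets are sampled per case,
uniformly within the case's matching stratum: same sex, birth year
within ±5 years (`birth_year_window`), same birth place, and the same
informativeness status. Matching on informativeness is on by default
because cases are conventionally drawn from the informative subset;
whether reference analyses also match on it is not documented, so it is
a switch in `matching_spec()`. Within a set controls are drawn without
replacement; across sets independently; cases are never eligible. Each
set consumes a substream seeded `seed + s`, so results do not depend on
evaluation order.

The empirical p uses the add-one rule $p = (1+b)/(1+n)$, never exactly
zero; with 1,000 sets the smallest attainable value is $1/1001 \approx
0.001$, so a reported $p = 0.002$ corresponds to a single exceedance.

**dGIF.** The distant GIF zeroes the kinship of pairs closer than
`min_distance` meioses while keeping the pair count in the denominator,
so GIF and dGIF share a scale and dGIF $\le$ GIF always. The cutoff is
not standardized across analyses; the default 3 excludes
parent–offspring, sibling and grandparent–grandchild pairs, the usual
reading of "close relatives". The per-distance
decomposition assigns each pair's kinship to its distance bin; unrelated
pairs have zero kinship and no bin, so the bins sum to the GIF exactly
(asserted to $10^{-9}$ relative tolerance).

## Relative risks in relatives

Cohorts are sex × 5-year birth interval × binarized birth place. Bins
are anchored at years divisible by 5 (configurable `anchor`); the
anchoring is a free convention and only shifts cohort
boundaries. Rates divide cohort cases by cohort individuals over the
*full* population — cases are not removed from denominators, keeping
the rate an unconditional incidence proportion.

Relative sets follow standard genetic degrees: degree 1 = parents,
offspring, full siblings; degree 2 = grandparents, grandchildren, full
aunts/uncles, nieces/nephews, half-siblings; degree 3 =
great-grandparents, great-grandchildren, first cousins,
half-aunts/uncles, half-nieces/nephews, grand-aunts/uncles,
grand-nieces/nephews. A relative reachable at several degrees (possible
under inbreeding) is counted once at the lowest; the union over cases is
deduplicated, but other cases are *not* excluded from relative sets or
denominators (no exclusion rule is documented; this is the simple,
stated choice). Observed counts affected individuals in the union;
expected sums their cohort rates; RR = observed / expected; significance
is the one-tailed Poisson upper tail.

**Confidence intervals.** Intervals invert small-sample one-sided
Poisson tests of $H_0: \mathrm{RR} = r$ (observed $\sim$
Poisson$(rE)$). The default mid-P flavor puts half weight on the
observed outcome, yielding intervals never wider than the conservative
exact (Garwood) inversion, which is available via `flavor = "exact"`.
The exact flavor has closed-form gamma-quantile bounds; mid-P bounds are
found by monotone root-finding to $10^{-6}$ on the Poisson-mean scale.
Mid-P inversion trades guaranteed $\ge 95\%$ coverage for near-nominal
average coverage; the acceptance suite verifies $\ge 93\%$ empirical
coverage at the 95% level across RR $\in \{0.5, 1, 5\}$.

## High-risk pedigree scan

"Common ancestor" is operationalized as genealogy *founders*
(individuals with no recorded parents), matching the practice of
labelling pedigrees by founder; intermediate-ancestor pedigrees are
derivable but not emitted. A founder couple necessarily yields two
pedigrees with identical descendant sets; `founder_pedigrees()` emits
both (documenting the overlap semantics) and `high_risk_scan()`
deduplicates by descendant-set identity, keeping the earlier-born
founder. Observed counts are cases among *strict* descendants, so an
affected founder does not count toward its own pedigree — the one corner
where a related case cluster can escape every founder pedigree.

Each pedigree's expected count sums cohort rates over all descendants;
p is the same `poisson_upper_p()` used for relative risks (asserted
identical, single source of truth). No multiplicity correction is
applied, deliberately: the scan is a sensitivity-first screen for
families worth follow-up, and the discrete Poisson test already has
per-pedigree type-I error $\le \alpha$. A pedigree with expected 0 but
observed cases is flagged with a warning and the smallest representable
p rather than crashing a whole scan.

## The synthetic genealogy generator

`simulate_genealogy()` produces non-overlapping generations: founders
with normally scattered birth years (mean `birth_year_start`, sd 5),
random 1:1-expectation sexes and iid in-state births
(`p_in_state`, default 0.8); each later generation pairs the previous
one by random assortment, avoiding full- and half-sibling unions, with
immigrant spouses (fresh founders) absorbing both the configured
`immigration_rate` and any pairing shortfall, so pairing never fails.
Couples draw Poisson(`mean_offspring`) children; child birth years are
the parental midpoint plus a noisy generation gap (mean
`generation_gap_years` = 28, never less than 16 years after either
parent). The defaults (65 founders, 5 generations, mean 3 offspring,
20% immigration) give genealogies of roughly 2,000 individuals in which
every close relationship class through second cousins arises — the
smallest structure that exercises the full distance decomposition.

What it deliberately does not emulate: overlapping generations,
mortality, demographic history, assortative or geographically structured
mating, and ascertainment. Passing calibration on these simulations
shows the inference machinery is correct and calibrated under clean
exchangeability — not that any real population satisfies it.

Three phenotype models sit on top, all seeded independently of the
structure so phenotype redraws never perturb the genealogy:

* **Null** — every individual affected independently at its (scalar or
  cohort) rate. Under it the GIF empirical p is approximately uniform;
  the acceptance suite requires a rejection rate at $\alpha = 0.05$
  within $[0.02, 0.09]$ across 200 simulated genealogies (binomial
  99% bounds around 0.05).
* **Carrier transmission** (`assign_phenotypes_clustered()`) — a
  fraction of founders carry a dominant-style risk factor transmitted to
  each child with probability 0.5 per carrier parent; carriers' baseline
  rate is multiplied by `familial_multiplier`. This produces vertical
  (parent–offspring, avuncular) excess and is the alternative the GIF
  power checks run against. It is a clustering mechanism, not a claim
  about any disease's biology. Note the realized relative risk among
  relatives is far below the multiplier: the multiplier also inflates
  population rates and only a minority of cases are carriers, so e.g.
  multiplier 13 yields degree-1 RRs around 2–4.
* **Calibrated direct injection** (`assign_phenotypes_familial_rr()`) —
  the generator for parameter-recovery testing, whose parameter *is* the
  degree-1 RR the standard estimator should recover. Baseline probands
  are drawn at rate $\lambda$; each first-degree relative of a proband
  receives an extra affection draw with probability $(m'-1)\lambda$.
  Calibration of $m'$ accounts for three desk-scale effects: (i) the
  symmetric elevation makes the pairwise enrichment $2m'-1$, (ii) the
  excess cases inflate the population rates by the factor
  $1 + \bar r (m'-1)\lambda$ (with $\bar r$ the genealogy's mean
  first-degree family size), entering expected counts squared, and
  (iii) each affected relative inflates its own finite cohort's realized
  rate, scaling expected counts by about $1/(1 - \mathrm{rr}\,h)$ with
  $h$ the mean reciprocal cohort size. $m'$ solves
  $(2m'-1)(1-\mathrm{rr}\,h) = \mathrm{rr}\,(1+\bar r(m'-1)\lambda)^2$.
  Effects (ii) and (iii) vanish as the genealogy grows. Recovery is
  measured by pooling observed and expected over replicates (ratio of
  sums) — averaging per-replicate ratios with expected counts near 1 is
  dominated by denominator noise.

## Problem sizes and reproducibility

The calibration experiments use genealogies of roughly 2,000 individuals
(200 null replicates, 200 control sets each, phenotype rate 0.8%);
power runs use ~3,000 individuals with baseline rate 1.5% so the
informative case sets carry 30+ cases; RR-recovery runs use ~8,000
individuals at baseline 0.4% (200 replicates), where no kinship matrices
are needed. These sizes keep each relationship class populated while the
whole suite stays desk-scale. In the matched-control experiments a
replicate is dropped when some case's stratum contains no eligible
control — a sparse-stratum artifact of small simulated populations that
cannot arise at population scale; the suite asserts such drops stay
rare (under 10%).

All randomness flows through explicit integer seeds; simulation,
phenotype assignment and control sampling each take their own seed, and
`gif_test()` derives one substream per control set. Rerunning any
function with the same inputs and seed is bit-reproducible, and the RNG
state of the calling session is always restored.

## Known limitations

* Kinship and distance matrices are dense $O(n^2)$; genealogies beyond a
  few tens of thousands of individuals need a sparse or per-pair
  strategy (the pairwise recursion remains available).
* Founder-rooted pedigrees only; clusters joined solely through an
  affected common ancestor are not scanned (strict-descendant
  semantics).
* No person-years or age-at-risk adjustment and no competing risks;
  cohort rates are lifetime proportions.
* The simulator's exchangeable, non-overlapping-generation population is
  a calibration instrument, not a demographic model.
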