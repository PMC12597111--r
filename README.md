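# famclust

Familial clustering analysis of a rare phenotype in population
genealogies.

Some diseases run in families. Given a multigenerational genealogy (a
table of individuals with father/mother links, sex, birth year and birth
place) and a list of affected individuals, `famclust` asks whether the
cases are more related to each other than chance predicts, how much the
risk is elevated among their close relatives, and which families carry a
significant excess of cases. It is aimed at genetic epidemiologists
working with linked genealogy–registry resources, and ships a forward-time
genealogy simulator so every stage of the pipeline can be exercised and
calibrated without access to protected population data.

## The statistics

**Malécot kinship.** For individuals $i,j$, the kinship coefficient
$\varphi(i,j)$ is the probability that one gene sampled from each is
identical by descent. It is computed exactly by the standard pedigree
recursion ($\varphi(i,i) = \tfrac12(1+\varphi(f_i,m_i))$, and
$\varphi(i,j) = \tfrac12(\varphi(f_i,j)+\varphi(m_i,j))$ recursing on the
non-ancestor), with a gene-dropping Monte Carlo oracle for verification.

**GIF (Genealogical Index of Familiality).** For a case set $C$,

$$\mathrm{GIF}(C) = 10^5 \cdot \binom{|C|}{2}^{-1}
  \sum_{\{i,j\}\subset C}\varphi(i,j).$$

Significance is empirical: the case GIF is compared with the GIFs of
matched control sets (controls matched to cases on sex, birth year within
±5 years, birth place and genealogical informativeness), with
$p = (1+b)/(1+n_{\text{sets}})$ where $b$ counts control sets at or above
the case statistic. The dGIF repeats the test with pairs closer than a
meiotic distance cutoff (default 3) contributing zero, isolating distant
aggregation, and the GIF sum is also decomposed by pairwise genetic
distance (1 = parent–offspring, 2 = sibling/grandparent, 3 = avuncular,
4 = first cousin, 6 = second cousin).

**Familial relative risks.** The population is stratified into cohorts by
sex × 5-year birth interval × birth place; each cohort's incidence is
cases over individuals. For first-, second- and third-degree relatives of
the cases (unioned without duplication), RR = observed / expected, where
expected sums the relatives' cohort rates. One-tailed significance uses
the Poisson upper tail, and confidence intervals invert small-sample
Poisson tests (mid-P by default, Garwood-exact optional).

**High-risk pedigrees.** Every genealogy founder whose descendants include
at least two cases defines a founder pedigree; its expected case count
sums the descendants' cohort rates and $P(X \ge \text{obs})$,
$X\sim\text{Poisson}(\text{exp})$, flags pedigrees with a significant
excess (no multiplicity correction, by design — the scan prioritizes
sensitivity).

## Worked example

The package ships a 40-person, five-generation pedigree with four affected
descendants of one founding couple. Embedded in a simulated background
population, the full pipeline runs in a few seconds:

```r
library(famclust)

fam <- read_pedigree(system.file("extdata", "high_risk_pedigree.tsv",
                                 package = "famclust"))
bg  <- simulate_genealogy(sim_params(n_founders = 40), seed = 2024)
g   <- genealogy(rbind(fam$df, bg$df))     # 995 individuals
cases <- g$df$id[g$df$affected]

gif_test(g, cases, spec = matching_spec(match_on = c("sex", "birth_year")),
         n_sets = 1000, seed = 1)
#> GIF test (4 cases, 1000 matched control sets)
#>   case GIF  9375   mean control GIF  1067   p = 0.004
#>   case dGIF 5208   mean control dGIF 483   p = 0.00599  (distance >= 3)
#>   contributions by genetic distance (case / mean control):
#>     d=1: 4167 / 325
#>     d=2: 0 / 258
#>     d=3: 3125 / 229
#>     d=4: 2083 / 254

head(high_risk_scan(g, cases), 2)
#>   founder n_descendants observed  expected           p high_risk
#> 1     P01             9        3 0.3500000 0.005508933      TRUE
#> 2     F01            21        4 0.7769231 0.008222873      TRUE
```

The four cases are ~9× more related than the average matched control set
(GIF 9375 vs 1067, empirical p = 0.004), the excess sits at genetic
distances 1 and 3 (a parent–offspring and two avuncular pairs — none of
the affected pairs are siblings), and the scan flags the founding couple's
pedigree (4 observed vs 0.78 expected) as high risk. Founder `P01`, a
married-in spouse, roots a tighter sub-pedigree with 3 of the same cases
and an even smaller p — founder pedigrees may overlap by design.

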