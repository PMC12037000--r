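---
title: "Measuring biobank impact: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring biobank impact: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifkit)
```

Biobanks — repositories of human biological samples linked to health and
lifestyle data — are foundational infrastructure for genetic epidemiology
and population health, yet citation counts systematically understate
their influence: many papers that use a biobank never cite its flagship
publications. bifkit quantifies biobank impact from *textual mentions*
across five document classes (research publications, grants, patents,
clinical trials and public policy documents), and provides the
surrounding accounting: hidden citations, scientific reach, locality,
coauthorship-for-access, disease-category structure, funding alignment
and a feature regression. This vignette records the models, the tunable
parameters and the design decisions behind them.

## The corpus data model

All analyses consume one container, the `bif_corpus`: five tables
(documents, mentions, citations, biobanks, funding) plus a reference
year. Tables travel as CSV with a `|` separator inside list-valued cells
(documents may alternatively be JSONL, which carries the nested
affiliation and MeSH fields natively). Referential integrity is enforced
at load time: every mention and citation endpoint must resolve, document
types come from the closed five-set, PI rosters must be contained in team
rosters, and each biobank must carry a complete vector of the fourteen
features. Duplicate mention pairs are collapsed with a warning rather
than rejected, because upstream mention-extraction pipelines commonly
emit duplicates. Country codes are treated as opaque exact-match strings
(ISO 3166-1 alpha-2 by convention); no entity resolution is attempted.

## The Biobank Impact Factor

Research impact standardizes each biobank's mention count per document
type against the scored cohort:

$$R = \sum_{i=1}^{5} \mathrm{clip}_{[-1,1]}\!\left(\frac{r_i - \mu_i}{\sigma_i}\right),$$

where $r_i$ is the count of distinct documents of type $i$ mentioning the
biobank and $\mu_i,\sigma_i$ are the cohort mean and (sample) SD for that
type. Two numerical choices deserve note:

* "normalized at $[-1,1]$" is implemented as **clipping** the z-score,
  not min–max rescaling. Clipping makes $R = 5$ mean per-type saturation
  ("exceptional visibility in every sector"), which is how the scale's
  anchor is described; min–max would let a single extreme biobank
  compress everyone else toward zero.
* a document type with zero spread across the cohort contributes exactly
  0 for every biobank, rather than producing 0/0.

Disease impact sums three components, each z-standardized across the
cohort and clipped the same way: **scope** (number of distinct MeSH
conditions on the biobank's mentioning publications), **depth** (mean,
over those conditions, of the biobank's share of all corpus publications
on the condition) and **rare** (the biobank's share of all rare-condition
publications), so $D = D_{scope} + D_{depth} + D_{rare} \in [-3, 3]$.
The z-then-clip normalization mirrors the $R$ components because each
disease measure is likewise defined to contribute a score in $[-1,1]$;
the raw component definitions are deliberately simple (distinct-condition
counts and publication shares) and multi-label: a publication tagged with
three conditions counts once toward each. When no rare-condition list is
supplied the rare component is zero for everyone, with a warning.

The final score is age-normalized:

$$\mathrm{bIF} = \frac{1}{Y}\,(0.9\,R + 0.1\,D),$$

so a one-year-old biobank at maximal $R=5$ and $D=3$ scores
$0.9\cdot5 + 0.1\cdot3 = 4.8$, and bIF always lies in $[-4.8/Y, 4.8/Y]$.
Age is $Y = \text{reference year} - \text{establishment year}$, floored
at 1 to keep newly established biobanks finite. The weights are exposed
(`compute_bif(..., weights =)`) so that sensitivity analyses are a
one-liner; at weights $(1,0)$ the ranking provably equals the ranking by
$R/Y$. Scoring is restricted to biobanks with at least 20 mentioning
publications by default; that scored set is also the standardization
cohort for $\mu_i, \sigma_i$ (computing the cohort moments after the
cutoff keeps the score self-contained in the published set; the
alternative — moments over all biobanks — is not exposed because the two
differ only through biobanks that are never reported).

## Hidden citations, reach, locality, coauthorship

A **hidden citation** is a publication that mentions a biobank but cites
none of its designated reference papers. The analysis is restricted to
publications (grants, patents, trials and policy documents have no
comparable citation convention), and a biobank without reference papers
is *excluded* — an explicitly distinct signal from a hidden rate of
zero. **Reach** is the number of unique documents citing at least one
mentioning publication. **Locality** attributes a publication to the
host country/institution if *any* author affiliation matches
(fractional author counting is a plausible alternative; the any-author
rule is the simplest defensible reading and the one implemented).
**Coauthorship-for-access** reports the share of mentioning publications
listing a team member, a PI, and a non-PI team member without any PI.

The locality null model permutes the biobank labels over the mention
table's rows. This is exactly a degree-preserving rewiring of the
bipartite document–biobank mention graph: each biobank keeps its mention
count and each document keeps its mention slots, and the invariant is
asserted at every iteration. Significance uses the add-one-corrected
empirical p-value $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$,
which is never zero and uniform under exchangeability.

## Cocitation network and disease alignment

Two biobanks are cocited when one third-party article cites publications
mentioning each of them; each such article adds 1 to the pair's edge
weight, and edges below `min_weight` (default 2) are dropped —
"frequently cited together" is operationalized as a weight threshold
since no specific value is canonical. Communities are found by Louvain
modularity maximization under a fixed seed; the contract is determinism
under seed plus a reported modularity, not a specific algorithm.
Alignment between communities and principal disease categories is
normalized mutual information from the contingency table,
$\mathrm{NMI} = I(X;Y)/\sqrt{H(X)H(Y)}$ by default (the arithmetic-mean
normalization is available and matches igraph's implementation). The
doubly degenerate case — one community and one category — is defined as
1. A biobank's principal category is its largest multi-label publication
count, ties broken lexicographically, `"general-purpose"` when it has no
disease-tagged publications.

## Funding alignment

Publication output per RCDC funding category is regressed on mean annual
funding by ordinary least squares on raw (unlogged) scales, reporting
Pearson's r; each category's representation is then the residual as a
percentage of expectation, $100(\text{actual} -
\text{expected})/\text{expected}$, positive for overrepresented
categories. Values are kept unrounded internally and rounded to integer
percent only for display.

## The feature regression

The relation between bIF and fourteen biobank characteristics (cohort
size class, open-data class, PI prestige class, population/hospital
based, four genetic-data flags, registries, surveys, follow-up, medical
records, general purpose) is modelled as a Gaussian GLM on the
log-transformed response, $\log(\mathrm{bIF}+1) = \beta_0 + \sum_k
\beta_k X_k + \epsilon$ — read literally from the additive-error form of
the model; a Gamma GLM was considered and rejected because bIF can be
negative. Covariates enter as binary indicators (the cohort-size and
PI-prestige covariates as top-decile flags). The fourteen feature
p-values are Bonferroni corrected ($\min(1, 14p)$); rows with
$\mathrm{bIF} \le -1$ are dropped with a warning; rank-deficient designs
raise an error naming the collinear columns. Diagnostics report
deviance and Pearson chi-square (identical for a Gaussian fit) both raw
and per residual degree of freedom.

## The synthetic corpus generator

The generator is the package's measurement bench: it plants every
parameter the estimators later recover, and ships the plants in a truth
record.

* **Mention volumes**: per-biobank total intensity is log-normal
  (default location $\log 60$, scale 1) — a two-parameter heavy-tailed
  law with finite moments that reproduces the qualitative skew of real
  mention counts; realized counts are Poisson around the intensity and
  split across the five document types with a publication-dominated mix
  (84.2/6.0/5.7/0.7/3.5%, echoing the composition of large mention
  corpora).
* **Hidden citations**: each biobank gets 1–3 reference papers (flagship
  publications by its PIs, matching the roughly two-per-biobank density
  of real reference-paper registries); each mentioning publication cites
  one with probability $1-h$ (default $h = 0.412$).
* **Locality**: one lead affiliation per mentioning publication is the
  host institution with probability 0.294, elsewhere in the host country
  with probability $0.735 - 0.294$, foreign otherwise, so the national
  share recovers the planted home bias directly.
* **Coauthorship**: per-biobank team-coauthorship probabilities come
  from a two-component mixture (means 0.05 and 0.95, weights 0.4/0.6),
  reproducing the strongly bimodal either-almost-never-or-almost-always
  pattern of team coauthorship, with mean share near 0.6. Half of the
  team-coauthor events involve a PI, keeping PI share below team share.
* **Disease structure**: each biobank has a Dirichlet category profile
  (20 categories, concentration 0.3 — focused biobanks) from which its
  publications draw conditions; a fixed tail of each category's
  condition pool is flagged rare.
* **Funding**: per-RCDC-category tag counts are
  $\max(0,\mathrm{round}(s f_c + \mathcal N(0,\sigma)))$ with default
  slope $s = 2.5\times10^{-8}$ pubs/USD over 20 categories funded
  between \$0.5B and \$12.8B/yr, so the OLS slope of actual counts on
  funding is the planted slope by construction.
* **Background citers**: third-party papers cite mentioning
  publications, preferring biobanks that share a focal disease category
  70% of the time; this makes reach non-trivial and gives the cocitation
  network community structure correlated with disease categories.

What the generator does **not** emulate: temporal dynamics (mention
counts do not grow with biobank age), author-level disambiguation noise,
multi-biobank papers beyond what random citation overlap produces, and
any calibration to a specific real dataset's exact distributions. A pass
on synthetic corpora therefore demonstrates estimator correctness under
the planted mechanism, not distributional fidelity to any particular
observed corpus.

## Problem sizes and determinism

The validation suite runs the estimators at the scale where their
sampling error is well inside the claimed tolerances: hidden-rate
recovery on corpora of roughly 9,000 mentioning publications (binomial
SE ≈ 0.005 against a ±0.02 band), home-bias recovery on ~1,200
publications (SE ≈ 0.013 against ±0.04), permutation tests at 199–999
iterations, and feature-model calibration over 200 replicate studies of
500 biobanks. Oracle-equivalence checks run brute-force enumeration
against 100 randomized 10-biobank corpora. All stochastic code paths
(generator, community detection, permutation null) take explicit integer
seeds and restore the caller's RNG state, so identical seeds give
byte-identical outputs end to end.

## Known limitations

* Mentions are consumed as given; extracting them from text, resolving
  biobank name variants and disambiguating authors are out of scope.
* The disease components use one fixed raw definition each; percentile
  or coverage-weighted variants would slot into the same standardization
  but are not implemented.
* The funding regression is a two-variable OLS on category aggregates;
  it describes alignment, not causation, and log-scale variants are not
  implemented.
* NMI between communities and categories is reported without a
  degree-corrected null; values should be compared between corpora, not
  read as absolute alignment.
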