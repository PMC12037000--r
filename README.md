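# bifkit

Quantifying the research footprint of biobanks from mention corpora.

Biobanks — cohort studies, registries, tissue and data banks — underpin
much of modern biomedical research, but citation counts badly
understate their influence: a large fraction of the papers that use a
biobank never cite its flagship publications. bifkit measures biobank
impact from *textual mentions* across five document classes
(publications, grants, patents, clinical trials, public policy
documents) and provides the full accounting around that idea, for
bibliometricians, funders and biobank operators working with tabular
scientometric corpora.

## What it computes

**The Biobank Impact Factor (bIF).** Research impact standardizes each
biobank's mention count per document type across the scored cohort and
clips each score to [−1, 1]:

    R = Σ_{i=1..5} clip( (r_i − μ_i) / σ_i )          R ∈ [−5, 5]

Disease impact sums three cohort-standardized, clipped components —
scope (distinct conditions studied), depth (share of each condition's
literature) and rare-disease share:

    D = D_scope + D_depth + D_rare                     D ∈ [−3, 3]

and the final score is age-normalized,

    bIF = (0.9·R + 0.1·D) / Y,

so a one-year-old biobank at maximal components scores
0.9·5 + 0.1·3 = **4.8**, the maximum impact score, and bIF always lies
in [−4.8/Y, 4.8/Y].

**Around it:** hidden-citation rates (mentioning papers citing none of
the biobank's reference papers) and scientific reach (unique papers
citing the mentioning papers); locality shares with a count-preserving
permutation null; coauthorship-for-access statistics; the biobank
cocitation network with Louvain communities and NMI against disease
categories; OLS funding-representation residuals; a Gaussian GLM of
log(bIF+1) on fourteen biobank features with Bonferroni correction; and
a synthetic corpus generator that plants every parameter these
estimators recover.

## Worked example

```r
library(bifkit)

gen    <- generate_corpus(generator_config(n_biobanks = 50), seed = 42)
corpus <- gen$corpus
corpus
#> <bif_corpus>
#>   documents : 6435 (publication=5874, grant=224, patent=192, clinical_trial=16, policy=129)
#>   mentions  : 3769
#>   citations : 8307
#>   biobanks  : 50
#>   funding   : 20 categories
#>   reference year: 2024

scores <- rank_biobanks(corpus, min_publications = 20)
head(as.data.frame(scores)[, c("biobank_id", "publication", "grant", "R", "D", "Y", "bIF")], 5)
#>   biobank_id publication grant        R        D  Y       bIF
#> 1      BB023         202    17 3.380871 2.000000 10 0.3242784
#> 2      BB017         171    10 4.396424 2.000000 15 0.2771188
#> 3      BB032         133     9 2.513387 1.976572  9 0.2733006
#> 4      BB010         138    14 5.000000 1.992653 20 0.2349633
#> 5      BB035          90     5 1.380403 1.078632 11 0.1227478
```

BB023 leads despite BB010's saturated research impact (R = 5, clipped at
the per-type bound) because bIF divides by age: BB010 is twice as old.
The corpus was generated with a hidden-citation rate of 0.412 and a
national home bias of 0.735; the estimators recover both:

```r
hidden <- hidden_citation_table(corpus)
weighted.mean(hidden$hidden_rate, hidden$n_mentioning)
#> [1] 0.417                                  # planted 0.412
mean_locality_share(corpus, "national")
#> [1] 0.74                                   # planted 0.735

fit <- funding_regression(corpus$funding, rcdc_actual_pubs(corpus))
c(r = fit$pearson_r, slope = fit$slope)
#>            r        slope
#> 0.9891208829 0.0000000247                   # planted slope 2.5e-08
subset(fit$table, rcdc_category == "RCDC_01")[, c("actual_pubs", "expected_pubs", "surplus_percent")]
#>   actual_pubs expected_pubs surplus_percent
#> 1          19      15.25714        24.53184
```

The surplus column is the representation residual,
100·(actual − expected)/expected: category RCDC_01 has ~25% more
publications than its funding predicts. The cocitation network ties it
together:

```r
g      <- build_cocitation(corpus, min_weight = 2)
part   <- detect_communities(g, seed = 7)
labels <- setNames(igraph::V(g)$category, igraph::V(g)$name)
c(edges = igraph::ecount(g), modularity = part$modularity,
  NMI = partition_nmi(part, labels))
#>      edges modularity        NMI
#>    500.000      0.285      0.744
```

Communities here align strongly with planted disease categories
(NMI 0.744) because the generator's background citers are
category-biased; on real corpora the alignment is typically much
weaker, which is exactly what the NMI quantifies.

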