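# vetlink

Anonymous record linkage and usage stratification for veteran charity
service registries.

UK veterans are assisted by a fragmented charity sector: the same
person is often helped by several organizations, and several charities
frequently co-fund a single case ("almonisation"), so naive
concatenation of provider extracts both double-counts people and
inflates usage. `vetlink` is for epidemiologists and service
researchers building an aggregated registry from such extracts without
any provider disclosing identities. It provides:

* **Salted-hash pseudonymization** — the person key is
  `sha256(service_number | date_of_birth | gender | salt)`, a
  64-hex-digit digest that is equal across providers exactly when the
  person is the same (given a shared salt) and is dictionary-attack
  resistant given the salt. Identifying fields are canonicalized first
  (case, whitespace, date dialect, gender spelling) and removed after
  hashing.
* **Harmonization and deduplication** — a *need* is one (person,
  category, year) triple: the same need contributed by several
  charities collapses to one record. Attributes resolve by a
  last-declared rule (missing never beats present), people recorded as
  both veteran and family member count as veterans, and age is
  completed years at the first recorded need, banded at 66.
* **A three-layer need taxonomy** — provider category → twelve Dual
  Diagnosis categories → the physical/mental/social pillars, shipped
  as validated, editable configuration.
* **Usage stratification** — per veteran: accesses *a* (distinct years
  helped), total needs *n*, and *m*, the maximum number of distinct
  years any single need category was met. Four a-priori strata: *a* =
  1, *n* = 1; *a* = 1, *n* ≥ 2; *a* ≥ 2 with a repeated need (*m* ≥
  2); *a* ≥ 2, all needs new (*m* = 1).
* **Cluster comparison** — z-scored (*a*, *n*, *m*) features, k-means
  (Lloyd with k-means++ seeding, 10 restarts) for k in 2..8, mean
  Euclidean silhouette to select k, and a contingency + adjusted Rand
  index comparison against the a-priori strata.
* **Descriptives** — frequency/percentage tables over non-missing
  denominators and Pearson chi-square subgroup comparisons.
* **A synthetic multi-charity generator** with known ground truth
  (true persons, planted strata, planted almonised duplicates,
  configurable missingness), so the whole pipeline is testable without
  confidential data.

## Worked example

```r
library(vetlink)

cfg <- pipeline_config(generator = generator_config(n_persons = 500, seed = 7))
result <- run_pipeline(cfg)           # simulate -> hash -> build -> stratify -> cluster -> report
result
#> pipeline: 500 persons, 844 needs, 110 almonised collapses | k = 4 , ARI = 1
```

500 true persons were split across five charities with overlapping
membership; linkage on the hashed identifier recovered exactly 500
people, and 110 cross-charity duplicates of single needs were collapsed
(844 distinct needs remain). Silhouette-based selection over the
z-scored usage features chose four clusters, and the k-means partition
corresponds exactly to the four a-priori strata:

```r
result$clusters
#> k-means usage clustering: k = 4 | ARI = 1 | exact stratum correspondence
#>                                 cluster
#> stratum                            1   2   3   4
#>   multiple_access_all_new_needs    0   0   0  29
#>   multiple_access_repeated_needs 150   0   0   0
#>   single_access_multiple_needs     0   0 165   0
#>   single_access_single_need        0 156   0   0

round(result$clusters$silhouette_by_k, 3)
#>     2     3     4
#> 0.708 0.905 1.000
```

An adjusted Rand index of 1 with a permutation-diagonal contingency
means the unsupervised clustering grouped every person the same way as
the a-priori rules. The population description (counts and percentages
over each variable's non-missing denominator):

```r
head(result$tables$table1, 8)
#>   variable       level                    count percent
#> 1 gender         F                           58    11.6
#> 2 gender         M                          442    88.4
#> 3 age_band       non_working                201    40.2
#> 4 age_band       working                    299    59.8
#> 5 rank           non_officer                356    98.6
#> 6 rank           officer                      5     1.4
#> 7 marital_status married_cohabiting_civil   190    38
#> 8 marital_status single_divorced_widowed    310    62
```

Passing an `out_dir` to `run_pipeline()` writes every stage artifact to
disk (per-charity extracts, registry CSVs, linkage report, usage
summaries, cluster report, the three tables, and a manifest with seeds
and file digests). See `vignette("registry-linkage")` for the model,
the design decisions, and what the synthetic tests do and do not
demonstrate.

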