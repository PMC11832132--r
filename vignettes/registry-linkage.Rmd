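---
title: "Anonymous linkage and usage stratification for charity service registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymous linkage and usage stratification for charity service registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vetlink)
```

## The problem

Assistance to UK veterans is split across a large charity sector in
which each organization counts service usage with its own definitions
and reporting systems. Two consequences follow. First, no single
extract describes the population: the same person may appear in several
charities' records. Second, usage is systematically over-counted,
because several charities often contribute financially to the
resolution of a single case ("almonisation") and each historically
recorded that case as a person helped.

`vetlink` implements a registry-building pipeline that addresses both
problems without any charity revealing identities: identifying fields
are replaced by a salted cryptographic pseudonym that is equal across
providers exactly when the underlying person is the same, records are
harmonized and deduplicated, and the resulting per-person usage
trajectories are stratified and clustered. Because real extracts are
confidential, the package ships a synthetic multi-charity generator
with known ground truth; every stage is tested against that truth.

## Anonymous identity

The person key is the SHA-256 digest of the canonicalized identifying
triple — service number, date of birth, gender — plus a salt:

```
hash = sha256("service_number|YYYY-MM-DD|gender|salt")
```

SHA-256 is the SHA-family digest that prints as exactly 64 hexadecimal
digits, which is the identifier width the registry uses. The field
order and `|` separator are arbitrary but must be fixed: any consistent
convention links correctly provided all providers use it, so the
package hard-codes one and documents it. Canonicalization
(`canonicalize_key()`) uppercases and de-whitespaces the service
number, renders the date ISO-8601 under an explicit per-provider date
dialect (`ymd`, `dmy` or `mdy`; no silent guessing), and maps gender
onto `{M, F, O}`. It is idempotent, so re-processing already-clean data
is safe.

The salt defeats dictionary attacks on the small identity space.
Hashing without a salt is refused outright. One design tension is
inherent: hashes from two providers link only if the providers use the
same salt, while a salt kept strictly per provider cannot link at all.
The package therefore models a *linkage domain*: a set of providers
sharing one salt under a data agreement. Per-provider salts are
supported (pass a different salt per extract) but are documented as
non-linking. Key-stretching (bcrypt, argon2) and fuzzy matching of
typo-ridden identities are out of scope.

After hashing, `strip_identifiers()` removes the identifying set from
the records. Date of birth is first converted to age at the event date
(completed whole years), so age remains derivable while the birth date
itself never leaves the hashing step. Gender is retained: it is a
reported exposure, and carries negligible re-identification risk once
the triple is gone.

## Needs, the taxonomy, and deduplication

The registry's statistic unit is a *need*: a request by a given person,
for a given reason, in a given year. Raw provider categories pass
through three aggregation layers:

1. the provider's own category vocabulary;
2. twelve Dual Diagnosis categories (`dd_categories()`);
3. three pillars of health — physical, mental, social.

The layer-2 to pillar assignment is an editorial judgement, not a
derivable fact, so it ships as editable configuration
(`default_pillar_map()`, YAML files via `read_taxonomy()`): mental
covers mental health, substance misuse and learning disability;
physical covers physical health and physical disability; the remaining
seven categories are social. Categories missing from a taxonomy map to
an explicit `unmapped` bucket and are counted, never silently dropped.
`validate_taxonomy()` reports unknown categories, categories assigned
to two pillars, and duplicate provider keys; the pipeline refuses to
run on a failing report.

Deduplication follows directly from the need definition: the same
hashed person, mapped category and calendar year is one need, however
many providers contributed it. `build_registry()` collapses on
`(hashed_id, layer-2 category, year)` by default and logs the collapse
count. Collapsing at layer 2 rather than the raw provider wording is
deliberate — two charities funding one case rarely word the category
identically — but `collapse_layer = "provider"` is available for
registries whose vocabularies are already shared. The collapse is
idempotent: rebuilding from an already-collapsed registry changes
nothing.

## Harmonizing person attributes

Attributes (gender, rank, marital status, service branch,
accommodation, benefits receipt, dependants) may be declared repeatedly
and inconsistently across records. Resolution rules:

* **Last declared wins** (`resolve_attribute()`), with the constraint
  that a missing value never beats a present one; the latest
  *non-missing* declaration is taken, and all-missing resolves to
  missing. Ties on the declaration date fall back to an optional
  priority and then input order, so resolution is otherwise
  order-independent.
* **Veteran precedence** (`resolve_role()`): a person recorded both as
  a veteran and as a family member is a veteran.
* **Age** is computed at the first recorded need, in completed whole
  years (day-before-birthday boundary handled exactly). The
  working-age band is `age < 66`, with 66 the state-pension boundary;
  both the threshold and, implicitly, the direction are configurable
  via `classify_age_band()`. We deliberately read "working age" as the
  *younger* side of 66 — the only direction consistent with ordinary
  usage and with a registry population described as predominantly
  working-age *and* younger than the veteran population at large.
* Persons are never dropped for missing attributes; each descriptive
  variable reports over its own non-missing denominator, which is why
  denominators differ visibly across variables.

## Usage patterns: the a-priori strata

Per person, `summarize_usage()` computes the number of accesses
(distinct calendar years with a need), the total needs (distinct
category-year pairs after collapse), and for each category the number
of distinct years it was met, summarized by its maximum. A *repeated
need* is a category met in a year strictly later than a year in which
it was already met — equivalently, the maximum is at least 2. Two
requests for the same category within one year are one need and no
repetition. The per-category year counts are a variable-length object;
the maximum is used because it is exactly the quantity that separates
repeated from all-new usage. (A mean-based summary would blur that
boundary; if needed it is a one-line change in `build_features()`.)

`classify_pattern()` assigns the four a-priori strata:

| accesses | needs | repetition | stratum |
|---|---|---|---|
| 1 | 1 | — | single access, single need |
| 1 | ≥ 2 | — | single access, multiple needs |
| ≥ 2 | any | yes | multiple access, repeated needs |
| ≥ 2 | any | no | multiple access, all new needs |

The rules are total and the four labels partition any population.

## Clustering and the number-of-clusters question

The unsupervised check asks whether plain k-means on the feature triple
(accesses, total needs, max years a single need was met) rediscovers
the four a-priori strata. The stage (`cluster_usage()`):

1. z-scores the features — unscaled, the needs count would dominate
   Euclidean distance by scale alone; constant columns map to 0 with a
   warning;
2. for each candidate k in 2..8 runs Lloyd's algorithm from 10
   independent k-means++ seedings, keeping the lowest-inertia solution;
3. computes each partition's mean Euclidean silhouette width and keeps
   the k with the largest mean silhouette (ties to the smallest k);
4. cross-tabulates clusters against strata, reporting the adjusted
   Rand index and an *exact correspondence* flag: the contingency is,
   up to column permutation, diagonal.

Candidate k values exceeding the number of distinct feature rows are
dropped before fitting: k-means is undefined with more centers than
distinct points (`stats::kmeans` refuses them), and a silhouette for
such a k would be meaningless. If all rows are identical the silhouette
itself is undefined and the stage stops with an error.

One divergence is worth naming. Commercial "two-step" auto-clustering
procedures select k with a likelihood-based criterion and report
silhouette as a quality measure; this package uses the silhouette
maximum itself as the selection rule, which is the stated criterion,
reproduces the qualitative finding, and avoids re-implementing a
proprietary procedure. BIC-based selection and model-based clustering
are non-goals.

All stochastic steps derive their seeds from one master seed (the
generator uses it directly, the extract split adds 1, the clustering
stage adds 1000), so every stage is individually reproducible.

## The synthetic generator: what it emulates, and what it does not

`generator_config()` defaults encode the registry conditions the
package is demonstrated under: five charities, the 2018–2023 window,
stratum mixture (29.4%, 30.8%, 33.0%, 6.8%), attribute marginals set to
the reported population percentages, and per-attribute missingness
equal to one minus each variable's reported denominator share (rank
28.4%, benefits 17.0%, accommodation 9.9%, dependants 16.3%). An
`overlap_rate` fraction of persons (default 20%, our choice; no
published value exists) appears in two charities, and each such person
gets one planted almonised duplicate — the same need contributed by
both, with independently drawn provider wording. A small share of
multi-record persons carries one `family`-tagged record to exercise the
precedence rule. Identity triples are drawn without replacement from a
10^8 ID space, so distinct persons cannot collide by key.

Trajectories are generated *constructively from the stratum
definitions* — years drawn first, then categories forced or forbidden
to repeat — so the a-priori classifier recovers the planted stratum for
100% of persons by construction. Each stratum is given its modal
characteristic trajectory: one year and one category; one year and two
categories; two years with the same category in both; two years with a
different category in each. The feature triples are then exactly
(1,1,1), (1,2,1), (2,2,2) and (2,2,1), and the generator's variation
lives in which categories, which years, which dates, which providers,
the attributes and the missingness — not in the feature coordinates.

This is a deliberate design decision, and the reasoning deserves to be
explicit because it is a genuine property of silhouette-based selection
on count features. The features are small integers, so the data live on
a coarse lattice. Splitting a k-means cluster at a lattice gap sends
the silhouette of the split-off points to 1 (zero within-cluster
distance, positive distance to everything else), whereas splitting a
continuous blob produces boundary points with silhouette near 0. On
lattice data the mean-silhouette curve therefore keeps rising as k
isolates individual lattice points, and the argmax lands at the number
of distinct feature values, not at the number of generating strata: a
generator whose strata each span several feature triples makes the
selection return 2 or 8, never 4, regardless of seed. The
characteristic-signature design is the configuration under which
"separation far exceeds spread" holds exactly, and under it the
selection returns k = 4 with exact stratum correspondence for every
seed. The cost is stated plainly: the synthetic needs-per-veteran
distribution is degenerate within strata (real veterans with repeated
needs accumulate 2–10+ needs, not exactly two), so passing the
clustering test demonstrates that the machinery — scaling, seeding,
silhouette, correspondence — is correct under separable conditions. It
does not demonstrate that four clusters would be recovered from real,
overdispersed trajectories; on such data the number-of-clusters
question must be answered by the selection curve itself, inspected, not
assumed.

Other limitations of the generator: attribute marginals are matched but
joint distributions are not (no age-rank correlation, for instance);
no covariate drift over time; dates are uniform within a year, which is
harmless because the year, not the date, carries the analysis signal.

## Descriptive output and testing conventions

`frequency_table()` reports counts and percentages over the non-missing
denominator, rounded half-up to one decimal — the convention of the
reported tables it mirrors (half-to-even would, for example, print
0.585% as 0.58%). `table_by_stratum()` attaches a Pearson chi-square
(no continuity correction, expected counts from margins, df
(r−1)(c−1)) per variable, flagging any expected cell below 5. Per-test
significance at p < .05 with no multiple-testing adjustment mirrors the
reporting convention of the field; with ten-odd variables tested, a
stray significant result is expected by chance, and users comparing
many variables should adjust.

Problem sizes are chosen for interactive use: the shipped demonstration
and acceptance computation use 2 000 persons (about 3 400 need
records), unit tests use 50–800, and the bulk hashing property suite
uses 100 000 identities. All are the package's own choices and run in
seconds; `n_persons` scales to registry-sized populations (10^5) with
memory dominated by the n × n silhouette distance matrix, for which a
subsample is the standard remedy.

## Worked example

```{r example}
cfg <- pipeline_config(generator = generator_config(n_persons = 500, seed = 7))
result <- run_pipeline(cfg)
result
result$clusters
head(result$tables$table1, 8)
```
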