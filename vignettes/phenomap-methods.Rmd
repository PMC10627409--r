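---
title: "Methods: phecode phenotyping and PheWAS in phenomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phecode phenotyping and PheWAS in phenomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomap)
```

# The phecode system as implemented here

Phecodes aggregate ICD billing codes into clinically meaningful phenotypes.
`phenomap` implements two dialects of the mapping:

* the **prefixed hierarchical dialect**: labels `<AA>_<DDD>` or
  `<AA>_<DDD>.<d{1..3}>` — a two-letter category prefix, a three-digit root
  (leading zeros significant, so codes survive spreadsheet round trips),
  and up to three decimal digits, each adding one level of specificity.
  One ICD code may map to several phecodes (multi-mapping), which is how
  pre-coordinated codes (organism + site, condition + pregnancy context)
  contribute to every concept they encode. No exclude ranges exist in this
  dialect. Phenotypes supported only by ICD-10-era codes carry an
  `icd10_only` flag and a `*` at the end of their description.
* the **legacy numeric dialect**: bare numeric labels (`427.2`), at most
  two decimals, one-to-one ICD mapping, and per-phecode *exclude ranges* —
  numeric intervals such as `410-414.99` whose carriers are removed from
  that phecode's control group.

The hierarchy is purely lexical: the parent of a code is obtained by
dropping its last decimal digit. We treat *hierarchy closure* (every
non-root code's parent exists) as a validation rule, not as something to
repair silently: the released map is authoritative, and an orphan child is
reported by `validate_phecode_map()` rather than patched. All matching of
ICD codes happens on a normalized form (uppercase, dots and whitespace
removed), because EHR extracts store the same ICD-10-CM code both dotted
and undotted. Matching is exact after normalization; an unmapped code goes
to the unmapped-event report, never to a silent truncation fallback, since
a fallback would change phenotype definitions invisibly.

## The category registry

Categories are identified by the two-letter prefix. The dialect defines 18
categories; the package ships a default registry
(`default_registry()`) that uses the six prefixes attested in published
worked examples (CV, ID, RE, GI, EM, GE) plus conventional names for the
remaining chapters, and any deployment against a real release should load
the release's own registry file via `read_category_registry()`. The
registry matters in two places: validation (an entry whose declared
category contradicts its prefix is a finding) and the category-grouped
phenome plot.

# From events to a phenome

`map_events()` expands each dated ICD event to its directly mapped
phecodes and, with `rollup = TRUE` (the default), to all of their
ancestors present in the map. Contributions are then deduplicated to one
per (person, phecode, date) before counting, so the **counting unit is
distinct coded dates**. The rationale: same-day duplicate billing is an
administrative artifact and should not be able to manufacture a case. Two
invariants follow by construction and are enforced in the test suite:
parent counts dominate child counts, and duplicating every event row
leaves the phenome unchanged.

`assign_case_control()` applies the standard minimum-code-count rule:

| count | status |
|---|---|
| `>= min_code_count` (default 2) | case |
| `0` | control |
| in between | neither (excluded from both arms) |

The intermediate "neither" band is the usual PheWAS convention: a single
mention of a diagnosis is weak evidence of true disease but makes the
person an unconvincing control. The cohort universe is the union of
persons seen in the event table and an optional explicit roster, so
zero-count persons are representable as genuine controls; the underlying
data sources rarely define the cohort in the billing table itself.

**Exclude ranges** (legacy dialect only) demote controls whose counts fall
inside a phecode's numeric interval to "neither". Two choices here were
genuinely open. First, the published material does not state whether any
nonzero in-range count triggers removal or only counts at the case
threshold; we default to *any nonzero count* (the stricter, more
conservative control group) and expose `threshold = "min_code_count"` as
the alternative. Second, interval membership is a numeric comparison with
inclusive endpoints, because ranges are printed as `410-414.99`-style
closed intervals. For prefixed-dialect maps the operation is the identity,
and attaching ranges to such a map is an error — the dialect removed them
deliberately.

**Crosswalking** a phenome between dialects re-keys the count table
through a partial translation table. When several source codes land on one
target we take the **maximum** of the source counts, not the sum: the
sources usually derive from overlapping ICD groupings of the same
underlying events, and summing would double-count toward case status. The
sum is available behind an explicit flag. Codes without a counterpart go
to a dropped-codes report; the crosswalk is partial by design (injury and
exposure codes have no counterpart in the prefixed dialect).

# The association scan

`run_phewas()` fits, per phecode with at least `min_cases` cases after
joining to the predictor table, a logistic regression of case status on
the predictor plus covariates. The fitting engine is iteratively
reweighted least squares (`stats::glm.fit`) with a tolerance of `1e-8`
and at most 25 iterations; p-values are Wald. We deliberately do not apply
a Firth-type correction in this version: the case-count filter keeps
fitted models away from the worst small-sample territory, and
quasi-separation (fitted probabilities pinned at 0 or 1) is detected and
reported through the `converged` flag rather than corrected silently.
Persons with "neither" status are dropped per phecode (test-wise
deletion), so each test uses the largest defensible case and control sets.

Defaults worth knowing:

* `min_cases = 100` — a working filter for adequately powered tests, not a
  mandate; configurable down to 1.
* `alpha = 0.05` with Bonferroni correction over the number of tests
  actually performed. Benjamini–Hochberg is deliberately not the default;
  `stats::p.adjust` can be applied to the returned p-values for
  exploratory use.
* Results are ordered by phecode label, so a scan is deterministic.

# The synthetic-data module

`simulate_phecode_map()` generates a miniature map that passes the
validator by construction: a 1–3-level tree per root, synthetic but
vocabulary-shaped ICD codes (letter + digits for ICD-10-like, digits for
ICD-9-like), an exact-up-to-rounding multi-mapping rate per vocabulary,
and a controllable fraction of ICD-10-only phecodes. The ground-truth
record includes `clean_leaves`: leaves untouched by any multi-mapped ICD,
whose counts therefore cannot be contaminated by events emitted for other
phenotypes. Effect-recovery studies plant their effect on a clean leaf —
multi-mapped contamination is a real attenuation mechanism, and isolating
the estimator from it is the point of a recovery study.

`simulate_cohort()` draws, per person, a genotype `g ~ Binomial(2, MAF)`;
per leaf phecode, affection with probability
`plogis(qlogis(prevalence) + beta * g)`; and, for each affected pair,
`D ~ 1 + Poisson(mean_dates - 1)` event dates drawn uniformly from a
two-year window, each date carrying one ICD drawn uniformly from the
leaf's mapped codes. With the default `mean_dates = 3`, the probability
that an affected person misses the minimum code count of 2 is
`dpois(0, 2)`, about 13.5% — computable, which is what the calibration
tests rely on. Background noise adds `Poisson(background_rate)` events per
person with ICDs drawn uniformly from the whole map (default rate 1 per
person — sparse contamination, enough to exercise the neither band and
the unmapped/contamination paths without dominating the signal). Effects
are planted **at leaves only**; ancestors show signal exclusively through
rollup, which is exactly the mechanism under test.

What the generator does *not* emulate, and what passing tests therefore do
not establish about real data: realistic ICD code frequencies, comorbidity
correlation between phenotypes, care-utilization patterns (visit
clustering, enrollment gaps), coding-practice drift across calendar time,
and any form of diagnostic misclassification beyond the date-count
mechanism. Results on synthetic cohorts validate the *machinery* —
mapping, rollup, thresholding, estimation — not the clinical validity of
any particular map.

# Numerical and design choices

* **Label grammar errors** name the offending component (prefix, root,
  suffix) and legacy-style numeric labels are rejected by the prefixed
  grammar, because silent acceptance would mix dialects.
* **Legacy labels** are stored as opaque numeric strings (digits, at most
  two decimals) to tolerate quirks like leading zeros (`008`).
* **Worked-example fixture**: the bundled demo map reproduces the
  published pre-coordinated-code examples. For staphylococcal pneumonia
  the two phenotype labels are asserted as a *set* — the source material's
  pairing of labels to descriptions is ambiguous, so the fixture does not
  bind which label carries which description.
* **High-level combination phecodes** can be excluded from leaf statistics
  in `summarize_phecode_map()` via a configurable list (default empty for
  synthetic maps; the published list lives in release supplements).
* **Ties and determinism**: all outputs are sorted (entries and results by
  label, mappings by vocabulary/code), and every stochastic routine takes
  a seed and restores the caller's RNG state.
* **Exit codes** in the CLI: 0 success, 1 validation findings or runtime
  failure, 2 usage error; outputs are never overwritten without
  `--force`; every artifact gets a provenance sidecar (tool version, map
  version, seed, parameters) because map releases are themselves
  versioned and a phenome is only interpretable relative to its map.

## Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` size their simulation studies
as follows, chosen to give stable statistics at desk scale: rollup-oracle
equivalence on 100 random cohorts of at most 50 phecodes and 200 persons
(exact equality, so size only affects coverage of edge cases); type-I
calibration on one null cohort of 5,000 persons over a map of roughly 500
phecodes, judged against a three-standard-error binomial band around
0.05; and effect recovery with a planted per-allele log-odds-ratio of 0.7
(MAF 0.3, prevalence 0.05) across 20 replicate cohorts of 5,000 persons,
judged by the simulation confidence interval of the mean estimate. Note
that the calibration cohort shares one genotype vector across all
phecodes, so rejections are positively correlated and the nominal
binomial band is approximate; the fixed-seed study sits comfortably
inside it.

# Known limitations

* No temporal phenotyping: onset dating, episode detection, date-window
  or age restriction are out of scope (filter events upstream).
* No Firth or exact logistic fallback for separated fits; they are
  flagged, not repaired.
* The WHO ICD-10 vocabulary is supported by the readers and the phenome
  builder, but the package ships no WHO content; phecodes absent from a
  WHO mapping file simply have no WHO-supported events.
* Curating the clinical content of a map — deciding which ICD codes
  belong to which phenotype — is expert work the package does not attempt;
  it validates structure, not medicine.
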