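---
title: "Mapping ICD-10 codes to phecodes: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ICD-10 codes to phecodes: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phemap)
library(dplyr)
```

## The problem

Phecodes are curated groupings of ICD diagnosis codes into clinically
meaningful phenotypes, organized hierarchically by a decimal identifier
(250 is diabetes mellitus; 250.2 is its child, type 2 diabetes) and
equipped with per-phenotype *exclusion ranges* that keep near-cases out of
control groups. The original phecode map was built against ICD-9-CM. When
US billing switched to ICD-10-CM (and much of the world uses WHO ICD-10),
every phenome-wide analysis needed a way to carry the roughly 90,000
ICD-10-CM codes onto the existing phecode structure without re-curating it
by hand.

`phemap` implements that translation as a small graph problem: each
candidate mapping is a *chain* of edges through intermediate vocabularies,
every chain is recorded as replayable provenance, and a hierarchy-aware
resolution step reduces each code's candidate set to its most specific
members.

## The terminology model

A `terminology_bundle` holds three tables:

* `codes` — one row per (vocabulary, code, description). Vocabularies:
  `ICD9CM`, `ICD10CM`, `ICD10`, `SNOMED`, `CUI`, `OHDSI_CONCEPT`,
  `PHECODE`.
* `edges` — directed crosswalk edges, each tagged with the resource it
  came from (`GEMS`, `UMLS_CUI`, `NLM_MAP`, `OHDSI_REL`,
  `ICD9_PHECODE_MAP`) and an `approximate_flag`.
* `phecodes` — phecode definitions with description and exclusion ranges
  (semicolon-separated `lo-hi` spans, e.g. `249-250.99` for the diabetes
  family).

Validation is structural and runs on construction: duplicate edges and
duplicate phecode definitions are errors, same-vocabulary edges are
rejected outside the OHDSI relationship graph (which legitimately hops
between concept ids), and edges that reference unknown codes are logged as
dangling rather than silently used.

The phecode hierarchy is purely lexical: `a` is a strict ancestor of `b`
when both share the same integer part and `b`'s digit string extends
`a`'s. So 250 → 250.2 → 250.23 is a chain, while 41 and 411 are
unrelated. Leading zeros are significant (`008` is a valid phecode; `8`
is not the same code).

## Mapping paths

`build_map()` takes the union of several independently computed paths, then
resolves the hierarchy. For ICD-10-CM all of A–F apply; for WHO ICD-10,
which has no GEMS crosswalk and no direct CUI links of its own in this
model, the GEMS and CUI-direct paths are dropped.

* **A — direct description match**: case-insensitive, whitespace-squashed
  equality between the source code's description and a phecode
  description.
* **B — GEMS**: ICD-10-CM → ICD-9-CM via the CMS General Equivalence
  Mappings, then the ICD-9-CM phecode map. Both "equivalent" (flag 0) and
  "approximate" (flag 1) GEMS rows are used: approximate mappings are the
  majority of GEMS and dropping them would gut coverage; the flag is
  preserved in provenance for auditing.
* **C — CUI direct**: source code → UMLS CUI → ICD-9-CM, where the CUI
  itself carries an ICD-9-CM atom.
* **D — NLM rule map**: source code → CUI → SNOMED CT → ICD-9-CM via the
  NLM SNOMED-to-ICD-9-CM maps. One-to-many NLM rows (one SNOMED concept
  mapping to several ICD-9-CM codes) are excluded by default
  (`nlm_exclude_one_to_many = TRUE`) because they are rule-based
  "map groups" rather than semantic equivalences; a flag re-enables them.
* **E — OHDSI relationships**: source code → CUI → SNOMED CT, then a walk
  through OHDSI concept-relationship edges until an ICD-9-CM concept is
  reached, capped at `max_ohdsi_hops = 5` with cycle detection (a node
  already present in the chain is never revisited; encountering one raises
  a warning and the cyclic continuation is dropped).
* **F — SNOMED via CUI**: source code → CUI → SNOMED CT → CUI → ICD-9-CM.

Every record carries its full chain as a provenance string, e.g.

```
ICD10CM:E11.9 -[GEMS]-> ICD9CM:250.0 -[ICD9_PHECODE_MAP]-> PHECODE:250.2
```

When several paths reach the same (source, phecode) pair, the records are
merged into one row whose `path_label` concatenates the contributing paths
and whose provenance joins the chains with `" | "`. `verify_map()` replays
every chain hop-by-hop against a bundle and is the package's audit
primitive: a forged or stale chain fails replay.

### Hierarchy resolution

A source code frequently reaches both a parent phecode and one of its
children (I10 reaches 401 and 401.1 through two GEMS-mapped ICD-9-CM
codes). `resolve_hierarchy()` drops any candidate that is a strict
ancestor of another candidate *for the same source code*. This keeps the
most specific phenotype assignment while preserving genuinely distinct
families: a sickle-cell code reaching 282.5 and 289.5 keeps both, because
neither is an ancestor of the other. The operation is idempotent and is
tested against a brute-force transitive-ancestor filter.

## Phenotyping

`map_events()` turns billing events into (patient, phecode, date)
assignments, counting *instances* as distinct (patient, date, code)
triples so that duplicate rows in an extract cannot inflate anything.
`define_cases_controls()` then applies the phecode model:

* **case** — at least `min_code_count` *distinct dates* carrying a
  phecode in the target's family (the target or any descendant). The
  default `min_code_count = 1` matches the common rule; raising it to 2
  is the usual stringency knob.
* **excluded** — not a case, but carrying any phecode inside the target's
  exclusion ranges. Case status takes precedence over exclusion.
* **control** — everyone else in the supplied population.

The three groups partition the population by construction, and the
package asserts this, plus control purity, on every build.

## Evaluation

`coverage_summary()` reports how much of a vocabulary and of an event
stream a map covers: unique official codes mapped, unique used codes
mapped, and instance-level coverage, with an exact official × used ×
mapped partition of the code universe and conservation of instances
(mapped + unmapped = total, asserted and tested).

`reproducibility()` measures phenotype stability across the ICD-9-CM →
ICD-10-CM coding transition: among patients who were cases in an ICD-9-era
window and had any code in both windows, what fraction are cases again in
the ICD-10-era window? Chronic diseases should reproduce at roughly
70–75%; acute ones should not. The two windows must not overlap and the
statistic is invariant to same-day duplicate events.

## PheWAS

`run_phewas()` fits, per phecode cohort, the logistic model

\[
\operatorname{logit} P(\text{case}) = \beta_0 + \beta_1 \cdot \text{dosage}
  + \text{covariates}
\]

with dosage coded additively (0/1/2 effect alleles) and age, sex and race
as default covariates (factor covariates are releveled to their largest
category). Confidence intervals are Wald, \(\exp(\hat\beta \pm 1.96\,
\mathrm{SE})\). Design choices worth noting:

* `min_cases = 20` — the common phenome-scan convention; below that the
  phecode is reported but flagged untested rather than contributing an
  unstable estimate.
* The Bonferroni threshold is \(\alpha / n_\text{tested}\) over phecodes
  *actually tested*, not over all phecodes in the phenome.
* Quasi-complete separation is flagged untested. `stats::glm` warns on
  separation for continuous designs but converges silently on a saturated
  2×2 table with an empty cell, so the package additionally flags any fit
  whose fitted probabilities come within \(10^{-10}\) of 0 or 1 — there
  the maximum-likelihood estimate does not exist.
* Constant or aliased design columns are errors ("singular design"), not
  silent drops.
* Patients in a phecode's excluded group are removed from that phecode's
  regression entirely, and this is asserted at fit time.

`tidy()`, `glance()` and `autoplot()` expose the per-phecode table, the
one-row scan summary, and a Manhattan-style plot; `compare_runs()` joins
two runs (for example one per coding era) and summarises direction
concordance among phecodes significant in both.

## The synthetic data

Nothing in the package requires licensed terminologies or patient data.

`build_fixture_bundle()` is a miniature bundle whose chains encode one
worked example per mapping mechanism: a case-insensitive description match
(H52.4 → 367.4), a GEMS chain (E11.9 → 250.2), a five-hop concept chain
(L01.00 → 686.2, also reachable through two other bridges so provenance
merging is exercised), parent/child pruning (I10 → 401.1), dual-family
targets (D57.812 → 282.5 + 289.5), non-CM ICD-10 chains (B21.1 → 071.1 +
202.2), many-to-one collapse (311/296.31/296.2 → 296.2), and decoy codes
with no complete chain. Public chain identifiers are real published ones;
two unpublished intermediate CUIs are synthetic stand-ins (`C90000xx`).

`simulate_cohort()` generates a two-era EHR cohort. Defaults are the study
conditions the package is calibrated against: 18-month windows
2014-01-01–2015-06-30 (ICD-9-CM era) and 2016-01-01–2017-06-30 (ICD-10-CM
era); 55.1% female; age ~ Normal(45, 25) truncated at zero by resampling;
Hardy-Weinberg genotypes at effect-allele frequency 0.07 with a planted
per-allele odds ratio of 1.6 on coronary atherosclerosis (phecode 411.4),
applied on the logit scale to that phenotype's window-1 prevalence and
window-2 incidence. Chronic phenotypes persist across windows with
probability 0.75, the acute intestinal infection with 0.05. Every
diseased patient-window emits 1–3 dated era-appropriate billing codes, and
every patient emits one unmapped filler code per window (V70.0 / Z00.00)
so the any-code-in-each-window cohort criterion is met by construction.
The simulator is a pure function of its seed and does not disturb the
caller's RNG stream.

**Scope and limitations.** The simulator plants marginal structure
(prevalence, persistence, one genotype effect) but no comorbidity
correlations, no coding intensity differences between sites, and no
miscoding; phenotype status maps to billing deterministically (diseased
patient-windows always bill). It is a test harness for the mapping →
phenotyping → PheWAS pipeline, not a realistic EHR generator.

## Numerical and testing choices

* Phecodes are kept as character strings end-to-end; numeric comparison
  happens only inside range checks, where 2-decimal phecodes are exactly
  representable.
* Coverage percentages are rounded to 2 decimals at the reporting edge
  only.
* The test suite sizes its statistical properties to run on one CPU in a
  few minutes: the hierarchy oracle runs 1,000 random candidate sets;
  persistence recovery uses n = 20,000 patients (binomial SE ≈ 0.6
  percentage points against a ±1.5-point tolerance); confidence-interval
  coverage of the planted log odds ratio uses 100 replicates at n = 5,000;
  family-wise error under the null uses 200 replicates of a 100-phecode
  null phenome at n = 1,000. Statistical property tests use allele
  frequency 0.25 for power at these sizes; the simulator's *default*
  stays at the study value 0.07.

## Command line

The same workflow is scriptable via `exec/phemap` (or `phemap_main()`):

```sh
phemap fixtures --out bundle/
phemap build --bundle bundle/ --vocab icd10cm --out map10cm.csv
phemap simulate --out cohort/ --seed 42 --n 2000
phemap phewas --bundle bundle/ --events cohort/events.csv \
  --subjects cohort/subjects.csv --vocab icd10cm --out phewas.csv
```

Every output gets a JSON run manifest (flags, config hash, package and R
versions) written next to it, so a result file can always be traced to the
invocation that produced it.
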