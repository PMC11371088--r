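---
title: "Methods: synthetic oncology extracts, mCODE profiles, and cohort analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic oncology extracts, mCODE profiles, and cohort analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mcodeflow)
```

## What the package models

`mcodeflow` is a desk-scale model of an oncology interoperability pilot: a
hospital's relational EHR extract is migrated into standards-based FHIR
profiles (the mCODE genomics set), stored behind a FHIR-style search API,
and analyzed as a cohort. Real extracts of this kind are private, so the
package carries its own statistical generator; everything downstream of the
generator — ETL, validation, storage, search, analytics — is the same code
one would run against real data of the same shape.

The pipeline has five modules:

1. **Synthetic source** — five linked tables (patients, diagnoses, reports,
   variants, specimens) emulating an Epic-Clarity-style CSV export.
2. **mCODE profiles** — typed in-memory representations of five mCODE
   genomics profiles with must-support validation, data-absent reasons, and
   anchored extensions; lossless FHIR R4 JSON in both directions.
3. **ETL** — a declarative mapping table driving
   extract → profiles → NDJSON → store, with a field-level conservation
   audit.
4. **Profile store** — entity–attribute–value storage with
   validation-on-write and keyset-paginated conjunctive search.
5. **Cohort analytics** — distributions, deidentified summary tables, and a
   Bayes conditional cancer-incidence calculator.

## The generative model

A cohort is described by `cohort_config()`. For `n` patients:

* Demographics: birth dates uniform over 1930–1995, sex/race/ethnicity
  categorical with realistic marginals. All event dates fall in 2000–2020
  and ages are computed against a fixed `as_of` date (2020-12-31 by
  default), never the wall clock, so results are reproducible forever.
* Each patient receives `reports_per_patient` genomic test reports (default
  1), each tied to one specimen.
* Variant counts per report are Poisson(`variant_rate`) (default 2), with
  genes drawn uniformly from the configured gene list (66 recurrently
  altered cancer genes by default). DNA changes are syntactically valid
  HGVS strings (SNV/deletion/insertion/duplication/delins); amino-acid
  changes use three-letter HGVS protein notation; allelic fractions are
  uniform on (0, 0.5], rounded to 4 decimals.
* **Diagnoses** follow a gene-conditional Bernoulli model. The
  `diagnosis_model` maps each gene to a named vector of per-Phecode
  probabilities; a patient carrying gene *g* receives diagnosis *c* with
  probability `model[[g]][[c]]`, independently per carried gene, and the
  patient's diagnosis set is the union of triggered codes. This
  construction makes the parameters *identifiable*: when no other carried
  gene loads on the same Phecode, the configured weight is exactly the
  population conditional probability P(*c* | carrier of *g*), so the
  incidence calculator's output can be checked against the generator's
  input (see the parameter-recovery test).
* **Missingness** is per-field Bernoulli masking over the seven maskable
  fields (race, ethnicity, and five variant attributes), applied last so
  that referential integrity always holds. Identifiers, dates, and gene
  symbols are never masked: the ETL needs them to build resources at all,
  which mirrors the practical observation that structural keys are curated
  while clinical detail goes missing.
* **Determinism**: each table draws from an independent RNG stream derived
  from the single seed, so identical configurations generate byte-identical
  extracts, and changing, say, the missingness model does not perturb the
  demographics stream.

The generator's scope is deliberately narrow: it emulates the *shape and
statistics* of a genomics extract, not medicine. Gene–cancer associations
are configurable fictions (the default model cycles genes over Phecodes),
the Phecode→TCGA-label mapping is a synthetic one-to-one stand-in, and no
claim of clinical realism is made for any generated value.

## Profiles, validation, and absence

Five mCODE profile kinds are implemented: CancerPatient (FHIR Patient),
GenomicsReport (DiagnosticReport), GenomicVariant and GenomicRegionStudied
(Observation), and GenomicSpecimen (Specimen). A sixth candidate —
a dedicated profile for Phecode diagnoses — was considered and rejected:
the mCODE genomics set has no natural home for aggregated phenotype codes,
so diagnoses travel as namespaced extensions on CancerPatient
(`<base>diagnosis/<phecode>` plus a companion `.../onset` extension). That
choice keeps the profile set standard while preserving every source cell,
and it is what the conservation audit checks.

Every profile kind declares must-support fields. The validation rule is the
load-time discipline of a real FHIR server: an unpopulated must-support
field must carry exactly one `dataAbsentReason` from
{`unknown`, `masked`, `not-performed`, `not-asked`}. The extract does not
record *why* a cell is empty, so the ETL applies `unknown` as the honest
default for empty source cells, reserving `not-performed` for the one case
it can infer structurally (a report with no variant rows has no results to
reference). Serialized
FHIR uses the standard machinery: component-level `dataAbsentReason` for
Observation components, primitive-companion `_field` extensions elsewhere.

Extensions are anchored: each extension names the field (or `resource`)
it attaches to, must live under the profile's namespace, and is unique by
URL. Serialization is canonical — recursively sorted keys, compact UTF-8 —
so structurally equal profiles serialize to byte-identical JSON.

## Numerical choices

* FHIR JSON carries numbers at 15 significant digits (jsonlite's shortest
  faithful decimal). This keeps interchange human-readable (0.42 stays
  "0.42") at the cost of bit-exactness in the 16th–17th digit.
* The EAV store is the bit-exact layer: numeric leaves are stored as
  `sprintf("%.17g", x)` strings with a type tag, so store round trips are
  `identical()`, not merely `all.equal()`.
* Ages are `floor(days / 365.25)` against the store's `as_of` date.
* Incidence estimates are exact ratios of integer counts over distinct
  patients; the Bayes identity
  P(c|v) = P(v|c)·P(c)/P(v) therefore holds to machine precision, which the
  tests assert at 1e-12.

## The store and search

The store follows the entity–attribute–value model: each resource is a set
of `(resource_id, resource_type, attribute_path, value, vtype)` rows with
dotted, 1-based-indexed paths (e.g.
`component[2].code.coding[1].code`), from which the resource is exactly
reconstructible. EAV was chosen over a fixed relational schema because the
five kinds have heterogeneous shapes and the mapping table is meant to be
editable without migrations; persistence is a single TSV file, inspectable
with standard tools.

Writes are validated: an invalid profile is rejected with its validation
report and the store is untouched. Re-putting a resource id replaces the
stored copy, and the bulk loader (`load_bundle`) batches profiles
(`ceiling(n / batch_size)` batches), optionally preparing batches on
parallel workers while applying insertions in deterministic order — the
final store contents are identical for any worker count.

Search is conjunctive with FHIR-style semantics: demographic and diagnosis
predicates resolve to a patient set that gates every profile through its
subject; the `gene` predicate additionally restricts GenomicVariant
profiles to their own gene. Results are ordered by
(resource_type, resource_id) and paged at 1,000 profiles — the deployed
server constraint the package treats as an interface constant — with keyset
continuation tokens (base64 of the last returned key), so inserts between
pages never duplicate results.

## Analytics

`distribution()` tallies gene variations or Phecode diagnoses (top 30 by
default). `summary_table()` returns deidentified patient-variant rows —
surrogate keys instead of identifiers, ages instead of birth dates — 10
rows initially and never more than 200 per request. `incidence()` estimates
P(cancer *c* | variant *v*) by distinct-patient counting over a 33-label
TCGA-style cancer set, reports the companion quantities (P(v|c), P(c),
P(v), and all four counts), and flags the zero-carrier case as
*not observed* rather than dividing by zero. `incidence_report()` ranks all
33 labels for one gene.

## Problem sizes

The problem sizes exercised by the tests and the acceptance script —
500-patient end-to-end runs, 2,500-profile pagination studies, n = 2,000
parameter recovery, 100-seed ranking studies — are the package's own
choices: large enough that the statistical assertions have power and the
pagination/batching machinery is genuinely exercised, small enough that the
whole suite runs in minutes on one CPU.

## Worked example

```{r example}
cfg <- cohort_config(n_patients = 50, seed = 42L, missingness = 0.15)
extract <- generate_cohort(cfg)
extract

mapping <- mapping_table()
bundle <- transform_cohort(extract, mapping)
bundle

store <- profile_store()
load_bundle(bundle, store)

audit <- audit_transform(extract, bundle, mapping)
all(audit$accounted)

distribution(store, axis = "gene", top_n = 5)

incidence_report(store, "TP53")[1:5, c("label", "count_v_and_c",
                                       "count_v", "p_c_given_v")]
```
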