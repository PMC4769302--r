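---
title: "Code-list construction, case finding and financial-year rates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Code-list construction, case finding and financial-year rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codesifter)
```

## The problem

Research on primary care databases starts from a case definition: which
clinical codes, out of the roughly hundred thousand in a hierarchical system
like Read, mean that a patient has the condition under study? Reusing a
pay-for-performance register (QOF business rules) is convenient but narrow —
such registers are built for quality indicators, not research, and they miss
cases. The alternative implemented here is a deliberately *high-sensitivity,
low-specificity* search of the code dictionaries, followed by expert review:
it is cheap to discard a false positive during review, and expensive to
discover a missed code after analysis.

`codesifter` implements that workflow end to end: dictionary search, review
templates, tiered code lists with superset checks, case finding in event
tables, and prevalence/incidence by UK financial year, plus a synthetic-data
generator that makes the whole pipeline testable without access to licensed
patient data.

## Matching semantics

Two matchers exist, and they are intentionally different.

**Code stubs** are matched as prefixes of the code field, case-sensitively
and with no wildcard expansion. In a hierarchical coding system a prefix
denotes a subtree — `H33` is asthma, and every code below it refines that
concept — so prefix search is subtree search. Case matters because the
coding system distinguishes it (`h33` and `H33` are different subtrees), and
a stub matches only at the start: `H33` finds `H331.11` but not `8H33.00`,
which merely contains the characters.

**Word stubs** are matched as plain contiguous substrings of the description
field. `angin` matches "Ludwig's angina" and also "Head-banging"; `stroke`
matches "sunstroke". That over-matching is a feature — the search must not
miss codes, and review removes the noise. Three refinements exist:
underscores build phrases (`ischemic_cardiomyopathy` searches for the
contiguous phrase "ischemic cardiomyopathy"), plus signs require every stub
somewhere in one description (`alcohol+depend`), and a leading dollar sign
turns a stub into an exclusion applied to the final hit set.

Design choices that needed deciding:

* **Description matching is case-insensitive by default.** Dictionary
  descriptions mix cases freely ("Asthma", "asthma", "ASTHMA"), and a
  sensitivity-first search should not miss case variants. The
  `case_sensitive` flag restores exact matching for users whose dictionaries
  are case-normalised. Code matching, by contrast, is always case-sensitive.
* **Exclusions apply to the whole hit set**, including hits found through
  code stubs. Exclusions exist to shrink the pile a reviewer faces; a rule
  that spared code-stub hits would silently re-admit rows the user asked to
  drop. A user who wants an un-excludable code can add it at the tiering
  stage.
* **No escape syntax.** `$` is only legal at position 0 of a word term and
  `+`/`_` are structural; terms violating this are rejected with the
  offending string named, rather than guessed at. Code stubs treat all
  characters literally.
* **Underscore maps to exactly one space**; no further whitespace or
  punctuation normalisation is applied. Hyphens are ordinary characters,
  which is precisely why `angin` matches "Head-banging".
* **Output order** is (code, description, row_id) — not specified by the
  method, chosen so that two runs over the same dictionary diff cleanly.

Dictionaries are read with an explicit delimiter (comma or tab, never
sniffed), an explicit column map (any layout with a code and a description
column works, e.g. CPRD's `medcode`/`readcode`/`desc`), UTF-8 decoding with
a logged Latin-1 fallback for legacy exports, code-field trimming but never
case folding, and descriptions kept verbatim so that all matching semantics
live in one place.

## Review and tiered lists

The hit list exports as a review sheet with an empty `category` per row.
The category vocabulary is fixed — diagnosis, management_or_symptom, drug,
complication, screening, history_or_resolved, other, not_relevant — and
unknown labels are rejected at ingest, because review sheets are hand-edited
and a typo that silently dropped a code would be invisible.

`build_codelist()` admits rows whose category the tier's policy allows. The
conservative tier defaults to `{diagnosis}`: each code on it should indicate
the condition and nothing else, so that a single occurrence can flag a
patient. The policy is configurable because some conditions have definitive
non-diagnosis codes (a drug prescribed for exactly one condition). The
speculative tier is the sensitivity analysis: conservative plus ambiguous
but strongly suggestive codes.

The normative relations — QOF minus exception-reporting codes &#8838;
conservative &#8838; speculative — are checked by `check_supersets()`, which
reports violations rather than throwing: the relations are requirements on
the curator, not on the software, and the CLI's `--strict` flag promotes a
failed report to a nonzero exit. Exception codes are taken as an explicit
input set, since how they are flagged inside business-rule files varies by
condition and release. Every built list carries provenance metadata
(reviewed file, term hashes, date) because a code list that cannot be traced
to its inputs cannot be replicated or deposited.

## Case finding

A patient is a case when their clinical and referral events (concatenated
before matching) contain at least `min_codes` codes from the list, with
onset dated to the first qualifying event. Decisions:

* **Event-to-list matching is exact string equality.** Prefix semantics
  belong to dictionary search; by the time a list exists, each code is a
  deliberate choice and must not silently pull in its subtree.
* **`min_codes` counts event occurrences**, not distinct codes: the
  stricter "two or more codes" criterion is about corroboration over time,
  and a repeat of the same diagnosis code on a later date is corroboration.
  Same-day duplicate rows would defeat that, so `distinct_dates = TRUE`
  offers date-based counting.
* Events with codes absent from any dictionary are legal and never match —
  real extracts contain retired and local codes.
* Impossible dates are an error at read time, never dropped.

## Prevalence and incidence

Rates are computed per UK financial year (1 April – 31 March, labelled
`"2000/01"`), overall and by sex. For year Y:

* **Prevalence** — denominator: patients whose registration interval
  overlaps the year; numerator: those with onset on or before its last day.
* **Incidence** — denominator: patients registered during the year with no
  onset before it starts (the population at risk); numerator: those whose
  first event falls inside the year. Each case is incident in exactly one
  year. A case whose onset year has no registration overlap never enters a
  numerator and is reported via a message.

The any-overlap denominator is the simplest defensible population
definition; database-specific denominators (mid-year census, person-years,
data-quality flags such as "acceptable patient") vary between studies and
are declared extension points, not silently approximated. Rates are stored
as exact ratios; text output prints percentages to 4 decimal places. A zero
denominator yields `NA`, never 0. One registration spell per patient is
assumed; multi-spell histories must be reduced to one interval upstream.

## The synthetic-data generator

The generator exists so that every pipeline stage has a ground truth.

`generate_lookup()` plants three row classes: *relevant* rows that contain
an inclusion stub as a standalone token (or a code in a searched subtree),
*trap* rows that contain a stub only glued inside a longer word — the
"sunstroke" false-positive mechanism, built by attaching random letters to a
stub — and *noise* rows assembled from a packaged word corpus from which
every word containing a query stub (or any word of a phrase stub) has been
removed, so noise can never match. The labels are therefore exact: a search
must return relevant &cup; trap and nothing else, which is what the tests
assert.

`generate_population()` builds a closed cohort: every patient registers
before the study window (uniformly within the preceding five years) and
stays registered, which keeps planted rates identifiable from any-overlap
denominators. Baseline-prevalent cases are drawn per patient with the
planted probability, with onset uniform between registration and the window
start; each later year, every patient still at risk becomes incident with
the planted annual probability, onset uniform in the year. A case's first
list-code event falls exactly on onset (making the labels an exact oracle
for the case finder) and further list events — count drawn from
`events_per_case`, default 1 + Poisson(2), minimum 1 so the single-code
pathway always works and the `min_codes = 2` pathway is exercisable — are
uniform to the window end. All patients get 1–3 noise-code events. Sex is
49% male, 49% female, 2% unknown, so the stratum-additivity invariant is
exercised on a non-trivial third stratum. Infeasible parameter combinations
(baseline prevalence plus cumulative incidence above 1) are an error.

Default study conditions are a cohort of 20,000 patients over the twelve
financial years 2000/01–2011/12 with 0.8% baseline prevalence and 0.05%
annual incidence — the scale of a severe-mental-illness-like condition in a
mid-sized database sample, and large enough that planted rates are
recovered within three binomial standard errors. Randomness comes from one
seeded stream per call; the seed is recorded in the truth sidecar, and
fixed-seed runs are byte-identical. The generator deliberately does not
mimic real-database features beyond the fields used here: no comorbidity
structure, no consultation-rate seasonality, no multi-spell registration,
no code-usage drift over calendar time. Passing tests therefore demonstrate
the pipeline's correctness on its own definitions, not the fidelity of any
particular database's denominators.

## Numerical and degenerate-input choices

Ties and edge cases are resolved explicitly: duplicate codes in a review
sheet collapse to the first-seen category with a warning naming the code;
merging lists resolves conflicts the same way; empty search results refuse
to become review templates (the query needs broadening); an empty admitted
category set builds an empty list with a warning rather than an error
(legitimate during early review rounds); superset violations enumerate
missing codes sorted, so reports are stable. Verification sizes were chosen
to exercise the asymptotics while keeping the default test run quick:
oracle-equivalence checks run 200 random dictionary instances up to 10,000
rows, and rate-recovery checks use the 20,000-patient default cohort under
three seeds.

## Known limitations

* Description matching has no synonym or term-table expansion: only strings
  present in the dictionary rows can match.
* No regular-expression or fuzzy matching, by design — reviewability beats
  expressiveness here.
* Rates come unadjusted: no age standardisation, no confidence intervals
  beyond what a user computes from the exact numerators and denominators,
  no trend testing.
* The expert-review step itself is human; the package manages its artefacts
  only.
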