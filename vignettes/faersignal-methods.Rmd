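---
title: "Methods: disproportionality screening of FAERS spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of FAERS spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous adverse-event databases such as the FDA Adverse Event
Reporting System (FAERS) are the main public resource for post-marketing
drug-safety screening.  They are also messy: a patient case can appear as
several report versions (initial plus follow-ups), the same event can be
filed under different case identifiers, ages arrive in six different
units, and dates are frequently partial or impossible.  `faersignal`
implements a complete screening pipeline for this setting, built around
the CDK4/6-inhibitor class (palbociclib, ribociclib, abemaciclib) and
cardiovascular adverse events, but configurable to any drug dictionary
and any set of event-term lists.

## Cleaning model

The cleaning cascade applies four stages, in a fixed order, each of which
can only shrink the corpus:

1. **Erroneous-case removal.**  Reports whose `caseid` appears in the
   FDA's quarterly deleted-case lists are dropped.
2. **Version deduplication.**  One report is kept per `caseid`.  "Most
   recent" is resolved by the triple `(fda_dt, caseversion, primaryid)`,
   descending.  The FDA receipt date is the natural clock; `caseversion`
   breaks same-day follow-ups; `primaryid` is unique, so ties cannot
   survive.
3. **Cross-caseid deduplication.**  Reports are considered the same event
   when age, event date, reporter country, the set of reaction Preferred
   Terms, and the set of *normalized* drug names are all identical.  Two
   design choices deserve note.  First, drug names are compared after
   normalization (uppercase, punctuation stripped), because identity of
   free-text verbatim names is otherwise undecidable — `"Ibrance"` and
   `"IBRANCE."` are the same prescription.  Second, missing compares
   equal to missing: two reports that both lack an event date can still
   be duplicates, since the rule is identity of fields.
4. **Age validation.**  Ages are converted to years with the FAERS unit
   codes (`DEC` ×10, `YR` ×1, `MON` /12, `WK` /52.143, `DY` /365.25,
   `HR` /8766).  A blank unit with a numeric value is read as years (the
   dominant FAERS convention; the count of such reports is kept for
   audit).  Plausibility bounds are [0, 120] years: wide enough for any
   real patient, tight enough to catch unit-coding errors.  Anything
   unconvertible or out of bounds counts as "unclear age" and is
   excluded.

The cascade is idempotent, and each run produces a manifest of stage
counts so a flow chart of exclusions can be reconstructed exactly.

## Cohort selection

A report belongs to drug *D*'s cohort iff at least one of its drug rows
has role code `PS` (primary suspect) and matches *D* in the dictionary.
Matching is substring containment of a normalized variant in the
normalized `drugname` or `prod_ai` field.  Substring (not equality)
matching was chosen because FAERS verbatim names embed strengths,
formulations and co-pack names; the shipped dictionary makes the variant
lists explicit and extendable.  A report whose only matching drug row is
a concomitant never enters a cohort; a report with two primary-suspect
rows matching two different drugs counts once in each cohort.

## Event mapping

Reactions in FAERS are MedDRA Preferred Terms.  MedDRA is licensed, so
the package bundles no MedDRA content: term lists (one SOC-level list and
seven narrow-scope SMQ stand-ins) are plain CSV configuration, and the
bundled files contain a small synthetic toy vocabulary used only by the
tests and the simulator.  PT matching is exact string match after
whitespace trimming — the REAC table is already MedDRA-coded, and fuzzy
matching would silently change counts.  A report is flagged by a query
when its PT set intersects the query's term set, once per report
regardless of how many member terms it carries.  Frequency tables are
report-level: the percent denominator is the number of reports carrying
at least one member term, so percents across terms may legitimately sum
past 100.

## Disproportionality statistics

For each (drug cohort, query) pair a 2×2 table is formed against the full
cleaned corpus:

|            | event | no event |
|------------|-------|----------|
| drug       |  a    |  b       |
| all others |  c    |  d       |

* **PRR** = (a/(a+b)) / (c/(c+d)); undefined when a = 0 or c = 0
  (reported as "-").
* **ROR** = ad/bc; undefined when a, b or c is 0.
* **Chi-square**: Pearson, *without* continuity correction, computable
  whenever all margins are positive (including a = 0).  The
  no-correction choice is empirical: reconstructing the published
  ribociclib rows from their printed marginals reproduces the printed
  chi-square values only without correction.
* **IC**: three selectable variants of the log2 observed-to-expected
  measure, labelled in every output row because published IC variants
  differ and the exact published formula is not always recoverable:
  * `bcpnn_bate1998` (default): the closed-form posterior expectation of
    the Bayesian Confidence Propagation Neural Network IC with the
    standard priors (uniform marginals, joint prior calibrated so the
    prior IC is 0).  Its IC025 is the true 2.5th percentile of the
    posterior, computed deterministically: the three Beta posteriors are
    combined by midpoint quadrature in probability space and the CDF is
    inverted with a root finder.  No Monte Carlo is involved, so results
    are bit-reproducible; the test suite checks the quantile against an
    independent 10⁶-draw posterior sample.
  * `log2_oe`: the unshrunk log2(O/E), with a delta-method normal bound
    (Poisson variance 1/a on the log scale); undefined at a = 0.
  * `log2_oe_shrunk`: log2((a+0.5)/(E+0.5)), finite at a = 0, with the
    widely used credibility approximation
    IC − 3.3(a+0.5)^−1/2 − 2(a+0.5)^−3/2.

* **Signal decision**: all of n ≥ 3, PRR ≥ 2, ROR ≥ 2, chi-square ≥ 4
  and IC025 ≥ 0; any undefined metric vetoes the signal.

The comparator population is *all other reports in the cleaned corpus*,
not a restricted drug class.  This choice was validated against the
published ribociclib rows: solving the background count from the printed
PRR reproduces the printed ROR and chi-square within rounding only under
this comparator and the age-filtered corpus size.

Metrics are carried at full double precision; rounding to two decimals
happens only in `format_signal_table()`, at the presentation boundary.

## Time to event

Onset is the number of days from the earliest 8-digit start date among
the matching primary-suspect drug rows to the report-level event date.
A pair is accepted only if both strings are 8 digits, parse as real
calendar dates, the start year is ≥ 1980, no year exceeds 2024, and the
event does not precede the start.  Each rejected pair receives exactly
one category (`non-8-digit`, `unparseable`, `year-bound`,
`negative-interval`, in that precedence), so rejection counts partition
the rejected set.  Negative intervals are rejected as illogical even
though the published rules list date examples non-exhaustively — a
negative onset cannot be a time-to-event.  Summaries use the
linear-interpolation quantile convention (R type 7); no convention is
standard in the field, so one is declared and fixed for reproducibility.

## The synthetic world

`generate_corpus()` emits FAERS-dialect files plus a ground-truth ledger
(one row per generated report version) so that every pipeline stage can
be tested against planted truth rather than against itself.  Defaults
encode the reporting structure of the CDK4/6 cohort as published:

* class share 30% of the corpus, split 0.60/0.25/0.15 across
  palbociclib/ribociclib/abemaciclib;
* sex mix 96.6/2.5/0.9 percent female/male/unknown; age normal(65, 12)
  truncated to 18–99; reporter occupations ≈ 42/45/13 percent
  healthcare professional/consumer/other;
* onset days log-normal with per-drug medians 83/63/33 days (class
  median ≈ 69) and log-sd 2.0 — the log-sd follows from the published
  interquartile ranges (e.g. 18–260 days around a median of 69), not
  from any stated distribution;
* 70% of reports carry corrupted or missing dates, reproducing the
  published ≈ 27% share of reports with a computable time-to-event;
* follow-up rate 0.2, cross-caseid duplicate rate 0.03, deleted-case
  rate 0.02, unclear-age rate 0.08;
* serious-outcome rates per the published cohort (hospitalization 17%,
  death 13.1%, ...);
* planted drug–event associations: for a pair planted at ratio ρ, every
  query term's per-report probability is multiplied by ρ within that
  drug's reports, so the true reporting-rate ratio is ρ.  The default
  world plants the two ribociclib pairs (QT prolongation at 8.43,
  arrhythmia-related terms at 8.19) and leaves every other pair at 1.

What the simulator does **not** emulate: temporal reporting trends,
country- or reporter-specific coding habits, correlated reaction terms
(beyond the planted associations), drug interactions, and free-text
noise beyond simple name variants.  A green test on synthetic data
therefore establishes that the machinery implements its stated rules
exactly and recovers planted effects of realistic size — not that any
particular real-world association is true.

## Numerical and degenerate-input choices

* The BCPNN quantile quadrature uses 160 midpoint nodes per Beta
  posterior (≈ 26k grid points per CDF evaluation) and a root-finder
  tolerance of 1e-7; against a 10⁶-draw posterior sample the resulting
  IC025 agrees to well under 0.01 on small tables.
* `contingency()` refuses tables whose implied d is negative.
* Empty drug cohorts produce warnings and n = 0 rows, not errors.
* Zero-row inputs (header-only files, empty result sets) round-trip
  through every reader and writer.
* CSV output serializes doubles with 17 significant digits so that a
  write-then-read round trip is lossless.

## Known limitations

* The pre-2012 legacy AERS format is not supported, and there is no
  download automation.
* The published IC/IC025 values cannot be matched exactly because the
  exact published IC variant is not recoverable from the text; the three
  implemented variants bracket the published values, and every output
  labels the variant used.  IC is therefore excluded from the package's
  hard acceptance checks, which pin PRR/ROR/chi-square instead.
* Full-scale reproduction of the published corpus counts requires the
  multi-gigabyte FAERS download and is out of desk-scale scope; the
  package validates against printed marginals and synthetic corpora.
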