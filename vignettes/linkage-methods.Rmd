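---
title: "Deterministic dual-registry linkage: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic dual-registry linkage: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Violent-death surveillance registries compiled from death certificates,
law-enforcement and coroner reports carry rich circumstance data but no
personal identifiers, and their military-history field is known to
misclassify Veteran status. Gold-standard Veteran mortality repositories
confirm Veteran status but carry none of the circumstance detail. Linking
the two — without identifiers, under a data-use agreement that forbids
re-identification — makes it possible to study the circumstances of
Veteran suicide, including among Veterans outside the VA healthcare
system.

`mortlink` implements such a linkage as a deterministic, multi-variable,
multi-stage procedure, together with the machinery needed to evaluate it:
a synthetic dual-registry generator with known ground truth, linkage
success metrics, and a diagnostic-accuracy assessment of the surveillance
military-history indicator.

## Record harmonization

Both registries are reduced to a shared schema. Six match variables are
used: age at death (completed years), sex, underlying cause of death
(UCOD, ICD-10), day-of-month of birth (dmb, 1–31), first initial of last
name (filn), and date of death. The gold registry arrives with a full
date of birth; harmonization derives dmb and age from it and then deletes
it — no package output retains a date of birth, which is the behaviour the
data-use constraints require. Age uses the completed-calendar-years
(birthday) rule; the package tests pin this to an independent
anniversary-counting oracle.

The gold registry has no manner-of-death variable; manner is classified
from the UCOD with a configurable code table defaulting to the standard
CDC groupings (suicide X60–X84, Y87.0, U03; undetermined intent Y10–Y34,
Y87.2, Y89.9). These code sets are a documented convention, not a claim
about any specific upstream system; the constructor refuses overlapping
sets. Eligibility keeps suicide and undetermined-intent deaths of
decedents aged 17+ (records with missing age are retained — age simply
becomes a missing key field — but drop out of age-stratified validity
tables).

## The linkage

Matching is purely deterministic: the stage's key variables are
canonically rendered (ISO dates, uppercased undotted codes, `M`/`F`) and
concatenated with `|`; records join only when the full strings are equal,
and only within a state-year stratum. Missingness is never a wildcard: a
record missing any key variable sits the pass out. Seven passes run in a
fixed order, with matched records removed from both sides between passes:

| pass | key | tier |
|------|-----|------|
| S1  | all six variables | exact |
| S2a | drops UCOD | probable |
| S2b | drops dmb | probable |
| S2c | drops filn | probable |
| S2d | drops death date | probable |
| S3a | drops dmb and filn | possible |
| S3b | drops UCOD, dmb, filn; surveillance pool limited to records missing *both* dmb and filn | possible |

The S3b design deserves a note: because its two dropped partial
identifiers are additionally *required missing* on the surveillance side,
its effective key is age + sex + death date, targeting exactly the states
that do not report dmb/filn rather than opening a loose key to the whole
pool. Age and sex are never relaxed: their missingness is rare and the
validity assessment is stratified by them.

A key occurring once on each side is a match (`unique_key`). Any key
admitting more than one pairing becomes a duplicate group and enters the
arbitration cascade:

1. **MCOD containment** — resolve if exactly one pairing has every gold
   MCOD code present in the surveillance MCOD set. Containment is exact
   on canonical codes; a surveillance record with an empty MCOD (or a
   gold record with none) is uninformative. Partially missing
   surveillance MCOD slots never block a candidate — only a contradiction
   does. Exact containment may under-resolve relative to a human
   reviewer who would accept near-miss codes; that is a deliberate,
   conservative choice.
2. **Relaxed-field review** — among the variables this pass relaxed:
   resolve on unique exact agreement, else (when death date was relaxed)
   on a unique strictly-minimal absolute date difference.
3. **Military indicator** — for single-gold-record groups only (the
   indicator is a surveillance attribute), resolve if exactly one
   candidate says `yes`.

Each rule is evaluated over the full pairing set rather than the
survivors of the previous rule; a rule fires only when it singles out
exactly one pairing. This makes the cascade order-invariant in the
candidate list and fully deterministic. Groups no rule can decide —
in particular when every reviewed surveillance field is missing — release
all members into the next pass.

The engine asserts the one-to-one property after every run: no record id
ever appears in two pairs. A brute-force all-pairs comparator (in the
test suite) replays every stage's field-equality and missingness rules
pair by pair and must agree exactly with the keyed join on pools of up to
200 records per side.

## Evaluating linkage success

Percentages are reported half-up at 2 decimals throughout, matching the
reporting convention of surveillance publications; a zero denominator
yields `NA`, never 0.

Strata are profiled on the surveillance side: per-variable missingness,
the share of records missing two or more match variables, and the
partial-reporting flag (supplied via configuration, as in the real
systems where partial reporting is known metadata). A stratum is
*complete* when it reports fully and its 2-plus-missing share does not
exceed the threshold (default 0.10). Exclusion is strictly
greater-than-threshold; a stratum sitting exactly at the threshold is
kept and flagged `at_threshold` in the profile so the ambiguity is
visible. Tier breakdowns (exact/probable/possible/unmatched) are
computed over all strata and over complete strata only.

Concordance diagnostics examine what the relaxed variable was doing in
the pairs each relaxed pass produced: for the UCOD-relaxed passes (2a,
3b), missing vs present-but-different; for the date-relaxed pass (2d),
missing vs within 30 days vs more than 30 days apart. The 30-day window
is inclusive so the two non-missing buckets partition the mismatches.

## Validity of the military-history indicator

Within complete strata, each surveillance record is cross-classified by
its indicator (`yes` / `no` / `unknown`) and by linked Veteran status.
Unlinked surveillance records are treated as status-negative: with no
identifiers, linkage *is* the only available status ascertainment, and an
unlinked gold Veteran is correspondingly a false negative of the linkage
+ indicator system. Metrics:

* sensitivity = linked-`yes` / all gold Veteran deaths in scope;
* specificity = unlinked-`no` / all unlinked records (the status-negative
  denominator; the alternative ratio over indicator-`no` records can
  exceed 1 and is not a proportion, so both raw counts are surfaced
  instead of implementing it);
* accuracy = (linked-`yes` + unlinked-`no`) / all surveillance records in
  scope;
* PPV / NPV = the linked share of `yes` records / the unlinked share of
  `no` records.

`unknown` indicators count against accuracy on both sides and are
excluded from the PPV/NPV denominators, which by definition range over
`yes` and `no` records. Stratification (manner of death; sex; age bands
17–39, 40–64, 65+) uses each record's own source's fields; an `all`
manner level is included alongside suicide and undetermined. Confidence
intervals are Wilson score by default (no CI method is canonical for this
kind of table; Wilson behaves well near the boundaries), with
Clopper–Pearson available via `ci_method = "clopper-pearson"`.

## The synthetic generator

`simulate_registries()` draws a decedent universe per stratum and emits
the two registries plus a truth table of correct links. What it emulates,
with study-calibrated defaults in `default_study_config()`:

* **Scale and strata** — 8 states × 2012–2018, 900 decedents per stratum
  (≈50,000 surveillance records, matching the scale of a national
  2012–2018 extract at desk-runnable size); veteran fraction 0.13 of the
  decedent universe.
* **Cohort mix** — 87% suicide vs undetermined; male share 0.95 among
  veterans, 0.76 otherwise; age bands weighted (0.19, 0.42, 0.39) for
  veterans and (0.38, 0.47, 0.15) otherwise; a 2% out-of-scope-manner
  contamination to exercise eligibility filtering.
* **Missingness** — surveillance rates: UCOD 5.44%, death date 4.26%,
  dmb 12%, filn 10%, age 0.5%, sex 0.2%; gold rates ≤ 0.25% per variable
  (date of birth 0.24%, filn 0.1%, UCOD and death date never missing).
  The dmb/filn defaults are conventions anchored to "non-required
  variables missing at around 10–12%"; the others are profiled values.
  A per-stratum override mechanism models a high-missingness state
  ("CO": dmb 55%, filn 50%, with a 45% *joint* component so both are
  missing together, the signature of states that simply do not report
  them). The joint mechanism preserves the configured marginals, so
  marginal checks remain exact.
* **Discrepancies** — linked pairs can disagree: UCOD recoded within
  manner (1%), death date shifted (0.8%, 80% of shifts within 30 days
  and the rest up to 180, giving the within-30-days diagnostic a
  synthetic analogue), dmb/filn typos (0.4% each).
* **Partial reporting** — "PA" samples 80% of its 2016–2018 strata.
* **Indicator error** — P(yes | veteran) varies by sex and age band
  (males 0.79/0.83/0.93, females 0.55/0.62/0.75; about 0.86 overall for
  males, 0.62 for females), 5% `unknown`, and a small false-positive
  rate among non-veterans (5.5% male, 1.2% female) — without which PPV
  would be trivially 100%.
* **Gold undercoverage** — 3% of true veterans missing from the gold
  registry, plus 7 points for ages 65+, mimicking incomplete electronic
  personnel records for older cohorts.

Ground-truth MCOD sets are constructed so the surveillance copy is a
superset of the gold copy; true pairs therefore always satisfy the
containment rule, and arbitration correctness against truth is testable.

What the generator does **not** model: manner-of-death discordance
between sources, within-state geography, real state-specific suicide
rates, seasonality of deaths (dates are uniform within year), duplicate
*decedents* (each decedent yields at most one row per registry), and
ICD-9 or free-text causes. Passing tests therefore demonstrate the
pipeline's correctness under these idealized mechanisms, not the
field-accuracy of any particular real-world extract.

## Numerical and reproducibility choices

* All randomness flows from one integer seed; a rerun with the same
  configuration is byte-identical (asserted on file hashes).
* Rounding is half-up (with an epsilon guard against binary
  representation just below the .5 boundary), applied only at the
  reporting surface; internal computation is full precision.
* Key canonicalization: ISO-8601 dates, uppercased undotted ICD-10,
  integer ages, `|` delimiter (barred from every field by construction).
* Degenerate inputs: empty pools, empty strata and zero denominators are
  defined behaviours (empty results, `complete = FALSE`, `NA` metrics),
  not errors; impossible probabilities and overlapping code tables are
  errors at construction time.
* Problem sizes in the shipped tests and analysis scripts: the full
  synthetic study runs at 900 decedents per stratum; oracle-equivalence
  checks run at ≤200 records per side where all-pairs comparison is
  exact and fast; the indicator parameter-recovery experiment uses 20
  replicates of the study-scale population with noise-free match fields
  so the validity estimators are unbiased for the configured indicator
  parameters, judged at nominal 95% CI coverage with a one-sided exact
  binomial test (α = 0.01) to tolerate seed luck without widening the
  claim.

## Known limitations

* Exact-containment MCOD arbitration under-resolves relative to human
  review of near-miss codes.
* The unlinked-equals-non-veteran operationalization deflates measured
  specificity/NPV when the linkage itself misses veterans; the
  synthetic study quantifies this (configured indicator parameters vs
  estimates under imperfect linkage) but real extracts cannot.
* Partial-reporting strata are taken from configuration; the package
  does not infer them from the data.
* The linkage is deterministic by design; no probabilistic
  (Fellegi–Sunter) weighting or fuzzy string comparison is provided.
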