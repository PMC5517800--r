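---
title: "From free-text medication entries to decision-support inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From free-text medication entries to decision-support inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medsig)
```

## The problem

Medication data in VistA-style EHR extracts arrive as two clinician-entered
free-text fields: a Drug Name, which frequently embeds a dose and assorted
decorations, and a sig, which states how the medication is taken. A
dedicated dose field exists but is typically blank. Decision-support logic,
by contrast, needs structured facts: the dose and unit, the schedule, the
total daily dose, the drug's formulary class, and — for screening —
per-patient counts and comorbidity flags. medsig is the bridge: a set of
small, composable, deterministic transformations from the messy text to
those facts, each of which fails *explicitly* (status flags, `UNMATCHED`
categories, `NULL` results) rather than guessing.

## Dose and schedule grammars

`extract_dose()` scans for an optional opening parenthesis, a decimal
number, optional whitespace, a unit (`MG`, `MCG`, `MEQ`, case-insensitive)
and an optional closing parenthesis, returning every non-overlapping match
left to right. Two properties are contractual and tested against an
independent character-by-character reference matcher: the match *set* is
exactly what the grammar admits, and every matched substring re-parses to
the same value and unit. The unit vocabulary is configuration
(`default_patterns()`), not code, because production vocabularies grow; the
same is true of schedule phrases and quantity words. Note one deliberate
consequence of grammar fidelity: a pathological string like `"0MG"` is a
grammatical match with value zero — the grammar, not a plausibility filter,
defines the match set, and downstream consumers see the value as extracted.

`extract_schedule()` maps phrase families to schedule codes with fixed
administrations-per-day multipliers (QD = QAM = QHS = 1, BID = Q12H = 2,
TID = 3, QID = 4, Q4H = 6). When several cues co-occur in one sig the
precedence is: as-needed phrases, then the frequency-phrase grammar, then
day-of-week lists, then as-directed phrases, else `UNKNOWN`. Putting PRN
first is a clinical-safety choice: an as-needed medication has no fixed
daily schedule even if the instruction also contains a frequency-like cap
("do not use more than twice per week"), so computing a daily dose from it
would overstate exposure. Day-of-week lists yield `WEEKLY_DAYS` with a
per-week count and deliberately **no** total daily dose: averaging a
three-times-a-week diuretic into a fractional daily dose would be
clinically misleading, so the per-administration dose and per-week
frequency are reported instead.

`parse_entry()` assembles the parse. Dose precedence is sig-over-name —
the sig states what the patient actually takes, the name what was
dispensed — but a disagreement (an 81 MG tablet taken as 162 MG) is never
silently resolved: the losing match is kept in `conflict_dose` and
`DOSE_CONFLICT` is flagged, suppressing the `OK` status even though a
daily dose might be computable. Within one field the leftmost dose wins
and later matches are retained as diagnostics. Units are never
interconverted: a silent MCG-to-MG conversion slip is the dominant
numerical risk in this domain, so `total_daily_dose()` simply carries the
dose's unit through. Quantity words ONE–FOUR (or digits 1–4) adjacent to an
administration unit multiply the dose; anything else defaults to one.
Entries from the standardized data-warehouse dialect (`source = "CDW"`)
bypass the phrase grammar: their schedule strings are matched directly
against the abbreviation set, and an empty or `NULL` schedule — the common
case — maps to `UNKNOWN`.

## Name normalization and classification

`normalize_name()` uppercases, blanks dose substrings (reusing the dose
grammar's spans), and strips decorations into tags: asterisk-delimited
inserts (`INLINE_SCHEDULE`), bracketed markers (a bare tag such as `OTC`),
angle-bracketed indications, parenthesized brand synonyms, and trailing
dose-form tokens (TAB, CAP, SA, EC, ...). The residual base name is the
match key; the function is idempotent, so normalized output can be safely
re-normalized. `match_formulary()` tries exact equality first, then a
*unique* token-prefix relation in either direction; a tie between two
candidate drugs (e.g. a bare "METOPROLOL" against both salts) returns
`UNMATCHED`, because for a screening application a missed match is safer
than a guessed drug.

`classify_medication()` then partitions each entry into exactly one of
`SUPPLY`, `EXCLUDED`, `OF_INTEREST` or `UNMATCHED`. Supplies — syringes,
lancets, inhaler spacers, diapers, which EHR medication lists store
alongside drugs — are detected by a formulary flag *or* a keyword list,
since either source alone is incomplete. Exclusions are class-driven
(vitamins, cough/cold, OTC items, topicals, ophthalmics by default, all
editable in `classification_policy()`), plus an explicit `[OTC]` tag on
the name itself. Short-term antibiotic courses cannot be recognized from
class alone, so an antibiotic is excluded only when a days-supply value is
supplied and is at or below the configurable threshold (default 30 days);
with no days-supply information the drug is retained, the conservative
choice for a polypharmacy count.

## The screening grid

`build_screening_grid()` filters to appointments in a half-open window
`[start, end)` — half-open so that consecutive weekly runs never double
count a boundary day — keeps one row per patient at the earliest in-window
appointment, and assigns each patient to one (age band, drug count) cell.
Age bands default to 65–74 / 75–84 / 85+ but are configuration; an age
outside every band goes to an explicit `"other"` band rather than being
dropped. Drug counts above a ceiling (default 10) share a top overflow
bucket. Within each cell the hypertension-only / diabetes-only / both
tallies come from ICD-9 category prefixes (401–405 and 250 by default;
the operational lists are configurable because deployed code sets vary).
Patients with neither condition remain in the cell total without a
dedicated tally. The construction is order-invariant and is tested cell by
cell against a brute-force per-patient tally.

## The staging store

The staging abstraction keeps only the minimum a real-time system needs:
`preprocess_diagnoses()` reduces a code list to one boolean per configured
disease (the default five-disease panel — diabetes, herpes zoster, chronic
kidney disease, depression, seizure disorder — is a plausible neuropathic
pain panel and pure configuration), and `derive_prior_medications()`
reduces a prescription history to panel drugs previously but not currently
prescribed, each with the maximum prescription date over its events.
"Currently prescribed" is defined by the supplied current-medication set
rather than by date arithmetic on fills, because no fill-to-active rule is
assumed. The serialized record provably contains no raw ICD-9 text and no
event-level history — the minimality test greps the JSON. The store is a
single-file JSON-lines table with full-replacement semantics per patient
per refresh, making the weekly-refresh model explicit; a missing patient
is a distinct not-found result, never confused with an all-false record.

## The FIB-4 panel state machine

The panel implements a dependent-field contract. In automatic mode, when
AST, ALT and platelet values are all present, FIB-4 is derived as

$$\mathrm{FIB4} = \frac{\text{age} \times \text{AST}}{\text{platelets}
\times \sqrt{\text{ALT}}}$$

with AST/ALT in U/L, platelets in 10⁹/L and age in years — the standard
published index definition, adopted here with the standard 1.45 / 3.25
cut-points (LOW below, HIGH above, boundary values in the closed
INDETERMINATE interval; both thresholds configurable). Manually setting
the range or value switches to manual mode and *removes* the three
component labs — the two representations never coexist, so a stale AST
can never silently contradict an overridden range. Leaving manual mode
(by editing a component, or clearing the override) starts from empty
components rather than restoring removed values: restoration would
resurrect exactly the stale state the removal was meant to prevent. Edits
are pure (the input state is untouched), unknown fields are rejected with
no partial update, and user-entered values are undated in the recency
view while EHR values carry the date obtained. The invariants are
exercised by 10,000 random edit trajectories in the test suite.
Smoking/alcohol/adherence-style fields are modeled as opaque pass-through
analytes: they are clinician-entered by design and nothing is inferred
from the record. A pluggable prognostic-score hook is out of scope; the
panel stops at FIB-4.

## The synthetic generator

`generate_medication_entries()` draws entries from seven archetypes —
clean name-borne dose, sig-borne dose, decorated name, as-directed, PRN,
weekly, and name/sig dose conflict — with default weights 0.30 / 0.20 /
0.15 / 0.10 / 0.10 / 0.10 / 0.05. The archetypes mirror the anomaly
families observed in this dialect; their true field frequencies are not
known publicly, so the mix is a spec parameter of the generator, chosen
once to keep every family represented at a few dozen instances per
thousand entries, not an estimate of any real population. An
`anomaly_rate` fraction of entries is corrupted so that neither grammar
can match (no dose anywhere, no schedule cue), with ground truth marking
them unparseable. `generate_patient_cohort()` adds ages (uniform 65–94 by
default), hypertension/diabetes at prevalences 0.6 / 0.35 — typical of an
older primary-care population — realized as actual ICD-9 codes plus
unrelated noise codes, appointment dates spanning a two-week window
widened by five days each side so window filtering is exercised, and
about seven medications per patient (1 + Poisson(6)).

Everything is deterministic under the spec seed, and generation restores
the caller's RNG state. The cohort generator derives its stream from the
seed with a fixed offset so entry and cohort fixtures are independent.

What passing tests on these fixtures shows — and does not. The round-trip
property (at `anomaly_rate = 0`, parse → classify → count recovers ground
truth for 100% of entries) demonstrates internal consistency of the
pipeline on the dialect the generator emulates: every archetype the
grammars claim to handle is actually handled, end to end. It does not
demonstrate coverage of a real extract, whose anomaly vocabulary is
open-ended (dose ranges like "1–2 TABLETS", free-text frequency caps,
misspellings, truncations); on real data those entries fall through to
the explicit-failure path (flags, retained raw text), which is the
designed behavior, and the pattern registry is the extension point.

## Numerical and degenerate-input choices

* Problem sizes in the shipped tests: exhaustive grammar equivalence over
  all strings of length ≤ 3 on an 11-character sub-alphabet plus several
  thousand seeded random strings of length ≤ 8 on the full 24-character
  alphabet; 1,000-entry round-trip fixtures; cohorts of 80–200 patients
  against the brute-force grid oracle; 10,000 panel edit trajectories.
* The anomaly-fraction check uses the exact binomial 99% band for the
  configured rate, not a normal approximation.
* Empty inputs are normal outcomes everywhere: empty sig → `UNKNOWN`
  schedule; no dose → `NO_DOSE` flag; empty base name after stripping →
  empty-string sentinel → `UNMATCHED`; empty cohort → all-zero grid;
  empty panel → empty recency view.
* Dates are `Date` objects end to end; the staging timestamp serializes
  as ISO-8601 to the second.
* FIB-4 inputs must be strictly positive; non-positive or non-finite
  values are domain errors, not NA propagation.

## Known limitations

Route of administration ("BY MOUTH") is ignored by design. Dose ranges
and PRN frequency caps are flagged, not quantified. Name matching is
token-prefix only — no edit-distance or standard-vocabulary (RxNorm)
mapping. The formulary shipped in `example_formulary()` is a small
illustrative table, not a clinical artifact. The grid's comorbidity
annotation is presence/absence of two conditions; it is not a general
phenotyping engine.
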