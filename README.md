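# medsig

**medsig** turns messy electronic-health-record medication and diagnosis
data into clinical decision-support inputs. It is written for informaticians
who work with VistA-style EHR extracts, where a prescription arrives as two
free-text fields — a Drug Name (`"GABAPENTIN 300 MG, CAP"`) and a sig
(`"TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY"`) — and everything a
decision-support rule needs (dose, unit, schedule, drug class, total daily
dose) must be recovered from that text.

The package covers six pieces of that preprocessing layer:

* **Sig parsing.** A pattern grammar extracts doses
  (`32.5 MG`, `18MCG`, `(1.5 meq)`), schedules (bedtime / once daily /
  twice daily / three times a day / four times a day, plus as-needed,
  as-directed and day-of-week lists) and quantity words, and computes the
  total daily dose `dose × quantity × administrations/day` where it is
  defined. Schedule abbreviations carry the fixed multipliers QD = QAM =
  QHS = 1, BID = Q12H = 2, TID = 3, QID = 4, Q4H = 6; PRN, as-directed,
  weekly and unknown schedules deliberately yield *no* daily dose, and the
  raw text is always retained for display as the fallback.
* **Formulary classification.** Decorated names
  (`"METOPROLOL*TWICE DAILY*TARTRATE TAB"`, `"NIACIN(SLO-NIACIN) [OTC]
  TAB, SA"`) are normalized into a base name plus tags, matched against a
  formulary table (exact, then unique token-prefix; ties never guess), and
  partitioned into non-drug supplies, excluded classes (vitamins,
  cough/cold, OTC, topicals, ophthalmics, short-term antibiotics) and
  drugs of interest for polypharmacy screening.
* **Cohort screening.** Patients with appointments in a half-open date
  window are bucketed into an age-band × drug-of-interest-count grid, each
  cell annotated with counts of hypertension-only, diabetes-only and both
  (ICD-9 categories 401–405 and 250 by default), with per-cell patient
  lists for recruitment.
* **Staging store.** Diagnosis histories are reduced to one boolean per
  configured disease and medication histories to prior-but-not-current
  panel drugs with their most recent prescription date — the minimum
  necessary for real-time lookup — with weekly-refresh replacement
  semantics and a JSON-lines serialization.
* **Panel consistency.** A lab panel whose FIB-4 liver-fibrosis index
  (age × AST)/(platelets × √ALT) is auto-derived whenever AST, ALT and
  platelets are all present, classified LOW / INDETERMINATE / HIGH at the
  1.45 / 3.25 cut-points; a manual override removes the three component
  values, and every lab remains inspectable with the date it was obtained.
* **Synthetic fixtures.** A seeded generator emulates the messy dialect —
  doses in either field, decorations, conflicts, weekly and as-needed sigs,
  unparseable anomalies — with complete ground truth, so the whole pipeline
  is testable without any real patient data.

## Worked example

```r
library(medsig)

e <- raw_medication_entry("GABAPENTIN 300 MG, CAP",
                          "TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY")
parse_entry(e)
#> <parsed_medication>
#>   name: GABAPENTIN 300 MG, CAP
#>   sig:  TAKE ONE CAPSULE BY MOUTH THREE TIMES A DAY
#>   dose: 300 MG (from NAME)
#>   schedule: TID (3/day)
#>   total daily dose: 900 MG
#>   status: OK
```

300 MG was found in the name field, the sig phrase mapped to TID (three
administrations a day), one capsule per administration, so the total daily
dose is 300 × 1 × 3 = 900 MG and the entry is flagged `OK`. A decorated
over-the-counter product instead classifies out of the polypharmacy count:

```r
cl <- classify_medication(parse_entry(
  raw_medication_entry("NIACIN(SLO-NIACIN) [OTC] TAB, SA")),
  example_formulary())
c(cl$base_name, cl$match_quality, cl$category)
#> [1] "NIACIN" "EXACT" "EXCLUDED"
```

A seeded synthetic cohort produces a recruitment grid; each row is one
(age band, drug count) cell, and the note gives hypertension-only /
diabetes-only / both counts:

```r
coh <- generate_patient_cohort(generator_spec(seed = 1, n = 120))
build_screening_grid(coh$patients,
                     as.Date(c("2015-11-11", "2015-11-25")),
                     formulary = example_formulary())
#> <screening_grid> window [2015-11-11, 2015-11-25), 70 patient(s)
#>  age_band drug_count n_total     note
#>     65-74          3       1 H1 D0 B0
#>     65-74          4       4 H1 D2 B0
#>     65-74          5       4 H0 D1 B3
#>     ...
```

And the dependent-field panel:

```r
st <- panel_state(50, list(AST = lab_result("AST", 40, "2015-10-01"),
                           ALT = lab_result("ALT", 25, "2015-10-02"),
                           PLATELETS = lab_result("PLATELETS", 200, "2015-10-03")))
st$fib4_value                          # (50*40)/(200*sqrt(25)) = 2
#> [1] 2
apply_field_edit(st, "FIB4_RANGE", "HIGH")
#> <panel_state> age 50, mode MANUAL
#>   FIB-4 range (manual): HIGH
```

The manual override removed the three component labs; editing any of them
returns the panel to automatic mode.

## Command line

A thin dispatcher over the same functions lives at `inst/cli/medsig.R`
(after installation: `system.file("cli", "medsig.R", package = "medsig")`):

```sh
Rscript medsig.R make-fixtures --seed 1 --n 100 --out fixtures/
Rscript medsig.R parse-meds --in fixtures/meds.csv --out parsed.jsonl --report report.json
Rscript medsig.R classify-meds --meds fixtures/meds.csv --out classified.csv
Rscript medsig.R screen-cohort --cohort fixtures/cohort.jsonl --window 2015-11-11:2015-11-25 --out grid/
Rscript medsig.R fib4 --age 50 --ast 40 --alt 25 --plt 200
```

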