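# rxsig

Structured extraction of free-text medication dosage instructions.

## The problem

Primary-care prescription records attach a free-text direction (the "sig")
to each prescription — `"2 puffs 6 hrly prn"`, `"a half to one tablet to 2
three times a day when required"` — and much of what a pharmacoepidemiologist
needs for drug-exposure modelling lives only in that text. Crucially, many
directions are *flexible*: they state ranges, optional administration
("when required"), or defer entirely ("as directed"). Collapsing that
flexibility into a single average silently decides the exposure model for
the analyst.

`rxsig` parses each direction into a seven-attribute record that keeps the
flexibility explicit:

| attribute | meaning |
|---|---|
| `dn_min`, `dn_max` | minimum/maximum **dose number** — units per administration |
| `df_min`, `df_max` | minimum/maximum **dose frequency** — administrations per interval |
| `di_min`, `di_max` | minimum/maximum **dose interval** — in days (daily = 1, weekly = 7, alternate days = 2) |
| `unit` | the dose unit (tablet, ml, puff, ...) |

A value the text does not pin down is *unspecified* (`?`). Optional
administration is modelled as `df_min = 0`. An hourly gap of *h* hours
converts to `24/h` administrations per day ("every 4 hours" → 6/day);
unequal doses at different times of day are averaged (`"one every morning
and two every night"` → dose 1.5, frequency 2, flagged `averaged_dose`).
Machine-readable flags (`as_required`, `as_directed`, `averaged_dose`,
`discarded_inconsistent`) keep these decisions visible downstream.

The extractor is rule-based and works in two steps: (1) thirteen editable
dictionaries (dose units, Latin shorthand such as `tds`/`qid`/`prn`, time
units, meal and time-of-day expressions, range operators, ...) plus a
pattern rule pack recognise typed candidate mentions; (2) structuring
meta-rules resolve minima/maxima, convert time units, apply defaults and
check min ≤ max consistency.

## Worked example

```r
library(rxsig)
res <- parse_dose(c("2 puffs 6 hrly prn",
                    "a half to one tablet to 2 three times a day when required",
                    "take as directed"))
print(res)
```

```
Structured dosage instructions: 3 record(s)
  text                                                      dn_min dn_max
1 2 puffs 6 hrly prn                                        2      2
2 a half to one tablet to 2 three times a day when required 0.5    2
3 take as directed                                          1      ?
  df_min df_max di_min di_max unit   flags
1 0      4      1      1      puff   as_required
2 0      3      1      1      tablet as_required
3 ?      ?      1      ?             as_directed
```

Reading row 1: 2 puffs per administration, up to 4 times a day (24/6) but
possibly none (`prn`), every day. Row 2 keeps the full dose range 0.5–2
tablets, up to 3 times daily, optional. Row 3 defers to instructions given
elsewhere: only the defaults (dose 1, daily interval minimum) are asserted
and the unit field is empty — an *absent* unit, distinct from `?`.

`summarize_corpus()` tabulates within-prescription variability over a
parsed corpus (how many records have `dn_min ≠ dn_max`, unspecified values,
no unit, ...), `score_extractions()` computes per-attribute, macro and
prescription-level accuracy against gold annotations, and
`generate_corpus()` produces seeded synthetic (text, gold) pairs for
end-to-end testing. `inst/scripts/rxsig.R` wraps parse/evaluate/summarize/
generate as shell subcommands.

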