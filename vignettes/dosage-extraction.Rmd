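---
title: "Extracting structured dosage information from free-text prescriptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting structured dosage information from free-text prescriptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxsig)
```

## The prescription model

A free-text dosage direction is reduced to seven attributes: minimum and
maximum *dose number* (`dn_min`, `dn_max`; units per administration),
minimum and maximum *dose frequency* (`df_min`, `df_max`; administrations
per interval), minimum and maximum *dose interval* (`di_min`, `di_max`;
whole days, the day being the smallest interval — sub-day timing is
expressed through frequency), and the *dose unit*. Min/max pairs make the
flexibility of a prescription explicit instead of averaging it away: the
analyst preparing drug-exposure data can then choose minimum, maximum, mean
or sampled exposure.

Three sentinel conventions matter:

* a value the text does not determine is **unspecified**, printed `?`
  (internally `NA`); it compares equal only to itself;
* an instruction with no unit information at all (e.g. `"take as
  directed"`) has an **absent** unit — an empty field, deliberately
  distinct from `?`;
* **optional administration** ("when required", `prn`) is `df_min = 0`,
  and an open dose bound ("up to 2 tablets") is `dn_min = 0`.

Dose numbers and frequencies are kept as exact rationals in double
precision — `"half a tablet"` is 0.5, averaging can give 1.5 or 8/3, and an
hourly gap of 5 hours gives 24/5 = 4.8 administrations per day. No rounding
is applied anywhere; the serialization writes enough digits to reproduce
each double bit-exactly.

Flags (`as_required`, `as_directed`, `averaged_dose`,
`discarded_inconsistent`) extend the seven columns so that distinctions the
structuring rules make in prose are machine-readable downstream.

## The two-step extractor

**Step 1 — mentions.** The instruction is tokenized: whitespace and
punctuation separate tokens, `/` is a hard clause separator, and a
digit-to-letter boundary splits glued tokens (`"5mls"` → `5`, `mls`;
`"2bd"` → `2`, `bd`) — a purely positional rule that needs no dictionary.
Thirteen dictionaries (verbs of administration, dose units, Latin/clinical
frequency shorthand, time units and adverbs, per-time-unit phrases,
periods, word numbers, range operators, as-required and as-directed
phrases, meal expressions, times of day) feed a pack of pattern rules whose
constituents are literal anchors, dictionary classes and numeric
placeholders. Numeric expressions cover digits, decimals, word numbers,
fractions, ranges under any range operator (`2-4`, `2 to 4`, `one or two`,
`between 2 and 4`) and open bounds (`up to three`). Matching is a
deterministic left-to-right scan per clause; for one attribute the longest
full match wins with pack order breaking ties, and a number consumed by a
frequency/interval/meal match is not also read as a dose number.

**Step 2 — structuring.** Meta-rules resolve the mentions into the record:

* ranges map to (min, max); reversed ranges (`"4 to 2"`) are kept in text
  order and flagged `discarded_inconsistent` by the validator rather than
  silently repaired;
* hourly gaps convert to per-day frequency, `df = 24/h`, and a gap range
  `every a to b hours` inverts to `(24/b, 24/a)`;
* weekly/monthly dosing sets the interval to 7/30 days, alternate days
  to 2; the days-per-month constant is configurable via `dose_config()`
  (months vary; 30 is the convention used);
* general meal expressions imply frequency 3 per day, named meals and
  times of day count 1 each and are summed; an explicit numeric frequency
  always beats the meal default (explicit numerals are more specific);
* several unequal doses at named administration times are averaged into
  both endpoints (`averaged_dose`), with frequency the number of named
  administrations, so total daily dose remains inferable;
* a missing dose number defaults to (1, 1) whenever any other dosage
  evidence is present; a missing interval defaults to (1, 1) — except
  under deferral ("as directed", or a bare as-required phrase), where the
  maxima stay unspecified.

Two asymmetric deferral conventions are applied literally as the worked
examples define them: `"take as directed"` gives dose (1, ?), frequency
(?, ?), interval (1, ?), while `"apply as needed"` asserts optional
administration, dose (1, 1), frequency (0, ?), interval (1, ?).

### Ambiguity conventions

Where the text is genuinely ambiguous the extractor picks one deterministic
reading and attaches a warning:

* `"take 1 2 3 times per day"` — first number is the dose, last binds to
  the frequency (`ambiguous_numeral_list`);
* `"6 per day"` with no unit — read as frequency 6, dose 1;
* `"a half to one tablet to 2 ..."` — the second `to` is a dose-range cue,
  widening the dose to (0.5, 2) rather than starting a frequency range;
* `od` is expanded to once daily although it can mean *oculus dexter*
  (right eye); a warning is attached since the instruction alone cannot
  disambiguate;
* conflicting unit mentions: first in reading order wins, with a warning.

A bare number with no supporting evidence (`"40n"`, `"1-2 four"`) is
treated as no information: the record is all-unspecified with an absent
unit, and no record ever aborts a corpus run.

An "up to N" bound attached to a dose zeroes only the dose minimum; applied
to a frequency ("up to three times a day") it zeroes the frequency minimum
through the ordinary range machinery. The interval for alternate-day dosing
is (2, 2) with the frequency left unspecified — the text names the gap, not
how often within it.

## Fuzzy matching

Misspellings are the dominant real-world failure mode (`"mnae"` for
`"mane"`, `"aplly"` for `"apply"`). The evaluated configuration leaves them
unrecognised — by default the parser reproduces the strict behaviour — and
an opt-in `fuzzy = TRUE` mode corrects unknown word tokens of four or more
characters to a unique dictionary word within restricted Damerau-Levenshtein
distance 1 (one substitution, insertion, deletion or adjacent
transposition; transposition counts as one edit precisely because swaps
like `mnae`/`mane` are the canonical clinical typo). Exact tokens are never
touched, so clean text parses identically in both modes; when two
candidates tie, no correction is made.

## The synthetic generator

`generate_corpus()` produces seeded (text, gold) pairs from eleven template
classes — plain dose+frequency, numeric ranges, open bounds, hourly gaps
(from the divisors of 24: 2, 3, 4, 6, 8, 12 hours, so conversions stay
integral), weekly, alternate-day, as-required, as-directed, meal-based,
unit-less and garbage strings — with weights chosen to over-represent the
constructions that carry variability, and counts allocated by largest
remainder so every class appears even at n = 100. Gold records are computed
from the sampled slot values through the dosage semantics directly, never
by running the parser: generator and extractor are independent
implementations of the same contract, and their agreement is the core
end-to-end test. Optional misspelling injection corrupts one keyword token
(≥ 4 characters) per affected record with a transposition or deletion,
leaving the gold record untouched.

The generator emulates the lexical space of common primary-care directions,
not their true frequency distribution, which is unknowable without licensed
record-level data. It contains no duration phrases, no titration schedules,
no multi-clause parallel regimens beyond simple time-of-day coordination,
and its misspellings are single edits in content words. A perfect score on
the clean synthetic corpus therefore demonstrates that every modelled
construction is parsed correctly end-to-end; it does not bound accuracy on
real corpora, where unmodelled constructions and heavier noise occur.

## Problem sizes and numerical checks

The test suite parses the full worked-example table exactly (including the
0.5/1.5 rationals and `?` placement), runs the clean round-trip at n = 500
(prescription-level accuracy must be 1.0), re-runs it with a 10%
misspelling rate to confirm degradation and that fuzzy matching recovers at
least half of the lost records, and checks the model invariants as
properties over seeded corpora: min ≤ max or flagged, hourly inversion,
as-required monotonicity (adding an as-required phrase never raises
`df_min` and never changes dose, interval or unit), bit-exact serialization
round-trips over both the CSV dialect and JSON Lines, and the
evaluation-report identities (macro accuracy equals the mean of the seven
attribute accuracies; prescription-level accuracy never exceeds the
smallest of them).

## Known limitations

Durations and breaks ("1 daily for 21 days then 7 day break"), one-off
administrations ("take 1 at 9 o clock"), per-time-point parallel dose
events, conditional titration, and drug-name/route extraction are outside
the model: directions carry no drug information, and schedule dynamics
would need an extended representation. Evaluation here scores only the
seven structured columns; flags are informative but unscored. The bundled
lexicon covers the constructions documented in the package; it is shipped
as editable YAML precisely so that site-specific vocabulary (local unit
abbreviations, new shorthand) can be added without touching code.
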