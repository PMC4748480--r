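# Bundled rule pack for Step-1 mention recognition.
#
# Syntax: one rule per line,
#     attribute[.tag] := constituent+
# with the capture sub-span delimited by [ and ].  Constituents:
#     w(token)        literal word token
#     a(dict)         single token from a lexicon dictionary
#     a(dict=value)   as above, restricted to entries with that payload
#     d(dict)         longest multi-word (or single-word) dictionary phrase
#     NUM             numeric expression (digits, word numbers, fractions,
#                     ranges "2-4" / "2 to 4" / "one or two" /
#                     "between 2 and 4", open bounds "up to 3")
#     ?x              optional constituent
# Rules are tried in pack order; for one attribute the longest full match
# wins, ties broken by pack order.  Tags: .ext marks a dose-number range
# extension ("tablet to 2"), .bare marks an unanchored number, .nperday an
# ambiguous "N per day" (dose vs frequency) reading.

# ---- dose number -------------------------------------------------------
dose_number      := a(verb) [ NUM ] ?w(a) ?a(doseUnit)
dose_number      := [ NUM ] ?w(a) a(doseUnit)
dose_number.ext  := a(doseUnit) w(to) [ NUM ]
dose_number      := a(verb) [ NUM ]
dose_number.bare := [ NUM ]

# ---- dose unit ---------------------------------------------------------
unit := NUM ?w(a) [ a(doseUnit) ]
unit := [ a(doseUnit) ]

# ---- dose frequency ----------------------------------------------------
frequency         := [ NUM ] w(times) d(perTimeUnit)
frequency         := [ NUM ] w(times) a(timeUnitLy)
frequency         := [ NUM ] w(times) ?w(a) ?w(per) ?w(every) ?w(each) a(timeUnit)
frequency         := [ NUM ] w(times)
frequency         := [ a(latinFrequency) ] d(perTimeUnit)
frequency         := [ a(latinFrequency) ] a(timeUnitLy)
frequency         := [ a(latinFrequency) ]
frequency.nperday := [ NUM ] d(perTimeUnit)
frequency         := [ a(timeUnitLy=day) ]
frequency         := [ a(timeUnitLy=week) ]
frequency         := [ a(timeUnitLy=month) ]
frequency         := [ d(perTimeUnit) ]

# ---- dose interval (hour-denominated gaps become frequency in Step 2) --
interval := w(every) [ NUM ] a(timeUnit)
interval := [ NUM ] a(timeUnitLy=hour)
interval := [ NUM ] a(timeUnit=hour)
interval := [ d(period) ]

# ---- optionality -------------------------------------------------------
optionality := [ d(asRequired) ]
optionality := [ d(asDirected) ]

# ---- meals and time of day ---------------------------------------------
meal   := [ d(mealExpression) ]
timing := [ d(timeOfDay) ]
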