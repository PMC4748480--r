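# Step-2 meta-rules: min/max resolution, conversions, defaults, optionality.

test_that("dose-number meta-rules: defaults, open bounds, averaging", {
  expect_tuple("apply four times a day when required",
               1, 1, 0, 4, 1, 1, NA)
  expect_tuple("up to 2 tablets", 0, 2, NA, NA, 1, 1, "tablet")
  r <- parse_dose("one every morning and two every night")
  expect_equal(c(r$dn_min, r$dn_max), c(1.5, 1.5))
  expect_true(has_flag(r$flags, "averaged_dose"))
  expect_equal(c(r$df_min, r$df_max), c(2, 2))
  r <- parse_dose("take 3 in the morning 2 at teattime and 3 at night")
  expect_equal(r$dn_min, 8 / 3)        # mean of per-administration doses
  expect_equal(r$df_max, 3)            # one per named administration
  # equal doses at two times of day: no averaging flag needed
  r <- parse_dose("take 1 mane/take 1 at night")
  expect_equal(c(r$dn_min, r$dn_max, r$df_min), c(1, 1, 2))
  expect_false(has_flag(r$flags, "averaged_dose"))
})

test_that("frequency meta-rules: hourly conversion, meals, optionality", {
  expect_tuple("2 puffs 6 hrly prn", 2, 2, 0, 4, 1, 1, "puff")
  expect_tuple("one or two to be taken every 4 to 6 hours",
               1, 2, 4, 6, 1, 1, NA)
  expect_tuple("2 with each meal", 2, 2, 3, 3, 1, 1, NA)
  expect_tuple("apply as needed", 1, 1, 0, NA, 1, NA, "")
  expect_tuple("1 every 5 hours", 1, 1, 4.8, 4.8, 1, 1, NA)
  expect_tuple("2 tablets with breakfast", 2, 2, 1, 1, 1, 1, "tablet")
})

test_that("interval meta-rules: weekly, day ranges, alternate days, deferral", {
  expect_tuple("10 mg to be taken weekly", 10, 10, 1, 1, 7, 7, "mg")
  expect_tuple("1 every 3 to 5 days", 1, 1, NA, NA, 3, 5, NA)
  expect_tuple("take as directed", 1, NA, NA, NA, 1, NA, "")
  expect_tuple("1 tablet on alternate days", 1, 1, NA, NA, 2, 2, "tablet")
  expect_tuple("1 every 2 to 3 months", 1, 1, NA, NA, 60, 90, NA)
  # month length is configurable
  expect_equal(parse_dose("1 every 2 months",
                          config = dose_config(month_days = 28))$di_min, 56)
})

test_that("ambiguous numeral lists bind first number to dose, last to frequency", {
  r <- parse_dose("take 1 2 3 times per day")
  expect_equal(c(r$dn_min, r$dn_max, r$df_min, r$df_max), c(1, 1, 3, 3))
  expect_match(attr(r, "warnings"), "ambiguous_numeral_list", all = FALSE)
  r <- parse_dose("6 per day")
  expect_equal(c(r$dn_min, r$df_max), c(1, 6))
  expect_match(attr(r, "warnings"), "ambiguous 'N per day'", all = FALSE)
})

test_that("structural-ambiguity reading extends the dose range over the unit cue", {
  expect_tuple("a half to one tablet to 2 three times a day when required",
               0.5, 2, 0, 3, 1, 1, "tablet")
})

test_that("instructions with no recognisable content give all-unspecified records", {
  for (txt in c("~ ~ ~ ~ ~ ~ ~", "40n", "human", "1-2 four", "28percent", "")) {
    r <- parse_dose(txt)
    expect_true(all(is_unspecified(unlist(r[seq_len(6) + 1L]))), label = txt)
    expect_identical(r$unit, "", label = txt)
  }
})

test_that("every bundled worked example reproduces its seven-tuple exactly", {
  ex <- example_instructions()
  expect_same_doses(parse_dose(ex$text), ex)
})

test_that("hourly inversion: every a-to-b hours gives 24/b to 24/a per day", {
  gaps <- expand.grid(a = c(2, 3, 4, 6, 8), b = c(2, 3, 4, 6, 8, 12))
  gaps <- gaps[gaps$a <= gaps$b, ]
  for (k in seq_len(nrow(gaps))) {
    a <- gaps$a[k]; b <- gaps$b[k]
    r <- parse_dose(sprintf("1 every %d to %d hours", a, b))
    expect_equal(r$df_min, 24 / b)
    expect_equal(r$df_max, 24 / a)
    expect_lte(r$df_min, r$df_max)
  }
})

test_that("adding an as-required phrase never raises df_min nor touches dn/di/unit", {
  base <- generate_corpus(60, seed = 11)
  base <- base[base$template %in% c("plain", "range", "upto", "hourly",
                                    "weekly", "alternate", "meal", "unitless"), ]
  suffixes <- c("when required", "if needed", "prn")
  p0 <- parse_dose(base$text)
  p1 <- parse_dose(paste(base$text,
                         suffixes[seq_len(nrow(base)) %% 3 + 1]))
  expect_true(all(is.na(p1$df_min) | p1$df_min == 0 |
                  p1$df_min <= p0$df_min))
  for (a in c("dn_min", "dn_max", "di_min", "di_max", "unit"))
    expect_true(all(rxsig:::value_equal(p0[[a]], p1[[a]])), label = a)
  expect_true(all(has_flag(p1$flags, "as_required")))
})

test_that("reversed ranges survive structuring and are flagged, not repaired", {
  r <- parse_dose("take 4 to 2 tablets daily")
  expect_true(has_flag(r$flags, "discarded_inconsistent"))
  expect_equal(c(r$dn_min, r$dn_max), c(4, 2))
})

test_that("parsed corpora pass validation or carry the inconsistency flag", {
  g <- generate_corpus(120, seed = 3)
  p <- parse_dose(g$text)
  v <- validate_dose(p)
  expect_identical(v$flags, p$flags)   # nothing newly flagged on re-check
  clean <- p[!has_flag(p$flags, "discarded_inconsistent"), ]
  expect_true(all(is.na(clean$dn_min) | is.na(clean$dn_max) |
                  clean$dn_min <= clean$dn_max))
})
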