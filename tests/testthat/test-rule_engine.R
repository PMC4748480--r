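test_that("the bundled pack loads with every attribute class represented", {
  rules <- default_rules()
  attrs <- vapply(rules, function(r) r$attribute, character(1))
  expect_true(all(c("dose_number", "frequency", "interval", "unit") %in% attrs))
})

test_that("malformed packs are rejected with the offending location", {
  bad <- withr::local_tempfile(lines = "dose_number := [ NUM", fileext = ".txt")
  expect_error(load_rules(bad), "capture")
  unk <- withr::local_tempfile(lines = "unit := [ a(nonexistent) ]")
  expect_error(load_rules(unk), "unknown dictionary 'nonexistent'")
  junk <- withr::local_tempfile(lines = "frequency := [ blurb ]")
  expect_error(load_rules(junk), "malformed constituent")
})

test_that("a single user rule file works stand-alone", {
  one <- withr::local_tempfile(lines = "frequency := [ NUM ] w(times)")
  rules <- load_rules(one)
  men <- match_rules(tokenize("take 2 tablets 4 times a day"), rules)
  expect_equal(nrow(men), 1L)
  expect_equal(men$attribute, "frequency")
  expect_equal(c(men$vmin, men$vmax), c(4, 4))
  toks <- tokenize("take 2 tablets 4 times a day")
  expect_equal(toks$surface[men$cap_from], "4")
})

test_that("matching produces the expected typed mentions", {
  men <- match_rules(tokenize("take 2 tablets 4 times a day"))
  expect_setequal(men$attribute, c("dose_number", "unit", "frequency"))
  expect_equal(men$vmin[men$attribute == "dose_number"], 2)
  expect_equal(men$value[men$attribute == "unit"], "tablet")
  fq <- men[men$attribute == "frequency", ]
  expect_equal(c(fq$vmin, fq$vmax, fq$tunit), c("4", "4", "day"))

  men <- match_rules(tokenize("two drops every 3 hrs when required"))
  expect_setequal(men$attribute,
                  c("dose_number", "unit", "interval", "optionality"))
  iv <- men[men$attribute == "interval", ]
  expect_equal(iv$vmin, 3)
  expect_equal(iv$tunit, "hour")
  expect_equal(men$value[men$attribute == "optionality"], "as_required")
})

test_that("uninformative strings yield no mentions", {
  expect_equal(nrow(match_rules(tokenize("~ ~ ~ ~ ~ ~ ~"))), 0L)
  expect_equal(nrow(match_rules(tokenize(""))), 0L)
  expect_equal(nrow(match_rules(tokenize("human"))), 0L)
})

test_that("matching is deterministic", {
  toks <- tokenize("a half to one tablet to 2 three times a day when required")
  expect_identical(match_rules(toks), match_rules(toks))
})

test_that("no mention crosses a slash separator", {
  men <- match_rules(tokenize("take 1 mane/take 1 at night"))
  toks <- tokenize("take 1 mane/take 1 at night")
  slash <- which(toks$surface == "/")
  expect_true(all(men$m_to < slash | men$m_from > slash))
  # both clauses contribute independently
  expect_equal(sum(men$attribute == "dose_number"), 2L)
  expect_equal(sum(men$attribute == "timing"), 2L)
})

test_that("numbers consumed by frequency or interval are not dose numbers", {
  men <- match_rules(tokenize("apply sparingly 1-2 times daily"))
  expect_equal(sum(men$attribute == "dose_number"), 0L)
  men <- match_rules(tokenize("2 puffs 6 hrly prn"))
  dn <- men[men$attribute == "dose_number", ]
  expect_equal(nrow(dn), 1L)
  expect_equal(dn$vmin, 2)
})
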