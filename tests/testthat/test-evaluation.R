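test_that("identical prediction and gold sets score perfectly", {
  g <- parse_dose(example_instructions()$text)
  rep <- score_extractions(g, g)
  expect_true(all(rep$per_attribute == 1))
  expect_equal(rep$macro_accuracy, 1)
  expect_equal(rep$prescription_accuracy, 1)
  expect_equal(rep$n, nrow(g))
})

test_that("a single wrong attribute is charged exactly once (hand count)", {
  gold <- rbind(structured_dose(2, 2, 4, 4, 1, 1, "tablet"),
                structured_dose(1, 2, 0, 3, 1, 1, "puff", "as_required"))
  pred <- gold
  pred$df_max[2] <- 2                   # one attribute wrong in one record
  rep <- score_extractions(pred, gold)
  expect_equal(unname(rep$per_attribute["df_max"]), 0.5)
  expect_equal(sum(rep$per_attribute == 1), 6L)
  expect_equal(rep$prescription_accuracy, 0.5)
  expect_equal(rep$macro_accuracy, (6 * 1 + 0.5) / 7)
})

test_that("unspecified never gets credit against a specified value", {
  gold <- structured_dose(1, 1, 2, 2, 1, 1, "ml")
  pred <- structured_dose(1, 1, NA, 2, 1, 1, NA)
  rep <- score_extractions(pred, gold)
  expect_equal(unname(rep$per_attribute[c("df_min", "unit")]), c(0, 0))
  # and absent unit is not unspecified unit
  rep2 <- score_extractions(structured_dose(1, 1, 2, 2, 1, 1, ""),
                            structured_dose(1, 1, 2, 2, 1, 1, NA))
  expect_equal(unname(rep2$per_attribute["unit"]), 0)
})

test_that("macro accuracy is the mean of the seven attribute accuracies", {
  # mirror a 220-record evaluation with known per-attribute error counts
  gold <- generate_corpus(220, seed = 17)
  pred <- gold
  errs <- c(dn_min = 9, dn_max = 10, df_min = 10, df_max = 13,
            di_min = 0, di_max = 3, unit = 0)
  for (a in names(errs)) {
    idx <- seq_len(errs[[a]])
    if (errs[[a]] == 0) next
    if (a == "unit") pred[[a]][idx] <- "wrong"
    else pred[[a]][idx] <- ifelse(is.na(pred[[a]][idx]), 99,
                                  pred[[a]][idx] + 1)
  }
  rep <- score_extractions(pred, gold)
  expect_equal(unname(rep$per_attribute), unname(1 - errs / 220))
  expect_equal(rep$macro_accuracy, mean(1 - errs / 220))
  expect_equal(round(100 * rep$macro_accuracy), 97)
  expect_lte(rep$prescription_accuracy, min(rep$per_attribute))
})

test_that("length mismatch is a hard error", {
  g <- parse_dose(c("1 bd", "2 tds"))
  expect_error(score_extractions(g[1, ], g), "differ in length")
})

test_that("corpus summary counts variability as the paper-style categories", {
  ex <- example_instructions()
  s <- summarize_corpus(ex)
  expect_equal(s$n_total, nrow(ex))
  expect_equal(s$n_dn_varies, 3)      # half-to-2, 1-to-3, one-or-two rows
  expect_equal(s$n_df_varies, 4)      # df_max '?' rows do not count
  expect_equal(s$n_di_varies, 0)
  expect_equal(s$n_varies_any, 5)     # exact union, not the sum
  expect_lte(s$n_varies_any, s$n_dn_varies + s$n_df_varies + s$n_di_varies)
  expect_equal(s$n_all_unspecified, 0)
  expect_equal(s$n_any_unspecified, 2)
  expect_equal(s$n_no_unit, 5)        # three '?' plus two absent
  expect_equal(unname(s$unit_histogram["tablet"]), 4L)
})

test_that("summary handles empty and degenerate corpora", {
  s <- summarize_corpus(parse_dose(character(0)))
  expect_true(all(unlist(s[startsWith(names(s), "n_")]) == 0))
  ten <- parse_dose(rep("take 2 tablets 4 times a day", 10))
  s <- summarize_corpus(ten)
  expect_equal(s$n_any_unspecified, 0)
  expect_equal(s$n_varies_any, 0)
  # inconsistent records are excluded
  mixed <- rbind(ten, validate_dose(structured_dose(4, 2, 1, 1, 1, 1, "ml")))
  expect_equal(summarize_corpus(mixed)$n_total, 10)
})
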