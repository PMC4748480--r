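test_that("tokenize splits on slash, punctuation and digit-letter boundaries", {
  toks <- tokenize("take 1 mane/take 1 at night")
  expect_true("/" %in% toks$surface)
  i <- which(toks$surface == "mane")
  expect_identical(toks$surface[i:(i + 2)], c("mane", "/", "take"))

  expect_identical(tokenize("5mls daily")$surface, c("5", "mls", "daily"))
  expect_identical(tokenize("2bd")$surface, c("2", "bd"))
  expect_identical(tokenize("6hrly")$surface, c("6", "hrly"))
  expect_identical(tokenize("2.5")$surface, "2.5")
  expect_identical(nrow(tokenize("")), 0L)
})

test_that("token offsets are 0-based half-open and reconstruct the input", {
  text <- "Take 2.5 ml/day NOW"
  toks <- tokenize(text)
  expect_identical(toks$surface, tolower(toks$raw))
  for (i in seq_len(nrow(toks)))
    expect_identical(substr(text, toks$start[i] + 1L, toks$end[i]),
                     toks$raw[i])
  expect_true(all(diff(toks$start) > 0))
  expect_true(all(toks$end > toks$start))
  expect_true(all(toks$start[-1] >= toks$end[-nrow(toks)]))
})

test_that("tokenize is deterministic and stable on its own output", {
  text <- "one or two to be taken every 4 to 6 hours"
  t1 <- tokenize(text)
  expect_identical(tokenize(text), t1)
  rejoined <- paste(t1$surface, collapse = " ")
  expect_identical(tokenize(rejoined)$surface, t1$surface)
})

test_that("parse_numeric resolves points, words, fractions and ranges", {
  pn <- function(text, i = 1) parse_numeric(tokenize(text), i)
  expect_equal(pn("7")[c("min", "max", "open_lower")],
               list(min = 7, max = 7, open_lower = FALSE))
  expect_equal(pn("two")$min, 2)
  expect_equal(pn("half a tablet")$min, 0.5)
  expect_equal(pn("a half to one")[c("min", "max")], list(min = 0.5, max = 1))
  expect_equal(pn("one or two")[c("min", "max")], list(min = 1, max = 2))
  expect_equal(pn("2-4")[c("min", "max")], list(min = 2, max = 4))
  expect_equal(pn("between 2 and 4")[c("min", "max")], list(min = 2, max = 4))
  expect_equal(pn("up to three")[c("min", "max", "open_lower")],
               list(min = 0, max = 3, open_lower = TRUE))
  expect_null(pn("daily"))
})

test_that("reversed ranges are kept in text order and flagged", {
  m <- parse_numeric(tokenize("4 to 2"), 1)
  expect_equal(c(m$min, m$max), c(4, 2))
  expect_true(m$reversed)
  expect_false(parse_numeric(tokenize("2 to 4"), 1)$reversed)
})

test_that("the tail of a range cannot start a new numeric mention", {
  toks <- tokenize("1 to 3 every day")
  expect_null(parse_numeric(toks, 3))       # "3" belongs to "1 to 3"
  expect_equal(parse_numeric(toks, 1)$max, 3)
})

test_that("fuzzy correction fixes close misspellings but never exact tokens", {
  vocab <- c(default_lexicon()$vocab, "times")
  fixed <- rxsig:::fuzzy_correct(tokenize("2 tabelts 3 tmies daily"), vocab)
  expect_identical(fixed$surface[c(2, 4)], c("tablets", "times"))
  clean <- tokenize("2 tablets 3 times daily")
  expect_identical(rxsig:::fuzzy_correct(clean, vocab)$surface, clean$surface)
  # short tokens are left alone
  expect_identical(rxsig:::fuzzy_correct(tokenize("2 mk"), vocab)$surface[2], "mk")
})

test_that("restricted edit distance recognises each single-edit class", {
  expect_true(rxsig:::dl_within1("mnae", "mane"))       # transposition
  expect_true(rxsig:::dl_within1("tablts", "tablets"))  # deletion
  expect_true(rxsig:::dl_within1("tabletts", "tablets"))# insertion
  expect_true(rxsig:::dl_within1("tablet", "tablet"))
  expect_false(rxsig:::dl_within1("tablet", "capsule"))
  expect_false(rxsig:::dl_within1("ablets", "tablet"))  # two edits
})
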