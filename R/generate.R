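# Template-based synthetic instruction generator.  Gold labels are derived
# from the sampled slot values through the dosage semantics directly (an
# hourly gap h gives frequency 24/h, a meal expression 3 per day, ...),
# never by running the parser, so generator and extractor are independent
# implementations of the same contract and their agreement is a real test.

GENERATOR_TEMPLATES <- c(plain = 0.18, range = 0.12, upto = 0.08,
                         hourly = 0.12, weekly = 0.08, alternate = 0.06,
                         as_required = 0.12, as_directed = 0.06,
                         meal = 0.08, unitless = 0.06, garbage = 0.04)

GEN_UNITS <- list(
  list(canon = "tablet", one = "tablet", many = "tablets"),
  list(canon = "capsule", one = "capsule", many = "capsules"),
  list(canon = "puff", one = "puff", many = "puffs"),
  list(canon = "drop", one = "drop", many = "drops"),
  list(canon = "ml", one = "ml", many = "ml"))

GARBAGE_STRINGS <- c("~ ~ ~ ~ ~ ~ ~", "40n", "human", "28percent",
                     "1-2 four", "nil", "xx xx", "see notes")

#' Generate a synthetic instruction corpus with gold annotations
#'
#' Produces (text, gold record) pairs from templates that emulate the
#' lexical space of common free-text dosage instructions: plain
#' dose-plus-frequency, numeric ranges, open "up to" bounds, hourly gaps,
#' weekly and alternate-day dosing, as-required and as-directed
#' instructions, meal-based timing, unit-less instructions and
#' uninformative noise strings.  Template counts are allocated
#' proportionally to \code{template_weights} (largest-remainder rounding),
#' so every class is exercised even at moderate \code{n}; the output order
#' is a seeded shuffle, and the whole corpus is byte-identical for a given
#' seed and configuration.
#'
#' With \code{misspell_rate > 0} the stated fraction of records receives a
#' single injected misspelling (an adjacent-character transposition or a
#' character deletion) in one keyword token of four or more characters, and
#' the \code{misspelled} column records which.  The gold record is not
#' changed: misspellings are a failure mode of the text, not of the
#' prescription.
#'
#' @param n Number of instructions.
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param template_weights Named probabilities over template classes
#'   (must be non-negative and sum to 1); defaults to
#'   \code{GENERATOR_TEMPLATES}.
#' @param misspell_rate Fraction of records to corrupt, in [0, 1].
#' @param lexicon A \code{dose_lexicon} (used only to avoid accidentally
#'   turning a misspelling into another valid token).
#' @return A \code{dose_table} with columns \code{text}, the seven gold
#'   attributes, \code{flags}, plus \code{template} and \code{misspelled}.
#' @examples
#' generate_corpus(5, seed = 42)
#' @export
generate_corpus <- function(n, seed = 1L,
                            template_weights = GENERATOR_TEMPLATES,
                            misspell_rate = 0, lexicon = default_lexicon()) {
  stopifnot(n >= 1L, misspell_rate >= 0, misspell_rate <= 1)
  if (is.null(names(template_weights)) ||
      !setequal(names(template_weights), names(GENERATOR_TEMPLATES)) ||
      any(template_weights < 0) ||
      abs(sum(template_weights) - 1) > 1e-8)
    stop("template_weights must be a complete named probability vector ",
         "over: ", paste(names(GENERATOR_TEMPLATES), collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  counts <- allocate_counts(template_weights, n)
  classes <- rep(names(counts), counts)
  classes <- classes[sample.int(length(classes))]
  rows <- lapply(classes, function(cl) gen_one(cl))
  res <- do.call(rbind, lapply(rows, function(r) r$record))
  res$text <- vapply(rows, function(r) r$text, character(1))
  res$template <- classes
  res$misspelled <- NA_character_

  if (misspell_rate > 0) {
    hit <- runif(n) < misspell_rate
    vocab <- c(lexicon$vocab, "times", "every")
    for (i in which(hit)) {
      m <- misspell_text(res$text[i], vocab)
      if (!is.null(m)) {
        res$text[i] <- m$text
        res$misspelled[i] <- m$token
      }
    }
  }
  class(res) <- c("dose_table", "data.frame")
  rownames(res) <- NULL
  res
}

# largest-remainder apportionment: deterministic, every class with
# positive weight gets its proportional share
allocate_counts <- function(weights, n) {
  raw <- weights * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1L
  }
  counts
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

num_text <- function(v) {
  words <- c("one", "two", "three", "four", "five")
  if (v == floor(v) && v >= 1 && v <= 5 && runif(1) < 0.4)
    words[v] else format(v, drop0trailing = TRUE)
}

unit_text <- function(u, n) if (n > 1) u$many else u$one

freq_phrase <- function(f) {
  opts <- list(paste(num_text(f), "times a day"),
               paste(f, "times daily"))
  if (f == 1) opts <- c(opts, "once a day", "once daily", "daily")
  if (f == 2) opts <- c(opts, "twice a day", "twice daily", "bd")
  if (f == 3) opts <- c(opts, "tds")
  if (f == 4) opts <- c(opts, "qid", "qds")
  pick(opts)
}

gold <- function(dn_min, dn_max, df_min, df_max, di_min, di_max, unit,
                 flags = character())
  structured_dose(dn_min, dn_max, df_min, df_max, di_min, di_max, unit,
                  flags = flags)

# one (text, gold) pair for a template class
gen_one <- function(class) {
  u <- pick(GEN_UNITS)
  N <- sample(1:4, 1L)
  f <- sample(1:4, 1L)
  verb <- pick(c("take", "take", "use", ""))
  lead <- if (nzchar(verb)) paste0(verb, " ") else ""
  switch(class,
    plain = {
      if (runif(1) < 0.15) {    # fractional dose
        text <- paste0(lead, "half a ", u$one, " ", freq_phrase(f))
        list(text = text, record = gold(0.5, 0.5, f, f, 1, 1, u$canon))
      } else {
        text <- paste0(lead, num_text(N), " ", unit_text(u, N), " ",
                       freq_phrase(f))
        list(text = text, record = gold(N, N, f, f, 1, 1, u$canon))
      }
    },
    range = {
      A <- sample(1:3, 1L); B <- A + sample(1:2, 1L)
      join <- pick(c(" to ", "-", " or "))
      rng <- if (join == "-") paste0(A, "-", B) else
        paste0(num_text(A), join, num_text(B))
      text <- paste0(lead, rng, " ", u$many, " ", freq_phrase(f))
      list(text = text, record = gold(A, B, f, f, 1, 1, u$canon))
    },
    upto = {
      B <- sample(2:4, 1L)
      text <- paste0(lead, "up to ", num_text(B), " ", u$many, " ",
                     freq_phrase(f))
      list(text = text, record = gold(0, B, f, f, 1, 1, u$canon))
    },
    hourly = {
      H <- pick(c(2, 3, 4, 6, 8, 12))
      if (runif(1) < 0.3) {     # gap range: every a to b hours
        H2 <- pick(c(2, 3, 4, 6, 8, 12))
        a <- min(H, H2); b <- max(H, H2)
        text <- paste0(lead, num_text(N), " ", unit_text(u, N),
                       " every ", a, " to ", b, " hours")
        list(text = text, record = gold(N, N, 24 / b, 24 / a, 1, 1, u$canon))
      } else if (runif(1) < 0.5) {
        text <- paste0(num_text(N), " ", unit_text(u, N), " ", H, " hrly")
        list(text = text, record = gold(N, N, 24 / H, 24 / H, 1, 1, u$canon))
      } else {
        text <- paste0(lead, num_text(N), " every ", H, " ",
                       pick(c("hours", "hrs")))
        list(text = text, record = gold(N, N, 24 / H, 24 / H, 1, 1,
                                        NA_character_))
      }
    },
    weekly = {
      if (runif(1) < 0.5) {
        text <- paste0(lead, num_text(N), " ", unit_text(u, N), " ",
                       f, " times a week")
        list(text = text, record = gold(N, N, f, f, 7, 7, u$canon))
      } else {
        text <- paste0(lead, num_text(N), " ", unit_text(u, N), " ",
                       pick(c("weekly", "once a week")))
        list(text = text, record = gold(N, N, 1, 1, 7, 7, u$canon))
      }
    },
    alternate = {
      text <- paste0(lead, num_text(N), " ", unit_text(u, N), " ",
                     pick(c("on alternate days", "every other day")))
      list(text = text, record = gold(N, N, NA, NA, 2, 2, u$canon))
    },
    as_required = {
      suffix <- pick(c("when required", "if needed", "prn", "as necessary"))
      if (runif(1) < 0.3) {     # frequency-only instruction, dose defaults to 1
        text <- paste0(freq_phrase(f), " ", suffix)
        list(text = text, record = gold(1, 1, 0, f, 1, 1, NA_character_,
                                        flags = "as_required"))
      } else {
        text <- paste0(lead, num_text(N), " ", unit_text(u, N), " ",
                       freq_phrase(f), " ", suffix)
        list(text = text, record = gold(N, N, 0, f, 1, 1, u$canon,
                                        flags = "as_required"))
      }
    },
    as_directed = {
      text <- paste0(pick(c("take", "use", "apply")), " as directed")
      list(text = text, record = gold(1, NA, NA, NA, 1, NA, "",
                                      flags = "as_directed"))
    },
    meal = {
      if (runif(1) < 0.5) {
        text <- paste0(lead, num_text(N), " ",
                       pick(c("with each meal", "with meals", "after meals")))
        list(text = text, record = gold(N, N, 3, 3, 1, 1, NA_character_))
      } else {
        text <- paste0(lead, num_text(N), " ", unit_text(u, N), " ",
                       pick(c("with breakfast", "at teatime", "with dinner")))
        list(text = text, record = gold(N, N, 1, 1, 1, 1, u$canon))
      }
    },
    unitless = {
      if (runif(1) < 0.5) {
        A <- sample(1:3, 1L); B <- A + 1L
        text <- paste0(num_text(A), " to ", num_text(B), " every day")
        list(text = text, record = gold(A, B, 1, 1, 1, 1, NA_character_))
      } else {
        text <- paste0(lead, num_text(N), " ",
                       pick(c("every morning", "at night", "every night")))
        list(text = text, record = gold(N, N, 1, 1, 1, 1, NA_character_))
      }
    },
    garbage = {
      text <- pick(GARBAGE_STRINGS)
      list(text = text, record = gold(NA, NA, NA, NA, NA, NA, ""))
    },
    stop("unknown template class: ", class))
}

# inject one transposition or deletion into a keyword token (>= 4 chars);
# NULL when the text has no eligible token
misspell_text <- function(text, vocab) {
  words <- regmatches(text, gregexpr("[a-zA-Z]+", text))[[1]]
  eligible <- unique(words[nchar(words) >= 4L & tolower(words) %in% vocab])
  if (!length(eligible)) return(NULL)
  tok <- pick(eligible)
  for (attempt in 1:10) {
    ch <- strsplit(tok, "", fixed = TRUE)[[1]]
    if (runif(1) < 0.5) {                       # adjacent transposition
      p <- sample.int(length(ch) - 1L, 1L)
      ch[c(p, p + 1L)] <- ch[c(p + 1L, p)]
    } else {                                    # deletion
      p <- sample.int(length(ch), 1L)
      ch <- ch[-p]
    }
    bad <- paste(ch, collapse = "")
    if (bad != tok && !(tolower(bad) %in% vocab)) {
      new_text <- sub(paste0("\\b", tok, "\\b"), bad, text)
      return(list(text = new_text, token = tok))
    }
  }
  NULL
}
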