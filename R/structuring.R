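# Step 2: meta-rules that turn candidate mentions into a validated
# structured dose: min/max resolution, time-unit conversion, optionality
# and defaults.

#' Extraction constants
#'
#' All conversion constants used by the structuring step live here: hours
#' per day for hourly-gap conversion (\code{"every 4 hours"} becomes 24/4 =
#' 6 administrations per day) and the number of days a "month" stands for
#' (\code{"every 2-3 months"}; months vary, 30 days is the convention used).
#'
#' @param month_days Days per month used for monthly intervals.
#' @param hours_per_day Hours per day for hourly-gap conversion.
#' @return A named list of constants.
#' @export
dose_config <- function(month_days = 30, hours_per_day = 24) {
  list(month_days = month_days, hours_per_day = hours_per_day)
}

men_of <- function(mentions, attr) {
  mentions[mentions$attribute == attr, , drop = FALSE]
}

opt_markers <- function(mentions) {
  unique(men_of(mentions, "optionality")$value)
}

# administration slots named by the instruction: times of day plus
# individual meals ("with breakfast" counts 1; general "with meals" does
# not name slots, it implies the 3-per-day default)
named_slots <- function(mentions) {
  meal <- men_of(mentions, "meal")
  nrow(men_of(mentions, "timing")) +
    sum(meal$vmin[!is.na(meal$vmin) & meal$vmin < 3])
}

#' Resolve the dose number from candidate mentions
#'
#' Applies the dose-number meta-rules: a range maps to (min, max); an open
#' lower bound ("up to 2 tablets") to (0, max); a range extension anchored
#' on the unit ("a half to one tablet to 2") widens the maximum; several
#' unequal doses at named times of day ("one every morning and two every
#' night") are averaged, with both endpoints set to the arithmetic mean and
#' the \code{averaged_dose} flag raised; and when the instruction carries
#' other dosage evidence but no explicit dose number, both endpoints
#' default to 1 (with an unspecified maximum when the instruction defers
#' via "as directed").
#'
#' @param mentions A mention data frame from \code{\link{match_rules}}.
#' @return A list with \code{dn_min}, \code{dn_max}, \code{flags} and
#'   \code{warnings}.
#' @export
resolve_dose_number <- function(mentions) {
  out <- list(dn_min = NA_real_, dn_max = NA_real_,
              flags = character(), warnings = character())
  dn <- men_of(mentions, "dose_number")
  ext <- dn[dn$tag == "ext", , drop = FALSE]
  main <- dn[dn$tag != "ext", , drop = FALSE]
  markers <- opt_markers(mentions)
  other <- nrow(mentions) > nrow(dn)
  if (nrow(main) == 0L) {
    if ("as_directed" %in% markers) {
      out$dn_min <- 1; out$dn_max <- NA_real_
    } else if (other) {
      out$dn_min <- out$dn_max <- 1
    }
    return(out)
  }
  slots <- named_slots(mentions)
  if (nrow(main) >= 2L && slots >= 2L) {
    vals <- (main$vmin + main$vmax) / 2
    avg <- mean(vals)
    out$dn_min <- out$dn_max <- avg
    if (length(unique(vals)) > 1L) out$flags <- "averaged_dose"
    return(out)
  }
  first <- main[1L, ]
  out$dn_min <- first$vmin
  out$dn_max <- first$vmax
  if (nrow(ext) >= 1L) {
    out$dn_min <- min(out$dn_min, ext$vmin[1L])
    out$dn_max <- max(out$dn_max, ext$vmax[1L])
  }
  if (nrow(main) > 1L) {
    out$warnings <- if (any(main$tag[-1L] == "bare"))
      "ambiguous_numeral_list: several unanchored numbers; first read as dose number"
    else
      "multiple dose-number mentions; first taken"
  }
  out
}

#' Resolve the dose frequency from candidate mentions
#'
#' Applies the frequency meta-rules.  "N times" per day maps to (N, N); an
#' hourly administration gap of h hours converts to 24/h administrations
#' per day, a gap range "every a to b hours" to (24/b, 24/a); general
#' meal-time expressions imply 3 administrations a day while named times of
#' day and individual meals count 1 each and are summed; an as-required
#' marker ("when required", "prn") sets the minimum frequency to 0, and
#' with no other frequency evidence yields (0, unspecified).  Frequencies
#' stated per week or month pass the matching interval to the interval
#' resolver via \code{di_min}/\code{di_max}.
#'
#' @param mentions A mention data frame from \code{\link{match_rules}}.
#' @param config Constants from \code{\link{dose_config}}.
#' @return A list with \code{df_min}, \code{df_max}, implied
#'   \code{di_min}/\code{di_max} (or \code{NA}), \code{flags} and
#'   \code{warnings}.
#' @export
resolve_frequency <- function(mentions, config = dose_config()) {
  out <- list(df_min = NA_real_, df_max = NA_real_,
              di_min = NA_real_, di_max = NA_real_,
              flags = character(), warnings = character())
  freq <- men_of(mentions, "frequency")
  hourly <- men_of(mentions, "interval")
  hourly <- hourly[hourly$tunit == "hour", , drop = FALSE]
  meal <- men_of(mentions, "meal")
  slots <- named_slots(mentions)
  markers <- opt_markers(mentions)
  evidence <- TRUE
  if (nrow(freq) >= 1L) {
    f <- freq[1L, ]
    out$df_min <- f$vmin; out$df_max <- f$vmax
    if (f$tunit == "week") { out$di_min <- out$di_max <- 7 }
    if (f$tunit == "month") { out$di_min <- out$di_max <- config$month_days }
    if (nrow(freq) > 1L)
      out$warnings <- c(out$warnings, "multiple frequency mentions; first taken")
    if (identical(f$tag, "nperday"))
      out$warnings <- c(out$warnings,
        "ambiguous 'N per day': read as frequency N with dose number 1")
  } else if (nrow(hourly) >= 1L) {
    h <- hourly[1L, ]
    out$df_min <- config$hours_per_day / h$vmax
    out$df_max <- config$hours_per_day / h$vmin
  } else if (slots >= 1L) {
    out$df_min <- out$df_max <- slots
  } else if (nrow(meal) >= 1L) {
    out$df_min <- out$df_max <- meal$vmin[1L]
  } else {
    evidence <- FALSE
  }
  if ("as_required" %in% markers) {
    out$flags <- c(out$flags, "as_required")
    out$df_min <- 0
    if (!evidence) out$df_max <- NA_real_
  }
  if ("as_directed" %in% markers)
    out$flags <- c(out$flags, "as_directed")
  out
}

#' Resolve the dose interval from candidate mentions
#'
#' Applies the interval meta-rules: day-denominated ranges pass through
#' ("every 3 to 5 days" gives 3-5 days), weekly administration gives 7
#' days, monthly 30 (configurable), alternate days 2; hourly gaps are
#' sub-day and leave the interval at its daily default.  With no interval
#' information the interval defaults to (1, 1), except when the
#' instruction defers elsewhere ("as directed", or a bare as-required
#' phrase with no dosage detail), where the maximum is unspecified.
#'
#' @param mentions A mention data frame from \code{\link{match_rules}}.
#' @param config Constants from \code{\link{dose_config}}.
#' @param freq_interval Optional (min, max) implied by a per-week/per-month
#'   frequency, from \code{\link{resolve_frequency}}.
#' @return A list with \code{di_min}, \code{di_max} and \code{warnings}.
#' @export
resolve_interval <- function(mentions, config = dose_config(),
                             freq_interval = c(NA_real_, NA_real_)) {
  out <- list(di_min = NA_real_, di_max = NA_real_, warnings = character())
  iv <- men_of(mentions, "interval")
  iv <- iv[iv$tunit != "hour", , drop = FALSE]
  markers <- opt_markers(mentions)
  if (nrow(iv) >= 1L) {
    m <- iv[1L, ]
    mult <- switch(m$tunit, day = 1, week = 7, month = config$month_days, 1)
    out$di_min <- m$vmin * mult
    out$di_max <- m$vmax * mult
    if (nrow(iv) > 1L)
      out$warnings <- "multiple interval mentions; first taken"
    return(out)
  }
  if (!is.na(freq_interval[1L])) {
    out$di_min <- freq_interval[1L]; out$di_max <- freq_interval[2L]
    return(out)
  }
  freq_evidence <- nrow(men_of(mentions, "frequency")) > 0L ||
    nrow(men_of(mentions, "interval")) > 0L ||
    nrow(men_of(mentions, "meal")) > 0L ||
    nrow(men_of(mentions, "timing")) > 0L
  if ("as_directed" %in% markers ||
      ("as_required" %in% markers && !freq_evidence)) {
    out$di_min <- 1; out$di_max <- NA_real_
  } else if (nrow(mentions) > 0L) {
    out$di_min <- out$di_max <- 1
  }
  out
}

resolve_unit <- function(mentions) {
  out <- list(unit = NA_character_, warnings = character())
  um <- men_of(mentions, "unit")
  if (nrow(um) >= 1L) {
    out$unit <- um$value[1L]
    if (length(unique(um$value)) > 1L)
      out$warnings <- "conflicting dose units; first taken"
    return(out)
  }
  if (nrow(mentions) == 0L ||
      all(mentions$attribute == "optionality"))
    out$unit <- ""            # instruction carries no unit information
  out
}

#' Parse free-text dosage instructions
#'
#' The main entry point: converts free-text dosage instructions into
#' structured dose records.  Each instruction is tokenized
#' (\code{\link{tokenize}}), scanned for candidate mentions by the rule
#' pack (\code{\link{match_rules}}) and structured by the meta-rules
#' (\code{\link{resolve_dose_number}}, \code{\link{resolve_frequency}},
#' \code{\link{resolve_interval}}), then checked for min/max consistency
#' (\code{\link{validate_dose}}).  An instruction with no recognisable
#' dosage content (including a bare number with no supporting context)
#' yields an all-unspecified record with an absent unit and never raises an
#' error, so corpus-scale runs are never aborted by a single record.
#'
#' @param text Character vector of instructions.
#' @param rules A \code{dose_rules} pack.
#' @param lexicon A \code{dose_lexicon}.
#' @param fuzzy Correct unknown tokens of four or more characters to a
#'   unique dictionary word within Damerau-Levenshtein distance 1 (one
#'   substitution, deletion, insertion or adjacent transposition).  Off by
#'   default; exact tokens are never touched, so clean text parses
#'   identically either way.
#' @param config Constants from \code{\link{dose_config}}.
#' @param verbose Print per-record warnings as they arise.
#' @return A \code{dose_table} with one row per instruction: \code{text},
#'   the seven attributes and \code{flags}.  Per-record warnings (ambiguous
#'   readings, conflicting mentions) are collected in
#'   \code{attr(result, "warnings")}.
#' @examples
#' parse_dose("2 puffs 6 hrly prn")
#' @export
parse_dose <- function(text, rules = default_rules(),
                       lexicon = default_lexicon(), fuzzy = FALSE,
                       config = dose_config(), verbose = FALSE) {
  stopifnot(is.character(text))
  if (length(text) == 0L) {
    res <- structured_dose()[0L, ]
    class(res) <- c("dose_table", "data.frame")
    attr(res, "warnings") <- character()
    return(res)
  }
  vocab <- if (fuzzy) c(lexicon$vocab, rule_literals(rules)) else NULL
  rows <- vector("list", length(text))
  warns <- character()
  for (i in seq_along(text)) {
    tokens <- tokenize(text[i])
    if (fuzzy) tokens <- fuzzy_correct(tokens, vocab)
    mentions <- match_rules(tokens, rules, lexicon)
    st <- structure_mentions(mentions, tokens, config)
    st$record$text <- text[i]
    rows[[i]] <- st$record
    if (length(st$warnings)) {
      w <- sprintf("record %d [%s]: %s", i, text[i], st$warnings)
      warns <- c(warns, w)
      if (verbose) message(paste(w, collapse = "\n"))
    }
  }
  res <- do.call(rbind, rows)
  res <- validate_dose(res)
  class(res) <- c("dose_table", "data.frame")
  rownames(res) <- NULL
  attr(res, "warnings") <- warns
  res
}

# Structure the mentions of one instruction (internal single-record core).
structure_mentions <- function(mentions, tokens, config = dose_config()) {
  warnings <- character()
  # a bare number with no other dosage evidence is no information at all
  informative <- nrow(mentions) > 0L &&
    !all(mentions$attribute == "dose_number" & mentions$tag == "bare")
  if (!informative)
    mentions <- empty_mentions()
  dn <- resolve_dose_number(mentions)
  df <- resolve_frequency(mentions, config)
  di <- resolve_interval(mentions, config,
                         freq_interval = c(df$di_min, df$di_max))
  un <- resolve_unit(mentions)
  fq <- men_of(mentions, "frequency")
  if (nrow(fq) && tokens$surface[fq$cap_from[1L]] == "od")
    warnings <- c(warnings,
      "'od' read as once daily; can also mean right eye (oculus dexter)")
  warnings <- c(warnings, dn$warnings, df$warnings, di$warnings, un$warnings)
  rec <- structured_dose(dn$dn_min, dn$dn_max, df$df_min, df$df_max,
                         di$di_min, di$di_max, un$unit,
                         flags = unique(c(dn$flags, df$flags)))
  list(record = rec, warnings = warnings)
}
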