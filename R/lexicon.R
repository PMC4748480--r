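# Lexicon: the 13 dictionaries behind the Step-1 rules, loaded from an
# editable YAML file so users can extend coverage without touching code.

REQUIRED_DICTS <- c("verb", "doseUnit", "latinFrequency", "timeUnit",
                    "timeUnitLy", "perTimeUnit", "period", "number",
                    "rangeOperator", "asRequired", "asDirected",
                    "mealExpression", "timeOfDay")

# Attribute type of each dictionary; a single token may not appear in two
# dictionaries with conflicting types (build-time check in load_lexicon).
DICT_TYPE <- c(verb = "verb", doseUnit = "unit", latinFrequency = "frequency",
               timeUnit = "time", timeUnitLy = "time", perTimeUnit = "time",
               period = "interval", number = "number",
               rangeOperator = "operator", asRequired = "optionality",
               asDirected = "optionality", mealExpression = "meal",
               timeOfDay = "timing")

.rxsig_env <- new.env(parent = emptyenv())

#' Load the extraction lexicon
#'
#' Reads the dictionaries used by the mention-recognition rules from a YAML
#' file.  Thirteen dictionaries are required (\code{verb}, \code{doseUnit},
#' \code{latinFrequency}, \code{timeUnit}, \code{timeUnitLy},
#' \code{perTimeUnit}, \code{period}, \code{number}, \code{rangeOperator},
#' \code{asRequired}, \code{asDirected}, \code{mealExpression},
#' \code{timeOfDay}).  Lookups are case-insensitive.  Entries of
#' user-supplied override files replace or extend the bundled entries
#' per dictionary.
#'
#' @param path Path to a lexicon YAML file; the bundled lexicon when
#'   \code{NULL}.
#' @param overrides Optional path to a YAML file (or a named list) whose
#'   entries are merged over the base lexicon, dictionary by dictionary.
#' @return A \code{dose_lexicon} object.
#' @examples
#' lex <- default_lexicon()
#' names(lex$dicts)
#' @export
load_lexicon <- function(path = NULL, overrides = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lexicon.yaml", package = "rxsig")
  raw <- yaml::read_yaml(path)
  if (!is.null(overrides)) {
    ov <- if (is.character(overrides)) yaml::read_yaml(overrides) else overrides
    for (nm in names(ov))
      raw[[nm]] <- utils::modifyList(as.list(raw[[nm]]), as.list(ov[[nm]]))
  }
  missing <- setdiff(REQUIRED_DICTS, names(raw))
  if (length(missing))
    stop("lexicon is missing required dictionaries: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), REQUIRED_DICTS)
  if (length(extra))
    stop("lexicon must contain exactly 13 dictionaries; unknown: ",
         paste(extra, collapse = ", "))
  dicts <- lapply(raw, function(d) {
    d <- as.list(d)
    names(d) <- tolower(names(d))
    d
  })
  # build-time conflict check on single-token keys
  single <- list()
  for (nm in names(dicts)) {
    keys <- names(dicts[[nm]])
    keys <- keys[!grepl(" ", keys, fixed = TRUE)]
    for (k in keys) {
      prev <- single[[k]]
      if (!is.null(prev) && DICT_TYPE[[prev]] != DICT_TYPE[[nm]])
        stop(sprintf(
          "token '%s' appears in dictionaries '%s' and '%s' with conflicting attribute types",
          k, prev, nm))
      single[[k]] <- nm
    }
  }
  lex <- list(dicts = dicts, vocab = lexicon_vocab(dicts))
  class(lex) <- "dose_lexicon"
  lex
}

# All single words occurring in dictionary keys (used by fuzzy matching).
lexicon_vocab <- function(dicts) {
  words <- unlist(lapply(dicts, function(d)
    unlist(strsplit(names(d), " ", fixed = TRUE))), use.names = FALSE)
  sort(unique(words))
}

#' @rdname load_lexicon
#' @export
default_lexicon <- function() {
  if (is.null(.rxsig_env$lexicon))
    .rxsig_env$lexicon <- load_lexicon()
  .rxsig_env$lexicon
}

dict_get <- function(lexicon, dict, token) {
  lexicon$dicts[[dict]][[tolower(token)]]
}

#' Expand a clinical shorthand token
#'
#' Maps a single token of clinical/Latin prescription shorthand to its
#' semantic payload: frequency abbreviations (\code{"tds"} = 3 per day,
#' \code{"qid"} = 4 per day) to an administrations-per-day value,
#' as-required markers (\code{"prn"}) to the optionality marker, and
#' time-of-day shorthand (\code{"mane"}, \code{"nocte"}) to a timing label.
#' Note that \code{"od"} (once daily) is expanded to frequency 1 per day
#' although it can also mean "right eye"; disambiguation needs context the
#' instruction alone does not carry.
#'
#' @param token A single surface token (case-insensitive).
#' @param lexicon A \code{dose_lexicon}.
#' @return A list with elements \code{attribute}
#'   (\code{"frequency"}, \code{"optionality"} or \code{"timing"}) and
#'   \code{value}, or \code{NULL} when the token is out of vocabulary.
#' @examples
#' expand_abbreviation("tds")
#' @export
expand_abbreviation <- function(token, lexicon = default_lexicon()) {
  stopifnot(length(token) == 1L)
  v <- dict_get(lexicon, "latinFrequency", token)
  if (!is.null(v))
    return(list(attribute = "frequency", value = as.numeric(v)))
  v <- dict_get(lexicon, "asRequired", token)
  if (!is.null(v))
    return(list(attribute = "optionality", value = "as_required"))
  v <- dict_get(lexicon, "asDirected", token)
  if (!is.null(v))
    return(list(attribute = "optionality", value = "as_directed"))
  v <- dict_get(lexicon, "timeOfDay", token)
  if (!is.null(v))
    return(list(attribute = "timing", value = as.character(v)))
  NULL
}

#' Canonicalize a dose-unit token
#'
#' Maps surface unit forms, including plurals and common clinical
#' abbreviations (\code{"tabs"}, \code{"mls"}), to a canonical singular
#' unit token.
#'
#' @param token A single surface token (case-insensitive).
#' @param lexicon A \code{dose_lexicon}.
#' @return The canonical unit as a string, or \code{NULL} for non-units.
#' @examples
#' lookup_unit("tabs")
#' @export
lookup_unit <- function(token, lexicon = default_lexicon()) {
  stopifnot(length(token) == 1L)
  v <- dict_get(lexicon, "doseUnit", token)
  if (is.null(v)) NULL else as.character(v)
}

#' @export
print.dose_lexicon <- function(x, ...) {
  cat("Dose-instruction lexicon:", length(x$dicts), "dictionaries\n")
  for (nm in names(x$dicts))
    cat(sprintf("  %-15s %4d entries\n", nm, length(x$dicts[[nm]])))
  invisible(x)
}
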