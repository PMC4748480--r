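# Structured prescription representation: seven attributes with min/max
# semantics, an "unspecified" sentinel and machine-readable flags.

#' The unspecified-value sentinel
#'
#' Attribute values that a dosage instruction does not pin down are recorded
#' as \emph{unspecified}, rendered as \code{"?"} in the CSV dialect.
#' Internally the sentinel is \code{NA}; these helpers make the intent
#' explicit at call sites.  An unspecified value compares equal only to
#' another unspecified value (see \code{\link{score_extractions}}): it never
#' equals any number or unit token.  An \emph{absent} dose unit (an
#' instruction that defers entirely, e.g. \code{"take as directed"}) is a
#' distinct state, represented by the empty string and rendered as an empty
#' CSV field.
#'
#' @param x A vector.
#' @return \code{unspecified()} returns the numeric sentinel;
#'   \code{is_unspecified(x)} a logical vector.
#' @examples
#' is_unspecified(c(1, unspecified()))
#' @export
unspecified <- function() NA_real_

#' @rdname unspecified
#' @export
is_unspecified <- function(x) is.na(x)

# Canonical attribute column order of the structured record.
DOSE_ATTRIBUTES <- c("dn_min", "dn_max", "df_min", "df_max",
                     "di_min", "di_max", "unit")

KNOWN_FLAGS <- c("as_required", "as_directed", "averaged_dose",
                 "discarded_inconsistent")

#' Construct a structured dose record
#'
#' Builds a one-row structured dose record: minimum/maximum dose number
#' (\code{dn}, units per administration), dose frequency (\code{df},
#' administrations per interval), dose interval (\code{di}, days), the dose
#' unit and optional flags.  Pass \code{unspecified()} (or \code{NA}) for
#' values the instruction leaves open; pass \code{unit = ""} for an
#' instruction that carries no unit information at all.
#'
#' @param dn_min,dn_max Minimum/maximum dose number (non-negative), or
#'   unspecified.
#' @param df_min,df_max Minimum/maximum dose frequency per interval
#'   (non-negative), or unspecified.  \code{df_min = 0} encodes optional
#'   administration ("when required").
#' @param di_min,di_max Minimum/maximum dose interval in days (>= 1), or
#'   unspecified.
#' @param unit Canonical dose unit token, \code{NA} (unspecified) or
#'   \code{""} (absent).
#' @param flags Character vector of markers, a subset of
#'   \code{c("as_required", "as_directed", "averaged_dose",
#'   "discarded_inconsistent")}.
#' @param text Optional raw instruction text.
#' @return A one-row \code{dose_table} data frame.
#' @examples
#' structured_dose(2, 4, 1, 1, 1, 1, "tablet")
#' @export
structured_dose <- function(dn_min = unspecified(), dn_max = unspecified(),
                            df_min = unspecified(), df_max = unspecified(),
                            di_min = unspecified(), di_max = unspecified(),
                            unit = NA_character_, flags = character(),
                            text = NA_character_) {
  stopifnot(length(flags) == 0 || all(flags %in% KNOWN_FLAGS))
  num <- c(dn_min, dn_max, df_min, df_max, di_min, di_max)
  if (any(num < 0, na.rm = TRUE))
    stop("dose attributes must be non-negative")
  if (any(c(di_min, di_max) < 1, na.rm = TRUE))
    stop("dose intervals are whole days and must be >= 1 when specified")
  rec <- data.frame(text = as.character(text),
                    dn_min = as.numeric(dn_min), dn_max = as.numeric(dn_max),
                    df_min = as.numeric(df_min), df_max = as.numeric(df_max),
                    di_min = as.numeric(di_min), di_max = as.numeric(di_max),
                    unit = as.character(unit),
                    flags = paste(flags, collapse = ";"),
                    stringsAsFactors = FALSE)
  class(rec) <- c("dose_table", "data.frame")
  rec
}

#' Check min/max consistency of structured dose records
#'
#' Verifies, for each record, that every fully specified (min, max) pair is
#' ordered (minimum not bigger than maximum).  Violating records are never
#' silently altered or dropped: they come back unchanged except for the
#' \code{discarded_inconsistent} flag, so that corpus runs do not abort and
#' downstream summaries can exclude them.  Pairs with an unspecified
#' endpoint never participate in the ordering check.  The operation is
#' idempotent.
#'
#' @param records A \code{dose_table} (or compatible data frame).
#' @return The same records, with \code{discarded_inconsistent} added to the
#'   \code{flags} field of inconsistent rows.
#' @examples
#' validate_dose(structured_dose(4, 2, 1, 1, 1, 1, "tablet"))$flags
#' @export
validate_dose <- function(records) {
  bad <- bad_pair(records$dn_min, records$dn_max) |
    bad_pair(records$df_min, records$df_max) |
    bad_pair(records$di_min, records$di_max)
  if (any(bad))
    records$flags[bad] <- vapply(records$flags[bad], add_flag,
                                 character(1), "discarded_inconsistent")
  records
}

bad_pair <- function(mn, mx) !is.na(mn) & !is.na(mx) & mn > mx

add_flag <- function(flags, flag) {
  cur <- flag_list(flags)
  if (flag %in% cur) return(flags)
  paste(c(cur, flag), collapse = ";")
}

flag_list <- function(flags) {
  if (is.na(flags) || !nzchar(flags)) character() else
    strsplit(flags, ";", fixed = TRUE)[[1]]
}

#' @rdname validate_dose
#' @param flags A \code{flags} field value (";"-joined markers).
#' @param flag A single marker name.
#' @return \code{has_flag} returns a logical vector over records.
#' @export
has_flag <- function(flags, flag) {
  vapply(as.character(flags),
         function(f) flag %in% flag_list(f), logical(1), USE.NAMES = FALSE)
}

# Render a numeric attribute for output: '?' for unspecified, no trailing
# zeros, and enough digits that reading the text back reproduces the double
# bit-exactly.
fmt_value <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("?")
    s <- format(v, scientific = FALSE, drop0trailing = TRUE, digits = 15)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

parse_value <- function(s) {
  s <- as.character(s)
  out <- suppressWarnings(as.numeric(s))
  out[!is.na(s) & s == "?"] <- NA_real_
  out
}

#' @export
print.dose_table <- function(x, n = 20L, ...) {
  cat(sprintf("Structured dosage instructions: %d record(s)\n", nrow(x)))
  shown <- utils::head(as.data.frame(x), n)
  for (a in setdiff(DOSE_ATTRIBUTES, "unit")) shown[[a]] <- fmt_value(shown[[a]])
  shown$unit[is.na(shown$unit)] <- "?"
  print(shown, right = FALSE)
  if (nrow(x) > n) cat(sprintf("... and %d more record(s)\n", nrow(x) - n))
  invisible(x)
}

#' @export
summary.dose_table <- function(object, ...) summarize_corpus(object)
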