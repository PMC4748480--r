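# Accuracy against gold annotations and corpus variability summaries.

#' Score extractions against gold annotations
#'
#' Compares predicted structured dose records with gold-standard
#' annotations aligned by position.  An attribute is counted correct only
#' on exact equality: an unspecified value matches only an unspecified
#' value, numeric values are compared exactly (no tolerance credit) and a
#' record counts as a prescription-level true positive only when all seven
#' attributes are correct.  Macro accuracy is the arithmetic mean of the
#' seven per-attribute accuracies.
#'
#' @param pred,gold \code{dose_table}s of equal length, row-aligned.
#' @return A \code{dose_eval} object: per-attribute accuracies,
#'   \code{macro_accuracy}, \code{prescription_accuracy} and \code{n}.
#' @examples
#' gold <- parse_dose(c("take 2 tablets 4 times a day", "2 tabs qid"))
#' score_extractions(gold, gold)
#' @export
score_extractions <- function(pred, gold) {
  if (nrow(pred) != nrow(gold))
    stop(sprintf("prediction and gold sets differ in length (%d vs %d)",
                 nrow(pred), nrow(gold)))
  n <- nrow(pred)
  correct <- sapply(DOSE_ATTRIBUTES, function(a)
    value_equal(pred[[a]], gold[[a]]))
  correct <- matrix(correct, nrow = n,
                    dimnames = list(NULL, DOSE_ATTRIBUTES))
  per_attribute <- colMeans(correct)
  res <- list(per_attribute = per_attribute,
              macro_accuracy = mean(per_attribute),
              prescription_accuracy = mean(rowSums(correct) == 7L),
              n = n)
  class(res) <- "dose_eval"
  res
}

# exact equality with the sentinel semantics: unspecified matches only
# unspecified, absent unit only absent unit
value_equal <- function(a, b) {
  (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
}

#' @export
print.dose_eval <- function(x, ...) {
  cat(sprintf("Extraction accuracy over %d records\n", x$n))
  labels <- c(dn_min = "dose number (minimum)",
              dn_max = "dose number (maximum)",
              df_min = "dose frequency (minimum)",
              df_max = "dose frequency (maximum)",
              di_min = "dose interval (minimum)",
              di_max = "dose interval (maximum)",
              unit = "dose unit")
  for (a in names(x$per_attribute))
    cat(sprintf("  %-26s %6.1f %%\n", labels[[a]], 100 * x$per_attribute[[a]]))
  cat(sprintf("  %-26s %6.1f %%\n", "(macro) accuracy",
              100 * x$macro_accuracy))
  cat(sprintf("  %-26s %6.1f %%\n", "prescription level",
              100 * x$prescription_accuracy))
  invisible(x)
}

#' Summarize prescription variability over a corpus
#'
#' Counts, over validated structured records, the markers of within-
#' prescription variability and flexibility: records whose minimum and
#' maximum differ for dose number, frequency or interval (counted only when
#' both endpoints are specified), records with at least one unspecified
#' min/max attribute, records with every attribute unspecified (no dosage
#' information), records without a dose unit, and a histogram of canonical
#' units.  Records flagged \code{discarded_inconsistent} are excluded.
#'
#' @param records A \code{dose_table}.
#' @return A \code{dose_summary} object with counts \code{n_total},
#'   \code{n_all_unspecified}, \code{n_any_unspecified},
#'   \code{n_dn_varies}, \code{n_df_varies}, \code{n_di_varies},
#'   \code{n_varies_any} (the exact union), \code{n_no_unit} and
#'   \code{unit_histogram}.
#' @examples
#' summarize_corpus(example_instructions())
#' @export
summarize_corpus <- function(records) {
  records <- records[!has_flag(records$flags, "discarded_inconsistent"), ,
                     drop = FALSE]
  n <- nrow(records)
  varies <- function(mn, mx) !is.na(mn) & !is.na(mx) & mn != mx
  dn_v <- varies(records$dn_min, records$dn_max)
  df_v <- varies(records$df_min, records$df_max)
  di_v <- varies(records$di_min, records$di_max)
  num <- as.matrix(records[, setdiff(DOSE_ATTRIBUTES, "unit"), drop = FALSE])
  any_unspec <- if (n) rowSums(is.na(num)) > 0L else logical()
  all_unspec <- if (n) rowSums(is.na(num)) == ncol(num) else logical()
  no_unit <- is.na(records$unit) | !nzchar(records$unit)
  units <- records$unit[!no_unit]
  res <- list(n_total = n,
              n_all_unspecified = sum(all_unspec),
              n_any_unspecified = sum(any_unspec),
              n_dn_varies = sum(dn_v),
              n_df_varies = sum(df_v),
              n_di_varies = sum(di_v),
              n_varies_any = sum(dn_v | df_v | di_v),
              n_no_unit = sum(no_unit),
              unit_histogram = if (length(units)) sort(table(units),
                                                       decreasing = TRUE)
                               else table(character()))
  class(res) <- "dose_summary"
  res
}

#' @export
print.dose_summary <- function(x, ...) {
  n <- max(x$n_total, 1L)
  line <- function(label, count)
    cat(sprintf("  %-38s %8d  (%.1f %%)\n", label, count, 100 * count / n))
  cat(sprintf("Prescription variability over %d records\n", x$n_total))
  line("all attributes unspecified ('?')", x$n_all_unspecified)
  line("at least one attribute unspecified", x$n_any_unspecified)
  line("dn_min != dn_max", x$n_dn_varies)
  line("df_min != df_max", x$n_df_varies)
  line("di_min != di_max", x$n_di_varies)
  line("variability in at least one attribute", x$n_varies_any)
  line("no dose unit", x$n_no_unit)
  if (length(x$unit_histogram)) {
    cat("  most frequent units:\n")
    top <- utils::head(x$unit_histogram, 5L)
    for (u in names(top))
      cat(sprintf("    %-12s %6d\n", u, top[[u]]))
  }
  invisible(x)
}
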