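# Tokenization and numeric normalization (Step-1 preprocessing).

#' Tokenize a dosage instruction
#'
#' Splits an instruction into word, number and punctuation tokens.  The
#' slash is a separator (so \code{"take 1 mane/take 1 at night"} yields
#' \code{"mane"}, \code{"/"}, \code{"take"} as separate tokens), and a
#' digit-to-letter boundary inside a token is split positionally (so glued
#' forms like \code{"5mls"} become \code{"5"}, \code{"mls"}).  Surfaces are
#' lowercased for matching; the original text and 0-based half-open
#' character offsets are preserved, so the input can be reconstructed from
#' \code{raw} and the offsets.
#'
#' @param text A single instruction string (may be empty).
#' @return A data frame with columns \code{surface} (lowercased),
#'   \code{raw}, \code{start}, \code{end} (0-based, half-open) and
#'   \code{kind} (\code{"word"}, \code{"number"} or \code{"punct"});
#'   zero rows for empty input.
#' @examples
#' tokenize("5mls daily")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(surface = character(), raw = character(),
                      start = integer(), end = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[0-9]+(?:\\.[0-9]+)?|[a-zA-Z]+|[^a-zA-Z0-9[:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m)
  len <- attr(m, "match.length")
  raw <- substring(text, start, start + len - 1L)
  kind <- ifelse(grepl("^[0-9]", raw), "number",
                 ifelse(grepl("^[a-zA-Z]", raw), "word", "punct"))
  data.frame(surface = tolower(raw), raw = raw,
             start = start - 1L, end = start + len - 1L,
             kind = kind, stringsAsFactors = FALSE)
}

# Numeric value of the token(s) starting at i, or NULL.
# Handles digits, word numbers ("two"), fractions ("half") and the
# article-prefixed "a half".
number_at <- function(tokens, i, lexicon) {
  if (i > nrow(tokens)) return(NULL)
  s <- tokens$surface[i]
  if (tokens$kind[i] == "number")
    return(list(value = as.numeric(s), len = 1L))
  v <- dict_get(lexicon, "number", s)
  if (!is.null(v)) return(list(value = as.numeric(v), len = 1L))
  if (s == "a" && i + 1L <= nrow(tokens)) {
    v <- dict_get(lexicon, "number", tokens$surface[i + 1L])
    if (!is.null(v)) return(list(value = as.numeric(v), len = 2L))
  }
  NULL
}

range_operator_at <- function(tokens, i, lexicon) {
  if (i > nrow(tokens)) return(NULL)
  v <- dict_get(lexicon, "rangeOperator", tokens$surface[i])
  if (is.null(v)) NULL else as.character(v)
}

#' Parse a numeric expression from a token window
#'
#' Reads a numeric mention starting at token \code{i}: a point value
#' (\code{"7"}, \code{"two"}, \code{"half"}, \code{"2.5"}), a range joined
#' by any range operator (\code{"1 to 3"}, \code{"2-4"}, \code{"one or
#' two"}, \code{"between 2 and 4"}) or an open lower bound (\code{"up to
#' three"}, read as minimum 0).  Range endpoints are kept in text order;
#' a reversed range (\code{"4 to 2"}) is returned as written with
#' \code{reversed = TRUE} so the consistency check in Step 2 can flag it.
#'
#' @param tokens A token data frame from \code{\link{tokenize}}.
#' @param i Index (1-based) of the candidate first token.
#' @param lexicon A \code{dose_lexicon}.
#' @return A list with \code{min}, \code{max}, \code{open_lower},
#'   \code{reversed}, \code{from}, \code{to} (token index range, inclusive),
#'   or \code{NULL} when no numeric expression starts at \code{i}.
#' @examples
#' parse_numeric(tokenize("one or two tablets"), 1)
#' @export
parse_numeric <- function(tokens, i, lexicon = default_lexicon()) {
  n <- nrow(tokens)
  if (i > n) return(NULL)
  mention <- function(mn, mx, open, to)
    list(min = mn, max = mx, open_lower = open,
         reversed = !open && mn > mx, from = i, to = to)
  s <- tokens$surface[i]
  # open lower bound: "up to N" / "upto N"
  if (s == "upto" || (s == "up" && i + 1L <= n && tokens$surface[i + 1L] == "to")) {
    at <- if (s == "upto") i + 1L else i + 2L
    b <- number_at(tokens, at, lexicon)
    if (!is.null(b))
      return(mention(0, b$value, TRUE, at + b$len - 1L))
    return(NULL)
  }
  # "between A and B"
  if (s == "between") {
    a <- number_at(tokens, i + 1L, lexicon)
    if (!is.null(a)) {
      j <- i + 1L + a$len
      if (j <= n && tokens$surface[j] == "and") {
        b <- number_at(tokens, j + 1L, lexicon)
        if (!is.null(b))
          return(mention(a$value, b$value, FALSE, j + b$len))
      }
    }
    return(NULL)
  }
  # a number that is the tail of a range ("1 to |3|", "between 2 and |4|")
  # does not start a numeric expression of its own
  if (i >= 3L) {
    op <- range_operator_at(tokens, i - 1L, lexicon)
    if (!is.null(op) && op %in% c("range", "between_and") &&
        !is.null(number_at(tokens, i - 2L, lexicon)))
      return(NULL)
  }
  a <- number_at(tokens, i, lexicon)
  if (is.null(a)) return(NULL)
  j <- i + a$len
  op <- range_operator_at(tokens, j, lexicon)
  if (!is.null(op) && op == "range") {
    b <- number_at(tokens, j + 1L, lexicon)
    if (!is.null(b))
      return(mention(a$value, b$value, FALSE, j + b$len))
  }
  mention(a$value, a$value, FALSE, i + a$len - 1L)
}

# ---- optional fuzzy token correction -----------------------------------
# Within restricted Damerau-Levenshtein distance 1 (one substitution,
# insertion, deletion or adjacent transposition)?
dl_within1 <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > 1L) return(FALSE)
  if (a == b) return(TRUE)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (la == lb) {
    diff <- which(ca != cb)
    if (length(diff) == 1L) return(TRUE)          # substitution
    if (length(diff) == 2L && diff[2] == diff[1] + 1L)
      return(ca[diff[1]] == cb[diff[2]] && ca[diff[2]] == cb[diff[1]])  # transposition
    return(FALSE)
  }
  # length differs by one: single insertion/deletion
  if (la > lb) { long <- ca; short <- cb } else { long <- cb; short <- ca }
  k <- 0L
  for (p in seq_along(long)) {
    if (k < length(short) && long[p] == short[k + 1L]) k <- k + 1L
    else if (p > k + 1L) return(FALSE)            # second mismatch
  }
  k == length(short)
}

# Replace unknown word tokens (length >= 4) by the unique vocabulary word
# within Damerau-Levenshtein distance 1, if any.  Exact dictionary hits and
# numbers are never touched, so clean text is parsed identically with the
# fuzzy mode on or off.
fuzzy_correct <- function(tokens, vocab) {
  for (i in seq_len(nrow(tokens))) {
    if (tokens$kind[i] != "word") next
    s <- tokens$surface[i]
    if (nchar(s) < 4L || s %in% vocab) next
    lens <- nchar(vocab)
    cand <- vocab[abs(lens - nchar(s)) <= 1L]
    hits <- cand[vapply(cand, dl_within1, logical(1), a = s)]
    if (length(hits) == 1L) tokens$surface[i] <- hits
  }
  tokens
}
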