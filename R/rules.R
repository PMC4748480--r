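# Step 1: pattern rules over tokens -> typed candidate mentions.
#
# A rule is an ordered pattern of constituents (literal anchors, dictionary
# classes, numeric placeholders, each optionally skippable) with a capture
# sub-span, bound to a target attribute.  Matching is a deterministic
# left-to-right scan; per attribute, overlapping matches are resolved
# longest-full-match-first with pack order breaking ties.

MENTION_ATTRIBUTES <- c("dose_number", "frequency", "interval", "unit",
                        "optionality", "meal", "timing")

#' Load a rule pack
#'
#' Parses mention-recognition rules from a plain-text rule pack.  Each
#' non-comment line has the form
#' \code{attribute[.tag] := constituent+} with the capture sub-span
#' delimited by \code{[} and \code{]}.  Constituents are \code{w(token)}
#' (literal word), \code{a(dict)} or \code{a(dict=payload)} (single token
#' from a lexicon dictionary), \code{d(dict)} (longest dictionary phrase),
#' \code{NUM} (numeric expression, see \code{\link{parse_numeric}}); a
#' leading \code{?} makes a constituent optional.  Syntax errors and
#' references to unknown dictionaries are reported with the file and line
#' of the offending rule.
#'
#' @param source Path to a rule-pack file; the bundled pack when
#'   \code{NULL}.
#' @param lexicon A \code{dose_lexicon}; dictionary references are checked
#'   against it at load time.
#' @return A \code{dose_rules} object (list of parsed rules).
#' @examples
#' rules <- default_rules()
#' length(rules)
#' @export
load_rules <- function(source = NULL, lexicon = default_lexicon()) {
  if (is.null(source))
    source <- system.file("extdata", "rules.txt", package = "rxsig")
  lines <- readLines(source, warn = FALSE)
  rules <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    rule <- tryCatch(parse_rule(line, lexicon),
                     error = function(e)
                       stop(sprintf("%s:%d: %s", source, ln, conditionMessage(e)),
                            call. = FALSE))
    rule$id <- length(rules) + 1L
    rule$line <- ln
    rules[[length(rules) + 1L]] <- rule
  }
  if (!length(rules)) stop("rule pack contains no rules: ", source)
  class(rules) <- "dose_rules"
  rules
}

parse_rule <- function(line, lexicon) {
  parts <- strsplit(line, ":=", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("expected 'attribute := pattern' in rule: ", line)
  head <- trimws(parts[1])
  attr_tag <- strsplit(head, ".", fixed = TRUE)[[1]]
  attribute <- attr_tag[1]
  tag <- if (length(attr_tag) > 1L) attr_tag[2] else ""
  if (!attribute %in% MENTION_ATTRIBUTES)
    stop("unknown attribute '", attribute, "'")
  toks <- strsplit(trimws(parts[2]), "[[:space:]]+")[[1]]
  cons <- list()
  cap_from <- cap_to <- NA_integer_
  for (t in toks) {
    if (t == "[") { cap_from <- length(cons) + 1L; next }
    if (t == "]") { cap_to <- length(cons); next }
    optional <- startsWith(t, "?")
    if (optional) t <- substring(t, 2L)
    if (t == "NUM") {
      cons[[length(cons) + 1L]] <- list(type = "num", optional = optional)
      next
    }
    m <- regmatches(t, regexec("^([wad])\\(([^)=]+)(?:=([^)]+))?\\)$", t))[[1]]
    if (length(m) == 0L)
      stop("malformed constituent '", t, "'")
    type <- m[2]; arg <- m[3]
    filter <- if (nzchar(m[4])) m[4] else NA_character_
    if (type %in% c("a", "d") && is.null(lexicon$dicts[[arg]]))
      stop("rule references unknown dictionary '", arg, "'")
    cons[[length(cons) + 1L]] <- list(type = type, arg = arg,
                                      filter = filter, optional = optional)
  }
  if (is.na(cap_from) || is.na(cap_to) || cap_from > cap_to ||
      cap_to > length(cons))
    stop("rule must contain a well-formed [ capture ] span")
  list(attribute = attribute, tag = tag, cons = cons,
       cap_from = cap_from, cap_to = cap_to)
}

#' @rdname load_rules
#' @export
default_rules <- function() {
  if (is.null(.rxsig_env$rules))
    .rxsig_env$rules <- load_rules(lexicon = default_lexicon())
  .rxsig_env$rules
}

#' @export
print.dose_rules <- function(x, ...) {
  tab <- table(vapply(x, function(r) r$attribute, character(1)))
  cat("Mention-recognition rule pack:", length(x), "rules\n")
  print(tab)
  invisible(x)
}

# Literal words used by a rule pack (part of the fuzzy-matching vocabulary).
rule_literals <- function(rules) {
  unique(unlist(lapply(rules, function(r)
    vapply(Filter(function(c) c$type == "w", r$cons),
           function(c) c$arg, character(1)))))
}

# dictionary phrases tokenized, longest first (cached per lexicon)
phrase_index <- function(lexicon) {
  if (!is.null(lexicon$phrases)) return(lexicon$phrases)
  idx <- lapply(lexicon$dicts, function(d) {
    ph <- lapply(names(d), function(k) strsplit(k, " ", fixed = TRUE)[[1]])
    ord <- order(vapply(ph, length, integer(1)), decreasing = TRUE)
    list(tokens = ph[ord], payload = unname(d)[ord])
  })
  idx
}

# Try to match rule constituents starting at constituent ci / token pos.
# Returns list(end, bind) or NULL; bind maps constituent index -> matched
# token range and payload.  Optional constituents are tried present-first.
match_cons <- function(rule, ci, pos, tokens, lexicon, phrases) {
  if (ci > length(rule$cons))
    return(list(end = pos, bind = list()))
  con <- rule$cons[[ci]]
  n <- nrow(tokens)
  try_with <- NULL
  if (pos <= n) {
    hit <- NULL
    if (con$type == "w") {
      if (tokens$surface[pos] == con$arg)
        hit <- list(to = pos, payload = NULL)
    } else if (con$type == "a") {
      p <- dict_get(lexicon, con$arg, tokens$surface[pos])
      if (!is.null(p) && (is.na(con$filter) || as.character(p) == con$filter))
        hit <- list(to = pos, payload = p)
    } else if (con$type == "d") {
      ph <- phrases[[con$arg]]
      for (k in seq_along(ph$tokens)) {
        pt <- ph$tokens[[k]]
        if (pos + length(pt) - 1L > n) next
        if (all(tokens$surface[pos:(pos + length(pt) - 1L)] == pt)) {
          p <- ph$payload[[k]]
          if (is.na(con$filter) || as.character(p) == con$filter) {
            hit <- list(to = pos + length(pt) - 1L, payload = p)
            break
          }
        }
      }
    } else if (con$type == "num") {
      nm <- parse_numeric(tokens, pos, lexicon)
      if (!is.null(nm))
        hit <- list(to = nm$to, payload = nm)
    }
    if (!is.null(hit)) {
      rest <- match_cons(rule, ci + 1L, hit$to + 1L, tokens, lexicon, phrases)
      if (!is.null(rest)) {
        rest$bind[[as.character(ci)]] <-
          list(from = pos, to = hit$to, type = con$type,
               arg = con$arg %||% "", payload = hit$payload)
        try_with <- rest
      }
    }
  }
  if (!is.null(try_with)) return(try_with)
  if (isTRUE(con$optional))
    return(match_cons(rule, ci + 1L, pos, tokens, lexicon, phrases))
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_mentions <- function() {
  data.frame(attribute = character(), tag = character(),
             cap_from = integer(), cap_to = integer(),
             m_from = integer(), m_to = integer(),
             vmin = numeric(), vmax = numeric(),
             open_lower = logical(), reversed = logical(),
             tunit = character(), value = character(),
             rule_id = integer(), stringsAsFactors = FALSE)
}

#' Match rules over a token stream
#'
#' Applies a rule pack to a tokenized instruction and returns the typed
#' candidate mentions (Step 1).  Matching never crosses a \code{"/"}
#' separator: the clauses on either side are matched independently.  When
#' two matches for the same attribute overlap, the longer full match wins,
#' with ties broken by pack order; a number already consumed by a frequency,
#' interval or meal mention is not also reported as a dose number.
#'
#' @param tokens A token data frame from \code{\link{tokenize}}.
#' @param rules A \code{dose_rules} pack.
#' @param lexicon A \code{dose_lexicon}.
#' @return A data frame of mentions with the attribute, capture and full
#'   match token ranges, numeric payload (\code{vmin}, \code{vmax},
#'   \code{open_lower}, \code{reversed}), time unit, semantic payload
#'   \code{value} and the matching rule id.  Zero rows when nothing
#'   matches.
#' @examples
#' match_rules(tokenize("take 2 tablets 4 times a day"))
#' @export
match_rules <- function(tokens, rules = default_rules(),
                        lexicon = default_lexicon()) {
  if (nrow(tokens) == 0L) return(empty_mentions())
  phrases <- phrase_index(lexicon)
  slash <- which(tokens$surface == "/")
  bounds <- c(0L, slash, nrow(tokens) + 1L)
  out <- list()
  for (s in seq_len(length(bounds) - 1L)) {
    lo <- bounds[s] + 1L; hi <- bounds[s + 1L] - 1L
    if (lo > hi) next
    seg <- tokens[lo:hi, , drop = FALSE]
    out[[length(out) + 1L]] <- match_segment(seg, rules, lexicon, phrases,
                                             offset = lo - 1L)
  }
  men <- if (length(out)) do.call(rbind, out) else empty_mentions()
  resolve_conflicts(men)
}

match_segment <- function(seg, rules, lexicon, phrases, offset) {
  res <- empty_mentions()
  n <- nrow(seg)
  for (r in rules) {
    for (pos in seq_len(n)) {
      m <- match_cons(r, 1L, pos, seg, lexicon, phrases)
      if (is.null(m)) next
      if (m$end == pos) next                       # zero-width (all optional)
      men <- assemble_mention(r, m, seg, offset)
      if (!is.null(men)) res <- rbind(res, men)
    }
  }
  res
}

# Build one mention row from a successful rule match: the capture span plus
# the semantic payload gathered across the whole pattern (numeric mention,
# time unit, dictionary value).
assemble_mention <- function(rule, m, seg, offset) {
  binds <- m$bind
  idx <- as.integer(names(binds))
  cap <- binds[idx >= rule$cap_from & idx <= rule$cap_to]
  if (!length(cap)) return(NULL)                   # capture entirely optional
  cf <- min(vapply(cap, function(b) b$from, integer(1)))
  ct <- max(vapply(cap, function(b) b$to, integer(1)))
  mf <- min(vapply(binds, function(b) b$from, integer(1)))
  mt <- max(vapply(binds, function(b) b$to, integer(1)))
  vmin <- vmax <- NA_real_
  open_lower <- reversed <- FALSE
  tunit <- NA_character_
  value <- NA_character_
  for (b in binds) {
    if (b$type == "num") {
      vmin <- b$payload$min; vmax <- b$payload$max
      open_lower <- b$payload$open_lower; reversed <- b$payload$reversed
    } else if (b$type %in% c("a", "d")) {
      if (b$arg %in% c("timeUnit", "timeUnitLy", "perTimeUnit"))
        tunit <- as.character(b$payload)
      else if (!is.null(b$payload))
        value <- as.character(b$payload)
    }
  }
  attribute <- rule$attribute
  # the ambiguous "N per day" reading (frequency N, dose 1) only exists for
  # a point numeral; a range before a daily adverb is a dose range
  if (rule$tag == "nperday" && (open_lower || vmin != vmax)) return(NULL)
  if (attribute == "frequency" && is.na(vmin)) {
    # payload-borne frequency: latin shorthand value, or 1 for a bare
    # time-unit adverb ("daily", "every week")
    f <- suppressWarnings(as.numeric(value))
    if (is.na(f)) f <- 1
    vmin <- vmax <- f
  }
  if (attribute == "interval" && is.na(vmin) && !is.na(value)) {
    vmin <- vmax <- suppressWarnings(as.numeric(value))   # period in days
    tunit <- "day"
  }
  if (attribute == "meal")
    vmin <- vmax <- suppressWarnings(as.numeric(value))
  if (attribute %in% c("frequency", "interval") && is.na(tunit))
    tunit <- "day"
  data.frame(attribute = attribute, tag = rule$tag,
             cap_from = cf + offset, cap_to = ct + offset,
             m_from = mf + offset, m_to = mt + offset,
             vmin = vmin, vmax = vmax,
             open_lower = open_lower, reversed = reversed,
             tunit = tunit, value = value,
             rule_id = rule$id, stringsAsFactors = FALSE)
}

overlaps <- function(f1, t1, f2, t2) f1 <= t2 & t1 >= f2

resolve_conflicts <- function(men) {
  if (nrow(men) == 0L) return(men)
  kept <- list()
  for (attr in unique(men$attribute)) {
    sub <- men[men$attribute == attr, , drop = FALSE]
    ord <- order(-(sub$m_to - sub$m_from), sub$rule_id)
    sub <- sub[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(sub))
    # a later (shorter) match is dropped when its capture lies inside a
    # kept match's full span; captures outside the span (e.g. a range
    # extension anchored on the same unit token) survive
    for (i in seq_len(nrow(sub))) {
      if (!keep[i]) next
      later <- which(keep & seq_len(nrow(sub)) > i)
      for (j in later)
        if (overlaps(sub$cap_from[j], sub$cap_to[j], sub$m_from[i], sub$m_to[i]))
          keep[j] <- FALSE
    }
    kept[[attr]] <- sub[keep, , drop = FALSE]
  }
  men <- do.call(rbind, kept)
  # numbers consumed by frequency/interval/meal matches are not dose numbers
  consumers <- men[men$attribute %in% c("frequency", "interval", "meal"), ,
                   drop = FALSE]
  if (nrow(consumers)) {
    dn <- men$attribute == "dose_number"
    drop <- dn & vapply(seq_len(nrow(men)), function(i)
      any(overlaps(men$cap_from[i], men$cap_to[i],
                   consumers$m_from, consumers$m_to)), logical(1))
    # likewise a frequency reading of a number inside an interval match
    iv <- consumers[consumers$attribute == "interval", , drop = FALSE]
    if (nrow(iv)) {
      fq <- men$attribute == "frequency"
      drop <- drop | (fq & vapply(seq_len(nrow(men)), function(i)
        any(overlaps(men$cap_from[i], men$cap_to[i],
                     iv$m_from, iv$m_to)), logical(1)))
    }
    men <- men[!drop, , drop = FALSE]
  }
  men <- men[order(men$cap_from, men$cap_to), , drop = FALSE]
  rownames(men) <- NULL
  men
}
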