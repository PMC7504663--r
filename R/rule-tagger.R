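# Rule-based PHI tagger.
#
# Deterministic keyword/suffix rules for four of the five tag types (there
# is no reliable surface rule for person names, so the rule tagger never
# predicts person spans):
#
#  * age:      numeral token immediately followed by 歳 / 才 / 代
#  * sex:      token equal to 男性 / 女性, or an English sex word
#  * time:     (i) slash dates yyyy/mm and mm/dd with the bounds
#              1 <= mm <= 12 and 1 <= dd <= 31, (ii) standalone calendar
#              keywords, (iii) numeral + classifier unit (年月週間日時分);
#              each detected span is then extended once over a following
#              extender string (より, まで, 頃, から, 頃から, ...) with
#              longest match winning
#  * hospital: context keywords (近医 当院 同院), and a maximal run of
#              noun tokens (detailed POS not "non-autonomous word") or
#              placeholder symbols immediately followed by a name suffix
#              (病院 クリニック 医院); a bare suffix token with no
#              preceding run is not tagged
#
# Overlaps between rules are resolved by longest span first, ties broken by
# the fixed priority age > time > hospital > sex.

# tokens immediately adjacent (no gap) helper: TRUE if token j+1 starts
# where token j ends
adjacent <- function(tokens, j) {
  j + 1 <= nrow(tokens) && tokens$begin[j + 1] == tokens$end[j]
}

is_numeral_token <- function(tokens) {
  tokens$detailed_pos == "numeral" | is_all_digits(tokens$surface)
}

#' Rule: tag age spans
#'
#' Every numeral token immediately followed by an age unit (歳, 才, 代)
#' yields one age span covering numeral + unit.
#'
#' @param tokens Token tibble for one document ([tokenize()]).
#' @param lexicon Rule lexicon ([default_rule_lexicon()]).
#' @return A span tibble.
#' @export
tag_age <- function(tokens, lexicon = default_rule_lexicon()) {
  if (nrow(tokens) < 2) return(empty_spans())
  num <- is_numeral_token(tokens)
  hits <- which(num[-nrow(tokens)] &
                tokens$surface[-1] %in% lexicon$age_units &
                tokens$begin[-1] == tokens$end[-nrow(tokens)])
  if (length(hits) == 0) return(empty_spans())
  phi_spans("a", tokens$begin[hits], tokens$end[hits + 1])
}

#' Rule: tag sex spans
#'
#' Tokens equal to a Japanese sex word, or (case-insensitively) to an
#' English sex word, yield a sex span.
#'
#' @inheritParams tag_age
#' @return A span tibble.
#' @export
tag_sex <- function(tokens, lexicon = default_rule_lexicon()) {
  hits <- which(tokens$surface %in% lexicon$sex_words_ja |
                tolower(tokens$surface) %in% tolower(lexicon$sex_words_en))
  if (length(hits) == 0) return(empty_spans())
  phi_spans("x", tokens$begin[hits], tokens$end[hits])
}

#' Rule: tag time spans
#'
#' Applies the three time patterns (slash dates with month/day bounds,
#' standalone calendar keywords, numeral + classifier unit) and then
#' extends each detected span once via [extend_time_span()].
#'
#' @inheritParams tag_age
#' @return A span tibble (entries may overlap before resolution).
#' @export
tag_time <- function(tokens, lexicon = default_rule_lexicon()) {
  n <- nrow(tokens)
  if (n == 0) return(empty_spans())
  num <- is_numeral_token(tokens)
  ndig <- nchar_cp(tokens$surface)
  spans <- list()

  # (i) slash dates: numeral / numeral token triples
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      if (!(num[i] && tokens$surface[i + 1] == "/" && num[i + 2])) next
      if (!(adjacent(tokens, i) && adjacent(tokens, i + 1))) next
      a <- digit_value(tokens$surface[i])
      b <- digit_value(tokens$surface[i + 2])
      ok <- (ndig[i] == 4 && ndig[i + 2] <= 2 && b >= 1 && b <= 12) ||     # yyyy/mm
            (ndig[i] <= 2 && ndig[i + 2] <= 2 &&
             a >= 1 && a <= 12 && b >= 1 && b <= 31)                       # mm/dd
      if (ok) {
        spans[[length(spans) + 1]] <-
          tibble::tibble(tag_type = "t", begin = tokens$begin[i],
                         end = tokens$end[i + 2])
      }
    }
  }

  # (ii) standalone calendar keywords
  kw <- which(tokens$surface %in% lexicon$time_keywords)
  for (i in kw) {
    spans[[length(spans) + 1]] <-
      tibble::tibble(tag_type = "t", begin = tokens$begin[i],
                     end = tokens$end[i])
  }

  # (iii) numeral + classifier unit
  if (n >= 2) {
    un <- which(num[-n] & tokens$surface[-1] %in% lexicon$time_units &
                tokens$begin[-1] == tokens$end[-n])
    for (i in un) {
      spans[[length(spans) + 1]] <-
        tibble::tibble(tag_type = "t", begin = tokens$begin[i],
                       end = tokens$end[i + 1])
    }
  }

  if (length(spans) == 0) return(empty_spans())
  spans <- dplyr::bind_rows(spans)
  spans$begin <- as.integer(spans$begin)
  spans$end <- as.integer(spans$end)
  # rule 3: extend each span once over a following extender
  for (k in seq_len(nrow(spans))) {
    spans$end[k] <- extend_time_span(spans[k, ], tokens, lexicon)$end
  }
  dplyr::distinct(spans)
}

#' Extend a time span over a following extender string
#'
#' If the tokens immediately following the span spell an extender (より,
#' まで, 前半, 後半, 以上, 以下, 時, 頃, ごろ, ころ, から, or a compound
#' such as 頃から), the span end advances to cover it. The longest matching
#' extender wins and extension is applied once (no cascading re-scan).
#'
#' @param span One-row span tibble of type time.
#' @param tokens Token tibble of the same document.
#' @inheritParams tag_age
#' @return The (possibly extended) one-row span tibble.
#' @export
extend_time_span <- function(span, tokens, lexicon = default_rule_lexicon()) {
  stopifnot(nrow(span) == 1)
  j <- which(tokens$begin == span$end)      # first token after the span
  if (length(j) != 1) return(span)
  # candidate strings spelled by the next 1..3 adjacent tokens
  cand <- character(0)
  ends <- integer(0)
  k <- j
  txt <- ""
  while (k <= nrow(tokens) && length(cand) < 3 &&
         (k == j || tokens$begin[k] == tokens$end[k - 1])) {
    txt <- paste0(txt, tokens$surface[k])
    cand <- c(cand, txt)
    ends <- c(ends, tokens$end[k])
    k <- k + 1
  }
  hit <- cand %in% lexicon$span_extenders
  if (!any(hit)) return(span)
  best <- max(which(hit))     # longest match
  span$end <- ends[best]
  span
}

#' Rule: tag hospital spans
#'
#' Context keywords (近医, 当院, 同院) are tagged directly. A maximal run
#' of noun tokens whose detailed POS is not "non-autonomous word", or
#' placeholder-symbol tokens (●◯▲■), immediately followed by a name suffix
#' (病院, クリニック, 医院) becomes one hospital span covering run +
#' suffix. A token that itself ends in a suffix (e.g. a dictionary-
#' registered full name) is tagged together with any preceding run.
#'
#' @inheritParams tag_age
#' @return A span tibble.
#' @export
tag_hospital <- function(tokens, lexicon = default_rule_lexicon()) {
  n <- nrow(tokens)
  if (n == 0) return(empty_spans())
  spans <- list()

  ctx <- which(tokens$surface %in% lexicon$hospital_context_keywords)
  for (i in ctx) {
    spans[[length(spans) + 1]] <-
      tibble::tibble(tag_type = "h", begin = tokens$begin[i],
                     end = tokens$end[i])
  }

  runnable <- (tokens$pos == "noun" &
               tokens$detailed_pos != "non-autonomous word") |
              tokens$detailed_pos == "placeholder"
  exact_suffix <- tokens$surface %in% lexicon$hospital_suffixes
  ends_suffix <- !exact_suffix & vapply(tokens$surface, function(s) {
    any(vapply(lexicon$hospital_suffixes, function(sf) {
      nchar_cp(s) > nchar_cp(sf) && endsWith(s, sf)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)

  for (j in which(exact_suffix | ends_suffix)) {
    i <- j
    while (i - 1 >= 1 && runnable[i - 1] &&
           tokens$begin[i] == tokens$end[i - 1] &&
           !tokens$surface[i - 1] %in% lexicon$hospital_suffixes) {
      i <- i - 1
    }
    if (i == j && exact_suffix[j]) next     # bare suffix, no run
    spans[[length(spans) + 1]] <-
      tibble::tibble(tag_type = "h", begin = tokens$begin[i],
                     end = tokens$end[j])
  }
  if (length(spans) == 0) return(empty_spans())
  out <- dplyr::distinct(dplyr::bind_rows(spans))
  out$begin <- as.integer(out$begin)
  out$end <- as.integer(out$end)
  out
}

# Resolve overlapping candidate spans: longest first, ties by tag priority
# (age > time > hospital > sex > person), then leftmost. Greedy selection.
resolve_spans <- function(spans) {
  if (nrow(spans) <= 1) return(dplyr::arrange(spans, .data$begin))
  priority <- c(a = 1, t = 2, h = 3, x = 4, p = 5)
  ord <- order(-(spans$end - spans$begin), priority[spans$tag_type],
               spans$begin)
  spans <- spans[ord, ]
  keep <- logical(nrow(spans))
  taken_b <- integer(0)
  taken_e <- integer(0)
  for (k in seq_len(nrow(spans))) {
    if (!any(spans$begin[k] < taken_e & spans$end[k] > taken_b)) {
      keep[k] <- TRUE
      taken_b <- c(taken_b, spans$begin[k])
      taken_e <- c(taken_e, spans$end[k])
    }
  }
  dplyr::arrange(spans[keep, ], .data$begin)
}

#' Apply the full rule-based tagger
#'
#' Runs the four rules on each document, resolves overlaps (longest span
#' wins; ties broken by the priority age > time > hospital > sex) and
#' returns the corpus with predicted spans. Deterministic and idempotent;
#' never produces person spans.
#'
#' @param x A corpus tibble ([parse_inline()]) or character vector of plain
#'   texts. Existing spans are ignored and replaced by predictions.
#' @param tokenizer Tokenizer backend.
#' @param lexicon Rule lexicon.
#' @return A corpus tibble with predicted `spans`.
#' @export
#' @examples
#' rule_tag("工場に勤めている64歳の男性。")$spans[[1]]
rule_tag <- function(x, tokenizer = deid_tokenizer(),
                     lexicon = default_rule_lexicon()) {
  validate_lexicon(lexicon)
  if (is.character(x)) x <- new_corpus(paste0("doc", seq_along(x)), x,
                                       "synthetic", rep(list(empty_spans()),
                                                        length(x)))
  x$spans <- lapply(x$text, function(txt) {
    toks <- tokenize(txt, tokenizer)
    cand <- dplyr::bind_rows(
      tag_age(toks, lexicon),
      tag_sex(toks, lexicon),
      tag_time(toks, lexicon),
      tag_hospital(toks, lexicon)
    )
    if (nrow(cand) == 0) return(empty_spans())
    resolve_spans(cand)
  })
  x
}
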