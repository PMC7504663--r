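# Independent brute-force reference for the rule tagger: enumerate every
# contiguous token window, test each rule predicate directly on the window,
# then resolve overlaps by repeatedly picking the best remaining span.
# Deliberately quadratic and naive; shares only the tokenizer with the
# implementation under test.

reference_rule_tag <- function(text, tokenizer = deid_tokenizer(),
                               lexicon = default_rule_lexicon()) {
  toks <- tokenize(text, tokenizer)
  n <- nrow(toks)
  cand <- list()
  add <- function(ty, b, e) {
    cand[[length(cand) + 1]] <<- data.frame(tag_type = ty, begin = b, end = e)
  }
  is_digit_surface <- function(s) {
    chs <- strsplit(s, "")[[1]]
    length(chs) > 0 && all(char_type(chs) == "number")
  }
  num_val <- function(s) {
    as.numeric(chartr("０１２３４５６７８９",
                      "0123456789", s))
  }
  contiguous <- function(i, j) {
    i == j || all(toks$begin[(i + 1):j] == toks$end[i:(j - 1)])
  }
  # extension: longest extender spelled exactly by the tokens following `j`
  extended_end <- function(j) {
    e <- toks$end[j]
    best <- e
    txt <- ""
    k <- j + 1
    while (k <= n && k <= j + 3 &&
           toks$begin[k] == (if (k == j + 1) e else toks$end[k - 1])) {
      txt <- paste0(txt, toks$surface[k])
      if (txt %in% lexicon$span_extenders) best <- toks$end[k]
      k <- k + 1
    }
    best
  }
  runnable <- function(i) {
    (toks$pos[i] == "noun" &&
       toks$detailed_pos[i] != "non-autonomous word") ||
      toks$detailed_pos[i] == "placeholder"
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j > i && !contiguous(i, j)) break
      w <- toks[i:j, ]
      len <- j - i + 1
      # age: numeral + age unit
      if (len == 2 && is_digit_surface(w$surface[1]) &&
          w$surface[2] %in% lexicon$age_units) {
        add("a", w$begin[1], w$end[2])
      }
      # sex: single token
      if (len == 1 && (w$surface %in% lexicon$sex_words_ja ||
                       tolower(w$surface) %in% tolower(lexicon$sex_words_en))) {
        add("x", w$begin, w$end)
      }
      # time: calendar keyword
      if (len == 1 && w$surface %in% lexicon$time_keywords) {
        add("t", w$begin, extended_end(j))
      }
      # time: numeral + classifier unit
      if (len == 2 && is_digit_surface(w$surface[1]) &&
          w$surface[2] %in% lexicon$time_units) {
        add("t", w$begin[1], extended_end(j))
      }
      # time: slash dates with month/day bounds
      if (len == 3 && is_digit_surface(w$surface[1]) &&
          w$surface[2] == "/" && is_digit_surface(w$surface[3])) {
        d1 <- nchar(w$surface[1]); d2 <- nchar(w$surface[3])
        a <- num_val(w$surface[1]); b <- num_val(w$surface[3])
        if ((d1 == 4 && d2 <= 2 && b >= 1 && b <= 12) ||
            (d1 <= 2 && d2 <= 2 && a >= 1 && a <= 12 && b >= 1 && b <= 31)) {
          add("t", w$begin[1], extended_end(j))
        }
      }
      # hospital: context keyword
      if (len == 1 && w$surface %in% lexicon$hospital_context_keywords) {
        add("h", w$begin, w$end)
      }
      # hospital: maximal noun/placeholder run + suffix
      last <- w$surface[len]
      exact <- last %in% lexicon$hospital_suffixes
      endsw <- !exact && any(vapply(lexicon$hospital_suffixes, function(sf) {
        nchar(last) > nchar(sf) && endsWith(last, sf)
      }, logical(1)))
      if ((exact || endsw) &&
          (len == 1 || all(vapply(i:(j - 1), runnable, logical(1)))) &&
          (len == 1 || !any(toks$surface[i:(j - 1)] %in%
                              lexicon$hospital_suffixes)) &&
          !(len == 1 && exact)) {
        maximal <- i == 1 || !runnable(i - 1) ||
          toks$end[i - 1] != toks$begin[i] ||
          toks$surface[i - 1] %in% lexicon$hospital_suffixes
        if (maximal) add("h", w$begin[1], w$end[len])
      }
    }
  }
  if (length(cand) == 0) return(empty_spans_tbl())
  cand <- unique(do.call(rbind, cand))
  # independent overlap resolution: repeatedly take the best remaining span
  prio <- c(a = 1, t = 2, h = 3, x = 4, p = 5)
  chosen <- list()
  while (nrow(cand) > 0) {
    size <- cand$end - cand$begin
    best <- order(-size, prio[cand$tag_type], cand$begin)[1]
    b <- cand[best, ]
    chosen[[length(chosen) + 1]] <- b
    overlap <- cand$begin < b$end & cand$end > b$begin
    cand <- cand[!overlap, , drop = FALSE]
  }
  out <- do.call(rbind, chosen)
  out <- out[order(out$begin), , drop = FALSE]
  tibble::tibble(tag_type = out$tag_type, begin = as.integer(out$begin),
                 end = as.integer(out$end))
}
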