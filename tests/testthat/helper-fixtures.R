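# Shared fixtures, generated in code.

# The three published example sentences with their gold annotations
# (discharge-summary, dummy-EHR and pathology styles). The rule tagger has
# no person rule, so `rule_expected` drops person spans.
worked_examples <- function() {
  tagged <- c(
    "工場に勤めている<a>64歳</a>の<x>男性</x>。",
    "施設入所中で寝たきりの<a>86歳</a><x>女性</x>。全介助",
    "院外標本 <h>静大皮フ科クリニック</h>、<p>桑田 智</p>"
  )
  gold <- parse_inline(tagged, doc_id = c("mednlp_ex", "dummy_ex", "path_ex"))
  rule_expected <- gold
  rule_expected$spans <- lapply(gold$spans,
                                function(s) s[s$tag_type != "p", ])
  list(tagged = tagged, gold = gold, rule_expected = rule_expected)
}

# Random "gnarly" sentence over atoms that stress every rule interaction
# (numerals, units, keywords, extenders, suffixes, placeholders, slashes).
random_rule_sentence <- function(max_chars = 40) {
  atoms <- c(
    as.character(sample(0:2030, 5)),
    "/", "/",
    "歳", "才", "代", "年", "月", "日",
    "時", "分", "週間",
    "昨日", "今年", "翌日", "同年", "本日",
    "より", "まで", "頃", "から", "ごろ",
    "前半", "後半", "以上", "以下",
    "男性", "女性", "woman", "MEN", "患者",
    "病院", "クリニック", "医院",
    "当院", "近医", "同院", "院外標本",
    "●", "●●", "▲",
    "発熱", "受診", "青葉", "静大皮フ科",
    "の", "に", "を", "、", "。", " "
  )
  n <- sample(2:9, 1)
  out <- paste(sample(atoms, n, replace = TRUE), collapse = "")
  substr(out, 1, max_chars)
}

# Random annotated document: random text plus random token-aligned,
# non-overlapping spans (for round-trip properties).
random_annotated_doc <- function(doc_id = "doc1") {
  alphabet <- c("あ", "い", "患", "者", "発", "熱",
                "ク", "リ", "ニ", "a", "b", "1", "9", "。",
                "、", " ", "病", "院", "昨", "日")
  n <- sample(5:60, 1)
  text <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
  toks <- tokenize(text)
  spans <- empty_spans_tbl()
  if (nrow(toks) > 0) {
    free <- rep(TRUE, nrow(toks))
    for (k in seq_len(sample(0:4, 1))) {
      i <- sample(nrow(toks), 1)
      j <- min(nrow(toks), i + sample(0:2, 1))
      if (!all(free[i:j])) next
      if (any(toks$surface[i:j] %in% c("。", "\n"))) next
      # spans must cover contiguous text
      if (toks$end[j] - toks$begin[i] !=
            sum(toks$end[i:j] - toks$begin[i:j])) next
      free[i:j] <- FALSE
      spans <- dplyr::bind_rows(spans, tibble::tibble(
        tag_type = sample(names(phi_tags()), 1),
        begin = toks$begin[i], end = toks$end[j]))
    }
  }
  spans <- dplyr::arrange(spans, begin)
  spans$begin <- as.integer(spans$begin)
  spans$end <- as.integer(spans$end)
  tibble::tibble(doc_id = doc_id, text = text, style = "synthetic",
                 spans = list(spans))
}

empty_spans_tbl <- function() {
  tibble::tibble(tag_type = character(), begin = integer(), end = integer())
}

span_df <- function(spans) {
  as.data.frame(dplyr::arrange(spans, begin, end, tag_type))
}

expect_same_spans <- function(a, b) {
  expect_equal(span_df(a), span_df(b), ignore_attr = TRUE)
}
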