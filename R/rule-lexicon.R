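#' Default keyword lexicon for the rule-based tagger
#'
#' The lexicon groups every keyword set the rules use: standalone calendar
#' vocabulary and its prefixed variants (`time_keywords`), numerical
#' classifier units that follow a numeral (`time_units`), span-extending
#' strings appended once after a detected time span (`span_extenders`,
#' longest match wins), age units (`age_units`), hospital context keywords
#' and name suffixes, sex words (Japanese plus English), and the placeholder
#' symbols used for manual masking.
#'
#' @return A named list of character vectors, class `deid_rule_lexicon`.
#' @seealso [read_rule_lexicon()], [rule_tag()]
#' @export
default_rule_lexicon <- function() {
  structure(list(
    time_keywords = c(
      "一昨年", "昨年", "先月", "先週",
      "昨日", "今年", "今月", "今週",
      "今日", "本日", "来年", "来月",
      "来週", "翌日", "再来週",
      "明後日", "同年", "同月", "同日",
      "翌年", "翌朝", "前日", "未明",
      "その後", "午前", "午後",
      "入院前", "入院後"
    ),
    time_units = c("年", "月", "週間", "日", "時", "分"),
    span_extenders = c(
      "より", "まで", "前半", "後半",
      "以上", "以下", "時", "頃",
      "ごろ", "ころ", "から",
      "前半から", "後半から", "頃から",
      "ごろから", "ころから"
    ),
    age_units = c("歳", "才", "代"),
    hospital_context_keywords = c("近医", "当院", "同院"),
    hospital_suffixes = c("病院", "クリニック", "医院"),
    sex_words_ja = c("男性", "女性"),
    sex_words_en = c("men", "women", "man", "woman"),
    placeholder_symbols = placeholder_chars()
  ), class = "deid_rule_lexicon")
}

validate_lexicon <- function(lexicon) {
  needed <- names(default_rule_lexicon())
  missing <- setdiff(needed, names(lexicon))
  if (length(missing)) {
    rlang::abort(paste0("rule lexicon is missing: ",
                        paste(missing, collapse = ", ")))
  }
  empty <- needed[vapply(lexicon[needed], length, integer(1)) == 0]
  if (length(empty)) {
    rlang::abort(paste0("rule lexicon sets must be non-empty: ",
                        paste(empty, collapse = ", ")))
  }
  invisible(lexicon)
}

#' Read / write a rule lexicon as a YAML config file
#'
#' One section per keyword set; sets omitted from the file fall back to the
#' defaults, so a config can override a single set.
#'
#' @param path File path.
#' @param lexicon A lexicon list (for writing).
#' @return `read_rule_lexicon()` returns a `deid_rule_lexicon`.
#' @export
read_rule_lexicon <- function(path) {
  raw <- yaml::read_yaml(path)
  lex <- default_rule_lexicon()
  for (nm in intersect(names(raw), names(lex))) {
    lex[[nm]] <- as.character(raw[[nm]])
  }
  validate_lexicon(lex)
  lex
}

#' @rdname read_rule_lexicon
#' @export
write_rule_lexicon <- function(lexicon, path) {
  yaml::write_yaml(unclass(lexicon), path)
  invisible(path)
}
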