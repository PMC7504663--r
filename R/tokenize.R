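# Tokenizer backend.
#
# Japanese has no inter-word spaces, so span taggers need a morphological
# analyzer front end. The package defines a pluggable backend contract (a
# `deid_tokenizer` object) and ships one deterministic built-in backend:
# longest match against a user dictionary and a built-in lexicon of function
# words, counters and clinical vocabulary, falling back to maximal runs of a
# single character class. POS output is normalized to a small internal
# vocabulary (`noun`, `particle`, `symbol`, `other` with detailed classes
# such as `numeral`, `suffix`, `temporal`, `non-autonomous word`,
# `placeholder`) so that downstream rules do not depend on the tagset
# dialect of any specific analyzer.

placeholder_chars <- function() c("●", "◯", "▲", "■") # ● ◯ ▲ ■

# Built-in lexicon: surfaces that must remain single tokens, with their
# normalized POS. Counters/units are `suffix`; calendar words `temporal`;
# hiragana function words `non-autonomous word`.
builtin_token_lexicon <- function() {
  entry <- function(surface, pos, detailed) {
    tibble::tibble(surface = surface, pos = pos, detailed_pos = detailed)
  }
  dplyr::bind_rows(
    # numerical classifiers / unit suffixes
    entry(c("歳", "才", "代",                       # 歳 才 代
            "年", "月", "日", "時", "分",   # 年 月 日 時 分
            "週間", "ヶ月", "か月",     # 週間 ヶ月 か月
            "頃"),                                          # 頃
          "noun", "suffix"),
    # calendar / relative-time vocabulary (standalone triggers and prefixes)
    entry(c("一昨年", "昨年", "先月", "先週",
            "昨日", "今年", "今月", "今週",
            "今日", "本日", "来年", "来月",
            "来週", "翌日", "再来週",
            "明後日", "同年", "同月", "同日",
            "翌年", "翌朝", "前日", "未明",
            "その後", "午前", "午後",
            "入院前", "入院後"),
          "noun", "temporal"),
    # span-extending vocabulary
    entry(c("前半", "後半", "以上", "以下",
            "上旬", "中旬", "下旬",
            "以前", "以降"),
          "noun", "temporal"),
    # hiragana function words
    entry(c("より", "まで", "から",     # より まで から
            "ごろ", "ころ", "ほど",     # ごろ ころ ほど
            "の", "に", "を", "は", "が", "で",
            "と", "も", "へ", "や",
            "され", "した", "して", "いる",
            "あり", "なし", "である"),
          "particle", "non-autonomous word"),
    # sex vocabulary
    entry(c("男性", "女性"), "noun", "general"), # 男性 女性
    # hospital vocabulary
    entry(c("病院", "クリニック", "医院"),
          "noun", "general"),                                    # 病院 クリニック 医院
    entry(c("近医", "当院", "同院"),     # 近医 当院 同院
          "noun", "general"),
    # common clinical vocabulary, kept whole for stable segmentation
    entry(c("院外標本",                          # 院外標本
            "発熱", "受診", "入院", "退院",
            "患者", "既往", "良好", "標本",
            "検査", "所見", "診断", "手術",
            "治療", "経過", "症状", "紹介"),
          "noun", "general")
  )
}

#' Create a tokenizer backend
#'
#' Builds the deterministic built-in analyzer backend. A custom user
#' dictionary can be supplied so that domain terms (hospital names, disease
#' names, ...) are segmented as single tokens and flagged `in_dictionary`,
#' mirroring how an IPADIC-style analyzer accepts user dictionaries.
#'
#' @param dictionary Optional tibble/data frame with columns `surface` and
#'   `pos` (optional `detailed_pos`, default `"proper"`). May also be a
#'   character vector of surfaces (all registered as nouns).
#' @return An object of class `deid_tokenizer`.
#' @seealso [register_dictionary()], [tokenize()], [read_dictionary_file()]
#' @export
deid_tokenizer <- function(dictionary = NULL) {
  tok <- structure(
    list(
      lexicon = builtin_token_lexicon(),
      dictionary = empty_dictionary()
    ),
    class = "deid_tokenizer"
  )
  if (!is.null(dictionary)) tok <- register_dictionary(tok, dictionary)
  tok
}

empty_dictionary <- function() {
  tibble::tibble(surface = character(), pos = character(),
                 detailed_pos = character())
}

#' Register user-dictionary entries with a tokenizer
#'
#' Subsequent [tokenize()] calls segment registered surfaces as single
#' tokens (longest match, taking precedence over the built-in lexicon) and
#' set their `in_dictionary` flag. Returns a new tokenizer; the original is
#' unchanged.
#'
#' @param tokenizer A `deid_tokenizer`.
#' @param entries Tibble with columns `surface`, `pos` (optional
#'   `detailed_pos`), or a character vector of surfaces.
#' @return The updated `deid_tokenizer`.
#' @export
#' @examples
#' tok <- register_dictionary(deid_tokenizer(), "静大皮フ科クリニック")
register_dictionary <- function(tokenizer, entries) {
  stopifnot(inherits(tokenizer, "deid_tokenizer"))
  if (is.character(entries)) {
    entries <- tibble::tibble(surface = entries, pos = "noun")
  }
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) return(tokenizer)
  if (!all(c("surface", "pos") %in% names(entries))) {
    rlang::abort("dictionary entries need columns `surface` and `pos`")
  }
  if (any(!nzchar(entries$surface) | is.na(entries$surface))) {
    rlang::abort("dictionary surfaces must be non-empty")
  }
  if (any(grepl("[。\n\t]", entries$surface))) {
    rlang::abort("dictionary surfaces must not contain sentence breaks or tabs")
  }
  if (!"detailed_pos" %in% names(entries)) entries$detailed_pos <- "proper"
  entries$detailed_pos[is.na(entries$detailed_pos)] <- "proper"
  tokenizer$dictionary <- dplyr::distinct(
    dplyr::bind_rows(tokenizer$dictionary,
                     entries[, c("surface", "pos", "detailed_pos")]),
    .data$surface, .keep_all = TRUE
  )
  tokenizer
}

#' Read a user-dictionary file
#'
#' Plain TSV, one entry per line: surface, POS, optionally detailed POS.
#'
#' @param path File path.
#' @return A tibble suitable for [register_dictionary()].
#' @export
read_dictionary_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_dictionary())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    surface = vapply(parts, `[`, character(1), 1),
    pos = vapply(parts, function(p) if (length(p) >= 2) p[2] else "noun",
                 character(1)),
    detailed_pos = vapply(parts, function(p) if (length(p) >= 3) p[3] else "proper",
                          character(1))
  )
}

# Build a lookup of match candidates indexed by first character, longest
# surface first. Dictionary entries beat lexicon entries of the same length.
match_index <- function(tokenizer) {
  dict <- tokenizer$dictionary
  lex <- tokenizer$lexicon
  all <- dplyr::bind_rows(
    dplyr::mutate(dict, in_dictionary = TRUE),
    dplyr::mutate(lex, in_dictionary = FALSE)
  )
  all <- dplyr::distinct(all, .data$surface, .keep_all = TRUE)
  all$first <- substr(all$surface, 1, 1)
  all$len <- nchar_cp(all$surface)
  all <- all[order(-all$len), ]
  split(all, all$first)
}

#' Tokenize Japanese text
#'
#' Segments text into sentences (split after `。` and newline) and tokens,
#' producing POS-annotated tokens whose surfaces tile the input text exactly
#' (character offsets are 0-based code points, document-wide).
#'
#' @param text A single string (UTF-8).
#' @param tokenizer A `deid_tokenizer`; defaults to the built-in backend.
#' @return A tibble with one row per token: `sentence_id`, `surface`, `pos`,
#'   `detailed_pos`, `begin`, `end`, `sentence_start`, `in_dictionary`.
#' @export
#' @examples
#' tokenize("64歳の男性。")
tokenize <- function(text, tokenizer = deid_tokenizer()) {
  if (!inherits(tokenizer, "deid_tokenizer")) {
    rlang::abort(paste0("unavailable tokenizer backend: ",
                        paste(class(tokenizer), collapse = "/")))
  }
  stopifnot(is.character(text), length(text) == 1)
  n <- nchar_cp(text)
  if (is.na(text) || n == 0) return(empty_tokens())

  chars <- strsplit(text, "")[[1]]
  types <- char_type(chars)
  idx <- match_index(tokenizer)
  placeholders <- placeholder_chars()

  # positions where a lexicon/dictionary match starts (character runs stop
  # there so counters and keywords stay separate tokens)
  lex_start <- logical(n)
  match_at <- vector("list", n)
  for (i in seq_len(n)) {
    cands <- idx[[chars[i]]]
    if (is.null(cands)) next
    for (k in seq_len(nrow(cands))) {
      len <- cands$len[k]
      if (i + len - 1 > n) next
      if (substr(text, i, i + len - 1) == cands$surface[k]) {
        lex_start[i] <- TRUE
        match_at[[i]] <- cands[k, ]
        break
      }
    }
  }

  surfaces <- character(0)
  pos <- character(0)
  det <- character(0)
  begin <- integer(0)
  in_dict <- logical(0)
  i <- 1L
  while (i <= n) {
    m <- match_at[[i]]
    if (!is.null(m)) {
      surfaces <- c(surfaces, m$surface)
      pos <- c(pos, m$pos)
      det <- c(det, m$detailed_pos)
      begin <- c(begin, i - 1L)
      in_dict <- c(in_dict, m$in_dictionary)
      i <- i + m$len
      next
    }
    ch <- chars[i]
    ty <- types[i]
    if (ch %in% c("。", "\n")) {            # sentence delimiters: single tokens
      j <- i
    } else if (ch %in% placeholders) {          # maximal placeholder run
      j <- i
      while (j + 1 <= n && chars[j + 1] %in% placeholders) j <- j + 1L
    } else {
      j <- i
      while (j + 1 <= n && types[j + 1] == ty && !lex_start[j + 1] &&
             !chars[j + 1] %in% c("。", "\n") &&
             !chars[j + 1] %in% placeholders) {
        j <- j + 1L
      }
    }
    surf <- substr(text, i, j)
    surfaces <- c(surfaces, surf)
    begin <- c(begin, i - 1L)
    in_dict <- c(in_dict, FALSE)
    if (ch %in% placeholders) {
      pos <- c(pos, "symbol"); det <- c(det, "placeholder")
    } else if (ty == "number") {
      pos <- c(pos, "noun"); det <- c(det, "numeral")
    } else if (ty %in% c("kanji", "katakana", "latin")) {
      pos <- c(pos, "noun"); det <- c(det, "general")
    } else if (ty == "hiragana") {
      pos <- c(pos, "other"); det <- c(det, "general")
    } else {
      pos <- c(pos, "symbol"); det <- c(det, "general")
    }
    i <- j + 1L
  }

  end <- begin + nchar_cp(surfaces)
  # sentence segmentation: a sentence ends after 。 or newline
  ends_sentence <- surfaces %in% c("。", "\n")
  sentence_id <- cumsum(dplyr::lag(ends_sentence, default = FALSE)) + 1L
  tibble::tibble(
    sentence_id = sentence_id,
    surface = surfaces,
    pos = pos,
    detailed_pos = det,
    begin = begin,
    end = end,
    sentence_start = !duplicated(sentence_id),
    in_dictionary = in_dict
  )
}

empty_tokens <- function() {
  tibble::tibble(
    sentence_id = integer(), surface = character(), pos = character(),
    detailed_pos = character(), begin = integer(), end = integer(),
    sentence_start = logical(), in_dictionary = logical()
  )
}
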