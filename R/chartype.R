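#' Classify characters by script type
#'
#' Maps every Unicode code point to exactly one of six classes:
#' `hiragana`, `katakana`, `kanji`, `number`, `latin`, `symbol`.
#' Half- and full-width digits both classify as `number`; half- and
#' full-width Latin letters as `latin`. Everything not covered by the
#' dedicated blocks (punctuation, spaces, the masking placeholders
#' ●◯▲■, ...) is `symbol`, which makes the function total.
#'
#' @param ch Character vector of single characters (one code point each).
#' @return Character vector of class names, same length as `ch`.
#' @export
#' @examples
#' char_type(c("歳", "６", "ク", "a", "の", "/"))
char_type <- function(ch) {
  if (length(ch) == 0) return(character())
  cp <- vapply(ch, function(c) utf8ToInt(c)[1], integer(1), USE.NAMES = FALSE)
  out <- rep("symbol", length(cp))
  out[(cp >= 0x3041 & cp <= 0x309F)] <- "hiragana"
  out[(cp >= 0x30A0 & cp <= 0x30FF) |    # incl. prolonged sound mark
      (cp >= 0x31F0 & cp <= 0x31FF) |
      (cp >= 0xFF66 & cp <= 0xFF9D)] <- "katakana"
  out[(cp >= 0x4E00 & cp <= 0x9FFF) |
      (cp >= 0x3400 & cp <= 0x4DBF) |
      (cp >= 0xF900 & cp <= 0xFAFF) |
      cp %in% c(0x3005, 0x3006, 0x3007)] <- "kanji"   # iteration marks, zero
  out[(cp >= 0x30 & cp <= 0x39) | (cp >= 0xFF10 & cp <= 0xFF19)] <- "number"
  out[(cp >= 0x41 & cp <= 0x5A) | (cp >= 0x61 & cp <= 0x7A) |
      (cp >= 0xFF21 & cp <= 0xFF3A) | (cp >= 0xFF41 & cp <= 0xFF5A)] <- "latin"
  out
}

# Dominant character class of a multi-character surface: the majority class
# of its characters; ties broken by the class of the first character.
surface_char_type <- function(surface) {
  vapply(surface, function(s) {
    types <- char_type(strsplit(s, "")[[1]])
    if (length(types) == 0) return("symbol")
    counts <- table(types)
    winners <- names(counts)[counts == max(counts)]
    if (length(winners) == 1) winners else types[types %in% winners][1]
  }, character(1), USE.NAMES = FALSE)
}

# TRUE where the surface consists entirely of digit characters
# (half- or full-width).
is_all_digits <- function(surface) {
  nzchar(surface) & !is.na(surface) &
    vapply(surface, function(s) {
      all(char_type(strsplit(s, "")[[1]]) == "number")
    }, logical(1), USE.NAMES = FALSE)
}

# Numeric value of a digit surface, converting full-width digits first.
digit_value <- function(surface) {
  half <- chartr("０１２３４５６７８９",
                 "0123456789", surface)
  suppressWarnings(as.numeric(half))
}
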