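# Inline-tag corpus format and IOB2 conversion.
#
# Annotated documents carry five PHI tag types as inline tags over raw
# UTF-8 text: <a> age, <x> sex, <t> time, <h> hospital, <p> person.
# Offsets are 0-based, half-open, and count Unicode code points, which keeps
# span positions independent of byte encoding and tokenizer choice.

tag_regex <- function() "<\\s*(/?)\\s*([A-Za-z]+)\\s*>"

new_corpus <- function(doc_id, text, style, spans, extra = NULL) {
  out <- tibble::tibble(
    doc_id = as.character(doc_id),
    text = as.character(text),
    style = as.character(style),
    spans = spans
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  out
}

#' Parse inline-tagged text into an annotated corpus
#'
#' Accepts tag variants with inner whitespace (`<a >`, `< x >`) as printed
#' in some sources. Tags must be well formed, non-nested, and drawn from the
#' five-type alphabet; violations raise an error naming the character
#' offset. Stray `<` characters that do not form a tag are treated as text.
#'
#' @param text Character vector of tagged document texts.
#' @param doc_id Optional document ids (default `doc1`, `doc2`, ...).
#' @param style Source style label stored with each document.
#' @return A corpus tibble with columns `doc_id`, `text` (tags stripped),
#'   `style`, and `spans` (list column of span tibbles, see [phi_spans()]).
#' @export
#' @examples
#' parse_inline("工場に勤めている<a>64歳</a>の<x>男性</x>。")
parse_inline <- function(text, doc_id = NULL, style = "synthetic") {
  stopifnot(is.character(text))
  if (is.null(doc_id)) doc_id <- paste0("doc", seq_along(text))
  stopifnot(length(doc_id) == length(text))
  parsed <- lapply(seq_along(text), function(i) parse_inline_one(text[i]))
  new_corpus(
    doc_id = doc_id,
    text = vapply(parsed, `[[`, character(1), "text"),
    style = style,
    spans = lapply(parsed, `[[`, "spans")
  )
}

parse_inline_one <- function(x) {
  stopifnot(length(x) == 1)
  if (is.na(x) || !nzchar(x)) {
    return(list(text = ifelse(is.na(x), "", x), spans = empty_spans()))
  }
  gm <- gregexpr(tag_regex(), x, perl = TRUE)
  m <- gm[[1]]
  if (m[1] == -1) return(list(text = x, spans = empty_spans()))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  tags <- regmatches(x, gm)[[1]]
  closing <- grepl("/", tags, fixed = TRUE)
  letters <- tolower(gsub("[^A-Za-z]", "", tags))

  spans <- empty_spans()
  open_type <- NULL
  open_begin <- NA_integer_
  removed <- 0L   # code points of tag markup consumed so far
  for (k in seq_along(starts)) {
    off_stripped <- starts[k] - 1L - removed
    if (!letters[k] %in% names(phi_tags())) {
      rlang::abort(sprintf("unknown tag <%s> at offset %d", letters[k],
                           off_stripped))
    }
    if (closing[k]) {
      if (is.null(open_type)) {
        rlang::abort(sprintf("closing </%s> without open tag at offset %d",
                             letters[k], off_stripped))
      }
      if (letters[k] != open_type) {
        rlang::abort(sprintf(
          "mismatched </%s> closing <%s> at offset %d",
          letters[k], open_type, off_stripped))
      }
      if (off_stripped == open_begin) {
        rlang::abort(sprintf("empty <%s> span at offset %d", open_type,
                             off_stripped))
      }
      spans <- dplyr::bind_rows(spans, tibble::tibble(
        tag_type = open_type, begin = open_begin, end = off_stripped))
      open_type <- NULL
    } else {
      if (!is.null(open_type)) {
        rlang::abort(sprintf("nested <%s> inside <%s> at offset %d",
                             letters[k], open_type, off_stripped))
      }
      open_type <- letters[k]
      open_begin <- off_stripped
    }
    removed <- removed + lens[k]
  }
  if (!is.null(open_type)) {
    rlang::abort(sprintf("unclosed <%s> at end of document", open_type))
  }
  stripped <- gsub(tag_regex(), "", x, perl = TRUE)
  spans$begin <- as.integer(spans$begin)
  spans$end <- as.integer(spans$end)
  validate_spans(spans, nchar_cp(stripped), check_overlap = TRUE)
  list(text = stripped, spans = spans)
}

#' Render an annotated corpus back to inline-tagged text
#'
#' Inverse of [parse_inline()]: tags are written in the compact form
#' `<a>...</a>`. Overlapping spans raise an error.
#'
#' @param corpus A corpus tibble as returned by [parse_inline()].
#' @return Character vector of tagged texts, one per document.
#' @export
render_inline <- function(corpus) {
  vapply(seq_len(nrow(corpus)), function(i) {
    render_inline_one(corpus$text[i], corpus$spans[[i]])
  }, character(1))
}

render_inline_one <- function(text, spans) {
  validate_spans(spans, nchar_cp(text), check_overlap = TRUE)
  if (nrow(spans) == 0) return(text)
  spans <- spans[order(spans$begin), ]
  out <- character(0)
  pos <- 0L
  for (k in seq_len(nrow(spans))) {
    out <- c(out,
             substr_cp(text, pos, spans$begin[k]),
             sprintf("<%s>", spans$tag_type[k]),
             substr_cp(text, spans$begin[k], spans$end[k]),
             sprintf("</%s>", spans$tag_type[k]))
    pos <- spans$end[k]
  }
  paste0(paste(out, collapse = ""), substr_cp(text, pos, nchar_cp(text)))
}

# substring by 0-based half-open code-point offsets
substr_cp <- function(text, from, to) {
  if (to <= from) return("")
  substr(text, from + 1L, to)
}

#' Convert character spans to token-level IOB2 labels
#'
#' The first token overlapping a span of type `tau` receives `B-tau`,
#' subsequent overlapping tokens `I-tau`, all others `O`. A span boundary
#' falling strictly inside a token is a boundary mismatch and raises an
#' error carrying the offending token and span (offsets are never silently
#' snapped).
#'
#' @param tokens Token tibble from [tokenize()] for one document.
#' @param spans Span tibble ([phi_spans()]), non-overlapping.
#' @return `tokens` with an added `label` column.
#' @export
spans_to_iob2 <- function(tokens, spans) {
  validate_spans(spans, check_overlap = TRUE)
  labels <- rep("O", nrow(tokens))
  if (nrow(spans) > 0 && nrow(tokens) > 0) {
    for (k in seq_len(nrow(spans))) {
      b <- spans$begin[k]; e <- spans$end[k]
      hit <- which(tokens$begin < e & tokens$end > b)
      if (length(hit) == 0) next
      if (tokens$begin[hit[1]] != b || tokens$end[hit[length(hit)]] != e) {
        rlang::abort(
          message = sprintf(
            "span (%d,%d,%s) does not align with token boundaries (token '%s' [%d,%d))",
            b, e, spans$tag_type[k],
            tokens$surface[hit[1]], tokens$begin[hit[1]], tokens$end[hit[1]]),
          class = "jpdeid_boundary_mismatch",
          span = spans[k, ], tokens = tokens[hit, ])
      }
      labels[hit] <- c(paste0("B-", spans$tag_type[k]),
                       rep(paste0("I-", spans$tag_type[k]), length(hit) - 1))
    }
  }
  tokens$label <- labels
  tokens
}

#' Recover character spans from an IOB2-labeled token sequence
#'
#' Maximal `B-tau (I-tau)*` runs become one span each. In `strict` mode an
#' IOB2-invalid sequence (an `I-tau` not preceded by `B-tau`/`I-tau`) raises
#' an error; in `lenient` mode such labels are repaired to `B-tau` with a
#' warning, which tolerates third-party tagger output.
#'
#' @param labeled Token tibble with a `label` column.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A span tibble.
#' @export
iob2_to_spans <- function(labeled, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  labels <- labeled$label
  bad <- which(!labels %in% iob2_labels())
  if (length(bad)) {
    rlang::abort(sprintf("unknown IOB2 label '%s' at position %d",
                         labels[bad[1]], bad[1]))
  }
  prev <- c("O", labels[-length(labels)])
  is_i <- startsWith(labels, "I-")
  tau <- sub("^[BI]-", "", labels)
  prev_tau <- sub("^[BI]-", "", prev)
  invalid <- is_i & (prev == "O" | prev_tau != tau)
  if (any(invalid)) {
    if (mode == "strict") {
      k <- which(invalid)[1]
      rlang::abort(sprintf(
        "IOB2-invalid label '%s' at position %d (preceded by '%s')",
        labels[k], k, prev[k]), class = "jpdeid_iob2_invalid")
    }
    rlang::warn(sprintf("repaired %d IOB2-invalid label(s) as B-*",
                        sum(invalid)))
    labels[invalid] <- sub("^I-", "B-", labels[invalid])
  }
  starts <- which(startsWith(labels, "B-"))
  if (length(starts) == 0) return(empty_spans())
  spans <- lapply(starts, function(s) {
    ty <- sub("^B-", "", labels[s])
    e <- s
    while (e + 1 <= length(labels) && labels[e + 1] == paste0("I-", ty)) {
      e <- e + 1
    }
    tibble::tibble(tag_type = ty, begin = labeled$begin[s],
                   end = labeled$end[e])
  })
  dplyr::arrange(dplyr::bind_rows(spans), .data$begin)
}

# ---- labeled-sequence corpus <-> CoNLL-style TSV -------------------------

#' Convert an annotated corpus into labeled token sequences
#'
#' Tokenizes every document and projects its gold spans onto IOB2 labels.
#' One row per document; the `tokens` list column holds labeled token
#' tibbles.
#'
#' @param corpus Corpus tibble.
#' @param tokenizer Tokenizer backend.
#' @return Tibble with columns `doc_id`, `tokens`.
#' @export
as_labeled_sequences <- function(corpus, tokenizer = deid_tokenizer()) {
  tibble::tibble(
    doc_id = corpus$doc_id,
    tokens = lapply(seq_len(nrow(corpus)), function(i) {
      spans_to_iob2(tokenize(corpus$text[i], tokenizer), corpus$spans[[i]])
    })
  )
}

#' Write labeled sequences as a CoNLL-style IOB2 TSV file
#'
#' One token per line (surface, POS, detailed POS, label), a blank line
#' between sentences, and a `# doc_id = ...` comment line before each
#' document. `write_iob2_file()` followed by [read_iob2_file()] is the
#' identity on these four columns.
#'
#' @param labeled Tibble with `doc_id` and `tokens` (see
#'   [as_labeled_sequences()]).
#' @param path Output path.
#' @export
write_iob2_file <- function(labeled, path) {
  lines <- character(0)
  for (i in seq_len(nrow(labeled))) {
    lines <- c(lines, sprintf("# doc_id = %s", labeled$doc_id[i]))
    toks <- labeled$tokens[[i]]
    if (nrow(toks) > 0) {
      for (sid in unique(toks$sentence_id)) {
        s <- toks[toks$sentence_id == sid, ]
        lines <- c(lines,
                   paste(s$surface, s$pos, s$detailed_pos, s$label, sep = "\t"),
                   "")
      }
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a CoNLL-style IOB2 TSV file
#'
#' @param path Input path.
#' @return Tibble with `doc_id` and `tokens` list column; token offsets are
#'   reconstructed from the tiling surfaces.
#' @export
read_iob2_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur_id <- NULL
  cur_rows <- list()
  sid <- 1L
  flush_doc <- function() {
    if (is.null(cur_id)) return()
    toks <- if (length(cur_rows)) dplyr::bind_rows(cur_rows) else
      dplyr::mutate(empty_tokens(), label = character(0))
    if (nrow(toks) > 0) {
      toks$end <- cumsum(nchar_cp(toks$surface))
      toks$begin <- toks$end - nchar_cp(toks$surface)
      toks$sentence_start <- !duplicated(toks$sentence_id)
      toks$in_dictionary <- FALSE
      toks <- toks[, c("sentence_id", "surface", "pos", "detailed_pos",
                       "begin", "end", "sentence_start", "in_dictionary",
                       "label")]
    }
    docs[[length(docs) + 1]] <<- tibble::tibble(doc_id = cur_id,
                                                tokens = list(toks))
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "# doc_id = ")) {
      flush_doc()
      cur_id <- sub("^# doc_id = ", "", line)
      cur_rows <- list()
      sid <- 1L
    } else if (!nzchar(line)) {
      sid <- sid + 1L
    } else {
      if (is.null(cur_id)) {
        rlang::abort(sprintf("line %d: token before any '# doc_id =' header", ln))
      }
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 4) {
        rlang::abort(sprintf("line %d: expected 4 tab-separated columns, got %d",
                             ln, length(parts)))
      }
      cur_rows[[length(cur_rows) + 1]] <- tibble::tibble(
        sentence_id = sid, surface = parts[1], pos = parts[2],
        detailed_pos = parts[3], label = parts[4])
    }
  }
  flush_doc()
  if (length(docs) == 0) {
    return(tibble::tibble(doc_id = character(), tokens = list()))
  }
  dplyr::bind_rows(docs)
}

#' Read / write inline-tagged corpus files
#'
#' Documents are stored in one UTF-8 text file, each introduced by a
#' `# doc_id = ...` header line and covering the lines until the next
#' header.
#'
#' @param path File path.
#' @param corpus Corpus tibble (for writing).
#' @param style Style label applied to all documents on reading.
#' @return `read_inline_file()` returns a corpus tibble.
#' @export
read_inline_file <- function(path, style = "synthetic") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- grepl("^# doc_id = ", lines)
  if (!any(hdr)) {
    txt <- paste(lines, collapse = "\n")
    return(parse_inline(txt, doc_id = sub("\\.[^.]*$", "", basename(path)),
                        style = style))
  }
  grp <- cumsum(hdr)
  ids <- sub("^# doc_id = ", "", lines[hdr])
  texts <- vapply(seq_along(ids), function(g) {
    body <- lines[grp == g & !hdr]
    paste(body, collapse = "\n")
  }, character(1))
  parse_inline(texts, doc_id = ids, style = style)
}

#' @rdname read_inline_file
#' @export
write_inline_file <- function(corpus, path) {
  rendered <- render_inline(corpus)
  lines <- unlist(lapply(seq_len(nrow(corpus)), function(i) {
    c(sprintf("# doc_id = %s", corpus$doc_id[i]),
      strsplit(rendered[i], "\n", fixed = TRUE)[[1]])
  }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
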