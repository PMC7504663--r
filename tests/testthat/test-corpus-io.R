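test_that("parse_inline recovers text and spans from the worked examples", {
  ex <- worked_examples()
  doc <- parse_inline("工場に勤めている<a>64歳</a>の<x>男性</x>。")
  expect_equal(doc$text, "工場に勤めている64歳の男性。")
  expect_same_spans(doc$spans[[1]],
                    phi_spans(c("a", "x"), c(8, 12), c(11, 14)))
  path <- parse_inline("院外標本 <h>静大皮フ科クリニック</h>、<p>桑田 智</p>")
  s <- path$spans[[1]]
  expect_equal(substr(path$text, s$begin[1] + 1, s$end[1]),
               "静大皮フ科クリニック")
  expect_equal(s$tag_type, c("h", "p"))
  expect_equal(substr(path$text, s$begin[2] + 1, s$end[2]), "桑田 智")
})

test_that("parse_inline handles empty input and spaced tag variants", {
  empty <- parse_inline("")
  expect_equal(empty$text, "")
  expect_equal(nrow(empty$spans[[1]]), 0L)
  spaced <- parse_inline("<a >64歳</a >の< x >男性</ x >")
  expect_same_spans(spaced$spans[[1]],
                    phi_spans(c("a", "x"), c(0, 4), c(3, 6)))
})

test_that("malformed tags raise errors naming the offset", {
  expect_error(parse_inline("a<z>b</z>"), "unknown tag <z> at offset 1")
  expect_error(parse_inline("<a>x<t>y</t></a>"), "nested")
  expect_error(parse_inline("x</a>"), "without open")
  expect_error(parse_inline("<a>x</t>"), "mismatched")
  expect_error(parse_inline("<a>x"), "unclosed")
  expect_error(parse_inline("<a></a>"), "empty")
  # stray '<' that forms no tag is plain text
  expect_equal(parse_inline("全介助<<院外標本")$text, "全介助<<院外標本")
})

test_that("render_inline inverts parse_inline and rejects overlaps", {
  ex <- worked_examples()
  expect_equal(render_inline(ex$gold), ex$tagged)
  plain <- parse_inline("タグのない文。")
  expect_equal(render_inline(plain), "タグのない文。")
  bad <- plain
  bad$spans[[1]] <- tibble::tibble(tag_type = c("t", "h"),
                                   begin = c(0L, 1L), end = c(3L, 4L))
  expect_error(render_inline(bad), "overlap")
})

test_that("parse/render round trip is exact on random documents", {
  set.seed(7)
  for (k in 1:200) {
    doc <- random_annotated_doc(paste0("d", k))
    back <- parse_inline(render_inline(doc), doc_id = doc$doc_id)
    expect_identical(back$text, doc$text)
    expect_same_spans(back$spans[[1]], doc$spans[[1]])
  }
})

test_that("spans_to_iob2 follows the IOB2 definition", {
  toks <- tokenize("64歳")
  lab <- spans_to_iob2(toks, phi_spans("a", 0, 3))
  expect_equal(lab$label, c("B-a", "I-a"))
  expect_equal(spans_to_iob2(tokenize("当院"), empty_spans_tbl())$label, "O")
  lab3 <- spans_to_iob2(tokenize("昨日より発熱"), phi_spans("t", 0, 4))
  expect_equal(lab3$label, c("B-t", "I-t", "O"))
})

test_that("a span cutting through a token is a boundary error, not a snap", {
  toks <- tokenize("昨日より")
  err <- expect_error(spans_to_iob2(toks, phi_spans("t", 0, 3)),
                      class = "jpdeid_boundary_mismatch")
  expect_match(conditionMessage(err), "token")
})

test_that("iob2_to_spans inverts spans_to_iob2 and handles edge labels", {
  toks <- tokenize("64歳の")
  toks$label <- c("B-a", "I-a", "O")
  expect_same_spans(iob2_to_spans(toks), phi_spans("a", 0, 3))
  toks$label <- c("O", "O", "O")
  expect_equal(nrow(iob2_to_spans(toks)), 0L)
  # two adjacent B tokens are two single-token spans
  toks2 <- tokenize("昨日本日")
  toks2$label <- c("B-t", "B-t")
  expect_equal(nrow(iob2_to_spans(toks2)), 2L)
})

test_that("invalid IOB2 errors in strict mode and is repaired when lenient", {
  toks <- tokenize("の昨日")
  toks$label <- c("O", "I-t")
  expect_error(iob2_to_spans(toks, mode = "strict"),
               class = "jpdeid_iob2_invalid")
  expect_warning(sp <- iob2_to_spans(toks, mode = "lenient"), "repaired")
  expect_same_spans(sp, phi_spans("t", 1, 3))
  toks$label <- c("O", "B-q")
  expect_error(iob2_to_spans(toks), "unknown IOB2 label")
})

test_that("spans -> IOB2 -> spans round trip holds on random documents", {
  set.seed(8)
  for (k in 1:200) {
    doc <- random_annotated_doc()
    labeled <- spans_to_iob2(tokenize(doc$text), doc$spans[[1]])
    expect_same_spans(iob2_to_spans(labeled), doc$spans[[1]])
  }
})

test_that("IOB2 TSV files round-trip byte-identically", {
  corp <- generate_corpus(synth_config(6, "dummy_ehr", seed = 3))
  labeled <- as_labeled_sequences(corp)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_iob2_file(labeled, path)
  back <- read_iob2_file(path)
  expect_equal(back$doc_id, labeled$doc_id)
  for (i in seq_len(nrow(back))) {
    expect_equal(back$tokens[[i]]$surface, labeled$tokens[[i]]$surface)
    expect_equal(back$tokens[[i]]$label, labeled$tokens[[i]]$label)
    expect_equal(back$tokens[[i]]$begin, labeled$tokens[[i]]$begin)
  }
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_iob2_file(back, path2)
  expect_identical(readLines(path2, warn = FALSE), readLines(path, warn = FALSE))
})

test_that("IOB2 reader reports format problems with the line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# doc_id = d1", "a\tnoun"), path, useBytes = TRUE)
  expect_error(read_iob2_file(path), "line 2")
  writeLines("a\tnoun\tgeneral\tO", path, useBytes = TRUE)
  expect_error(read_iob2_file(path), "header")
  writeLines(character(0), path)
  expect_equal(nrow(read_iob2_file(path)), 0L)
})

test_that("inline corpus files round-trip with document ids", {
  corp <- generate_corpus(synth_config(4, "pathology", seed = 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_inline_file(corp, path)
  back <- read_inline_file(path, style = "pathology")
  expect_equal(back$doc_id, corp$doc_id)
  expect_equal(back$text, corp$text)
  for (i in seq_len(nrow(back))) {
    expect_same_spans(back$spans[[i]], corp$spans[[i]])
  }
})
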