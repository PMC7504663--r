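test_that("name lists are deterministic and structurally sound", {
  a <- make_name_lists(7, n_hospitals = 80)
  b <- make_name_lists(7, n_hospitals = 80)
  expect_identical(a, b)
  expect_length(a$family_names, 20)
  expect_length(a$given_names, 20)
  suffixes <- default_rule_lexicon()$hospital_suffixes
  expect_true(all(vapply(a$hospital_names, function(h) {
    any(vapply(suffixes, function(sf) endsWith(h, sf), logical(1)))
  }, logical(1))))
  # the person surrogate scheme spans at most 20 + 20 x 20 distinct names
  combos <- c(a$family_names,
              as.vector(outer(a$family_names, a$given_names, paste)))
  expect_lte(length(unique(combos)), 20 + 20 * 20)
})

test_that("generation is seed-deterministic and style presets hold", {
  cfg <- synth_config(15, "pathology", seed = 13)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)

  spans_p <- dplyr::bind_rows(a$spans)
  expect_false(any(spans_p$tag_type %in% c("a", "x")))   # no age/sex
  expect_true(all(c("p", "h", "t") %in% spans_p$tag_type))

  m <- generate_corpus(synth_config(25, "mednlp", seed = 13))
  spans_m <- dplyr::bind_rows(m$spans)
  expect_false(any(spans_m$tag_type == "p"))             # no person names
  expect_true(all(c("a", "x", "t", "h") %in% spans_m$tag_type))

  d <- generate_corpus(synth_config(10, "dummy_ehr", seed = 13))
  spans_d <- dplyr::bind_rows(d$spans)
  expect_true("p" %in% spans_d$tag_type)

  expect_equal(nrow(generate_corpus(synth_config(0, "mednlp"))), 0L)
})

test_that("generated spans are in bounds, non-overlapping and render-safe", {
  corp <- generate_corpus(synth_config(20, "dummy_ehr", seed = 17))
  for (i in seq_len(nrow(corp))) {
    s <- corp$spans[[i]]
    expect_true(all(s$begin < s$end))
    expect_true(all(s$end <= nchar(corp$text[i])))
    if (nrow(s) > 1) expect_true(all(s$begin[-1] >= s$end[-nrow(s)]))
    back <- parse_inline(render_inline(corp[i, ]))
    expect_identical(back$text, corp$text[i])
    expect_same_spans(back$spans[[1]], s)
  }
})

test_that("gold spans align with token boundaries in every style", {
  tok <- benchmark_tokenizer(make_name_lists(19))
  for (style in c("mednlp", "dummy_ehr", "pathology")) {
    corp <- generate_corpus(synth_config(15, style, seed = 19))
    for (i in seq_len(nrow(corp))) {
      expect_no_error(spans_to_iob2(tokenize(corp$text[i], tok),
                                    corp$spans[[i]]))
    }
  }
})

test_that("the rule tagger recovers conforming documents almost perfectly", {
  corp <- generate_corpus(synth_config(40, "mednlp", seed = 23))
  conf <- corp[corp$conforming, ]
  m <- strict_match_metrics(conf, rule_tag(conf))
  expect_gte(m$f1[m$tag_type == "total"], 0.95)
  # the full corpus (with rule-breaking variants) scores strictly lower
  m_all <- strict_match_metrics(corp, rule_tag(corp))
  expect_lt(m_all$f1[m_all$tag_type == "total"],
            m$f1[m$tag_type == "total"])
})

test_that("surrogate replacement substitutes typed placeholder runs", {
  lists <- make_name_lists(29)
  doc <- parse_inline("院外標本 <h>●●病院</h>、<p>■■■</p>。",
                      style = "pathology")
  out <- surrogate_replace(doc, lists, seed = 4)
  expect_false(grepl("[●◯▲■]", out$text))
  s <- out$spans[[1]]
  expect_equal(s$tag_type, c("h", "p"))
  hosp <- substr(out$text, s$begin[1] + 1, s$end[1])
  expect_true(endsWith(hosp, "病院"))
  pers <- substr(out$text, s$begin[2] + 1, s$end[2])
  expect_true(sub(" .*$", "", pers) %in% lists$family_names)
  # deterministic per seed
  expect_identical(surrogate_replace(doc, lists, seed = 4), out)
  expect_false(identical(surrogate_replace(doc, lists, seed = 5)$text,
                         out$text))
})

test_that("surrogate replacement infers hospital runs from a suffix", {
  doc <- parse_inline("●●クリニックを受診。")
  out <- surrogate_replace(doc, make_name_lists(1), seed = 2)
  s <- out$spans[[1]]
  expect_equal(s$tag_type, "h")
  expect_true(endsWith(substr(out$text, s$begin + 1, s$end), "クリニック"))
  # untyped, suffix-less runs are an error naming the offset
  bare <- parse_inline("標本は▲▲▲とする。")
  expect_error(surrogate_replace(bare, make_name_lists(1)), "offset")
})

test_that("documents without placeholders pass through unchanged", {
  corp <- generate_corpus(synth_config(5, "mednlp", seed = 31))
  out <- surrogate_replace(corp, make_name_lists(1), seed = 9)
  expect_identical(out$text, corp$text)
  for (i in seq_len(nrow(corp))) {
    expect_same_spans(out$spans[[i]], corp$spans[[i]])
  }
})

test_that("replacement keeps spans consistent through render/parse", {
  lists <- make_name_lists(3)
  doc <- parse_inline(paste0("<t>昨日</t>受領 <h>◯◯◯医院</h>、",
                             "<p>●●</p>。"), style = "pathology")
  out <- surrogate_replace(doc, lists, seed = 11)
  back <- parse_inline(render_inline(out))
  expect_identical(back$text, out$text)
  expect_same_spans(back$spans[[1]], out$spans[[1]])
})
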