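# build a labeled-sequences tibble from hand-made token rows
toy_sequences <- function(sentences) {
  tibble::tibble(
    doc_id = paste0("d", seq_along(sentences)),
    tokens = lapply(sentences, function(s) {
      surf <- s$surface
      ends <- cumsum(nchar(surf))
      tibble::tibble(
        sentence_id = 1L, surface = surf,
        pos = s$pos, detailed_pos = s$detailed_pos,
        begin = as.integer(ends - nchar(surf)), end = as.integer(ends),
        sentence_start = seq_along(surf) == 1L,
        in_dictionary = s$in_dictionary, label = s$label
      )
    })
  )
}

test_that("the five feature families and their context window are extracted", {
  tok <- register_dictionary(deid_tokenizer(), "青葉病院")
  toks <- tokenize("青葉病院を受診。", tok)
  fm <- extract_features(toks, window = 2)
  expect_equal(ncol(fm), 5 * 5)
  expect_equal(nrow(fm), nrow(toks))
  r1 <- fm[1, ]
  expect_true("first=TRUE[+0]" %in% r1)
  expect_true("dict=TRUE[+0]" %in% r1)
  expect_true("ctype=kanji[+0]" %in% r1)
  expect_true("pos=noun[+0]" %in% r1)
  # the first token's left context is padding, its +1 neighbor a particle
  expect_true("BOS[-1]" %in% r1)
  expect_true("pos=particle[+1]" %in% r1)
  fm2 <- extract_features(tokenize("64歳"), window = 2)
  expect_true("ctype=number[+0]" %in% fm2[1, ])
  expect_true("dpos=numeral[+0]" %in% fm2[1, ])
  expect_equal(nrow(extract_features(tokenize(""), window = 2)), 0L)
})

test_that("analytic CRF gradients match finite differences", {
  set.seed(5)
  E <- matrix(rnorm(4 * 11), 4, 11)
  trans <- matrix(rnorm(121) * 0.3, 11, 11)
  start <- rnorm(11) * 0.3
  y <- c(1L, 2L, 3L, 1L)
  g <- jpdeid:::crf_layer_grad(E, trans, start, y)
  eps <- 1e-6
  for (probe in 1:15) {
    i <- sample(length(E), 1)
    Ep <- E; Em <- E
    Ep[i] <- Ep[i] + eps; Em[i] <- Em[i] - eps
    num <- (jpdeid:::crf_layer_grad(Ep, trans, start, y)$nll -
              jpdeid:::crf_layer_grad(Em, trans, start, y)$nll) / (2 * eps)
    expect_equal(g$dE[i], num, tolerance = 1e-4)
  }
  i <- sample(length(trans), 1)
  tp <- trans; tm <- trans
  tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
  num <- (jpdeid:::crf_layer_grad(E, tp, start, y)$nll -
            jpdeid:::crf_layer_grad(E, tm, start, y)$nll) / (2 * eps)
  expect_equal(g$dtrans[i], num, tolerance = 1e-4)
})

test_that("a feature-separable corpus is learned to perfect accuracy", {
  # label is a deterministic function of detailed POS
  set.seed(71)
  make_sent <- function() {
    n <- sample(3:8, 1)
    kind <- sample(c("numeral", "general", "non-autonomous word"), n,
                   replace = TRUE)
    list(surface = ifelse(kind == "numeral", "9", "あ"),
         pos = ifelse(kind == "non-autonomous word", "particle", "noun"),
         detailed_pos = kind,
         in_dictionary = kind == "general",
         label = ifelse(kind == "numeral", "B-t",
                        ifelse(kind == "general", "B-h", "O")))
  }
  train <- toy_sequences(replicate(30, make_sent(), simplify = FALSE))
  heldout <- toy_sequences(replicate(10, make_sent(), simplify = FALSE))
  model <- fit_crf(train, max_iter = 60)
  for (i in seq_len(nrow(heldout))) {
    dec <- decode_crf(model, heldout$tokens[[i]][, -9])
    expect_identical(dec$label, heldout$tokens[[i]]$label)
  }
})

test_that("a single-sentence corpus trains and is memorized", {
  toks <- spans_to_iob2(tokenize("64歳の男性。"),
                        phi_spans(c("a", "x"), c(0, 4), c(3, 6)))
  seqs <- tibble::tibble(doc_id = "d1", tokens = list(toks))
  model <- fit_crf(seqs, max_iter = 50)
  dec <- decode_crf(model, toks[, setdiff(names(toks), "label")])
  expect_identical(dec$label, toks$label)
})

test_that("training rejects empty or invalid corpora", {
  expect_error(fit_crf(tibble::tibble(doc_id = character(), tokens = list())),
               "empty")
  toks <- tokenize("64歳")
  toks$label <- c("I-a", "I-a")        # IOB2-invalid: starts with I
  expect_error(fit_crf(tibble::tibble(doc_id = "d", tokens = list(toks))),
               class = "jpdeid_iob2_invalid")
  toks$label <- c("B-a", "B-z")
  expect_error(fit_crf(tibble::tibble(doc_id = "d", tokens = list(toks))),
               "invalid label")
})

test_that("decoding is length-preserving, IOB2-valid and deterministic", {
  corp <- generate_corpus(synth_config(10, "mednlp", seed = 41))
  tok <- benchmark_tokenizer(make_name_lists(41))
  model <- fit_crf(as_labeled_sequences(corp, tok), max_iter = 40)
  expect_equal(nrow(decode_crf(model, tokenize(""))), 0L)
  set.seed(43)
  for (k in 1:25) {
    toks <- tokenize(random_rule_sentence(), tok)
    dec <- decode_crf(model, toks)
    expect_equal(nrow(dec), nrow(toks))
    expect_no_error(iob2_to_spans(dec, mode = "strict"))   # always valid
    expect_identical(decode_crf(model, toks)$label, dec$label)
  }
})

test_that("models survive a save/load round trip", {
  corp <- generate_corpus(synth_config(6, "mednlp", seed = 47))
  model <- fit_crf(as_labeled_sequences(corp), max_iter = 30)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  back <- read_model(path)
  toks <- tokenize(corp$text[1])
  expect_identical(decode_crf(back, toks)$label, decode_crf(model, toks)$label)
  saveRDS(list(format = "other"), path)
  expect_error(read_model(path), "not a jpdeid model")
})

test_that("tidy and glance summarize a fitted CRF", {
  corp <- generate_corpus(synth_config(5, "mednlp", seed = 53))
  model <- fit_crf(as_labeled_sequences(corp), max_iter = 20)
  td <- tidy(model)
  expect_true(all(c("feature", "label", "weight") %in% names(td)))
  expect_equal(nrow(td), length(model$feature_vocab) * 11)
  gl <- glance(model)
  expect_equal(gl$n_labels, 11L)
  expect_true(gl$n_features > 0)
})
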