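test_that("default configuration matches the published parameter settings", {
  cfg <- lstm_config()
  expect_equal(cfg$word_embedding_size, 200L)
  expect_equal(cfg$char_embedding_size, 100L)
  expect_equal(cfg$char_hidden_size, 100L)
  expect_equal(cfg$lstm_hidden_size, 300L)
  expect_equal(cfg$learning_rate, 0.001)
  expect_error(lstm_config(dropout = 1), "dropout")
  expect_error(lstm_config(epochs = -1), "epochs")
})

test_that("word-vector files round-trip in text and binary formats", {
  set.seed(61)
  vecs <- matrix(rnorm(3 * 8), 3, 8,
                 dimnames = list(c("病院", "昨日", "woman"), NULL))
  txt <- withr::local_tempfile(fileext = ".vec")
  bin <- withr::local_tempfile(fileext = ".bin")
  write_word_vectors(vecs, txt, format = "text")
  write_word_vectors(vecs, bin, format = "binary")
  back_t <- load_word_vectors(txt)
  back_b <- load_word_vectors(bin)
  expect_equal(rownames(back_t), rownames(vecs))
  expect_equal(back_t, vecs, tolerance = 1e-6)
  expect_equal(rownames(back_b), rownames(vecs))
  expect_equal(back_b, vecs, tolerance = 1e-6)     # float32 round trip
  # explicit and auto-detected formats agree
  expect_equal(load_word_vectors(bin, format = "binary"), back_b)
  expect_error(load_word_vectors(txt, expected_dim = 200), "dimension")
})

test_that("pretrained vectors seed the embedding table; OOV gets UNK", {
  corp <- generate_corpus(synth_config(4, "mednlp", seed = 63))
  seqs <- as_labeled_sequences(corp)
  vocab_word <- seqs$tokens[[1]]$surface[1]
  vecs <- matrix(seq_len(6 * 2) / 10, 2, 6,
                 dimnames = list(c(vocab_word, "語彙外の語"), NULL))
  path <- withr::local_tempfile(fileext = ".vec")
  write_word_vectors(vecs, path)
  cfg <- lstm_config(word_embedding_size = 6L, char_embedding_size = 4L,
                     char_hidden_size = 3L, lstm_hidden_size = 5L,
                     epochs = 0L, dropout = 0, seed = 3, word_vectors = path)
  model <- fit_lstm(seqs, cfg)
  i <- match(vocab_word, model$vocabs$words)
  expect_equal(unname(model$params$Eword[i, ]), unname(vecs[vocab_word, ]))
  # dimension mismatch is a load error
  cfg_bad <- lstm_config(word_embedding_size = 7L, epochs = 0L,
                         word_vectors = path)
  expect_error(fit_lstm(seqs, cfg_bad), "dimension")
})

test_that("an untrained model still decodes with preserved lengths", {
  corp <- generate_corpus(synth_config(4, "mednlp", seed = 67))
  cfg <- lstm_config(word_embedding_size = 6L, char_embedding_size = 4L,
                     char_hidden_size = 3L, lstm_hidden_size = 5L,
                     epochs = 0L, dropout = 0, seed = 5)
  model <- fit_lstm(as_labeled_sequences(corp), cfg)
  expect_equal(nrow(model$history), 0L)
  expect_equal(nrow(decode_lstm(model, tokenize(""))), 0L)
  for (txt in c(corp$text[1], "未知の語彙と未知文字𠮷。")) {
    toks <- tokenize(txt)
    dec <- decode_lstm(model, toks)
    expect_equal(nrow(dec), nrow(toks))
    expect_no_error(iob2_to_spans(dec, mode = "strict"))
  }
})

test_that("training loss decreases and a tiny corpus is memorized", {
  corp <- generate_corpus(synth_config(4, "mednlp", seed = 71))
  seqs <- as_labeled_sequences(corp)
  model <- fit_lstm(seqs, lstm_config_small(seed = 11, epochs = 25L,
                                            dropout = 0))
  expect_lt(model$history$nll[nrow(model$history)], model$history$nll[1])
  # training-set reproduction after enough epochs (capacity check)
  for (i in seq_len(nrow(seqs))) {
    dec <- decode_lstm(model, seqs$tokens[[i]][, -ncol(seqs$tokens[[i]])])
    expect_identical(dec$label, seqs$tokens[[i]]$label)
  }
})

test_that("training is reproducible for a fixed seed", {
  corp <- generate_corpus(synth_config(3, "mednlp", seed = 73))
  seqs <- as_labeled_sequences(corp)
  cfg <- lstm_config_small(seed = 13, epochs = 3L)
  m1 <- fit_lstm(seqs, cfg)
  m2 <- fit_lstm(seqs, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params$Wout, m2$params$Wout)
})

test_that("empty corpora are rejected", {
  expect_error(fit_lstm(tibble::tibble(doc_id = character(), tokens = list()),
                        lstm_config()), "empty")
})

test_that("LSTM models survive a save/load round trip", {
  corp <- generate_corpus(synth_config(3, "mednlp", seed = 79))
  seqs <- as_labeled_sequences(corp)
  model <- fit_lstm(seqs, lstm_config_small(seed = 17, epochs = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  back <- read_model(path)
  toks <- tokenize(corp$text[1])
  expect_identical(decode_lstm(back, toks)$label,
                   decode_lstm(model, toks)$label)
})

test_that("tidy, glance and autoplot expose the training history", {
  corp <- generate_corpus(synth_config(3, "mednlp", seed = 83))
  model <- fit_lstm(as_labeled_sequences(corp),
                    lstm_config_small(seed = 19, epochs = 2L))
  expect_equal(nrow(tidy(model)), 2L)
  gl <- glance(model)
  expect_equal(gl$epochs, 2L)
  expect_true(gl$vocab_words > 1)
  p <- autoplot(model)
  expect_s3_class(p, "ggplot")
})
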