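# Feature-based linear-chain CRF tagger.
#
# Each token contributes exactly five feature families: POS, detailed POS,
# character type of the surface (majority class of its characters), a binary
# user-dictionary membership flag, and a binary sentence-beginning flag.
# At template level every family is expanded over a +/-2 token context
# window (configurable), with label-transition (bigram) weights learned
# jointly. Training maximizes the L2-penalized conditional log-likelihood by
# L-BFGS; decoding is Viterbi under IOB2 structural constraints, so decoded
# output is always IOB2-valid.

#' Extract the five CRF feature families for a sentence
#'
#' @param tokens Token tibble of one sentence.
#' @param window Context window half-width (features of tokens at offsets
#'   `-window..window` are attached to each position).
#' @return Character matrix, one row per token, one column per
#'   (family, offset) slot; out-of-sentence offsets read `BOS`/`EOS`.
#' @export
extract_features <- function(tokens, window = 2) {
  T_ <- nrow(tokens)
  base <- cbind(
    pos = paste0("pos=", tokens$pos),
    dpos = paste0("dpos=", tokens$detailed_pos),
    ctype = paste0("ctype=", surface_char_type(tokens$surface)),
    dict = paste0("dict=", tokens$in_dictionary),
    bos = paste0("first=", tokens$sentence_start)
  )
  if (T_ == 0) {
    out <- matrix(character(0), 0, 5 * (2 * window + 1))
    return(out)
  }
  slots <- list()
  for (o in -window:window) {
    idx <- seq_len(T_) + o
    pad <- if (o < 0) "BOS" else "EOS"
    shifted <- matrix(pad, T_, 5)
    ok <- idx >= 1 & idx <= T_
    shifted[ok, ] <- base[idx[ok], , drop = FALSE]
    colnames(shifted) <- colnames(base)
    slots[[length(slots) + 1]] <-
      matrix(sprintf("%s[%+d]", shifted, o), T_, 5)
  }
  do.call(cbind, slots)
}

# split a document token table into per-sentence tables
split_sentences <- function(tokens) {
  if (nrow(tokens) == 0) return(list())
  unname(split(tokens, tokens$sentence_id))
}

#' Train the linear-chain CRF tagger
#'
#' @param sequences Labeled sequences ([as_labeled_sequences()]): a tibble
#'   with `doc_id` and `tokens` (token tibbles carrying a `label` column).
#' @param window Feature context window half-width.
#' @param l2 L2 regularization strength (Gaussian prior precision).
#' @param max_iter Maximum L-BFGS iterations.
#' @param seed Unused by the deterministic zero initialization; kept so the
#'   training interface matches the stochastic taggers.
#' @param verbose Print optimizer progress.
#' @return A fitted model of class `deid_crf`.
#' @export
fit_crf <- function(sequences, window = 2, l2 = 1.0, max_iter = 100L,
                    seed = NULL, verbose = FALSE) {
  sents <- unlist(lapply(sequences$tokens, split_sentences),
                  recursive = FALSE)
  sents <- Filter(function(s) nrow(s) > 0, sents)
  if (length(sents) == 0) rlang::abort("empty training corpus")
  labels <- iob2_labels()
  L <- length(labels)
  for (s in sents) {
    if (!all(s$label %in% labels)) {
      rlang::abort(paste0("invalid label(s): ",
                          paste(setdiff(s$label, labels), collapse = ", ")))
    }
    iob2_to_spans(s, mode = "strict")    # errors on IOB2-invalid input
  }

  featmats <- lapply(sents, extract_features, window = window)
  vocab <- sort(unique(unlist(featmats)))
  nfeat <- length(vocab)
  nslot <- 5 * (2 * window + 1)
  Fs <- lapply(featmats, function(fm) {
    T_ <- nrow(fm)
    Matrix::sparseMatrix(
      i = rep(seq_len(T_), nslot),
      j = match(as.vector(fm), vocab),
      x = 1, dims = c(T_, nfeat)
    )
  })
  ys <- lapply(sents, function(s) match(s$label, labels))

  nW <- nfeat * L
  nT <- L * L
  npar <- nW + nT + L
  unpack <- function(theta) {
    list(W = matrix(theta[seq_len(nW)], nfeat, L),
         trans = matrix(theta[nW + seq_len(nT)], L, L),
         start = theta[nW + nT + seq_len(L)])
  }

  cache <- new.env()
  cache$theta <- NULL
  evaluate <- function(theta) {
    p <- unpack(theta)
    nll <- 0
    dW <- matrix(0, nfeat, L)
    dtrans <- matrix(0, L, L)
    dstart <- numeric(L)
    for (k in seq_along(Fs)) {
      E <- as.matrix(Fs[[k]] %*% p$W)
      g <- crf_layer_grad(E, p$trans, p$start, ys[[k]])
      nll <- nll + g$nll
      dW <- dW + as.matrix(Matrix::crossprod(Fs[[k]], g$dE))
      dtrans <- dtrans + g$dtrans
      dstart <- dstart + g$dstart
    }
    nll <- nll + l2 / 2 * sum(theta^2)
    grad <- c(as.vector(dW), as.vector(dtrans), dstart) + l2 * theta
    cache$theta <- theta
    cache$value <- nll
    cache$grad <- grad
    invisible(NULL)
  }
  fn <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) evaluate(theta)
    cache$value
  }
  gr <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) evaluate(theta)
    cache$grad
  }

  opt <- stats::optim(rep(0, npar), fn = fn, gr = gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter,
                                     trace = if (verbose) 1 else 0))
  p <- unpack(opt$par)
  structure(list(
    W = p$W, trans = p$trans, start = p$start,
    feature_vocab = vocab, labels = labels,
    config = list(window = window, l2 = l2, max_iter = max_iter,
                  seed = seed),
    nll = opt$value, convergence = opt$convergence,
    n_sentences = length(Fs)
  ), class = "deid_crf")
}

# emission matrix for one sentence under a fitted CRF (unknown features at
# decode time are dropped)
crf_emissions <- function(model, tokens) {
  fm <- extract_features(tokens, window = model$config$window)
  T_ <- nrow(fm)
  j <- match(as.vector(fm), model$feature_vocab)
  keep <- !is.na(j)
  Fs <- Matrix::sparseMatrix(
    i = rep(seq_len(T_), ncol(fm))[keep], j = j[keep], x = 1,
    dims = c(T_, length(model$feature_vocab))
  )
  as.matrix(Fs %*% model$W)
}

#' Decode a sentence with a fitted CRF
#'
#' Constrained Viterbi decoding; the label sequence has the same length as
#' the sentence and is always IOB2-valid.
#'
#' @param model A `deid_crf`.
#' @param tokens Token tibble (one or more sentences; decoded per sentence).
#' @return `tokens` with a `label` column.
#' @export
decode_crf <- function(model, tokens) {
  stopifnot(inherits(model, "deid_crf"))
  if (nrow(tokens) == 0) {
    tokens$label <- character(0)
    return(tokens)
  }
  out <- lapply(split_sentences(tokens), function(s) {
    E <- crf_emissions(model, s)
    s$label <- model$labels[crf_viterbi(E, model$trans, model$start)]
    s
  })
  dplyr::bind_rows(out)
}

#' @export
predict.deid_crf <- function(object, corpus, tokenizer = deid_tokenizer(),
                             ...) {
  tag_corpus_with(corpus, tokenizer, function(toks) decode_crf(object, toks))
}

# shared prediction plumbing: tag every document of a corpus with a
# token-labeling function and convert labels back to spans
tag_corpus_with <- function(corpus, tokenizer, label_fun) {
  if (is.character(corpus)) {
    corpus <- new_corpus(paste0("doc", seq_along(corpus)), corpus,
                         "synthetic", rep(list(empty_spans()), length(corpus)))
  }
  corpus$spans <- lapply(corpus$text, function(txt) {
    labeled <- label_fun(tokenize(txt, tokenizer))
    iob2_to_spans(labeled, mode = "strict")
  })
  corpus
}

#' Save / load a fitted tagger model
#'
#' Serializes the model (with a format version stamp) via RDS.
#'
#' @param model A fitted `deid_crf` or `deid_lstm`.
#' @param path File path.
#' @return `read_model()` returns the model.
#' @export
write_model <- function(model, path) {
  saveRDS(list(format = "jpdeid-model-v1", model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "jpdeid-model-v1")) {
    rlang::abort("not a jpdeid model file")
  }
  obj$model
}

#' Tagger factories for cross-validation
#'
#' Each factory returns a `function(train_corpus)` that fits (or, for the
#' rule tagger, simply configures) a tagger and returns a prediction
#' function `function(corpus) -> corpus` with predicted spans — the
#' interface [cross_validate()] expects.
#'
#' @param tokenizer Tokenizer backend shared by training and prediction.
#' @param lexicon Rule lexicon (rule factory).
#' @param ... Passed on to [fit_crf()] / [fit_lstm()].
#' @return A tagger factory function.
#' @export
rule_factory <- function(tokenizer = deid_tokenizer(),
                         lexicon = default_rule_lexicon()) {
  function(train) {
    function(corpus) rule_tag(corpus, tokenizer, lexicon)
  }
}

#' @rdname rule_factory
#' @export
crf_factory <- function(tokenizer = deid_tokenizer(), ...) {
  function(train) {
    model <- fit_crf(as_labeled_sequences(train, tokenizer), ...)
    function(corpus) predict(model, corpus, tokenizer)
  }
}
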