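# BiLSTM-CRF tagger.
#
# Architecture: each word is represented by the concatenation of (i) its
# word-embedding lookup and (ii) the final forward and backward hidden
# states of a character-level BiLSTM run over its letters. The per-word
# representations feed a sentence-level BiLSTM whose forward/backward
# outputs are concatenated and projected to per-label emission scores, with
# a CRF output layer scoring label transitions. Training minimizes the CRF
# negative log-likelihood with Adam (hand-written backpropagation through
# both BiLSTM levels); decoding is constrained Viterbi, so output is always
# IOB2-valid. The character path is what gives the model robustness to
# out-of-vocabulary words that share characters with training words.

#' BiLSTM-CRF configuration
#'
#' Defaults for the five architecture parameters are the published settings
#' (word embedding 200, character embedding 100, character hidden layer
#' 100, sentence LSTM hidden layer 300, learning rate 0.001); optimizer
#' choices the source does not pin down (Adam, batch size 16, 30 epochs,
#' dropout 0.5 before the output layer) live here too, so tests can scale
#' the network down without touching code.
#'
#' @param word_embedding_size,char_embedding_size,char_hidden_size,lstm_hidden_size
#'   Layer sizes.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size Training schedule.
#' @param dropout Dropout rate applied to the concatenated BiLSTM output.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param clip Global gradient-norm clip.
#' @param fine_tune_word_embeddings Update word embeddings during training?
#' @param word_vectors Optional pretrained word-vector matrix (rownames =
#'   words) or path to a word2vec-format file; dimension must equal
#'   `word_embedding_size`.
#' @return A list of class `lstm_config`.
#' @export
lstm_config <- function(word_embedding_size = 200L,
                        char_embedding_size = 100L,
                        char_hidden_size = 100L,
                        lstm_hidden_size = 300L,
                        learning_rate = 0.001,
                        epochs = 30L,
                        batch_size = 16L,
                        dropout = 0.5,
                        seed = 1L,
                        clip = 5,
                        fine_tune_word_embeddings = TRUE,
                        word_vectors = NULL) {
  cfg <- list(
    word_embedding_size = as.integer(word_embedding_size),
    char_embedding_size = as.integer(char_embedding_size),
    char_hidden_size = as.integer(char_hidden_size),
    lstm_hidden_size = as.integer(lstm_hidden_size),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    dropout = dropout,
    seed = as.integer(seed),
    clip = clip,
    fine_tune_word_embeddings = isTRUE(fine_tune_word_embeddings),
    word_vectors = word_vectors
  )
  stopifnot(cfg$epochs >= 0, cfg$batch_size >= 1,
            cfg$dropout >= 0, cfg$dropout < 1)
  structure(cfg, class = "lstm_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -r, r), nr, nc)
}

init_lstm_cell <- function(d, h) {
  list(Wx = glorot(d, 4 * h), Wh = glorot(h, 4 * h), b = rep(0, 4 * h))
}

init_lstm_params <- function(Vc, Vw, cfg) {
  dc <- cfg$char_embedding_size
  hc <- cfg$char_hidden_size
  dw <- cfg$word_embedding_size
  h <- cfg$lstm_hidden_size
  L <- length(iob2_labels())
  d <- dw + 2 * hc
  list(
    Echar = glorot(Vc, dc),
    char_f = init_lstm_cell(dc, hc),
    char_b = init_lstm_cell(dc, hc),
    Eword = glorot(Vw, dw),
    word_f = init_lstm_cell(d, h),
    word_b = init_lstm_cell(d, h),
    Wout = glorot(2 * h, L),
    bout = rep(0, L),
    trans = matrix(0, L, L),
    start = rep(0, L)
  )
}

# one batched LSTM pass over a padded id-free input: X_t supplied by a
# closure; returns final H plus caches for backprop
lstm_forward_batch <- function(cell, X_list, mask) {
  B <- nrow(mask)
  Tm <- ncol(mask)
  hdim <- nrow(cell$Wh)
  H <- matrix(0, B, hdim)
  C <- matrix(0, B, hdim)
  caches <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    X <- X_list[[t]]
    act <- mask[, t]
    Z <- X %*% cell$Wx + H %*% cell$Wh
    Z <- sweep(Z, 2, cell$b, `+`)
    i <- sigmoid(Z[, seq_len(hdim), drop = FALSE])
    f <- sigmoid(Z[, hdim + seq_len(hdim), drop = FALSE])
    o <- sigmoid(Z[, 2 * hdim + seq_len(hdim), drop = FALSE])
    g <- tanh(Z[, 3 * hdim + seq_len(hdim), drop = FALSE])
    Ccell <- f * C + i * g
    tanhC <- tanh(Ccell)
    Hcell <- o * tanhC
    caches[[t]] <- list(X = X, Hprev = H, Cprev = C, i = i, f = f, o = o,
                        g = g, tanhC = tanhC, act = act)
    H <- act * Hcell + (1 - act) * H
    C <- act * Ccell + (1 - act) * C
  }
  list(H = H, caches = caches)
}

# backprop through lstm_forward_batch; returns per-step input gradients and
# accumulated cell-parameter gradients
lstm_backward_batch <- function(cell, caches, dH_final) {
  Tm <- length(caches)
  hdim <- nrow(cell$Wh)
  B <- nrow(dH_final)
  dWx <- matrix(0, nrow(cell$Wx), ncol(cell$Wx))
  dWh <- matrix(0, hdim, 4 * hdim)
  db <- rep(0, 4 * hdim)
  dX_list <- vector("list", Tm)
  dH <- dH_final
  dC <- matrix(0, B, hdim)
  for (t in rev(seq_len(Tm))) {
    cc <- caches[[t]]
    act <- cc$act
    dHcell <- dH * act
    dCcell <- dC * act
    do_ <- dHcell * cc$tanhC
    dCin <- dCcell + dHcell * cc$o * (1 - cc$tanhC^2)
    di <- dCin * cc$g
    df <- dCin * cc$Cprev
    dg <- dCin * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dX_list[[t]] <- dZ %*% t(cell$Wx)
    dWx <- dWx + crossprod(cc$X, dZ)
    dWh <- dWh + crossprod(cc$Hprev, dZ)
    db <- db + colSums(dZ)
    dH <- dZ %*% t(cell$Wh) + dH * (1 - act)
    dC <- dCin * cc$f + dC * (1 - act)
  }
  list(dX_list = dX_list, dWx = dWx, dWh = dWh, db = db)
}

# ids: B x Tm matrix (0 = pad); returns final states + caches
char_lstm_pass <- function(cell, Echar, ids, mask) {
  X_list <- lapply(seq_len(ncol(ids)), function(t) {
    rows <- ids[, t]
    X <- matrix(0, nrow(ids), ncol(Echar))
    nz <- rows > 0
    X[nz, ] <- Echar[rows[nz], , drop = FALSE]
    X
  })
  c(lstm_forward_batch(cell, X_list, mask), list(ids = ids, mask = mask))
}

# map sentence word surfaces to padded char-id matrices (fwd and reversed)
char_id_matrices <- function(surfaces, char_vocab) {
  chars <- lapply(surfaces, function(s) strsplit(s, "")[[1]])
  ids <- lapply(chars, function(cs) {
    j <- match(cs, char_vocab)
    j[is.na(j)] <- length(char_vocab)      # UNK = last row
    j
  })
  lens <- lengths(ids)
  Tm <- max(lens)
  B <- length(ids)
  fwd <- matrix(0L, B, Tm)
  bwd <- matrix(0L, B, Tm)
  mask <- matrix(0, B, Tm)
  for (b in seq_len(B)) {
    fwd[b, seq_len(lens[b])] <- ids[[b]]
    bwd[b, seq_len(lens[b])] <- rev(ids[[b]])
    mask[b, seq_len(lens[b])] <- 1
  }
  list(fwd = fwd, bwd = bwd, mask = mask)
}

# full forward pass for one sentence; returns emissions and all caches
lstm_forward_sentence <- function(params, vocabs, cfg, surfaces,
                                  dropout_mask = NULL) {
  B <- length(surfaces)
  wid <- match(surfaces, vocabs$words)
  wid[is.na(wid)] <- length(vocabs$words)  # UNK = last row
  cm <- char_id_matrices(surfaces, vocabs$chars)
  cf <- char_lstm_pass(params$char_f, params$Echar, cm$fwd, cm$mask)
  cb <- char_lstm_pass(params$char_b, params$Echar, cm$bwd, cm$mask)
  V <- cbind(params$Eword[wid, , drop = FALSE], cf$H, cb$H)
  # sentence-level BiLSTM: batch of size 1 per time step
  Vrows_f <- lapply(seq_len(B), function(t) V[t, , drop = FALSE])
  wf <- lstm_forward_batch_seq(params$word_f, Vrows_f)
  wb <- lstm_forward_batch_seq(params$word_b, rev(Vrows_f))
  Hf <- do.call(rbind, wf$H_list)                    # B x h
  Hb <- do.call(rbind, rev(wb$H_list))               # B x h (original order)
  Hcat <- cbind(Hf, Hb)
  Hd <- if (is.null(dropout_mask)) Hcat else Hcat * dropout_mask
  E <- sweep(Hd %*% params$Wout, 2, params$bout, `+`)
  list(E = E, wid = wid, cm = cm, cf = cf, cb = cb, V = V,
       wf = wf, wb = wb, Hcat = Hcat, Hd = Hd, dropout_mask = dropout_mask)
}

# sequence LSTM over a list of 1-row inputs, keeping every hidden state
lstm_forward_batch_seq <- function(cell, X_list) {
  hdim <- nrow(cell$Wh)
  H <- matrix(0, 1, hdim)
  C <- matrix(0, 1, hdim)
  caches <- vector("list", length(X_list))
  H_list <- vector("list", length(X_list))
  for (t in seq_along(X_list)) {
    X <- X_list[[t]]
    Z <- X %*% cell$Wx + H %*% cell$Wh
    Z <- sweep(Z, 2, cell$b, `+`)
    i <- sigmoid(Z[, seq_len(hdim), drop = FALSE])
    f <- sigmoid(Z[, hdim + seq_len(hdim), drop = FALSE])
    o <- sigmoid(Z[, 2 * hdim + seq_len(hdim), drop = FALSE])
    g <- tanh(Z[, 3 * hdim + seq_len(hdim), drop = FALSE])
    C2 <- f * C + i * g
    tanhC <- tanh(C2)
    H2 <- o * tanhC
    caches[[t]] <- list(X = X, Hprev = H, Cprev = C, i = i, f = f, o = o,
                        g = g, tanhC = tanhC)
    H <- H2
    C <- C2
    H_list[[t]] <- H
  }
  list(H_list = H_list, caches = caches)
}

# backprop through lstm_forward_batch_seq given gradients of every hidden
# state (list of 1-row matrices)
lstm_backward_seq <- function(cell, caches, dH_list) {
  hdim <- nrow(cell$Wh)
  dWx <- matrix(0, nrow(cell$Wx), 4 * hdim)
  dWh <- matrix(0, hdim, 4 * hdim)
  db <- rep(0, 4 * hdim)
  dX_list <- vector("list", length(caches))
  dH <- matrix(0, 1, hdim)
  dC <- matrix(0, 1, hdim)
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    dHt <- dH + dH_list[[t]]
    do_ <- dHt * cc$tanhC
    dCin <- dC + dHt * cc$o * (1 - cc$tanhC^2)
    di <- dCin * cc$g
    df <- dCin * cc$Cprev
    dg <- dCin * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dX_list[[t]] <- dZ %*% t(cell$Wx)
    dWx <- dWx + crossprod(cc$X, dZ)
    dWh <- dWh + crossprod(cc$Hprev, dZ)
    db <- db + colSums(dZ)
    dH <- dZ %*% t(cell$Wh)
    dC <- dCin * cc$f
  }
  list(dX_list = dX_list, dWx = dWx, dWh = dWh, db = db)
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

# elementwise binary op over nested param lists
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(map2_params, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    return(out)
  }
  f(a, b)
}

map_params <- function(a, f) {
  if (is.list(a)) return(lapply(a, map_params, f = f))
  f(a)
}

param_sq_norm <- function(a) {
  if (is.list(a)) return(sum(vapply(a, param_sq_norm, numeric(1))))
  sum(a^2)
}

# gradient of one sentence; returns list(nll, grads)
lstm_sentence_grad <- function(params, vocabs, cfg, surfaces, y,
                               dropout_mask) {
  fw <- lstm_forward_sentence(params, vocabs, cfg, surfaces, dropout_mask)
  cl <- crf_layer_grad(fw$E, params$trans, params$start, y)
  g <- zero_like(params)
  g$trans <- cl$dtrans
  g$start <- cl$dstart
  dE <- cl$dE
  g$Wout <- crossprod(fw$Hd, dE)
  g$bout <- colSums(dE)
  dHd <- dE %*% t(params$Wout)
  dHcat <- if (is.null(dropout_mask)) dHd else dHd * dropout_mask
  h <- cfg$lstm_hidden_size
  B <- length(surfaces)
  dHf_list <- lapply(seq_len(B), function(t) dHcat[t, seq_len(h), drop = FALSE])
  dHb_list <- lapply(seq_len(B), function(t) {
    dHcat[t, h + seq_len(h), drop = FALSE]
  })
  bf <- lstm_backward_seq(params$word_f, fw$wf$caches, dHf_list)
  bb <- lstm_backward_seq(params$word_b, fw$wb$caches, rev(dHb_list))
  g$word_f$Wx <- bf$dWx; g$word_f$Wh <- bf$dWh; g$word_f$b <- bf$db
  g$word_b$Wx <- bb$dWx; g$word_b$Wh <- bb$dWh; g$word_b$b <- bb$db
  dV <- do.call(rbind, bf$dX_list) + do.call(rbind, rev(bb$dX_list))
  dw <- cfg$word_embedding_size
  hc <- cfg$char_hidden_size
  if (cfg$fine_tune_word_embeddings) {
    dEw <- dV[, seq_len(dw), drop = FALSE]
    agg <- rowsum(dEw, fw$wid)
    rows <- as.integer(rownames(agg))
    g$Eword[rows, ] <- g$Eword[rows, , drop = FALSE] + agg
  }
  dHfc <- dV[, dw + seq_len(hc), drop = FALSE]
  dHbc <- dV[, dw + hc + seq_len(hc), drop = FALSE]
  bcf <- lstm_backward_batch(params$char_f, fw$cf$caches, dHfc)
  bcb <- lstm_backward_batch(params$char_b, fw$cb$caches, dHbc)
  g$char_f$Wx <- bcf$dWx; g$char_f$Wh <- bcf$dWh; g$char_f$b <- bcf$db
  g$char_b$Wx <- bcb$dWx; g$char_b$Wh <- bcb$dWh; g$char_b$b <- bcb$db
  add_char_emb_grad <- function(gE, dX_list, ids, mask) {
    for (t in seq_along(dX_list)) {
      act <- mask[, t] > 0
      if (!any(act)) next
      agg <- rowsum(dX_list[[t]][act, , drop = FALSE], ids[act, t])
      rows <- as.integer(rownames(agg))
      gE[rows, ] <- gE[rows, , drop = FALSE] + agg
    }
    gE
  }
  g$Echar <- add_char_emb_grad(g$Echar, bcf$dX_list, fw$cm$fwd, fw$cm$mask)
  g$Echar <- add_char_emb_grad(g$Echar, bcb$dX_list, fw$cm$bwd, fw$cm$mask)
  list(nll = cl$nll, grads = g)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      skip = character(0)) {
  upd <- function(p, g, m, v, name) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        child <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]],
                     if (nzchar(name)) paste0(name, ".", nm) else nm)
        out_p[[nm]] <- child$p; out_m[[nm]] <- child$m; out_v[[nm]] <- child$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    if (name %in% skip) return(list(p = p, m = m, v = v))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- upd(params, grads, state$m, state$v, "")
  list(params = res$p, state = list(m = res$m, v = res$v))
}

#' Train the BiLSTM-CRF tagger
#'
#' @param sequences Labeled sequences ([as_labeled_sequences()]).
#' @param config An [lstm_config()].
#' @return A fitted model of class `deid_lstm` with a per-epoch training
#'   loss `history`.
#' @export
fit_lstm <- function(sequences, config = lstm_config()) {
  stopifnot(inherits(config, "lstm_config"))
  sents <- unlist(lapply(sequences$tokens, split_sentences),
                  recursive = FALSE)
  sents <- Filter(function(s) nrow(s) > 0, sents)
  if (length(sents) == 0) rlang::abort("empty training corpus")
  labels <- iob2_labels()
  surfaces <- lapply(sents, `[[`, "surface")
  ys <- lapply(sents, function(s) match(s$label, labels))
  if (anyNA(unlist(ys))) rlang::abort("invalid IOB2 labels in training data")

  words <- c(sort(unique(unlist(surfaces))), "<UNK>")
  chars <- c(sort(unique(unlist(strsplit(unlist(surfaces), "")))), "<UNK>")
  vocabs <- list(words = words, chars = chars)

  wv <- config$word_vectors
  if (is.character(wv) && length(wv) == 1) wv <- load_word_vectors(wv)
  if (!is.null(wv) && ncol(wv) != config$word_embedding_size) {
    rlang::abort(sprintf(
      "word vectors have dimension %d but config expects %d",
      ncol(wv), config$word_embedding_size))
  }

  model <- with_seed(config$seed, {
    params <- init_lstm_params(length(chars), length(words), config)
    if (!is.null(wv)) {
      hit <- intersect(rownames(wv), words)
      params$Eword[match(hit, words), ] <- wv[hit, , drop = FALSE]
    }
    state <- list(m = zero_like(params), v = zero_like(params))
    skip <- if (config$fine_tune_word_embeddings) character(0) else "Eword"
    history <- numeric(0)
    step <- 0L
    h2 <- 2L * config$lstm_hidden_size
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(sents))
      total <- 0
      bstart <- 1L
      while (bstart <= length(ord)) {
        bidx <- ord[bstart:min(bstart + config$batch_size - 1L, length(ord))]
        acc <- NULL
        for (k in bidx) {
          dm <- if (config$dropout > 0) {
            matrix(stats::rbinom(length(surfaces[[k]]) * h2, 1,
                                 1 - config$dropout) / (1 - config$dropout),
                   length(surfaces[[k]]), h2)
          } else NULL
          sg <- lstm_sentence_grad(params, vocabs, config, surfaces[[k]],
                                   ys[[k]], dm)
          total <- total + sg$nll
          acc <- if (is.null(acc)) sg$grads else
            map2_params(acc, sg$grads, `+`)
        }
        acc <- map_params(acc, function(x) x / length(bidx))
        gn <- sqrt(param_sq_norm(acc))
        if (is.finite(config$clip) && gn > config$clip) {
          acc <- map_params(acc, function(x) x * config$clip / gn)
        }
        step <- step + 1L
        st <- adam_step(params, acc, state, config$learning_rate, step,
                        skip = skip)
        params <- st$params
        state <- st$state
        bstart <- bstart + config$batch_size
      }
      history <- c(history, total / length(sents))
    }
    list(params = params, history = history)
  })

  structure(list(
    params = model$params, vocabs = vocabs, labels = labels,
    config = config,
    history = tibble::tibble(epoch = seq_along(model$history),
                             nll = model$history),
    n_sentences = length(sents)
  ), class = "deid_lstm")
}

#' Decode tokens with a fitted BiLSTM-CRF
#'
#' Constrained Viterbi over the CRF output layer; the label sequence is
#' length-preserving and IOB2-valid. Out-of-vocabulary words map to the
#' shared unknown word vector, but their characters still drive the
#' character BiLSTM.
#'
#' @param model A `deid_lstm`.
#' @param tokens Token tibble (decoded per sentence).
#' @return `tokens` with a `label` column.
#' @export
decode_lstm <- function(model, tokens) {
  stopifnot(inherits(model, "deid_lstm"))
  if (nrow(tokens) == 0) {
    tokens$label <- character(0)
    return(tokens)
  }
  out <- lapply(split_sentences(tokens), function(s) {
    fw <- lstm_forward_sentence(model$params, model$vocabs, model$config,
                                s$surface)
    y <- crf_viterbi(fw$E, model$params$trans, model$params$start)
    s$label <- model$labels[y]
    s
  })
  dplyr::bind_rows(out)
}

#' @export
predict.deid_lstm <- function(object, corpus, tokenizer = deid_tokenizer(),
                              ...) {
  tag_corpus_with(corpus, tokenizer, function(toks) decode_lstm(object, toks))
}

#' @rdname rule_factory
#' @param config [lstm_config()] used by the LSTM factory.
#' @export
lstm_factory <- function(tokenizer = deid_tokenizer(), config = lstm_config()) {
  function(train) {
    model <- fit_lstm(as_labeled_sequences(train, tokenizer), config)
    function(corpus) predict(model, corpus, tokenizer)
  }
}

# ---- word2vec-format vector files ----------------------------------------

#' Load pretrained word vectors
#'
#' Reads word2vec-format files, text (`V D` header, then one
#' space-separated entry per line) or binary (`V D` header line, then per
#' entry the word, a space, and D little-endian float32 values). Format is
#' auto-detected unless given.
#'
#' @param path File path.
#' @param expected_dim If non-NULL, error unless the file dimension matches.
#' @param format `"auto"`, `"text"` or `"binary"`.
#' @return Numeric matrix with one row per word (rownames = words).
#' @export
load_word_vectors <- function(path, expected_dim = NULL,
                              format = c("auto", "text", "binary")) {
  format <- match.arg(format)
  if (format == "auto") {
    head_bytes <- readBin(path, "raw", n = 4096)
    format <- if (any(head_bytes == as.raw(0)) ||
                  {
                    txt <- suppressWarnings(readLines(path, n = 2, warn = FALSE))
                    length(txt) >= 2 &&
                      anyNA(suppressWarnings(
                        as.numeric(strsplit(txt[2], " +")[[1]][-1])))
                  }) "binary" else "text"
  }
  mat <- if (format == "text") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    hdr <- as.integer(strsplit(trimws(lines[1]), " +")[[1]])
    v <- hdr[1]; d <- hdr[2]
    entries <- strsplit(lines[1 + seq_len(v)], " +")
    m <- t(vapply(entries, function(e) as.numeric(e[-1]), numeric(d)))
    rownames(m) <- vapply(entries, `[`, character(1), 1)
    m
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_raw <- raw(0)                         # header line ends at \n
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0 || b == as.raw(0x0A)) break
      hdr_raw <- c(hdr_raw, b)
    }
    hdr_parts <- as.integer(strsplit(trimws(rawToChar(hdr_raw)), " +")[[1]])
    if (length(hdr_parts) < 2 || anyNA(hdr_parts)) {
      rlang::abort("malformed word2vec binary header")
    }
    v <- hdr_parts[1]; d <- hdr_parts[2]
    m <- matrix(0, v, d)
    words <- character(v)
    for (k in seq_len(v)) {
      chs <- raw(0)
      repeat {
        b <- readBin(con, "raw", n = 1)
        if (length(b) == 0 || b == as.raw(0x20)) break
        if (b != as.raw(0x0A)) chs <- c(chs, b)
      }
      words[k] <- rawToChar(chs)
      m[k, ] <- readBin(con, "numeric", n = d, size = 4)
    }
    Encoding(words) <- "UTF-8"
    rownames(m) <- words
    m
  }
  if (!is.null(expected_dim) && ncol(mat) != expected_dim) {
    rlang::abort(sprintf("word vectors have dimension %d, expected %d",
                         ncol(mat), expected_dim))
  }
  mat
}

#' @rdname load_word_vectors
#' @param vectors Numeric matrix with rownames (the words).
#' @export
write_word_vectors <- function(vectors, path, format = c("text", "binary")) {
  format <- match.arg(format)
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (format == "text") {
    lines <- c(paste(nrow(vectors), ncol(vectors)),
               vapply(seq_len(nrow(vectors)), function(k) {
                 paste(c(rownames(vectors)[k],
                         format(vectors[k, ], scientific = FALSE,
                                trim = TRUE, digits = 8)), collapse = " ")
               }, character(1)))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste(nrow(vectors), ncol(vectors))), con)
    writeBin(charToRaw("\n"), con)
    for (k in seq_len(nrow(vectors))) {
      writeBin(charToRaw(rownames(vectors)[k]), con)
      writeBin(charToRaw(" "), con)
      writeBin(as.numeric(vectors[k, ]), con, size = 4)
      writeBin(charToRaw("\n"), con)
    }
  }
  invisible(path)
}
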