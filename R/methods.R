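# broom-style accessors and plots for fitted taggers and metrics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted CRF: one row per (feature, label) weight
#'
#' @param x A `deid_crf`.
#' @param ... Unused.
#' @return Tibble with `feature`, `label`, `weight`, sorted by `|weight|`.
#' @method tidy deid_crf
#' @export
tidy.deid_crf <- function(x, ...) {
  out <- tibble::tibble(
    feature = rep(x$feature_vocab, times = length(x$labels)),
    label = rep(x$labels, each = length(x$feature_vocab)),
    weight = as.vector(x$W)
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$weight)))
}

#' @method glance deid_crf
#' @export
glance.deid_crf <- function(x, ...) {
  tibble::tibble(
    n_sentences = x$n_sentences,
    n_features = length(x$feature_vocab),
    n_labels = length(x$labels),
    window = x$config$window,
    l2 = x$config$l2,
    nll = x$nll,
    converged = x$convergence == 0
  )
}

#' Tidy a fitted BiLSTM-CRF: the training loss history
#'
#' @param x A `deid_lstm`.
#' @param ... Unused.
#' @return Tibble with `epoch` and mean per-sentence `nll`.
#' @method tidy deid_lstm
#' @export
tidy.deid_lstm <- function(x, ...) x$history

#' @method glance deid_lstm
#' @export
glance.deid_lstm <- function(x, ...) {
  tibble::tibble(
    n_sentences = x$n_sentences,
    vocab_words = length(x$vocabs$words),
    vocab_chars = length(x$vocabs$chars),
    word_embedding_size = x$config$word_embedding_size,
    char_hidden_size = x$config$char_hidden_size,
    lstm_hidden_size = x$config$lstm_hidden_size,
    epochs = x$config$epochs,
    final_nll = if (nrow(x$history)) x$history$nll[nrow(x$history)] else NA_real_
  )
}

#' Plot the training loss of a BiLSTM-CRF
#'
#' @param object A `deid_lstm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deid_lstm
#' @export
autoplot.deid_lstm <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$nll)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "mean sentence NLL",
                  title = "BiLSTM-CRF training loss") +
    ggplot2::theme_minimal()
}

#' Plot per-type precision/recall/F1
#'
#' @param object A `deid_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot (scores x100, faceted by fold when present).
#' @method autoplot deid_metrics
#' @export
autoplot.deid_metrics <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if ("fold" %in% names(df)) df <- df[df$fold == "pooled", ]
  df <- tidyr::pivot_longer(df, c("precision", "recall", "f1"),
                            names_to = "measure", values_to = "score")
  df$score <- 100 * df$score
  df$tag_type <- factor(df$tag_type, levels = c(names(phi_tags()), "total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tag_type, y = .data$score,
                                   fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tag type", y = "score (x100)") +
    ggplot2::theme_minimal()
}

#' @export
print.deid_crf <- function(x, ...) {
  cat(sprintf(
    "<deid_crf> linear-chain CRF: %d features x %d labels, window +/-%d, trained on %d sentences\n",
    length(x$feature_vocab), length(x$labels), x$config$window,
    x$n_sentences))
  invisible(x)
}

#' @export
print.deid_lstm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<deid_lstm> BiLSTM-CRF: word %d + 2x char %d -> hidden %d, %d epochs, trained on %d sentences\n",
    cfg$word_embedding_size, cfg$char_hidden_size, cfg$lstm_hidden_size,
    cfg$epochs, x$n_sentences))
  invisible(x)
}
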