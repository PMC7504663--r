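# Strict-span evaluation.
#
# A predicted span scores as a true positive iff an identical
# (begin, end, tag_type) gold span exists in the same document (strict,
# phrase-level matching). Precision/recall/F1 are reported per tag type and
# in total; the total row is micro-averaged (counts summed over types, then
# P/R/F1 recomputed). Word-level accuracy is the fraction of tokens whose
# B-*/I-*/O label agrees.

# Normalize inputs: a span tibble (single document) or a corpus tibble.
collect_spans <- function(x) {
  if (is.data.frame(x) && "spans" %in% names(x)) {
    out <- lapply(seq_len(nrow(x)), function(i) {
      s <- x$spans[[i]]
      if (nrow(s)) s$doc_id <- x$doc_id[i] else s$doc_id <- character(0)
      s
    })
    out <- dplyr::bind_rows(out)
    if (nrow(out) == 0) {
      out <- dplyr::mutate(empty_spans(), doc_id = character(0))
    }
    return(out)
  }
  s <- tibble::as_tibble(x)
  if (!"doc_id" %in% names(s)) s$doc_id <- if (nrow(s)) "doc1" else character(0)
  s
}

#' Strict span-level precision, recall and F1
#'
#' Computes per-type and micro-averaged total counts under strict matching.
#' Conventions: precision/recall are 0 when their denominator is 0 and the
#' other is non-zero; a tag type with neither gold nor predicted spans is
#' reported as `NA` (printed `N/A`).
#'
#' @param gold,pred Span tibbles (with optional `doc_id`) or corpus tibbles
#'   whose `spans` columns are compared document by document.
#' @return A `deid_metrics` tibble: one row per tag type plus `total`, with
#'   columns `tag_type`, `n_gold`, `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1` (fractions in `[0, 1]`; see [format_metrics()] for the x100
#'   presentation).
#' @export
#' @examples
#' gold <- phi_spans(c("a", "x"), c(0, 5), c(3, 7))
#' pred <- phi_spans(c("a", "x"), c(0, 5), c(3, 8))
#' strict_match_metrics(gold, pred)
strict_match_metrics <- function(gold, pred) {
  g <- collect_spans(gold)
  p <- collect_spans(pred)
  key <- c("doc_id", "tag_type", "begin", "end")
  g <- dplyr::distinct(g[, key])
  p <- dplyr::distinct(p[, key])
  tp_rows <- dplyr::inner_join(p, g, by = key)
  per_type <- lapply(names(phi_tags()), function(ty) {
    ng <- sum(g$tag_type == ty)
    np <- sum(p$tag_type == ty)
    tp <- sum(tp_rows$tag_type == ty)
    tibble::tibble(tag_type = ty, n_gold = ng, tp = tp, fp = np - tp,
                   fn = ng - tp)
  })
  counts <- dplyr::bind_rows(per_type)
  total <- tibble::tibble(tag_type = "total", n_gold = sum(counts$n_gold),
                          tp = sum(counts$tp), fp = sum(counts$fp),
                          fn = sum(counts$fn))
  counts <- dplyr::bind_rows(counts, total)
  finish_metrics(counts)
}

finish_metrics <- function(counts) {
  prf <- function(tp, fp, fn) {
    absent <- tp + fp + fn == 0
    precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    f1 <- ifelse(precision + recall > 0,
                 2 * precision * recall / (precision + recall), 0)
    precision[absent] <- NA_real_
    recall[absent] <- NA_real_
    f1[absent] <- NA_real_
    tibble::tibble(precision = precision, recall = recall, f1 = f1)
  }
  out <- dplyr::bind_cols(counts, prf(counts$tp, counts$fp, counts$fn))
  class(out) <- c("deid_metrics", class(out))
  out
}

#' Word-level label accuracy
#'
#' The agreement ratio of B-*, I-* and O labels between two labeled
#' sequences of equal length.
#'
#' @param gold,pred Character label vectors, or labeled token tibbles with a
#'   `label` column.
#' @return A fraction in `[0, 1]` (1 for two empty sequences).
#' @export
token_accuracy <- function(gold, pred) {
  if (is.data.frame(gold)) gold <- gold$label
  if (is.data.frame(pred)) pred <- pred$label
  if (length(gold) != length(pred)) {
    rlang::abort(sprintf("label sequences differ in length: %d vs %d",
                         length(gold), length(pred)))
  }
  if (length(gold) == 0) return(1)
  mean(gold == pred)
}

#' k-fold cross-validation of a span tagger
#'
#' Documents are shuffled with the given seed and partitioned into `k`
#' folds at document level (so no document contributes to both training and
#' test). For each fold the tagger factory is called on the training
#' documents and must return a prediction function mapping a corpus
#' (spans stripped) to a corpus with predicted spans. Pooled metrics are
#' computed from the summed tp/fp/fn across folds.
#'
#' @param corpus Annotated corpus tibble with at least `k` documents.
#' @param tagger_factory `function(train_corpus) -> function(corpus) ->
#'   corpus` with predicted spans.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed for the fold shuffle.
#' @return A `deid_metrics` tibble with an extra `fold` column; pooled rows
#'   have `fold == "pooled"`.
#' @export
cross_validate <- function(corpus, tagger_factory, k = 4, seed = 1) {
  if (k < 2) rlang::abort("k-fold cross-validation needs k >= 2")
  n <- nrow(corpus)
  if (n < k) rlang::abort(sprintf("%d documents cannot fill %d folds", n, k))
  fold_of <- with_seed(seed, {
    idx <- sample.int(n)
    f <- integer(n)
    f[idx] <- rep_len(seq_len(k), n)
    f
  })
  per_fold <- lapply(seq_len(k), function(f) {
    train <- corpus[fold_of != f, ]
    test <- corpus[fold_of == f, ]
    tagger <- tagger_factory(train)
    blank <- test
    blank$spans <- rep(list(empty_spans()), nrow(blank))
    pred <- tagger(blank)
    m <- strict_match_metrics(test, pred)
    m$fold <- as.character(f)
    m
  })
  all <- dplyr::bind_rows(per_fold)
  pooled <- dplyr::summarise(
    dplyr::group_by(all, .data$tag_type),
    n_gold = sum(.data$n_gold), tp = sum(.data$tp), fp = sum(.data$fp),
    fn = sum(.data$fn), .groups = "drop"
  )
  pooled <- pooled[match(c(names(phi_tags()), "total"), pooled$tag_type), ]
  pooled <- finish_metrics(pooled)
  pooled$fold <- "pooled"
  out <- dplyr::bind_rows(all, pooled)
  attr(out, "fold_of") <- fold_of
  class(out) <- c("deid_metrics", class(out))
  out
}

#' Inter-annotator agreement as average pairwise F1
#'
#' For every unordered pair of annotation sets the strict-match total F1 is
#' computed (F1 is symmetric in the pair); the agreement is the arithmetic
#' mean over pairs, pooled over documents.
#'
#' @param annotations A list of two or more span tibbles or corpus tibbles
#'   over the same text(s).
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' s <- phi_spans("t", 0, 2)
#' pairwise_agreement(list(s, s, s))
pairwise_agreement <- function(annotations) {
  m <- length(annotations)
  if (m < 2) rlang::abort("agreement needs at least two annotation sets")
  pairs <- utils::combn(m, 2)
  f1s <- apply(pairs, 2, function(pr) {
    met <- strict_match_metrics(annotations[[pr[1]]], annotations[[pr[2]]])
    f1 <- met$f1[met$tag_type == "total"]
    if (is.na(f1)) 1 else f1     # both annotators empty: full agreement
  })
  mean(f1s)
}

#' Format metrics in the x100 presentation
#'
#' @param metrics A `deid_metrics` tibble.
#' @return The tibble with `precision`, `recall`, `f1` replaced by strings
#'   multiplied by 100 with two decimals (`N/A` for absent types).
#' @export
format_metrics <- function(metrics) {
  dplyr::mutate(tibble::as_tibble(metrics),
                precision = percent2(.data$precision),
                recall = percent2(.data$recall),
                f1 = percent2(.data$f1))
}

#' Write a metrics report as TSV and JSON
#'
#' One row per tag type (and fold, if present) plus totals, scores x100
#' with two decimals, mirroring the layout of published evaluation tables.
#'
#' @param metrics A `deid_metrics` tibble.
#' @param path Output path without extension; `.tsv` and `.json` are
#'   appended.
#' @return Invisibly, the two file paths.
#' @export
write_metrics_report <- function(metrics, path) {
  fm <- format_metrics(metrics)
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(fm, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  jsonlite::write_json(fm, json, auto_unbox = TRUE, digits = NA, na = "string")
  invisible(c(tsv = tsv, json = json))
}
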