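# Benchmark workflows: the standard experiment setups used by the tests,
# the acceptance script and the vignette.

#' A clinical custom dictionary for the tokenizer
#'
#' Emulates a customized analyzer dictionary built from named-entity lists
#' and a standard disease-code master: hospital names from the surrogate
#' lists (registered as organization nouns) plus common disease/symptom
#' vocabulary (registered as disease nouns). As in IPADIC-style user
#' dictionaries, each entry carries its POS subcategory, so the detailed-POS
#' and `in_dictionary` feature families reflect the entry type.
#'
#' @param lists [make_name_lists()] whose hospital names are included.
#' @return A tibble of dictionary entries for [register_dictionary()].
#' @export
clinical_dictionary <- function(lists = make_name_lists(1)) {
  dplyr::bind_rows(
    tibble::tibble(surface = lists$hospital_names, pos = "noun",
                   detailed_pos = "organization"),
    tibble::tibble(
      surface = c("発熱", "咳嗽", "腹痛", "頭痛",
                  "嘔気", "倦怠感", "胸痛", "めまい",
                  "糖尿病", "高血圧症", "肺炎", "胃潰瘍",
                  "心不全", "脳梗塞", "気管支喘息"),
      pos = "noun", detailed_pos = "disease")
  )
}

#' Standard benchmark tokenizer
#'
#' The built-in tokenizer backend with the clinical custom dictionary
#' registered.
#'
#' @inheritParams clinical_dictionary
#' @return A `deid_tokenizer`.
#' @export
benchmark_tokenizer <- function(lists = make_name_lists(1)) {
  register_dictionary(deid_tokenizer(), clinical_dictionary(lists))
}

#' Train/test split with out-of-vocabulary person surnames
#'
#' Builds two pathology-style corpora whose person names come from disjoint
#' surname sets that share their characters: test surnames are never seen
#' in training, but every character in them occurs in training surnames.
#' This isolates the benefit of the character-level path of the BiLSTM-CRF:
#' a purely word/feature-based tagger cannot recognize the unseen names,
#' while character representations generalize to them.
#'
#' @param n_train,n_test Documents per side.
#' @param seed Integer seed.
#' @return A list with `train`, `test` (corpus tibbles) and `lists`
#'   (name lists used for hospitals).
#' @export
oov_person_split <- function(n_train = 60, n_test = 30, seed = 1) {
  # surname pairs drawn from a shared character pool
  train_families <- c("山田", "田中", "中村", "村川",
                      "林本", "井上", "木田", "川上",
                      "山本", "田村", "小林", "上田")
  test_families <- c("山中", "田川", "中林", "村田",
                     "井本", "木村", "川田", "上山")
  stopifnot(all(unlist(strsplit(test_families, "")) %in%
                  unlist(strsplit(train_families, ""))))
  lists <- make_name_lists(seed)
  train_lists <- lists
  train_lists$family_names <- train_families
  test_lists <- lists
  test_lists$family_names <- test_families
  train <- generate_corpus(synth_config(n_train, "pathology", seed = seed),
                           train_lists)
  test <- generate_corpus(synth_config(n_test, "pathology", seed = seed + 1),
                          test_lists)
  test$doc_id <- sub("^pathology", "pathology_test", test$doc_id)
  list(train = train, test = test, lists = lists)
}

#' Reduced BiLSTM-CRF configuration for desk-scale experiments
#'
#' The published layer sizes (see [lstm_config()]) remain the defaults of
#' the model; this helper returns a scaled-down configuration that trains
#' in seconds on a single CPU while keeping the architecture intact, for
#' test suites and reproducibility scripts.
#'
#' @param seed,epochs,dropout Passed through.
#' @param ... Further overrides for [lstm_config()].
#' @return An `lstm_config`.
#' @export
lstm_config_small <- function(seed = 1L, epochs = 12L, dropout = 0.3, ...) {
  lstm_config(word_embedding_size = 24L, char_embedding_size = 8L,
              char_hidden_size = 12L, lstm_hidden_size = 24L,
              learning_rate = 0.01, epochs = epochs, batch_size = 8L,
              dropout = dropout, seed = seed, ...)
}
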