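test_that("strict matching scores hand-computed cases", {
  gold <- phi_spans(c("a", "x"), c(0, 5), c(3, 7))
  perfect <- strict_match_metrics(gold, gold)
  tot <- perfect[perfect$tag_type == "total", ]
  expect_equal(c(tot$precision, tot$recall, tot$f1), c(1, 1, 1))

  # one exact hit, one boundary miss: tp=1 fp=1 fn=1, P=R=F1=0.5
  pred <- phi_spans(c("a", "x"), c(0, 5), c(3, 8))
  m <- strict_match_metrics(gold, pred)
  tot <- m[m$tag_type == "total", ]
  expect_equal(c(tot$tp, tot$fp, tot$fn), c(1, 1, 1))
  expect_equal(c(tot$precision, tot$recall, tot$f1), c(0.5, 0.5, 0.5))

  # empty prediction: zero-denominator convention
  m0 <- strict_match_metrics(gold, phi_spans())
  tot0 <- m0[m0$tag_type == "total", ]
  expect_equal(c(tot0$precision, tot0$recall, tot0$f1), c(0, 0, 0))
})

test_that("totals are micro-averages and absent types print N/A", {
  gold <- phi_spans(c("a", "t", "t"), c(0, 5, 10), c(3, 7, 12))
  pred <- phi_spans(c("a", "t", "h"), c(0, 5, 20), c(3, 7, 22))
  m <- strict_match_metrics(gold, pred)
  per <- m[m$tag_type != "total", ]
  tot <- m[m$tag_type == "total", ]
  expect_equal(tot$tp, sum(per$tp))
  expect_equal(tot$fp, sum(per$fp))
  expect_equal(tot$fn, sum(per$fn))
  fm <- format_metrics(m)
  expect_equal(fm$f1[fm$tag_type == "x"], "N/A")   # no gold, no predicted
  expect_equal(fm$f1[fm$tag_type == "a"], "100.00")
})

test_that("F1 is symmetric under swapping gold and prediction", {
  set.seed(21)
  for (k in 1:30) {
    a <- random_annotated_doc()$spans[[1]]
    b <- random_annotated_doc()$spans[[1]]
    ma <- strict_match_metrics(a, b)
    mb <- strict_match_metrics(b, a)
    expect_equal(ma$f1[ma$tag_type == "total"], mb$f1[mb$tag_type == "total"])
    expect_equal(ma$precision[ma$tag_type == "total"],
                 mb$recall[mb$tag_type == "total"])
  }
})

test_that("matching is per document when doc ids are present", {
  g <- tibble::tibble(doc_id = c("d1", "d2"), tag_type = "t",
                      begin = c(0L, 0L), end = c(2L, 2L))
  p <- tibble::tibble(doc_id = c("d1", "d3"), tag_type = "t",
                      begin = c(0L, 0L), end = c(2L, 2L))
  m <- strict_match_metrics(g, p)
  expect_equal(m$tp[m$tag_type == "t"], 1L)
  expect_equal(m$fp[m$tag_type == "t"], 1L)
  expect_equal(m$fn[m$tag_type == "t"], 1L)
})

test_that("token accuracy counts exact label agreement", {
  expect_equal(token_accuracy(c("B-a", "I-a", "O"), c("B-a", "I-a", "O")), 1)
  expect_equal(token_accuracy(c("O", "O"), c("O", "O")), 1)
  expect_equal(token_accuracy(c("B-a", "I-a", "O"), c("B-a", "O", "O")), 2 / 3)
  expect_error(token_accuracy(c("O"), c("O", "O")), "length")
})

test_that("cross-validation partitions documents and pools counts", {
  corp <- generate_corpus(synth_config(12, "mednlp", seed = 9))
  expect_error(cross_validate(corp, rule_factory(), k = 1), "k >= 2")
  expect_error(cross_validate(corp[1:2, ], rule_factory(), k = 4), "folds")

  cv <- cross_validate(corp, rule_factory(), k = 4, seed = 2)
  fold_of <- attr(cv, "fold_of")
  expect_length(fold_of, 12)
  expect_equal(sort(unique(fold_of)), 1:4)       # every doc in exactly one fold

  pooled <- cv[cv$fold == "pooled", ]
  folds <- cv[cv$fold != "pooled", ]
  for (ty in c(names(phi_tags()), "total")) {
    expect_equal(pooled$tp[pooled$tag_type == ty],
                 sum(folds$tp[folds$tag_type == ty]))
  }

  # the rule tagger has no training dependence: pooled CV equals whole-corpus
  whole <- strict_match_metrics(corp, rule_tag(corp))
  expect_equal(pooled$tp, whole$tp)
  expect_equal(pooled$fn, whole$fn)
  expect_equal(pooled$f1, whole$f1)
})

test_that("pairwise agreement averages strict F1 over annotator pairs", {
  s <- phi_spans(c("t", "h"), c(0, 5), c(2, 8))
  expect_equal(pairwise_agreement(list(s, s, s)), 1)
  disjoint <- phi_spans("t", 10, 12)
  expect_equal(pairwise_agreement(list(s, disjoint)), 0)
  # one agreeing pair, two disjoint pairs: (1 + 0 + 0) / 3
  expect_equal(pairwise_agreement(list(s, s, disjoint)), 1 / 3)
  expect_error(pairwise_agreement(list(s)), "at least two")
})

test_that("metrics reports are written as TSV and JSON in x100 format", {
  gold <- phi_spans(c("a", "x"), c(0, 5), c(3, 7))
  m <- strict_match_metrics(gold, gold)
  prefix <- file.path(withr::local_tempdir(), "report")
  paths <- write_metrics_report(m, prefix)
  expect_true(all(file.exists(paths)))
  tsv <- read.delim(paths["tsv"], colClasses = "character")
  expect_equal(tsv$f1[tsv$tag_type == "total"], "100.00")
  js <- jsonlite::read_json(paths["json"])
  expect_equal(js[[length(js)]]$f1, "100.00")
})
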