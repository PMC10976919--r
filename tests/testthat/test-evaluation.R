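pred_frame <- function(ids, t, n) {
  data.frame(report_id = ids, t = t, n = n, stringsAsFactors = FALSE)
}
gold_frame <- function(ids, t, n) {
  data.frame(report_id = ids, gold_t = t, gold_n = n,
             stringsAsFactors = FALSE)
}

test_that("evaluate computes accuracies and confusion matrices", {
  ids <- paste0("r", 1:4)
  gold <- gold_frame(ids, c("T1a", "T1a", "T2a", "T4"),
                     c("N0", "N0", "N2", "N3"))
  pred <- pred_frame(ids, c("T1a", "T1a", "T2a", "T3"),
                     c("N0", "N0", "N2", "N3"))
  m <- evaluate(pred, gold)
  expect_equal(m$accuracy_tn, 0.75)
  expect_equal(m$accuracy_t, 0.75)
  expect_equal(m$accuracy_n, 1)
  expect_equal(sum(m$confusion_tn), 4L)
  expect_equal(sum(m$confusion_t), 4L)

  perfect <- evaluate(pred_frame(ids, gold$gold_t, gold$gold_n), gold)
  expect_equal(perfect$accuracy_tn, 1)
  expect_equal(sum(diag(perfect$confusion_tn)), 4L)
  expect_equal(perfect$weighted_f1, 1)
})

test_that("weighted F1 matches the hand-computed 2-class example", {
  # gold A,A,B; pred A,B,B.  Class A: P = 1, R = 1/2, F1 = 2/3, support 2/3;
  # class B: P = 1/2, R = 1, F1 = 2/3, support 1/3.  Weighted F1 = 2/3 and
  # weighted precision = 5/6 (checked against scikit-learn's
  # precision_recall_fscore_support(average = "weighted")).
  gold <- gold_frame(paste0("r", 1:3), c("A", "A", "B"), c("", "", ""))
  pred <- pred_frame(paste0("r", 1:3), c("A", "B", "B"), c("", "", ""))
  m <- evaluate(pred, gold)
  expect_equal(m$weighted_f1, 2 / 3, tolerance = 1e-12)
  expect_equal(m$weighted_precision, 5 / 6, tolerance = 1e-12)
  expect_equal(m$weighted_recall, 2 / 3, tolerance = 1e-12)
})

test_that("evaluate matches the reference implementation on random pairs", {
  set.seed(2024)
  labels_t <- t_labels[-1L]
  for (i in 1:100) {
    n <- sample(5:40, 1)
    ids <- paste0("r", seq_len(n))
    gold <- gold_frame(ids, sample(labels_t, n, TRUE),
                       sample(n_labels, n, TRUE))
    pred <- pred_frame(ids, sample(labels_t, n, TRUE),
                       sample(n_labels, n, TRUE))
    m <- evaluate(pred, gold)
    ref <- oracle_weighted_prf(paste0(pred$t, pred$n),
                               paste0(gold$gold_t, gold$gold_n))
    expect_equal(m$weighted_precision, ref$precision, tolerance = 1e-9)
    expect_equal(m$weighted_recall, ref$recall, tolerance = 1e-9)
    expect_equal(m$weighted_f1, ref$f1, tolerance = 1e-9)
    expect_equal(m$weighted_recall, m$accuracy_tn, tolerance = 1e-12)
    expect_lte(m$accuracy_tn, min(m$accuracy_t, m$accuracy_n))
  }
})

test_that("evaluate is permutation-invariant and strict about ids", {
  ids <- paste0("r", 1:10)
  set.seed(8)
  gold <- gold_frame(ids, sample(t_labels[-1], 10, TRUE),
                     sample(n_labels, 10, TRUE))
  pred <- pred_frame(ids, sample(t_labels[-1], 10, TRUE),
                     sample(n_labels, 10, TRUE))
  m1 <- evaluate(pred, gold)
  m2 <- evaluate(pred[sample(10), ], gold[sample(10), ])
  expect_equal(m1$accuracy_tn, m2$accuracy_tn)
  expect_equal(m1$confusion_tn, m2$confusion_tn)

  expect_error(evaluate(pred[-1, ], gold), "missing from predictions: r1")
})

test_that("error_report tags mismatches by trace and skips correct reports", {
  corp <- generate_corpus(generator_spec(
    n_reports = 40L, seed = 17L,
    adversarial_rates = c(negation = 0, uncertainty = 0, blacklist_trap = 0,
                          missing_subheadings = 0, multidim_size = 0,
                          implicit_satellite = 0, avidity_conflict = 0)))
  res <- stage_corpus(corp, test_lexicon(), test_rules())
  expect_equal(nrow(error_report(res, corp)), 0L)

  # force mismatches by corrupting predictions; traces still drive categories
  res[[1]]$t <- if (res[[1]]$t == "T4") "T1a" else "T4"
  res[[2]]$n <- if (res[[2]]$n == "N3") "N0" else "N3"
  res[[2]]$trace <- c(res[[2]]$trace,
                      "[sectionizer] no subheadings matched; whole text unsectioned")
  err <- error_report(res, corp)
  expect_equal(nrow(err), 2L)
  expect_setequal(err$axis, c("T", "N"))
  expect_true("sectionizer" %in% err$auto_category)
  expect_true(all(err$predicted != err$gold))
})
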