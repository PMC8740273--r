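test_that("confusion_matrix counts pairs like brute force", {
  expect_equal(diag(confusion_matrix(c(0, 1, 2), c(0, 1, 2), k = 3)),
               c(1, 1, 1), ignore_attr = TRUE)
  anti <- confusion_matrix(c(0, 1), c(1, 0), k = 2)
  expect_equal(as.vector(anti), c(0L, 1L, 1L, 0L))
  expect_error(confusion_matrix(0:3, 0:2, k = 5),
               class = "fundusdr_length_mismatch")

  withr::with_seed(401, {
    truth <- sample(0:4, 100, replace = TRUE)
    pred <- sample(0:4, 100, replace = TRUE)
    cm <- confusion_matrix(truth, pred, k = 5)
    for (a in 0:4) for (b in 0:4)
      expect_equal(cm[a + 1, b + 1], sum(truth == a & pred == b),
                   ignore_attr = TRUE)
  })
})

test_that("per-class scores follow the one-vs-rest definitions", {
  withr::with_seed(402, {
    truth <- sample(0:2, 60, replace = TRUE)
    pred <- sample(0:2, 60, replace = TRUE)
    pc <- per_class_scores(confusion_matrix(truth, pred, k = 3))
    for (g in 0:2) {
      tp <- sum(truth == g & pred == g)
      fp <- sum(truth != g & pred == g)
      fn <- sum(truth == g & pred != g)
      tn <- sum(truth != g & pred != g)
      row <- pc[pc$grade == g, ]
      expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(row$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
      expect_equal(row$specificity, tn / (fp + tn))
      pr <- row$precision; rc <- row$recall
      expect_equal(row$f1, if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc))
    }
  })
})

test_that("harmonic-mean F1 at the published precision/recall rounds to 0.89", {
  # counts realizing precision 1577/1900 = 0.83, recall 1577/1660 = 0.95
  cm <- matrix(c(1577, 83, 323, 6000), 2, 2, byrow = TRUE)
  pc <- per_class_scores(cm)
  expect_equal(pc$precision[1], 0.83)
  expect_equal(pc$recall[1], 0.95)
  expect_equal(round(pc$f1[1], 2), 0.89)
  expect_equal(pc$f1[1],
               2 * pc$precision[1] * pc$recall[1] /
                 (pc$precision[1] + pc$recall[1]))
})

test_that("degenerate per-class denominators follow the zero convention", {
  # class 2 present in truth but never predicted
  cm <- confusion_matrix(c(0, 0, 1, 2), c(0, 0, 1, 1), k = 3)
  pc <- per_class_scores(cm)
  expect_equal(pc$precision[3], 0)
  expect_equal(pc$recall[3], 0)
  expect_equal(pc$f1[3], 0)

  perfect <- per_class_scores(confusion_matrix(rep(0, 4), rep(0, 4), k = 1))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
})

test_that("aggregate scores: ACA is the row-normalized diagonal mean", {
  ideal <- aggregate_scores(confusion_matrix(0:4, 0:4, k = 5))
  expect_equal(ideal$aca, 1)
  expect_equal(ideal$macro_f1, 1)
  expect_equal(ideal$micro_f1, 1)

  cm <- matrix(c(8, 2, 4, 6), 2, 2, byrow = TRUE)
  agg <- aggregate_scores(cm)
  expect_equal(agg$aca, (0.8 + 0.6) / 2)

  empty <- matrix(c(3, 1, 0, 0), 2, 2, byrow = TRUE)
  expect_error(aggregate_scores(empty), class = "fundusdr_empty_class")
})

test_that("micro-F1 equals accuracy for single-label multiclass", {
  withr::with_seed(403, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      truth <- sample(0:(k - 1), 50, replace = TRUE)
      truth[1:k] <- 0:(k - 1)        # every class present
      pred <- sample(0:(k - 1), 50, replace = TRUE)
      agg <- aggregate_scores(confusion_matrix(truth, pred, k))
      expect_equal(agg$micro_f1, agg$accuracy, tolerance = 1e-12)
      expect_equal(agg$accuracy, mean(truth == pred))
    }
  })
})

test_that("macro-F1 lies between the per-class extremes", {
  withr::with_seed(404, {
    for (rep in 1:10) {
      truth <- sample(0:3, 40, replace = TRUE); truth[1:4] <- 0:3
      pred <- sample(0:3, 40, replace = TRUE)
      cm <- confusion_matrix(truth, pred, k = 4)
      agg <- aggregate_scores(cm)
      pc <- per_class_scores(cm)
      expect_gte(agg$macro_f1, min(pc$f1))
      expect_lte(agg$macro_f1, max(pc$f1))
    }
  })
})

test_that("one-vs-rest AUC matches exhaustive pair counting", {
  truth <- c(0, 0, 1, 1, 2, 2)
  prob <- matrix(c(0.7, 0.2, 0.1,
                   0.5, 0.3, 0.2,
                   0.3, 0.5, 0.2,
                   0.2, 0.5, 0.3,
                   0.1, 0.3, 0.6,
                   0.3, 0.3, 0.4), 6, 3, byrow = TRUE)
  by_hand <- mean(vapply(0:2, function(g)
    oracle_auc_pairs(prob[, g + 1], truth == g), numeric(1)))
  expect_equal(auc_ovr(truth, prob), by_hand, tolerance = 1e-12)

  onehot <- matrix(0, 6, 3); onehot[cbind(1:6, truth + 1)] <- 1
  expect_equal(auc_ovr(truth, onehot), 1)

  flat <- matrix(1 / 3, 6, 3)
  expect_equal(auc_ovr(truth, flat), 0.5)

  expect_error(auc_ovr(c(0, 0, 0), matrix(1 / 2, 3, 2)),
               class = "fundusdr_degenerate_class")
})

test_that("AUC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(405, {
    truth <- sample(0:2, 40, replace = TRUE); truth[1:3] <- 0:2
    raw <- matrix(runif(120), 40, 3)
    prob <- raw / rowSums(raw)
    ours <- auc_ovr(truth, prob)
    ref <- mean(vapply(0:2, function(g)
      as.numeric(pROC::auc(pROC::roc(
        as.integer(truth == g), prob[, g + 1], quiet = TRUE,
        direction = "<"))), numeric(1)))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("metrics_report bundles everything and writes the report table", {
  withr::with_seed(406, {
    truth <- sample(0:4, 80, replace = TRUE); truth[1:5] <- 0:4
    raw <- matrix(runif(400), 80, 5)
    prob <- raw / rowSums(raw)
    pred <- max.col(prob, ties.method = "first") - 1L
    rep_ <- metrics_report(truth, pred, prob)
    expect_s3_class(rep_, "dr_metrics")
    expect_true(all(unlist(rep_$aggregate) >= 0 & unlist(rep_$aggregate) <= 1))
    expect_equal(nrow(tidy(rep_)), 5)
    expect_equal(glance(rep_)$auc, auc_ovr(truth, prob))

    path <- withr::local_tempfile(fileext = ".csv")
    write_report(rep_, path)
    tab <- readr::read_csv(path, show_col_types = FALSE)
    expect_equal(nrow(tab), 6)             # five grades + overall
    expect_equal(tab$accuracy[1:5], rep_$per_class$recall)
    expect_equal(tab$support[6], 80)
  })
})
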