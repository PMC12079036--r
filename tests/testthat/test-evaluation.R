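labels_of <- function(x) {
  tibble::tibble(segment_id = sprintf("s%d", seq_along(x)),
                 label = as.integer(x))
}

test_that("confusion counts cross-tabulate predictions against consensus", {
  truth <- labels_of(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  cm <- confusion_counts(truth, truth)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(4, 6, 0, 0))
  inverted <- truth
  inverted$label <- 1L - inverted$label
  cm2 <- confusion_counts(inverted, truth)
  expect_equal(c(cm2$tp, cm2$tn), c(0, 0))
  expect_equal(c(cm2$fp, cm2$fn), c(6, 4))
  expect_error(confusion_counts(truth[1:9, ], truth),
               "only in truth: \\{s10\\}")
})

test_that("confusion counts match brute-force pair counting on simulated data", {
  sim <- simulate_segments(simulation_config(n_segments = 79, seed = 71))
  clf <- bilateral_classifier("mouthSmile_L", "mouthSmile_R", 0.45)
  feats <- aggregate_segments(sim$frames, c("mouthSmile_L", "mouthSmile_R"))
  preds <- predict(clf, feats)
  cm <- confusion_counts(preds, sim$truth)
  p <- preds$label[match(sim$truth$segment_id, preds$segment_id)]
  t <- sim$truth$label
  counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(t)) {
    key <- if (p[i] == 1 && t[i] == 1) "tp" else if (p[i] == 1) "fp"
           else if (t[i] == 1) "fn" else "tn"
    counts[key] <- counts[key] + 1
  }
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), unname(counts))
  expect_equal(cm$n, 79)
})

test_that("sensitivity and specificity follow their margins", {
  expect_equal(sens_spec(confusion_matrix(tp = 27, fp = 2, fn = 1, tn = 49)),
               c(sensitivity = 27 / 28, specificity = 49 / 51))
  expect_equal(sens_spec(confusion_matrix(5, 0, 0, 5)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sens_spec(confusion_matrix(tp = 0, fp = 0, fn = 5, tn = 5)),
               c(sensitivity = 0, specificity = 1))
  expect_error(sens_spec(confusion_matrix(0, 5, 0, 5)),
               "sensitivity undefined")
  expect_error(sens_spec(confusion_matrix(5, 0, 5, 0)),
               "specificity undefined")
})

test_that("Cohen's kappa matches hand-evaluated examples", {
  # p_o = 0.8, p_e = 0.58 -> kappa = 0.22 / 0.42
  res <- cohen_kappa(confusion_matrix(tp = 2, fp = 1, fn = 1, tn = 6))
  expect_equal(res$p_bar, 0.8)
  expect_equal(res$p_e, 0.58)
  expect_equal(res$kappa, 11 / 21, tolerance = 1e-12)
  expect_equal(cohen_kappa(confusion_matrix(4, 0, 0, 6))$kappa, 1)
  expect_error(cohen_kappa(confusion_matrix(5, 0, 0, 0)), "undefined")
})

test_that("Cohen's kappa matches the determinant identity on random tables", {
  withr::with_seed(73, {
    checked <- 0
    while (checked < 50) {
      cts <- as.vector(stats::rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1)))
      if (min(cts[1] + cts[2], cts[1] + cts[3],
              cts[4] + cts[2], cts[4] + cts[3]) == 0) next
      res <- cohen_kappa(confusion_matrix(cts[1], cts[2], cts[3], cts[4]))
      expect_equal(res$kappa, cohen_direct(cts[1], cts[2], cts[3], cts[4]),
                   tolerance = 1e-12)
      checked <- checked + 1
    }
  })
})

test_that("kappa invariances hold", {
  cm <- confusion_matrix(tp = 27, fp = 2, fn = 1, tn = 49)
  swapped <- confusion_matrix(tp = 49, fp = 1, fn = 2, tn = 27)
  expect_equal(cohen_kappa(cm)$kappa, cohen_kappa(swapped)$kappa,
               tolerance = 1e-12)
  # chance correction can only lower agreement
  expect_lte(cohen_kappa(cm)$kappa, cohen_kappa(cm)$p_bar)
})

test_that("evaluation runs on the test half only and conserves counts", {
  sim <- simulate_segments(simulation_config(seed = 81))
  split <- stratified_split(sim$truth, segment_participants(sim$frames),
                            seed = 82)
  feats <- aggregate_segments(sim$frames, c("mouthSmile_L", "mouthSmile_R"))
  train_feats <- feats[feats$segment_id %in% split$train, ]
  train_labels <- sim$truth[sim$truth$segment_id %in% split$train, ]
  fit <- fit_threshold(train_feats, train_labels)
  report <- evaluate_classifier(sim$frames, fit$classifier, sim$truth, split)
  expect_equal(report$n_test, length(split$test))
  cm <- report$confusion
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, length(split$test))
  leaky <- split
  leaky$train <- c(leaky$train, leaky$test[1])
  expect_error(evaluate_classifier(sim$frames, fit$classifier, sim$truth,
                                   leaky),
               "leakage")
})

test_that("a threshold of 1 predicts nothing positive", {
  sim <- simulate_segments(simulation_config(seed = 83))
  split <- stratified_split(sim$truth, segment_participants(sim$frames),
                            seed = 84)
  clf <- bilateral_classifier("mouthSmile_L", "mouthSmile_R", 1.0)
  report <- evaluate_classifier(sim$frames, clf, sim$truth, split)
  expect_equal(report$sensitivity, 0)
  expect_equal(report$specificity, 1)
})

test_that("evaluation reports serialize with audit quantities", {
  sim <- simulate_segments(simulation_config(seed = 85))
  split <- stratified_split(sim$truth, segment_participants(sim$frames),
                            seed = 86)
  clf <- bilateral_classifier("mouthSmile_L", "mouthSmile_R", 0.45)
  report <- evaluate_classifier(sim$frames, clf, sim$truth, split)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(report, f)
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(x$sensitivity, report$sensitivity)
  expect_equal(x$cohen_kappa$estimate, report$kappa$kappa)
  expect_true(all(c("observed_agreement", "chance_agreement", "se")
                  %in% names(x$cohen_kappa)))
})
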