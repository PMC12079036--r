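scores_of <- function(pos, neg) {
  tibble::tibble(
    segment_id = sprintf("s%d", seq_len(length(pos) + length(neg))),
    score = c(pos, neg)
  )
}
truth_of <- function(pos, neg) {
  tibble::tibble(
    segment_id = sprintf("s%d", seq_len(length(pos) + length(neg))),
    label = rep(1:0, c(length(pos), length(neg)))
  )
}

test_that("ROC grid has 1001 points and monotone rates", {
  roc <- roc_curve(scores_of(c(0.8, 0.6), c(0.4, 0.2)),
                   truth_of(c(0.8, 0.6), c(0.4, 0.2)))
  expect_equal(nrow(roc), 1001)
  expect_equal(roc$threshold, (0:1000) / 1000)
  expect_true(all(diff(roc$tpr) <= 0))
  expect_true(all(diff(roc$fpr) <= 0))
  expect_true(all(roc$j >= -1 & roc$j <= 1))
  expect_equal(roc$j, roc$tpr - roc$fpr)
})

test_that("AUC matches closed-form cases", {
  expect_equal(roc_auc(roc_curve(scores_of(c(0.8, 0.6), c(0.4, 0.2)),
                                 truth_of(c(0.8, 0.6), c(0.4, 0.2)))), 1.0)
  same <- scores_of(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(roc_auc(roc_curve(same, truth_of(c(1, 1), c(1, 1)))), 0.5)
  # 3 of 4 (positive, negative) pairs concordant
  expect_equal(roc_auc(roc_curve(scores_of(c(0.6, 0.3), c(0.4, 0.1)),
                                 truth_of(c(1, 1), c(1, 1)))), 0.75)
})

test_that("trapezoidal AUC equals pairwise concordance on tie-free scores", {
  withr::with_seed(41, {
    for (i in 1:25) {
      n_pos <- sample(2:20, 1)
      n_neg <- sample(2:20, 1)
      s <- tie_free_scores(n_pos + n_neg)
      pos <- s[seq_len(n_pos)]
      neg <- s[-seq_len(n_pos)]
      auc <- roc_auc(roc_curve(scores_of(pos, neg), truth_of(pos, neg)))
      expect_equal(auc, mw_auc(pos, neg), tolerance = 1e-9)
    }
  })
})

test_that("fixed-grid AUC matches pROC's empirical AUC on tie-free scores", {
  withr::with_seed(43, {
    s <- tie_free_scores(35)
    pos <- s[1:15]
    neg <- s[16:35]
    ours <- roc_auc(roc_curve(scores_of(pos, neg), truth_of(pos, neg)))
    ref <- as.numeric(pROC::auc(
      rep(1:0, c(15, 20)), c(pos, neg),
      levels = c(0, 1), direction = "<", quiet = TRUE))
    expect_equal(ours, ref, tolerance = 1e-9)
  })
})

test_that("single-class truth is rejected", {
  s <- scores_of(c(0.7, 0.6), numeric(0))
  expect_error(roc_curve(s, tibble::tibble(segment_id = s$segment_id,
                                           label = c(1L, 1L))),
               "single class")
})

test_that("Youden threshold takes the smallest maximizer", {
  # separation at 0.4: 0.4 > 0.399 keeps FPR = 0.5, so J = 1 first at 0.400
  roc <- roc_curve(scores_of(c(0.8, 0.6), c(0.4, 0.2)),
                   truth_of(c(0.8, 0.6), c(0.4, 0.2)))
  expect_equal(youden_threshold(roc), 0.400)
  expect_equal(max(roc$j), 1)
  same <- roc_curve(scores_of(c(0.5, 0.5), c(0.5, 0.5)),
                    truth_of(c(1, 1), c(1, 1)))
  expect_true(all(same$j == 0))
  expect_equal(youden_threshold(same), 0.000)
})

test_that("stratified split balances participants and classes", {
  sim <- simulate_segments(simulation_config(seed = 51))
  labels <- sim$truth
  participants <- segment_participants(sim$frames)
  split <- stratified_split(labels, participants, seed = 52)
  expect_length(split$train, 79)
  expect_length(split$test, 79)
  expect_length(intersect(split$train, split$test), 0)
  expect_setequal(c(split$train, split$test), labels$segment_id)
  d <- dplyr::inner_join(labels, participants, by = "segment_id")
  d$half <- ifelse(d$segment_id %in% split$train, "train", "test")
  imbalance <- tapply(d$half, paste(d$participant_id, d$label),
                      function(h) abs(sum(h == "train") - sum(h == "test")))
  expect_true(all(imbalance <= 1))
  # deterministic per seed
  expect_identical(split, stratified_split(labels, participants, seed = 52))
  expect_false(identical(split,
                         stratified_split(labels, participants, seed = 53)))
})

test_that("small strata split evenly with odd remainders shared", {
  labels <- tibble::tibble(segment_id = sprintf("s%d", 1:4),
                           label = c(1L, 1L, 1L, 1L))
  participants <- tibble::tibble(segment_id = labels$segment_id,
                                 participant_id = "P1")
  split <- stratified_split(labels, participants, seed = 1)
  expect_length(split$train, 2)
  expect_length(split$test, 2)
  odd <- tibble::tibble(segment_id = sprintf("s%d", 1:5),
                        label = c(1L, 1L, 1L, 1L, 1L))
  podd <- tibble::tibble(segment_id = odd$segment_id, participant_id = "P1")
  s2 <- stratified_split(odd, podd, seed = 2)
  expect_true(length(s2$train) %in% 2:3)
  expect_equal(length(s2$train) + length(s2$test), 5)
})

test_that("threshold fitting recovers the class gap on simulated data", {
  sim <- simulate_segments(simulation_config(seed = 61))
  feats <- aggregate_segments(sim$frames, c("mouthSmile_L", "mouthSmile_R"))
  fit <- fit_threshold(feats, sim$truth)
  score <- pmax(feats$mouthSmile_L, feats$mouthSmile_R)
  lab <- sim$truth$label[match(feats$segment_id, sim$truth$segment_id)]
  expect_gt(fit$classifier$threshold, max(score[lab == 0]))
  expect_lt(fit$classifier$threshold, min(score[lab == 1]))
  expect_equal(roc_auc(fit$roc), 1.0)
})
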