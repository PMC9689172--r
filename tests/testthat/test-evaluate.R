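test_that("vote aggregation equals a brute-force tally", {
  set.seed(30)
  for (i in 1:50) {
    n <- sample(1:300, 1)
    votes <- rbinom(n, 1, runif(1))
    agg <- aggregate_votes(votes)
    expect_identical(agg$votes_positive, as.integer(sum(votes == 1)))
    expect_equal(agg$vote_fraction, sum(votes) / n)
    expect_identical(agg$predicted_label, as.integer(sum(votes) / n > 0.5))
  }
  expect_identical(aggregate_votes(rep(1L, 256))$vote_fraction, 1)
  expect_identical(aggregate_votes(rep(1L, 256))$predicted_label, 1L)
})

test_that("an exact half split of votes is a negative call", {
  agg <- aggregate_votes(c(rep(1L, 128), rep(0L, 128)))
  expect_equal(agg$vote_fraction, 0.5)
  expect_identical(agg$predicted_label, 0L)  # strict majority rule
})

test_that("frame prediction votes over every A-line segment", {
  m <- build_model(small_cnn(), 1)
  set.seed(31)
  w <- matrix(runif(256 * 40), 256, 40)
  fp <- predict_frame(m, w, true_label = 1L, case_id = "t")
  expect_s3_class(fp, "frame_prediction")
  expect_identical(fp$n_segments, 40L)
  # brute-force: classify each column independently
  cls <- apply(w, 2, function(col) {
    s <- cnn_forward(m, col)
    as.integer(s[1, 2] > s[1, 1])
  })
  expect_identical(fp$votes_positive, as.integer(sum(cls)))
  expect_equal(fp$p_correct, mean(cls == 1L))
  expect_identical(fp$predicted_label, as.integer(mean(cls) > 0.5))
  expect_error(predict_frame(m, w[, 0, drop = FALSE]), "no A-lines")
})

test_that("confusion counts tally the four outcomes", {
  expect_identical(unclass(confusion_counts(c(1, 0, 1), c(1, 0, 1))),
                   c(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  expect_identical(unclass(confusion_counts(1L, 0L)),
                   c(TP = 0L, TN = 0L, FP = 1L, FN = 0L))
  # 46-frame set with 25 positives / 21 negatives
  pred <- c(rep(1, 23), rep(0, 2), rep(0, 19), rep(1, 2))
  truth <- c(rep(1, 25), rep(0, 21))
  cm <- confusion_counts(pred, truth)
  expect_identical(unclass(cm), c(TP = 23L, TN = 19L, FP = 2L, FN = 2L))
  expect_identical(sum(cm), 46L)
  expect_error(confusion_counts(c(1, 0), 1L), "equal length")
})

test_that("ACC/SEN/SPE are the exact confusion ratios", {
  m <- classification_metrics(c(TP = 23, TN = 19, FP = 2, FN = 2))
  expect_equal(m[["ACC"]], 42 / 46)   # 91.30%
  expect_equal(m[["SEN"]], 23 / 25)   # 92.00%
  expect_equal(m[["SPE"]], 19 / 21)   # 90.48%
  expect_equal(unname(classification_metrics(c(TP = 1, TN = 1, FP = 0, FN = 0))),
               c(1, 1, 1))
  expect_equal(classification_metrics(c(TP = 0, TN = 3, FP = 1, FN = 5))[["SEN"]], 0)
  expect_error(classification_metrics(c(TP = 0, TN = 1, FP = 0, FN = 0)),
               "SEN")
  expect_true(is.na(classification_metrics(c(TP = 0, TN = 1, FP = 0, FN = 0),
                                           strict = FALSE)[["SEN"]]))
})

test_that("accuracy is the prevalence-weighted mean of SEN and SPE", {
  set.seed(32)
  for (i in 1:20) {
    cm <- c(TP = sample(1:30, 1), TN = sample(1:30, 1),
            FP = sample(1:30, 1), FN = sample(1:30, 1))
    m <- classification_metrics(cm)
    n_pos <- cm["TP"] + cm["FN"]; n_neg <- cm["TN"] + cm["FP"]
    expect_equal(m[["ACC"]],
                 unname((n_pos * m["SEN"] + n_neg * m["SPE"]) / (n_pos + n_neg)))
  }
})

test_that("ROC/AUC handles the canonical boundary cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), ci = FALSE)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5), ci = FALSE)$auc, 0.5)
  # 3 of the 4 pos/neg pairs are wins
  expect_equal(roc_auc(c(0.9, 0.6, 0.7, 0.2), c(1, 1, 0, 0), ci = FALSE)$auc,
               0.75)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic", {
  set.seed(33)
  for (i in 1:100) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    # ties made likely by rounding to one decimal
    sc <- round(c(runif(n1), runif(n0)), 1)
    lb <- c(rep(1L, n1), rep(0L, n0))
    r <- roc_auc(sc, lb, ci = FALSE)
    pos <- sc[lb == 1L]; neg <- sc[lb == 0L]
    wins <- 0
    for (p in pos) for (q in neg)
      wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(r$auc, wins / (n1 * n0))
    # ROC anchored at (0,0) and (1,1), monotone in both coordinates
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with pROC and DeLong CI brackets the estimate", {
  set.seed(34)
  sc <- c(rnorm(20, 1), rnorm(15, 0))
  lb <- c(rep(1L, 20), rep(0L, 15))
  r <- roc_auc(sc, lb)
  ref <- suppressMessages(as.numeric(pROC::auc(lb, sc, levels = c(0, 1),
                                               direction = "<", quiet = TRUE)))
  expect_equal(r$auc, ref)
  expect_true(r$auc_ci95[1] <= r$auc && r$auc <= r$auc_ci95[2])
  expect_true(all(r$auc_ci95 >= 0 & r$auc_ci95 <= 1))
})

test_that("evaluate_windows assembles per-frame reports", {
  m <- build_model(small_cnn(), 2)
  set.seed(35)
  ws <- lapply(1:12, function(i) matrix(runif(256 * 10), 256, 10))
  labels <- rep(0:1, 6)
  rep_ <- evaluate_windows(m, ws, labels)
  expect_identical(nrow(rep_$frames), 12L)
  expect_identical(sum(rep_$confusion), 12L)
  expect_identical(rep_$frames$predicted,
                   vapply(ws, function(w)
                     predict_frame(m, w)$predicted_label, integer(1)))
})
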