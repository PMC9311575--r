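test_that("one-vs-rest confusion counts match hand tallies", {
  # binary case tallied by hand: predictions (1,1,0,0) vs labels (1,0,0,1)
  pred <- c(2, 2, 1, 1); lab <- c(2, 1, 1, 2) # class 2 plays "positive"
  cc <- confusion_counts(pred, lab, 2)
  expect_identical(unlist(cc[2, ]), c(TP = 1, FN = 1, FP = 1, TN = 1))
  expect_true(all(rowSums(cc) == 4))

  perfect <- confusion_counts(c(1, 2, 3, 2), c(1, 2, 3, 2), 3)
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))

  # swapping predictions and labels exchanges FP and FN
  a <- confusion_counts(pred, lab, 2)
  b <- confusion_counts(lab, pred, 2)
  expect_identical(a$TP, b$TP)
  expect_identical(a$FP, b$FN)
  expect_error(confusion_counts(c(1, 5), c(1, 2), 3), "1..num_classes")
})

test_that("metric formulas evaluate literally", {
  m <- classification_metrics(c(TP = 40, FN = 10, TN = 35, FP = 15))
  expect_equal(m[["accuracy"]], 0.75, tolerance = 1e-12)
  expect_equal(m[["sensitivity"]], 0.80, tolerance = 1e-12)
  expect_equal(m[["specificity"]], 0.70, tolerance = 1e-12)
  expect_equal(m[["f_score"]], 80 / 105, tolerance = 1e-12)

  perfect <- classification_metrics(c(TP = 1, TN = 1, FP = 0, FN = 0))
  expect_true(all(perfect == 1))

  # algebraic oracle: F = 2PR/(P+R) from precision/recall identities
  set.seed(1)
  for (rep in 1:20) {
    counts <- c(TP = sample(0:30, 1), FN = sample(1:30, 1),
                TN = sample(0:30, 1), FP = sample(1:30, 1))
    m <- classification_metrics(counts)
    prec <- counts[["TP"]] / (counts[["TP"]] + counts[["FP"]])
    rec <- counts[["TP"]] / (counts[["TP"]] + counts[["FN"]])
    f_ref <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(m[["f_score"]], f_ref, tolerance = 1e-12)
    expect_equal(m[["accuracy"]],
                 1 - (counts[["FP"]] + counts[["FN"]]) / sum(counts),
                 tolerance = 1e-12)
  }
  expect_error(classification_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)),
               "zero")
  zden <- classification_metrics(c(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_identical(zden[["sensitivity"]], 0)
})

test_that("macro AUC agrees with brute-force pair counting and pROC", {
  # 6-item binary toy set: count concordant pairs explicitly
  scores <- cbind(1 - c(0.9, 0.8, 0.35, 0.6, 0.2, 0.1),
                  c(0.9, 0.8, 0.35, 0.6, 0.2, 0.1))
  labels <- c(2, 2, 1, 2, 1, 1)
  pos <- which(labels == 2); neg <- which(labels == 1)
  conc <- 0
  for (i in pos) for (j in neg)
    conc <- conc + (scores[i, 2] > scores[j, 2]) + 0.5 * (scores[i, 2] == scores[j, 2])
  expect_equal(macro_auc(scores, labels), conc / (length(pos) * length(neg)),
               tolerance = 1e-12)

  expect_equal(macro_auc(scores, labels), 1) # these scores separate

  skip_if_not_installed("pROC")
  set.seed(2)
  s <- runif(40)
  l <- rbinom(40, 1, 0.5) + 1
  ours <- macro_auc(cbind(1 - s, s), l)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                        direction = "<", levels = c(1, 2))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("macro AUC is invariant to monotone score transforms", {
  set.seed(3)
  s <- matrix(runif(60), 20, 3)
  s <- s / rowSums(s)
  l <- sample(1:3, 20, replace = TRUE)
  v <- macro_auc(s, l)
  expect_equal(macro_auc(qlogis(s * 0.98 + 0.01), l), v, tolerance = 1e-12)
  expect_equal(macro_auc(s^3, l), v, tolerance = 1e-12)
  # label-independent scores hover near 1/2
  set.seed(4)
  big_s <- matrix(runif(3000), 1000, 3)
  big_l <- sample(1:3, 1000, replace = TRUE)
  expect_lt(abs(macro_auc(big_s, big_l) - 0.5), 3 * 1 / sqrt(12) / sqrt(250))
  expect_error(macro_auc(s, rep(1, 20)), "single")
})

test_that("majority voting aggregates patches with probability tie-breaks", {
  expect_identical(unname(majority_vote(c(1, 1, 2), c("a", "a", "a"))), 1L)
  expect_identical(unname(majority_vote(5L, "img")), 5L)
  # unanimity wins regardless of probabilities
  pr <- matrix(runif(6), 3, 2)
  expect_identical(unname(majority_vote(c(2, 2, 2), rep("a", 3), pr)), 2L)
  # tie (1, 2) broken by the larger mean class probability
  pr2 <- rbind(c(0.55, 0.45), c(0.29, 0.71)) # means: 0.42 vs 0.58
  expect_identical(unname(majority_vote(c(1, 2), c("a", "a"), pr2)), 2L)
  expect_error(majority_vote(c(1, 2), c("a", "a")), "tie")
  # grouping across images
  out <- majority_vote(c(1, 1, 2, 3, 3), c("a", "a", "a", "b", "b"))
  expect_identical(out, c(a = 1L, b = 3L))
})

test_that("metric reports assemble normalized confusion matrices", {
  pred <- c(1, 2, 2, 3, 3, 3, 1, 2)
  lab <- c(1, 2, 3, 3, 3, 1, 1, 2)
  rep_ <- metric_report(pred, lab, num_classes = 3)
  expect_equal(rowSums(rep_$confusion_normalized), rep(1, 3))
  expect_equal(rep_$accuracy, mean(pred == lab))
  expect_equal(rep_$macro[["sensitivity"]],
               mean(vapply(1:3, function(k)
                 sum(pred == k & lab == k) / sum(lab == k), numeric(1))))
  expect_output(print(rep_), "accuracy")
})
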