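test_that("confusion counts partition the cases and match the naive loop", {
  cc <- confusion_counts(rep(c("m", "b"), each = 4),
                         rep(c("m", "b"), each = 4), positive = "m")
  expect_equal(unclass(cc), list(tp = 4L, tn = 4L, fp = 0L, fn = 0L))

  # all predictions inverted on 3 pos / 2 neg
  cc <- confusion_counts(c("m", "m", "m", "b", "b"),
                         c("b", "b", "b", "m", "m"), positive = "m")
  expect_equal(unclass(cc), list(tp = 0L, tn = 0L, fp = 2L, fn = 3L))

  set.seed(0)
  for (i in 1:20) {
    y <- random_labels(50); p <- random_labels(50)
    got <- confusion_counts(y, p, "pos")
    want <- oracle_confusion(y, p, "pos")
    expect_equal(c(tp = got$tp, tn = got$tn, fp = got$fp, fn = got$fn),
                 want)
    expect_equal(got$tp + got$tn + got$fp + got$fn, 50L)
  }
})

test_that("confusion counts reject malformed input", {
  expect_error(confusion_counts(character(), character(), "m"), "non-empty")
  expect_error(confusion_counts(c("m", "b"), "m", positive = "m"),
               "same length")
  expect_error(confusion_counts(c("a", "b"), c("c", "a"), positive = "a"),
               "two-value")
  expect_error(confusion_counts(c("m", "b"), c("m", "b"), positive = "x"),
               "does not occur")
})

test_that("criterion vector evaluates the metric formulas", {
  perfect <- criterion_vector(
    confusion_counts(rep(c("m", "b"), each = 4),
                     rep(c("m", "b"), each = 4), "m"))
  for (nm in c("acc", "pre", "sen", "f1", "spe", "mcc")) {
    expect_equal(unname(perfect[nm]), 1)
  }
  for (nm in c("err", "fpr", "fnr")) {
    expect_equal(unname(perfect[nm]), 0)
  }

  # total disagreement: all four marginals nonzero, so mcc = -1 exactly
  inverted <- criterion_vector(
    confusion_counts(c("m", "m", "m", "b", "b"),
                     c("b", "b", "b", "m", "m"), "m"))
  expect_equal(unname(inverted["acc"]), 0)
  expect_equal(unname(inverted["mcc"]), -1)

  # hand-derived: (3*4 - 1*2) / sqrt(4*5*5*6) = 10 / sqrt(600)
  cc <- structure(list(tp = 3L, tn = 4L, fp = 1L, fn = 2L),
                  class = "confusion_counts")
  expect_equal(unname(criterion_vector(cc)["mcc"]), 10 / sqrt(600))
  expect_error(criterion_vector(
    structure(list(tp = 0L, tn = 0L, fp = 0L, fn = 0L),
              class = "confusion_counts")), "all zero")
})

test_that("degenerate denominators follow the documented conventions", {
  # never predicts positive: pre = 0, f1 = 0, zero marginal tp+fp -> mcc = 0
  cc <- confusion_counts(c("m", "m", "b"), c("b", "b", "b"), "m")
  v <- criterion_vector(cc)
  expect_equal(unname(v[c("pre", "f1", "mcc")]), c(0, 0, 0))

  # constant truth: tn + fp marginal is zero -> mcc = 0
  cc <- confusion_counts(c("m", "m"), c("m", "b"), "m")
  expect_equal(unname(criterion_vector(cc)["mcc"]), 0)
})

test_that("metrics match the independent oracle on 200 random vectors", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    y <- random_labels(n)
    p <- random_labels(n)
    if (length(unique(c(y, p))) < 2) next
    got <- criterion_vector(confusion_counts(y, p, "pos"))
    want <- oracle_metrics(y, p, "pos")
    expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-12)
  }
})

test_that("complement identities hold to machine precision", {
  set.seed(7)
  for (i in 1:50) {
    y <- random_labels(30); p <- random_labels(30)
    v <- criterion_vector(confusion_counts(y, p, "pos"))
    expect_equal(unname(v["acc"] + v["err"]), 1)
    expect_equal(unname(v["sen"] + v["fnr"]), 1)
    expect_equal(unname(v["spe"] + v["fpr"]), 1)
    expect_true(v["mcc"] >= -1 && v["mcc"] <= 1)
    expect_equal(unname(v["f1"]),
                 if (v["pre"] + v["sen"] == 0) 0 else
                   unname(2 * v["pre"] * v["sen"] / (v["pre"] + v["sen"])))
  }
})

test_that("fold aggregation gives the arithmetic mean and n-1 sd", {
  acc <- c(81.82, 94.44, 96.97, 98.99, 99.49)
  folds <- lapply(acc, function(a)
    structure(c(acc = a), class = "criterion_vector"))
  s <- aggregate_folds(folds)
  expect_equal(round(unname(s$mean["acc"]), 2), 94.34)
  expect_equal(round(unname(s$sd["acc"]), 2), 7.28)
  expect_equal(s$n_folds, 5L)

  same <- aggregate_folds(lapply(1:5, function(i)
    structure(c(acc = 0.9), class = "criterion_vector")))
  expect_equal(unname(same$sd["acc"]), 0)

  alex <- aggregate_folds(matrix(c(78.28, 89.9, 86.87, 90.4, 89.9),
                                 ncol = 1, dimnames = list(NULL, "acc")))
  expect_equal(round(unname(alex$mean["acc"]), 2), 87.07)

  expect_error(aggregate_folds(list()), "no folds")
  expect_error(aggregate_folds(list(
    structure(c(acc = 1), class = "criterion_vector"),
    structure(c(sen = 1), class = "criterion_vector")
  )), "different criterion sets")
})

test_that("single-fold aggregation reports the mean with an NA sd", {
  s <- aggregate_folds(list(
    structure(c(acc = 0.9, sen = 0.8), class = "criterion_vector")))
  expect_equal(unname(s$mean), c(0.9, 0.8))
  expect_true(all(is.na(s$sd)))
})

test_that("fold_metrics computes per-fold criteria from a prediction table", {
  preds <- rbind(
    data.frame(alternative = "A", fold = 1,
               y_true = c("m", "m", "b", "b"),
               y_pred = c("m", "m", "b", "b")),
    data.frame(alternative = "A", fold = 2,
               y_true = c("m", "m", "b", "b"),
               y_pred = c("m", "b", "b", "m")),
    data.frame(alternative = "B", fold = 1,
               y_true = c("m", "m", "b", "b"),
               y_pred = c("b", "b", "m", "m"))
  )
  fm <- fold_metrics(preds, positive = "m", n_params = c(A = 10, B = 2))
  expect_equal(sort(names(fm$summaries)), c("A", "B"))
  a1 <- fm$per_fold[fm$per_fold$alternative == "A" & fm$per_fold$fold == 1, ]
  expect_equal(a1$acc, 1)
  a2 <- fm$per_fold[fm$per_fold$alternative == "A" & fm$per_fold$fold == 2, ]
  expect_equal(a2$acc, 0.5)
  expect_equal(unname(fm$summaries$A$mean["acc"]), 0.75)
  expect_equal(unname(fm$summaries$A$mean["n_params"]), 10)

  expect_error(fold_metrics(preds[, -2], "m"), "lacks column")
  expect_error(fold_metrics(preds, "m", n_params = c(A = 10)), "missing for")
})

test_that("summary_table renders percent-scale mean/sd pairs", {
  preds <- data.frame(alternative = "A", fold = rep(1:2, each = 4),
                      y_true = rep(c("m", "m", "b", "b"), 2),
                      y_pred = rep(c("m", "m", "b", "b"), 2))
  fm <- fold_metrics(preds, "m", n_params = c(A = 5))
  tab <- summary_table(fm$summaries)
  expect_equal(tab$mean_acc, 100)
  expect_equal(tab$mean_n_params, 5)  # millions, not percent
  expect_equal(tab$sd_acc, 0)
})
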