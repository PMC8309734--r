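# Brute-force scoring oracle used to cross-check the metric formulas.
oracle_metrics <- function(truth, pred, positive = "1") {
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fn <- sum(truth == positive & pred != positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(accuracy = mean(truth == pred), precision = prec, recall = rec, f1 = f1)
}

test_that("binary task construction filters, codes and balances per subject", {
  seg <- tiny_clean_segments()
  task <- make_binary_task(seg, "B", "P4")
  expect_setequal(unique(seg$info$temp_label[task$idx]), c("B", "P4"))
  expect_equal(levels(task$labels), c("0", "1"))
  # per-subject balance: 8 baselines against the 8 P4 stimuli
  tab <- table(task$subjects, task$labels)
  expect_true(all(tab == 8L))

  raw <- make_binary_task(seg, "B", "P4", balance = FALSE)
  expect_equal(sum(raw$labels == "0"), 120L)
  expect_equal(sum(raw$labels == "1"), 24L)

  cv <- make_binary_task(seg, "C0", "C4", "covas")
  expect_true(all(seg$info$covas_label[cv$idx] %in% c("C0", "C4")))

  expect_error(make_binary_task(seg, "B", "P9"), "not present")
})

test_that("metric formulas match their definitions including degenerate denominators", {
  m <- classification_metrics(list(tp = 3, fp = 1, tn = 2, fn = 2))
  expect_equal(unname(m["accuracy"]), 0.625)
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.6)
  expect_equal(unname(m["f1"]), 2 * 0.75 * 0.6 / 1.35)

  perfect <- classification_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unname(perfect), rep(1, 4))

  degen <- classification_metrics(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(unname(degen[c("precision", "recall", "f1")]), c(0, 0, 0))

  expect_error(classification_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "no samples")
  expect_equal(macro_f1(c(0.8, 0.4)), 0.6)
  expect_equal(macro_f1(0.7), 0.7)
  expect_error(macro_f1(numeric(0)), "F1")
})

test_that("metrics agree with a brute-force confusion recomputation on random predictions", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    truth <- as.character(rbinom(n, 1, runif(1, 0.1, 0.9)))
    pred <- as.character(rbinom(n, 1, runif(1)))
    m <- classification_metrics(confusion_counts(truth, pred))
    expect_equal(m, oracle_metrics(truth, pred))
    o0 <- oracle_metrics(truth, pred, positive = "0")
    expect_equal(binary_macro_f1(truth, pred),
                 mean(c(o0["f1"], oracle_metrics(truth, pred)["f1"])))
  }
})

test_that("LOSO folds are subject-disjoint and score by held-out subject", {
  set.seed(12)
  n_subj <- 6; per <- 10
  subj <- rep(sprintf("S%d", seq_len(n_subj)), each = per)
  y <- rep(rep(c("0", "1"), per / 2), n_subj)
  X <- matrix(rnorm(length(y) * 4), ncol = 4)
  X[, 1] <- X[, 1] + 3 * (y == "1")
  res <- loso_evaluate(X, y, subj, n_runs = 1, base_seed = 2)
  expect_equal(nrow(res$per_cell), n_subj)
  expect_setequal(res$per_cell$subject, unique(subj))
  expect_gt(res$aggregate$accuracy[["mean"]], 0.9)

  res5 <- loso_evaluate(X, y, subj, n_runs = 5, base_seed = 2)
  expect_equal(nrow(res5$per_cell), 5L * n_subj)
  expect_true(all(table(res5$per_cell$subject) == 5L))
  expect_true(all(res5$aggregate$accuracy >= 0 & res5$aggregate$accuracy <= 1))

  expect_error(loso_evaluate(X, y, rep("A", length(y))), "2 subjects")
})

test_that("shuffled labels drive LOSO accuracy to chance", {
  set.seed(13)
  n_subj <- 10; per <- 16
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = per)
  y <- rep(rep(c("0", "1"), per / 2), n_subj)
  X <- matrix(rnorm(length(y) * 6), ncol = 6)
  X[, 1] <- X[, 1] + 2 * (y == "1")
  null_acc <- vapply(1:3, function(i) {
    ysh <- sample(y)
    loso_evaluate(X, ysh, subj, n_runs = 1,
                  base_seed = 3 + i)$aggregate$accuracy[["mean"]]
  }, numeric(1))
  expect_gt(mean(null_acc), 0.4)
  expect_lt(mean(null_acc), 0.6)
})

test_that("the paired method test matches the closed-form t statistic", {
  tt <- paired_method_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$direction, 1)
  ref <- t.test(c(2, 3, 4), c(1, 1, 1), paired = TRUE)
  expect_equal(tt$p_value, ref$p.value)

  same <- paired_method_test(c(0.5, 0.6), c(0.5, 0.6))
  expect_false(same$significant)
  expect_equal(same$p_value, 1)

  const <- paired_method_test(c(0.7, 0.8), c(0.6, 0.7))
  expect_true(const$significant)
  expect_equal(const$p_value, 0)

  a <- c(0.9, 0.7, 0.85, 0.6); b <- c(0.8, 0.75, 0.7, 0.65)
  ab <- paired_method_test(a, b); ba <- paired_method_test(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$direction, -ba$direction)

  expect_error(paired_method_test(1:3, 1:4), "equal length")
})

test_that("subject accuracies aggregate per subject across runs", {
  pc <- data.frame(run = rep(1:2, each = 2), subject = rep(c("A", "B"), 2),
                   n_test = 4, accuracy = c(0.5, 1, 0.7, 0.8),
                   macro_f1 = 0.5)
  res <- structure(list(per_cell = pc), class = "pain_loso")
  expect_equal(subject_accuracies(res), c(A = 0.6, B = 0.9))
})

test_that("subjective rating labels classify at least as well as temperature labels", {
  seg <- tiny_clean_segments()
  X <- extract_features(seg, "hcf")
  f1_of <- function(baseline, pain, source) {
    task <- make_binary_task(seg, baseline, pain, source)
    loso_evaluate(X[task$idx, , drop = FALSE], task$labels, task$subjects,
                  n_runs = 1, base_seed = 6)$aggregate$macro_f1[["mean"]]
  }
  expect_gte(f1_of("C0", "C4", "covas"), f1_of("B", "P4", "temperature"))
})
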