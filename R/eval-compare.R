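# Fixed classification and evaluation stage: binary task construction,
# random forest on any feature matrix, repeated leave-one-subject-out
# cross-validation, accuracy / macro-F1, paired significance testing.

subset_segments <- function(segments, idx) {
  segments$data <- segments$data[idx]
  segments$info <- segments$info[idx, , drop = FALSE]
  segments$covas <- NULL
  segments
}

#' Build a binary no-pain vs pain task
#'
#' Keeps only the segments of the two named levels, coding the baseline
#' level as class 0 and the pain level as class 1. Labels are taken either
#' from the objective stimulus temperature (`temp_label`) or the
#' subjective CoVAS classes (`covas_label`).
#'
#' @param segments A `pain_segments` object (pooled over subjects).
#' @param baseline,pain Level codes, e.g. `"B"` and `"P4"`, or `"C0"` and
#'   `"C4"` with `label_source = "covas"`.
#' @param label_source `"temperature"` or `"covas"`.
#' @param balance Balance the two classes within every subject by
#'   subsampling the majority class to the minority count (default
#'   `TRUE`). The continuous-protocol segmentation yields one baseline
#'   window per stimulus, so the baseline class would otherwise dominate
#'   5:1 and a majority vote alone would score far above 50%; the
#'   published per-task accuracies (chance-level no-pain vs non-painful
#'   discrimination in particular) presuppose balanced classes.
#' @param balance_seed Seed for the subsampling draws.
#' @return A list of class `pain_task`: `segments`, `labels` (factor with
#'   levels `"0"`, `"1"`), `subjects`, `idx` (row indices into the input
#'   segments), and the task definition.
#' @export
make_binary_task <- function(segments, baseline, pain,
                             label_source = c("temperature", "covas"),
                             balance = TRUE, balance_seed = 1L) {
  stopifnot(inherits(segments, "pain_segments"))
  label_source <- match.arg(label_source)
  lab <- if (label_source == "temperature") segments$info$temp_label
         else segments$info$covas_label
  if (label_source == "covas" && all(is.na(lab)))
    stop_invalid("segments carry no CoVAS labels")
  for (lv in c(baseline, pain))
    if (!lv %in% lab)
      stop_invalid(sprintf("level '%s' not present in the data", lv))
  keep <- which(lab %in% c(baseline, pain))
  if (balance) {
    subj <- segments$info$subject_id[keep]
    kept <- with_seed(balance_seed, {
      unlist(lapply(split(keep, subj), function(rows) {
        by_class <- split(rows, lab[rows])
        n_min <- min(lengths(by_class))
        if (n_min == 0L) return(rows)
        unlist(lapply(by_class, function(r)
          if (length(r) > n_min) sort(sample(r, n_min)) else r))
      }), use.names = FALSE)
    })
    keep <- sort(kept)
  }
  structure(list(
    segments = subset_segments(segments, keep),
    labels = factor(as.integer(lab[keep] == pain), levels = c("0", "1")),
    subjects = segments$info$subject_id[keep], idx = keep,
    baseline = baseline, pain = pain, label_source = label_source
  ), class = "pain_task")
}

#' Confusion counts and binary classification metrics
#'
#' `confusion_counts` tallies true/false positives/negatives of predicted
#' against true binary labels. `classification_metrics` computes accuracy
#' `(tp + tn) / total`, precision `tp / (tp + fp)`, recall
#' `tp / (tp + fn)` and the F1 score (harmonic mean of precision and
#' recall); any metric with a zero denominator is 0.
#'
#' @param truth,pred Binary label vectors.
#' @param positive The level counted as positive.
#' @param counts A list or vector with elements `tp`, `fp`, `tn`, `fn`.
#' @return `confusion_counts`: list with `tp`, `fp`, `tn`, `fn`;
#'   `classification_metrics`: named vector `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
confusion_counts <- function(truth, pred, positive = "1") {
  stopifnot(length(truth) == length(pred))
  tpos <- truth == positive; ppos <- pred == positive
  list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
       tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos))
}

#' @rdname confusion_counts
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop_invalid("no samples to score")
  safe <- function(num, den) if (den > 0) num / den else 0
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  c(accuracy = (tp + tn) / total, precision = precision, recall = recall,
    f1 = safe(2 * precision * recall, precision + recall))
}

#' Macro-averaged F1 score
#'
#' `macro_f1` averages per-class F1 values. `binary_macro_f1` computes it
#' from raw labels of a two-class problem, scoring each class one-vs-rest.
#'
#' @param f1_values Numeric vector of per-class F1 scores.
#' @param truth,pred Binary label vectors.
#' @return A single number in `[0, 1]`.
#' @export
macro_f1 <- function(f1_values) {
  if (!length(f1_values)) stop_invalid("no per-class F1 values supplied")
  mean(f1_values)
}

#' @rdname macro_f1
#' @param classes The class set to average over; both classes of the
#'   binary task by default, so a class absent from a held-out subject
#'   contributes an F1 of 0.
#' @export
binary_macro_f1 <- function(truth, pred, classes = c("0", "1")) {
  macro_f1(vapply(classes, function(cl)
    classification_metrics(confusion_counts(truth, pred, positive = cl))[["f1"]],
    numeric(1)))
}

#' Repeated leave-one-subject-out evaluation with a random forest
#'
#' For each of `n_runs` repetitions and each subject, fits a
#' `rf_trees`-tree random forest on all other subjects' rows and scores
#' the held-out subject's rows with accuracy and macro-F1. Feature
#' extractors that require training (`extractor` given) are fitted inside
#' each fold on training subjects only. Aggregates are the mean over
#' subjects per run, averaged over runs, with the spread reported as the
#' per-run standard deviation over subjects averaged over runs.
#'
#' @param features Numeric feature matrix (rows = samples); omit when an
#'   `extractor` is supplied.
#' @param labels Two-class label vector.
#' @param subjects Subject identifier per row.
#' @param segments `pain_segments` matching `labels` (required with
#'   `extractor`). A `pain_task` may be given instead of
#'   `features`/`labels`/`subjects`.
#' @param extractor Optional [feature_extractor()] or registry name,
#'   refitted per fold.
#' @param n_runs Number of repetitions (default 5).
#' @param rf_trees Trees per forest (default 100).
#' @param base_seed Seed; run `r` uses `base_seed + r` for the forests and
#'   derived per-fold seeds for extractor training.
#' @return Object of class `pain_loso` with `per_cell` (one row per run x
#'   subject) and `aggregate` (mean and spread of accuracy and macro-F1,
#'   proportions in `[0, 1]`).
#' @export
loso_evaluate <- function(features = NULL, labels = NULL, subjects = NULL,
                          segments = NULL, extractor = NULL, n_runs = 5L,
                          rf_trees = 100L, base_seed = 1L) {
  if (inherits(features, "pain_task")) {
    task <- features
    segments <- task$segments; labels <- task$labels
    subjects <- task$subjects; features <- NULL
  }
  if (!is.null(extractor)) {
    extractor <- get_feature_extractor(extractor)
    if (is.null(segments)) stop_invalid("extractor-based evaluation needs segments")
    if (extractor$kind != "learned") {
      # stateless: compute once, no leakage possible
      features <- extractor$fit(segments, labels, base_seed)(segments)
      extractor <- NULL
    }
  }
  labels <- factor(labels)
  subj <- as.character(subjects)
  ids <- unique(subj)
  if (length(ids) < 2L) stop_invalid("LOSO needs at least 2 subjects")
  if (nlevels(labels) != 2L) stop_invalid("labels must contain two classes")

  cells <- list()
  for (r in seq_len(n_runs)) {
    run_seed <- base_seed + r
    for (fi in seq_along(ids)) {
      s <- ids[fi]
      te <- subj == s; tr <- !te
      stopifnot(!any(subj[tr] %in% subj[te]))   # LOSO hygiene
      if (!is.null(extractor)) {
        fit_seed <- (run_seed * 1000L + fi) %% .Machine$integer.max
        fe <- extractor$fit(subset_segments(segments, which(tr)),
                            labels[tr], fit_seed)
        xtr <- fe(subset_segments(segments, which(tr)))
        xte <- fe(subset_segments(segments, which(te)))
      } else {
        xtr <- features[tr, , drop = FALSE]
        xte <- features[te, , drop = FALSE]
      }
      pred <- with_seed(run_seed, {
        rf <- randomForest::randomForest(x = xtr, y = droplevels(labels[tr]),
                                         ntree = rf_trees)
        predict(rf, xte)
      })
      truth <- as.character(labels[te]); pred <- as.character(pred)
      acc <- mean(truth == pred)
      cells[[length(cells) + 1L]] <- data.frame(
        run = r, subject = s, n_test = sum(te), accuracy = acc,
        macro_f1 = binary_macro_f1(truth, pred), stringsAsFactors = FALSE)
    }
  }
  per_cell <- do.call(rbind, cells)
  agg <- function(metric) {
    by_run <- split(per_cell[[metric]], per_cell$run)
    c(mean = mean(vapply(by_run, mean, numeric(1))),
      sd = mean(vapply(by_run, stats::sd, numeric(1))))
  }
  structure(list(per_cell = per_cell, n_runs = n_runs, rf_trees = rf_trees,
                 base_seed = base_seed, n_subjects = length(ids),
                 aggregate = list(accuracy = agg("accuracy"),
                                  macro_f1 = agg("macro_f1"))),
            class = "pain_loso")
}

#' @export
print.pain_loso <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<pain_loso> %d subjects x %d run(s), %d-tree random forest\n",
              x$n_subjects, x$n_runs, x$rf_trees))
  cat(sprintf("  accuracy: %.2f%% +/- %.2f   macro-F1: %.2f%% +/- %.2f\n",
              100 * a$accuracy["mean"], 100 * a$accuracy["sd"],
              100 * a$macro_f1["mean"], 100 * a$macro_f1["sd"]))
  invisible(x)
}

#' @export
summary.pain_loso <- function(object, ...) {
  by_subj <- aggregate(cbind(accuracy, macro_f1) ~ subject,
                       data = object$per_cell, FUN = mean)
  cat(sprintf("Leave-one-subject-out results (%d runs, per-subject means):\n",
              object$n_runs))
  print(by_subj, row.names = FALSE)
  print(object)
  invisible(by_subj)
}

#' Per-subject accuracies averaged over runs
#'
#' Subject-aligned vector suitable for [paired_method_test()].
#'
#' @param result A `pain_loso` object.
#' @return Named numeric vector, ordered by subject id.
#' @export
subject_accuracies <- function(result) {
  stopifnot(inherits(result, "pain_loso"))
  m <- tapply(result$per_cell$accuracy, result$per_cell$subject, mean)
  stats::setNames(as.vector(m), dimnames(m)[[1]])[order(dimnames(m)[[1]])]
}

#' Paired comparison of two methods' per-subject accuracies
#'
#' Two-sided paired t-test on the subject-aligned differences, reporting
#' the direction of the mean difference. Zero-variance differences are
#' handled explicitly: all-zero differences are not significant; constant
#' nonzero differences are reported as significant with p = 0.
#'
#' @param acc_a,acc_b Equal-length, subject-aligned accuracy vectors.
#' @param alpha Significance level (default 0.05).
#' @return List of class `pain_method_test` with `statistic`, `p_value`,
#'   `df`, `mean_diff`, `direction` (sign of mean difference) and
#'   `significant`.
#' @export
paired_method_test <- function(acc_a, acc_b, alpha = 0.05) {
  if (length(acc_a) != length(acc_b))
    stop_invalid("accuracy vectors must be subject-aligned and equal length")
  if (length(acc_a) < 2L) stop_invalid("need at least 2 subjects")
  d <- acc_a - acc_b
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    res <- if (mean(d) == 0)
      list(statistic = 0, p_value = 1, significant = FALSE)
    else
      list(statistic = sign(mean(d)) * Inf, p_value = 0, significant = TRUE)
    res$df <- length(d) - 1L
  } else {
    tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                significant = tt$p.value < alpha,
                df = unname(tt$parameter))
  }
  res$mean_diff <- mean(d)
  res$direction <- sign(mean(d))
  structure(res, class = "pain_method_test")
}

#' @export
print.pain_method_test <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.3f (df %d), p = %.4g, mean diff %+.4f%s\n",
              x$statistic, x$df, x$p_value, x$mean_diff,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}
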