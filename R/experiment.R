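# End-to-end experiment orchestration: simulate -> segment -> extract ->
# evaluate -> compare, from one declarative configuration.

parse_task <- function(task) {
  if (is.list(task)) return(task)
  parts <- strsplit(task, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop_invalid("tasks must look like 'B_vs_P4'")
  baseline <- toupper(parts[1]); pain <- toupper(parts[2])
  list(label_source = if (startsWith(baseline, "C")) "covas" else "temperature",
       baseline = baseline, pain = pain)
}

#' Experiment configuration
#'
#' Collects every knob of a full comparison run. Defaults reproduce the
#' evaluation protocol: 256 Hz common rate, 5 LOSO repetitions, 100-tree
#' random forests, 50-epoch network training with batch size 8 and
#' learning rate 1e-4.
#'
#' @param scheme `"pmdb"` or `"bvdb"`.
#' @param n_subjects Number of simulated subjects.
#' @param repetitions Stimuli per level (`NULL` = scheme default).
#' @param fs Acquisition sampling rate in Hz.
#' @param methods Feature extractors to compare (registry names).
#' @param tasks Character tasks like `"B_vs_P4"` or `"C0_vs_C4"` (CoVAS
#'   classes select the subjective label source automatically).
#' @param n_runs LOSO repetitions.
#' @param rf_trees Trees per random forest.
#' @param epochs,batch_size,learning_rate Network training settings.
#' @param preset Simulator effect-size preset, see [profile_preset()].
#' @param seed Master seed for simulation and evaluation.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(scheme = "pmdb", n_subjects = 12L,
                              repetitions = NULL, fs = 256,
                              methods = "hcf", tasks = "B_vs_P4",
                              n_runs = 5L, rf_trees = 100L, epochs = 50L,
                              batch_size = 8L, learning_rate = 1e-4,
                              preset = "default", seed = 1L) {
  for (m in methods) get_feature_extractor(m)   # fail fast on unknown methods
  cfg <- list(scheme = match_scheme(scheme), n_subjects = as.integer(n_subjects),
              repetitions = repetitions, fs = fs, methods = methods,
              tasks = lapply(tasks, parse_task), n_runs = as.integer(n_runs),
              rf_trees = as.integer(rf_trees), epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, preset = preset,
              seed = as.integer(seed))
  for (tk in cfg$tasks)
    if (tk$label_source == "covas" && cfg$scheme != "pmdb")
      stop_invalid("CoVAS tasks require the pmdb scheme")
  structure(cfg, class = "experiment_config")
}

experiment_method <- function(cfg, method) {
  ex <- get_feature_extractor(method)
  if (ex$kind == "learned")
    deep_extractor(ex$name, epochs = cfg$epochs, batch_size = cfg$batch_size,
                   learning_rate = cfg$learning_rate)
  else ex
}

#' Run a full feature-extraction comparison experiment
#'
#' Simulates the dataset, segments and labels it, then evaluates every
#' configured feature extractor on every task with repeated
#' leave-one-subject-out random-forest classification. When `out_dir` is
#' given, writes the dataset manifest, per-task/method tidy results, an
#' aggregated table and a run log capturing every seed and parameter.
#' Failure of one method is logged and does not abort the others.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `pain_experiment`: `config`, `results` (nested
#'   `results[[task]][[method]]`, each a `pain_loso` or a failure record)
#'   and `table` (aggregated data.frame).
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  dataset <- generate_dataset(cfg$n_subjects, cfg$scheme, cfg$repetitions,
                              cfg$fs, master_seed = cfg$seed,
                              preset = cfg$preset)
  segments <- segment_dataset(dataset)
  results <- list()
  for (tk in cfg$tasks) {
    task_id <- paste0(tk$baseline, "_vs_", tk$pain)
    task <- make_binary_task(segments, tk$baseline, tk$pain, tk$label_source)
    results[[task_id]] <- list()
    for (m in cfg$methods) {
      res <- tryCatch(
        loso_evaluate(task, extractor = experiment_method(cfg, m),
                      n_runs = cfg$n_runs, rf_trees = cfg$rf_trees,
                      base_seed = cfg$seed),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "pain_loso_failure"))
      results[[task_id]][[m]] <- res
    }
  }
  tab <- comparison_table(results)
  out <- structure(list(config = cfg, results = results, table = tab),
                   class = "pain_experiment")
  if (!is.null(out_dir)) write_experiment(out, dataset, segments, out_dir)
  out
}

#' Aggregate experiment results into a comparison table
#'
#' One row per task and method with mean and spread of accuracy and
#' macro-F1 (reported as percentages).
#'
#' @param results Nested list `results[[task]][[method]]` of `pain_loso`
#'   objects (as in a `pain_experiment`).
#' @return A data.frame.
#' @export
comparison_table <- function(results) {
  rows <- list()
  for (task_id in names(results)) for (m in names(results[[task_id]])) {
    r <- results[[task_id]][[m]]
    rows[[length(rows) + 1L]] <- if (inherits(r, "pain_loso")) data.frame(
      task = task_id, method = m,
      accuracy = 100 * r$aggregate$accuracy[["mean"]],
      accuracy_sd = 100 * r$aggregate$accuracy[["sd"]],
      macro_f1 = 100 * r$aggregate$macro_f1[["mean"]],
      macro_f1_sd = 100 * r$aggregate$macro_f1[["sd"]],
      status = "ok", stringsAsFactors = FALSE)
    else data.frame(task = task_id, method = m, accuracy = NA_real_,
                    accuracy_sd = NA_real_, macro_f1 = NA_real_,
                    macro_f1_sd = NA_real_, status = "failed",
                    stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pairwise method comparison on one task
#'
#' Paired t-tests on per-subject accuracies (averaged over runs) for every
#' pair of successfully evaluated methods.
#'
#' @param task_results Named list of `pain_loso` objects for one task.
#' @param alpha Significance level.
#' @return Data.frame with one row per ordered method pair.
#' @export
compare_methods <- function(task_results, alpha = 0.05) {
  ok <- Filter(function(r) inherits(r, "pain_loso"), task_results)
  ms <- names(ok)
  rows <- list()
  for (i in seq_along(ms)) for (j in seq_along(ms)) {
    if (i >= j) next
    tt <- paired_method_test(subject_accuracies(ok[[ms[i]]]),
                             subject_accuracies(ok[[ms[j]]]), alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      method_a = ms[i], method_b = ms[j], t = tt$statistic,
      p_value = tt$p_value, mean_diff = tt$mean_diff,
      significant = tt$significant, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

write_experiment <- function(exp, dataset, segments, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- exp$config
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(cfg_plain, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  js <- utf8ToInt(as.character(jsonlite::toJSON(cfg_plain, auto_unbox = TRUE)))
  cfg_hash <- sum(js * seq_along(js)) %% .Machine$integer.max
  utils::write.csv(segments$info, file.path(out_dir, "segment_index.csv"),
                   row.names = FALSE)
  cells <- list()
  for (task_id in names(exp$results))
    for (m in names(exp$results[[task_id]])) {
      r <- exp$results[[task_id]][[m]]
      if (inherits(r, "pain_loso")) {
        pc <- r$per_cell
        pc$task <- task_id; pc$method <- m
        cells[[length(cells) + 1L]] <- pc
      }
    }
  if (length(cells))
    utils::write.csv(do.call(rbind, cells),
                     file.path(out_dir, "results_per_subject.csv"),
                     row.names = FALSE)
  utils::write.csv(cbind(exp$table, config_hash = cfg_hash),
                   file.path(out_dir, "results_aggregate.csv"),
                   row.names = FALSE)
  log <- c(sprintf("config hash: %d", cfg_hash),
           sprintf("master seed: %d", cfg$seed),
           sprintf("scheme: %s, subjects: %d, fs: %g Hz, preset: %s",
                   cfg$scheme, cfg$n_subjects, cfg$fs, cfg$preset),
           sprintf("runs: %d, trees: %d, epochs: %d, batch: %d, lr: %g",
                   cfg$n_runs, cfg$rf_trees, cfg$epochs, cfg$batch_size,
                   cfg$learning_rate),
           sprintf("methods: %s", paste(cfg$methods, collapse = ", ")),
           sprintf("tasks: %s", paste(names(exp$results), collapse = ", ")),
           vapply(seq_len(nrow(exp$table)), function(i)
             sprintf("%s / %s: %s", exp$table$task[i], exp$table$method[i],
                     exp$table$status[i]), ""))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.pain_experiment <- function(x, ...) {
  cat(sprintf("<pain_experiment> scheme %s, %d subjects, seed %d\n",
              x$config$scheme, x$config$n_subjects, x$config$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}
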