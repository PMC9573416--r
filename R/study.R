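# End-to-end orchestration: simulate -> window -> thresholds -> train ->
# evaluate, per group.

#' Study configuration
#'
#' @param groups named integer vector of subject counts per group (default
#'   `c(A = 9, PP = 8, P = 6)`).
#' @param simulator a [simulator_config()].
#' @param tcn a [tcn_config()].
#' @param train a [train_config()].
#' @param seed master integer seed; all subject-level seeds derive from it.
#' @param output_dir directory for per-group artifacts (`NULL` disables
#'   writing).
#' @param split_mode `"sample"` or `"subject"` (see [split_data()]).
#' @param normalize z-score signals on the training split (default TRUE).
#' @param targets model targets to fit (`"ee"`, optionally also `"vo2"`).
#' @return a `study_config` list.
#' @export
study_config <- function(groups = c(A = 9L, PP = 8L, P = 6L),
                         simulator = simulator_config(),
                         tcn = tcn_config(),
                         train = train_config(),
                         seed = 1L,
                         output_dir = NULL,
                         split_mode = "sample",
                         normalize = TRUE,
                         targets = "ee") {
  if (is.null(names(groups)) || !all(names(groups) %in% c("A", "PP", "P")))
    stop("groups must be a named vector with names among A, PP, P",
         call. = FALSE)
  if (any(groups < 1)) stop("subject counts must be at least 1", call. = FALSE)
  validate_simulator_config(simulator)
  stopifnot(inherits(tcn, "tcn_config"), inherits(train, "train_config"),
            all(targets %in% c("ee", "vo2")))
  structure(list(groups = groups, simulator = simulator, tcn = tcn,
                 train = train, seed = seed, output_dir = output_dir,
                 split_mode = split_mode, normalize = normalize,
                 targets = targets),
            class = "study_config")
}

#' Simulate one subject end to end
#'
#' Profile, protocol, gas exchange, RMP trace, windowing, target alignment
#' and intensity labeling (via detected ventilatory thresholds) for a
#' single synthetic subject.
#'
#' @param group group label (`"A"`, `"PP"`, `"P"`).
#' @param seed integer seed for this subject.
#' @param config a [simulator_config()].
#' @param posture `"sitting"` or `"standing"`.
#' @param window_s,overlap segmentation parameters (see
#'   [segment_windows()]).
#' @return a labeled `window_set`; the profile, phases, breaths, trace and
#'   partition ride along as attributes `profile`, `phases`, `breaths`,
#'   `trace`, `partition`.
#' @export
simulate_subject_windows <- function(group, seed,
                                     config = simulator_config(),
                                     posture = "sitting",
                                     window_s = 5, overlap = 0.8) {
  prof <- simulate_subject(group, seed = seed)
  phases <- simulate_protocol(prof, posture, config, seed = seed + 1L)
  breaths <- simulate_gas_exchange(prof, phases, config, seed = seed + 2L)
  trace <- simulate_rmp(breaths, prof, config, seed = seed + 3L)
  ws <- segment_windows(trace, window_s, overlap, subject_id = prof$id)
  ws <- align_targets(ws, breaths, prof$body_mass)
  eq <- compute_equivalents(breaths)
  part <- detect_thresholds(eq, phases)
  ws <- label_windows(ws, part, phases)
  attr(ws, "profile") <- prof
  attr(ws, "phases") <- phases
  attr(ws, "breaths") <- breaths
  attr(ws, "partition") <- part
  ws
}

#' Run the full synthetic study
#'
#' For every group: simulates the configured number of subjects (alternating
#' sitting/standing postures), pools their labeled windows, splits
#' train/validation/test, normalizes signals on the training split, trains
#' one TCN per target, predicts the test split and computes the evaluation
#' report. Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return a `study_report`: per-group list with `samples` (split
#'   bookkeeping), `eval` (an `eval_report` per target) and `summary`, plus
#'   a study-level `summary` table (per-group n, R2 and RMSE per target)
#'   and `total_samples`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  groups <- names(config$groups)
  group_reports <- list()
  summary_rows <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("study stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n_subj <- config$groups[[g]]
    sets <- stage(paste0("simulate:", g), lapply(seq_len(n_subj), function(i) {
      simulate_subject_windows(
        g, seed = config$seed + 1000L * gi + 10L * i,
        config = config$simulator,
        posture = if (i %% 2 == 1) "sitting" else "standing")
    }))
    ws <- bind_windows(sets)
    parts <- stage(paste0("split:", g),
                   split_data(ws, config$train$split,
                              seed = config$seed + gi,
                              mode = config$split_mode))
    if (config$normalize) {
      tr_stats <- normalize_signals(parts$train)
      parts$train <- tr_stats
      parts$valid <- normalize_with(parts$valid, tr_stats$norm_stats)
      parts$test <- normalize_with(parts$test, tr_stats$norm_stats)
    }
    evals <- list()
    for (tgt in config$targets) {
      model <- build_tcn(config$tcn, in_channels = 4L,
                         seed = config$seed + 100L * gi)
      fit <- stage(paste0("train:", g, ":", tgt),
                   train_tcn(model, parts$train, parts$valid,
                             config = config$train, target = tgt))
      pred <- predict_ee(fit, parts$test)
      ref <- parts$test$meta[[target_column(tgt)]]
      evals[[tgt]] <- evaluate_model(pred, ref, labels = parts$test$meta$label)
    }
    samples <- list(total = n_windows(ws),
                    train = n_windows(parts$train),
                    valid = n_windows(parts$valid),
                    test = n_windows(parts$test))
    group_reports[[g]] <- list(group = g, n_subjects = n_subj,
                               samples = samples, eval = evals)
    row <- data.frame(group = g, subjects = n_subj, samples = samples$total,
                      valid = samples$valid,
                      train_plus_test = samples$train + samples$test,
                      stringsAsFactors = FALSE)
    for (tgt in config$targets) {
      row[[paste0("r2_", tgt)]] <- evals[[tgt]]$r2
      row[[paste0("rmse_", tgt)]] <- evals[[tgt]]$rmse
    }
    summary_rows[[g]] <- row
    if (!is.null(config$output_dir))
      write_report(group_reports[[g]],
                   file.path(config$output_dir, paste0("report_", g, ".json")))
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  report <- structure(list(groups = group_reports, summary = summary,
                           total_samples = sum(summary$samples)),
                      class = "study_report")
  if (!is.null(config$output_dir))
    write_report(list(summary = summary, total_samples = report$total_samples),
                 file.path(config$output_dir, "study_summary.json"))
  report
}

normalize_with <- function(ws, stats) {
  for (c in seq_len(dim(ws$signal)[1]))
    ws$signal[c, , ] <- (ws$signal[c, , ] - stats$mean[c]) / stats$sd[c]
  ws$norm_stats <- stats
  ws
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d group(s), %d windows total\n",
              nrow(x$summary), x$total_samples))
  print(x$summary, digits = 3)
  invisible(x)
}
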