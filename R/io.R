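# CSV and JSON interchange: breath records, distance traces, reports.

BREATH_COLUMNS <- c("t", "duration", "vo2", "vco2", "ve", "ee", "rer")
TRACE_COLUMNS <- c("t", "rc", "ab", "cw", "sp")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
}

# Coerce required columns to numeric; warn (with 1-based data line numbers)
# and drop rows that fail to parse or contain NA.
drop_malformed <- function(df, cols, path) {
  suppress <- function(x) suppressWarnings(as.numeric(x))
  num <- lapply(df[cols], suppress)
  bad <- Reduce(`|`, lapply(num, is.na))
  if (any(bad))
    warning(sprintf("%s: dropping %d malformed row(s) at line(s) %s", path,
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  out <- as.data.frame(num, stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a breath-by-breath calorimetry CSV
#'
#' Expects columns `t`, `duration`, `vo2`, `vco2`, `ve`, `ee`, `rer`;
#' missing columns are an error naming them, malformed rows are dropped
#' with a warning carrying line numbers, an empty file yields an empty
#' record with a warning.
#'
#' @param path CSV path.
#' @return a `breath_samples` data frame.
#' @export
read_breaths_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning(sprintf("%s contains no rows", path))
    df <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(BREATH_COLUMNS)), BREATH_COLUMNS))
    return(structure(df, class = c("breath_samples", "data.frame")))
  }
  check_columns(df, BREATH_COLUMNS, path)
  out <- drop_malformed(df, BREATH_COLUMNS, path)
  structure(out, class = c("breath_samples", "data.frame"))
}

#' Write a breath-by-breath calorimetry CSV
#' @param breaths a `breath_samples` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breaths_csv <- function(breaths, path) {
  stopifnot(inherits(breaths, "data.frame"))
  write.csv(as.data.frame(breaths)[BREATH_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a 15 Hz RMP trace CSV
#'
#' Expects columns `t`, `rc`, `ab`, `cw`, `sp` on a uniform time grid.
#'
#' @param path CSV path.
#' @return an `rmp_trace`.
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning(sprintf("%s contains no rows", path))
    ch <- matrix(numeric(0), 0, 4, dimnames = list(NULL, RMP_CHANNELS))
    return(structure(list(fs = RMP_FS, t0 = 0, t = numeric(0), channels = ch),
                     class = "rmp_trace"))
  }
  check_columns(df, TRACE_COLUMNS, path)
  out <- drop_malformed(df, TRACE_COLUMNS, path)
  fs <- if (nrow(out) > 1) 1 / stats::median(diff(out$t)) else RMP_FS
  ch <- as.matrix(out[RMP_CHANNELS])
  structure(list(fs = round(fs, 6), t0 = out$t[1], t = out$t, channels = ch),
            class = "rmp_trace")
}

#' Write an RMP trace CSV
#' @param trace an `rmp_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "rmp_trace"))
  df <- data.frame(t = trace$t, trace$channels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation or study report as JSON
#'
#' @param report an `eval_report`, `bland_altman` or plain list.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "bland_altman")) x$data <- NULL
    if (is.list(x)) x <- lapply(x, strip)
    x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a study configuration from YAML
#'
#' @param path YAML file with optional keys `groups` (named subject
#'   counts), `simulator`, `tcn`, `train` (argument lists) and `seed`.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  study_config(
    groups = if (!is.null(y$groups)) unlist(y$groups) else c(A = 9L, PP = 8L, P = 6L),
    simulator = do.call(simulator_config, y$simulator %||% list()),
    tcn = do.call(tcn_config, y$tcn %||% list()),
    train = do.call(train_config, y$train %||% list()),
    seed = y$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
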