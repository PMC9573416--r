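# Data splitting, TCN training (Adam on mean squared error), prediction
# and k-fold cross-validation.

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param batch minibatch size (default 1024).
#' @param epochs training epochs (default 80).
#' @param split train/validation/test fractions, summing to 1 (default
#'   0.55 / 0.20 / 0.25).
#' @param folds folds for [cross_validate()] (default 5).
#' @param seed integer seed governing shuffling (and weight initialization
#'   when [train_tcn()] builds the model itself).
#' @param loss loss function; only `"mse"` is available.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, batch = 1024L, epochs = 80L,
                         split = c(train = 0.55, valid = 0.20, test = 0.25),
                         folds = 5L, seed = 1L, loss = "mse") {
  assert_scalar_number(lr, "lr", lo = 1e-8)
  assert_scalar_number(batch, "batch", lo = 1)
  assert_scalar_number(epochs, "epochs", lo = 1)
  stopifnot(length(split) == 3L)
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  if (folds < 2) stop("folds must be at least 2", call. = FALSE)
  loss <- match.arg(loss, "mse")
  structure(list(lr = lr, batch = as.integer(batch),
                 epochs = as.integer(epochs),
                 split = stats::setNames(as.numeric(split),
                                         c("train", "valid", "test")),
                 folds = as.integer(folds), seed = seed, loss = loss),
            class = "train_config")
}

#' Split windows into train / validation / test sets
#'
#' Sample mode assigns individual windows uniformly at random to the three
#' parts (sizes are the rounded fractions, validation and test rounded
#' first), reproducing a window-level split in which overlapping windows
#' can fall on different sides. Subject mode keeps every subject's windows
#' in a single part for leakage-free generalization estimates.
#'
#' @param ws a `window_set`.
#' @param split named or positional train/valid/test fractions.
#' @param seed integer seed; the split is deterministic given the seed.
#' @param mode `"sample"` (default) or `"subject"`.
#' @return a list with `window_set` elements `train`, `valid`, `test`.
#' @export
split_data <- function(ws, split = c(train = 0.55, valid = 0.20, test = 0.25),
                       seed = NULL, mode = c("sample", "subject")) {
  stopifnot(inherits(ws, "window_set"))
  mode <- match.arg(mode)
  if (abs(sum(split) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  n <- n_windows(ws)
  n_va <- round(split[[2]] * n)
  n_te <- round(split[[3]] * n)
  n_tr <- n - n_va - n_te
  if (min(n_tr, n_va, n_te) < 1)
    stop("not enough windows for a non-empty train/valid/test split",
         call. = FALSE)
  if (mode == "sample") {
    perm <- with_local_seed(seed, sample.int(n))
    idx <- list(train = perm[seq_len(n_tr)],
                valid = perm[n_tr + seq_len(n_va)],
                test = perm[n_tr + n_va + seq_len(n_te)])
  } else {
    subj <- unique(ws$meta$subject_id)
    if (length(subj) < 3)
      stop("subject-mode split needs at least 3 subjects", call. = FALSE)
    ord <- with_local_seed(seed, sample(subj))
    counts <- vapply(ord, function(s) sum(ws$meta$subject_id == s), numeric(1))
    cum <- cumsum(counts) / n
    part <- ifelse(cum <= split[[1]], "train",
                   ifelse(cum <= split[[1]] + split[[2]], "valid", "test"))
    # guarantee every part has a subject
    for (p in c("train", "valid", "test"))
      if (!p %in% part) part[which.max(part != p)] <- p
    assign_of <- stats::setNames(part, ord)
    idx <- lapply(c(train = "train", valid = "valid", test = "test"),
                  function(p) which(ws$meta$subject_id %in%
                                      names(assign_of)[assign_of == p]))
  }
  lapply(idx, function(i) ws[sort(i)])
}

# One Adam update on the flattened parameter vector.
adam_step <- function(pvec, gvec, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- b1 * state$m + (1 - b1) * gvec
  state$v <- b2 * state$v + (1 - b2) * gvec^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  state$p <- pvec - lr * mhat / (sqrt(vhat) + eps)
  state
}

target_column <- function(target) {
  switch(match.arg(target, c("ee", "vo2")),
         ee = "target_ee", vo2 = "target_vo2")
}

#' Train the TCN regressor
#'
#' Minimizes mean squared error on standardized targets by minibatch Adam.
#' Targets are standardized with training-set statistics (stored in the
#' result and inverted at prediction time). When a validation set is given
#' the weights from the best-validation-loss epoch are retained; otherwise
#' the final weights are kept. Training aborts with the epoch index if the
#' loss becomes non-finite.
#'
#' @param model a [build_tcn()] model, or `NULL` to build one from
#'   `tcn_config()` defaults with the training seed.
#' @param train_set,valid_set `window_set`s with targets (normalize signals
#'   first with [normalize_signals()]; `valid_set` may be `NULL`).
#' @param config a [train_config()].
#' @param target `"ee"` (kcal/min) or `"vo2"` (mL/min/kg).
#' @param verbose print per-epoch losses.
#' @return a `trained_tcn`: the fitted model plus training history
#'   (`epoch`, `train_loss`, `valid_loss` on the standardized scale),
#'   target statistics, the signal normalization statistics carried from
#'   `train_set`, and the configs.
#' @export
train_tcn <- function(model = NULL, train_set, valid_set = NULL,
                      config = train_config(), target = "ee",
                      verbose = FALSE) {
  stopifnot(inherits(train_set, "window_set"))
  tgt <- target_column(target)
  if (is.null(model))
    model <- build_tcn(tcn_config(), in_channels = dim(train_set$signal)[1],
                       seed = config$seed)
  stopifnot(inherits(model, "tcn_model"))
  T_len <- dim(train_set$signal)[2]
  n <- n_windows(train_set)
  y_raw <- train_set$meta[[tgt]]
  if (anyNA(y_raw)) stop("training targets contain NA; run align_targets()",
                         call. = FALSE)
  ymu <- mean(y_raw)
  ysd <- sd(y_raw)
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  y <- (y_raw - ymu) / ysd
  x_all <- as_tcn_input(train_set)

  xv <- yv <- NULL
  if (!is.null(valid_set) && n_windows(valid_set) > 0) {
    xv <- as_tcn_input(valid_set)
    yv <- (valid_set$meta[[tgt]] - ymu) / ysd
  }

  skel <- model$params
  pvec <- unlist(skel, use.names = FALSE)
  state <- list(m = numeric(length(pvec)), v = numeric(length(pvec)),
                t = 0L, p = pvec)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        valid_loss = numeric(0))
  best <- list(loss = Inf, p = pvec)

  with_local_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      ep_sse <- 0
      for (b0 in seq(1L, n, by = config$batch)) {
        bidx <- perm[b0:min(b0 + config$batch - 1L, n)]
        rows <- rep((bidx - 1L) * T_len, each = T_len) + seq_len(T_len)
        xb <- x_all[rows, , drop = FALSE]
        model$params <- utils::relist(state$p, skel)
        fw <- tcn_forward(model, xb, T_len, cache = TRUE)
        resid <- fw$pred - y[bidx]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d", ep),
               call. = FALSE)
        ep_sse <- ep_sse + sum(resid^2)
        grads <- tcn_backward(model, fw, 2 * resid / length(bidx), T_len)
        state <- adam_step(state$p, unlist(grads, use.names = FALSE), state,
                           config$lr)
      }
      tr_loss <- ep_sse / n
      va_loss <- NA_real_
      if (!is.null(xv)) {
        model$params <- utils::relist(state$p, skel)
        pv <- predict_batched(model, xv, T_len, config$batch)
        va_loss <- mean((pv - yv)^2)
        if (va_loss < best$loss) best <- list(loss = va_loss, p = state$p)
      }
      history[ep, ] <- list(ep, tr_loss, va_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  valid %s", ep, tr_loss,
                        ifelse(is.na(va_loss), "-", sprintf("%.5f", va_loss))))
    }
  })
  final_p <- if (!is.null(xv)) best$p else state$p
  model$params <- utils::relist(final_p, skel)
  structure(list(model = model, train_config = config, target = target,
                 target_stats = list(mean = ymu, sd = ysd),
                 norm_stats = train_set$norm_stats, history = history,
                 T_len = T_len, fold_scores = NULL),
            class = "trained_tcn")
}

predict_batched <- function(model, x, T_len, batch) {
  n <- nrow(x) %/% T_len
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch)) {
    bidx <- b0:min(b0 + batch - 1L, n)
    rows <- rep((bidx - 1L) * T_len, each = T_len) + seq_len(T_len)
    out[bidx] <- tcn_forward(model, x[rows, , drop = FALSE], T_len)$pred
  }
  out
}

#' @export
print.trained_tcn <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<trained_tcn> target %s, %d epochs (final train loss %.4f%s)\n",
              x$target, nrow(x$history), last$train_loss,
              if (is.na(last$valid_loss)) ""
              else sprintf(", valid %.4f", last$valid_loss)))
  invisible(x)
}

#' Predict per-window targets with a trained TCN
#'
#' Runs the forward pass, restores the target scale and clips negative
#' values at zero. Signals are normalized with the statistics stored at
#' training time when the supplied windows are still on the raw scale.
#'
#' @param trained a [train_tcn()] result.
#' @param ws a `window_set` with the training geometry (same sampling rate
#'   and window length).
#' @param batch forward-pass batch size.
#' @return a numeric vector of predictions (kcal/min for an `"ee"` model,
#'   mL/min/kg for a `"vo2"` model), one per window, in window order.
#' @export
predict_ee <- function(trained, ws, batch = 1024L) {
  stopifnot(inherits(trained, "trained_tcn"), inherits(ws, "window_set"))
  if (dim(ws$signal)[2] != trained$T_len)
    stop(sprintf("window length mismatch: model expects %d samples, got %d",
                 trained$T_len, dim(ws$signal)[2]), call. = FALSE)
  if (is.null(ws$norm_stats) && !is.null(trained$norm_stats)) {
    for (c in seq_len(dim(ws$signal)[1]))
      ws$signal[c, , ] <- (ws$signal[c, , ] - trained$norm_stats$mean[c]) /
        trained$norm_stats$sd[c]
    ws$norm_stats <- trained$norm_stats
  }
  x <- as_tcn_input(ws)
  pred <- predict_batched(trained$model, x, dim(ws$signal)[2], batch)
  pmax(pred * trained$target_stats$sd + trained$target_stats$mean, 0)
}

#' K-fold cross-validation of the TCN
#'
#' Retrains from scratch on each fold complement (fresh seeded weights per
#' fold) and scores the held-out fold, over the pooled training +
#' validation windows.
#'
#' @param ws pooled `window_set` (normalized, targets set).
#' @param tcn_cfg a [tcn_config()].
#' @param config a [train_config()]; `config$folds` folds are used.
#' @param target `"ee"` or `"vo2"`.
#' @return a data frame with one row per fold: `fold`, `n`, `r2`, `rmse`.
#' @export
cross_validate <- function(ws, tcn_cfg = tcn_config(),
                           config = train_config(), target = "ee") {
  stopifnot(inherits(ws, "window_set"))
  n <- n_windows(ws)
  folds <- config$folds
  fold_of <- with_local_seed(config$seed,
                             sample(rep_len(seq_len(folds), n)))
  out <- data.frame(fold = seq_len(folds), n = NA_integer_,
                    r2 = NA_real_, rmse = NA_real_)
  for (f in seq_len(folds)) {
    tr <- ws[fold_of != f]
    te <- ws[fold_of == f]
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    model <- build_tcn(tcn_cfg, in_channels = dim(ws$signal)[1],
                       seed = cfg_f$seed)
    fit <- train_tcn(model, tr, valid_set = NULL, config = cfg_f,
                     target = target)
    pred <- predict_ee(fit, te)
    ref <- te$meta[[target_column(target)]]
    out$n[f] <- n_windows(te)
    out$r2[f] <- r_squared(pred, ref)
    out$rmse[f] <- rmse(pred, ref)
  }
  out
}
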