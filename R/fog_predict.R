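# Prediction of the two-year change in FOG-Q items from session-1 acoustic
# features: gradient-boosted regression trees under repeated stratified
# 10-fold cross-validation, evaluated by MAE, RMSE, EER, SSE and R^2.

#' Regression evaluation metrics
#'
#' MAE = mean |y - yhat|; RMSE = sqrt(mean (y - yhat)^2);
#' EER = 100 * MAE / r, the estimation error rate, where `r` is the observed
#' range of the clinical scale in the dataset; SSE = sum (y - yhat)^2;
#' R^2 = 1 - SSE / sum (y - ybar)^2.
#'
#' @param y_true,y_pred numeric vectors of equal length (n >= 2).
#' @param scale_range `r`, the range of response values present in the
#'   dataset (> 0); defaults to `diff(range(y_true))`.
#' @return Named list `mae`, `rmse`, `eer` (percent), `sse`, `r2`.
#' @examples
#' fog_metrics(c(0, 4), c(1, 1), scale_range = 4)
#' @export
fog_metrics <- function(y_true, y_pred, scale_range = NULL) {
  n <- length(y_true)
  if (n < 2 || length(y_pred) != n)
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  if (!all(is.finite(y_true)) || !all(is.finite(y_pred)))
    stop("non-finite values in inputs", call. = FALSE)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss == 0)
    stop("constant y_true: R^2 undefined", call. = FALSE)
  scale_range <- scale_range %||% diff(range(y_true))
  if (scale_range <= 0) stop("scale_range must be positive", call. = FALSE)
  err <- y_true - y_pred
  sse <- sum(err^2)
  list(mae = mean(abs(err)),
       rmse = sqrt(mean(err^2)),
       eer = 100 * mean(abs(err)) / scale_range,
       sse = sse,
       r2 = 1 - sse / tss)
}

#' Stratified fold assignment for a continuous response
#'
#' The response is binned into (at most) `bins` quantile bins -- fewer when
#' ties collapse quantiles -- and each bin's members are dealt round-robin to
#' folds after a seeded shuffle, so every fold's bin composition is within
#' one of proportional. Deterministic for a fixed seed.
#'
#' @param y numeric response.
#' @param k number of folds (<= n).
#' @param seed integer seed.
#' @param bins target number of quantile bins (default 4).
#' @return Integer vector of fold labels 1..k.
#' @export
stratified_folds <- function(y, k, seed = 1, bins = 4) {
  n <- length(y)
  if (k > n) stop("more folds than observations", call. = FALSE)
  qs <- unique(quantile(y, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  bin <- if (length(qs) > 2) {
    cut(y, breaks = qs, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, n)
  fold <- integer(n)
  with_seed(seed, {
    offset <- sample.int(k, 1) - 1L
    for (b in sort(unique(bin))) {
      idx <- which(bin == b)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

# one boosted-tree fit; single thread for bitwise determinism
fit_gbt <- function(X, y, config) {
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(max_depth = config$max_depth, eta = config$learning_rate,
                  objective = "reg:squarederror", nthread = 1),
    data = dtrain, nrounds = config$n_trees, verbose = 0)
}

predict_gbt <- function(model, X) {
  as.numeric(predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1)))
}

# one repetition: redraw folds, fit per fold, pool out-of-fold predictions
cv_repetition <- function(X, y, config, seed) {
  fold <- stratified_folds(y, config$folds, seed, config$strat_bins)
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(fold))) {
    te <- fold == f
    m <- fit_gbt(X[!te, , drop = FALSE], y[!te], config)
    pred[te] <- predict_gbt(m, X[te, , drop = FALSE])
  }
  pred
}

mean_cv_eer <- function(X, y, config, seed, reps) {
  r <- diff(range(y))
  mean(vapply(seq_len(reps), function(i) {
    pred <- cv_repetition(X, y, config, derive_seed(seed, i))
    100 * mean(abs(y - pred)) / r
  }, 0))
}

#' Greedy forward feature selection by cross-validated EER
#'
#' Starting from the empty set, repeatedly adds the candidate that minimises
#' the mean cross-validated estimation error rate; stops when no addition
#' improves the EER by more than `config$selection_tol` points or when
#' `config$selection_cap` features are selected. Selection uses
#' `config$selection_reps` fold redraws per candidate (cheaper than the full
#' evaluation's repetitions) and is deterministic given the seed.
#'
#' @param data data.frame holding the response and candidate columns
#'   (complete cases used).
#' @param response response column name.
#' @param candidates candidate feature column names.
#' @param config an [hd_config].
#' @param seed integer seed.
#' @return Character vector of selected feature names (in selection order).
#' @export
select_features <- function(data, response, candidates, config = hd_config(),
                            seed = 1) {
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  df <- data[complete.cases(data[c(response, candidates)]), , drop = FALSE]
  y <- df[[response]]
  if (length(y) < config$folds) stop("too few complete cases", call. = FALSE)
  selected <- character(0)
  best_eer <- Inf
  while (length(selected) < min(config$selection_cap, length(candidates))) {
    remaining <- setdiff(candidates, selected)
    eers <- vapply(remaining, function(cand) {
      mean_cv_eer(df[c(selected, cand)], y, config, seed,
                  config$selection_reps)
    }, 0)
    cand_best <- remaining[which.min(eers)]
    if (min(eers) < best_eer - config$selection_tol) {
      selected <- c(selected, cand_best)
      best_eer <- min(eers)
    } else break
  }
  if (!length(selected)) selected <- remaining[which.min(eers)]
  selected
}

#' Fit and evaluate the FOG-change prediction model
#'
#' The package's model-fitting entry point. For the chosen response (a
#' per-item change in FOG-Q, or any numeric column) and candidate feature
#' set -- typically one HD dimension via [dimension_features] -- the
#' procedure optionally performs greedy forward selection, then runs
#' `repetitions` independent redraws of stratified k-fold cross-validation
#' with a gradient-boosted tree regressor, pooling out-of-fold predictions
#' per repetition and computing MAE, RMSE, EER, SSE and R^2 on each pooled
#' vector. Reported metrics are mean and SD across repetitions; EER's scale
#' range is the observed range of the response. A final model on all data is
#' kept for [predict.fog_cv].
#'
#' With `nested = TRUE` selection is re-run inside every repetition on
#' training folds only (costlier, avoids selection bias); the default
#' selects once on the full data before evaluation.
#'
#' @param data data.frame with the response and feature columns (e.g. a
#'   merged feature table / cohort).
#' @param response response column name (e.g. `"dQ5"`).
#' @param candidates candidate feature columns; default: every `measure_task`
#'   column found in `data`.
#' @param select run greedy forward selection (default `TRUE`); when
#'   `FALSE`, all candidates are used as-is.
#' @param config an [hd_config] (folds, repetitions, hyperparameters,
#'   selection settings, `nested`).
#' @param seed master seed; every repetition derives its own seed from it.
#' @return An object of class `fog_cv`.
#' @export
fog_cv <- function(data, response, candidates = NULL, select = TRUE,
                   config = hd_config(), seed = 1) {
  if (is.null(candidates)) {
    candidates <- grep("_TSK[0-9]+$", names(data), value = TRUE)
    candidates <- setdiff(candidates, response)
  }
  missing_cand <- setdiff(candidates, names(data))
  if (length(missing_cand))
    stop("candidates not in data: ", paste(missing_cand, collapse = ", "),
         call. = FALSE)
  if (!response %in% names(data)) stop("response not in data", call. = FALSE)
  df <- data[complete.cases(data[c(response, candidates)]), , drop = FALSE]
  y <- df[[response]]
  n <- length(y)
  if (n < config$folds) stop("too few complete cases for the fold count",
                             call. = FALSE)
  if (diff(range(y)) <= 0) stop("constant response", call. = FALSE)
  r <- diff(range(y))

  selected <- if (select && !config$nested) {
    select_features(df, response, candidates, config, derive_seed(seed, 0))
  } else if (!select) candidates else NULL

  reps <- config$repetitions
  per_rep <- matrix(NA_real_, reps, 5,
                    dimnames = list(NULL, c("mae", "rmse", "eer", "sse", "r2")))
  preds <- matrix(NA_real_, reps, n)
  sel_per_rep <- vector("list", reps)
  for (i in seq_len(reps)) {
    rep_seed <- derive_seed(seed, i)
    feats <- if (select && config$nested) {
      select_features(df, response, candidates, config,
                      derive_seed(rep_seed, 1))
    } else selected
    sel_per_rep[[i]] <- feats
    pred <- cv_repetition(df[feats], y, config, rep_seed)
    preds[i, ] <- pred
    m <- fog_metrics(y, pred, r)
    per_rep[i, ] <- unlist(m)
  }
  if (is.null(selected)) selected <- sel_per_rep[[1]]
  final <- fit_gbt(df[selected], y, config)

  structure(list(
    response = response, candidates = candidates, selected = selected,
    n = n, scale_range = r, config = config, seed = seed,
    metrics = data.frame(metric = colnames(per_rep),
                         mean = colMeans(per_rep),
                         sd = apply(per_rep, 2, sd), row.names = NULL),
    per_repetition = as.data.frame(per_rep),
    predictions = preds, y = y, subject_id = df$subject_id %||% seq_len(n),
    model = final),
    class = "fog_cv")
}

#' @export
print.fog_cv <- function(x, ...) {
  cat(sprintf("<fog_cv> response %s, n = %d, %d features selected of %d candidates\n",
              x$response, x$n, length(x$selected), length(x$candidates)))
  cat(sprintf("  %d x %d-fold stratified CV (seed %s)\n",
              x$config$repetitions, x$config$folds, format(x$seed)))
  m <- x$metrics
  cat(sprintf("  MAE %.3f +/- %.3f | RMSE %.3f +/- %.3f | EER %.2f +/- %.2f %% | SSE %.2f +/- %.2f | R2 %.3f +/- %.3f\n",
              m$mean[1], m$sd[1], m$mean[2], m$sd[2], m$mean[3], m$sd[3],
              m$mean[4], m$sd[4], m$mean[5], m$sd[5]))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.fog_cv <- function(object, ...) {
  print(object)
  cat("\nPer-repetition metric quantiles:\n")
  print(apply(object$per_repetition, 2, quantile,
              probs = c(0.05, 0.25, 0.5, 0.75, 0.95)), digits = 3)
  invisible(object)
}

#' @export
coef.fog_cv <- function(object, ...) {
  imp <- tryCatch(xgboost::xgb.importance(model = object$model),
                  error = function(e) NULL)
  out <- setNames(rep(0, length(object$selected)), object$selected)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

#' @export
predict.fog_cv <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  predict_gbt(object$model, newdata[object$selected])
}

#' @export
fitted.fog_cv <- function(object, ...) {
  setNames(colMeans(object$predictions), object$subject_id)
}

#' @export
residuals.fog_cv <- function(object, ...) {
  setNames(object$y - colMeans(object$predictions), object$subject_id)
}

#' @export
plot.fog_cv <- function(x, ...) {
  fit <- colMeans(x$predictions)
  graphics::plot(x$y, fit,
                 xlab = sprintf("observed %s", x$response),
                 ylab = "mean out-of-fold prediction",
                 main = sprintf("fog_cv: %s (EER %.1f%%)", x$response,
                                x$metrics$mean[x$metrics$metric == "eer"]), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Run the prediction stage across responses and HD dimensions
#'
#' Convenience wrapper reproducing the shape of the per-dimension prediction
#' table: one [fog_cv] fit per (response, dimension) combination.
#'
#' @param data merged data.frame of features and responses.
#' @param responses response column names.
#' @param dimensions HD dimensions to run (see [dimension_features]).
#' @param config an [hd_config].
#' @param seed master seed.
#' @return A data.frame with one row per combination (metric means and SDs,
#'   number and list of selected features); fits attached as attribute
#'   `"fits"`.
#' @export
fog_predict_table <- function(data, responses, dimensions = "combination",
                              config = hd_config(), seed = 1) {
  rows <- list(); fits <- list(); idx <- 0L
  for (dim in dimensions) {
    cand <- intersect(dimension_features(dim), names(data))
    if (!length(cand)) next
    for (resp in responses) {
      idx <- idx + 1L
      fit <- fog_cv(data, resp, cand, config = config,
                    seed = derive_seed(seed, idx))
      m <- fit$metrics
      rows[[idx]] <- data.frame(
        dimension = dim, response = resp,
        mae = m$mean[1], mae_sd = m$sd[1],
        rmse = m$mean[2], rmse_sd = m$sd[2],
        eer = m$mean[3], eer_sd = m$sd[3],
        sse = m$mean[4], sse_sd = m$sd[4],
        r2 = m$mean[5], r2_sd = m$sd[5],
        n_selected = length(fit$selected),
        selected = paste(fit$selected, collapse = ";"),
        stringsAsFactors = FALSE)
      fits[[paste(dim, resp, sep = ".")]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
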