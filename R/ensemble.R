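# Bagged elastic-net ensembles: 1000x repeated 10-fold cross-validation and
# 2n bootstrap resampling, producing averaged left-out predictions with
# per-sample dispersion and averaged, max-normalized feature weights.

#' Ensemble configuration
#'
#' @param scheme `"repeated_kfold"` or `"bootstrap_2n"`.
#' @param n_folds Folds per cross-validation (default 10).
#' @param n_repeats Repeats of the scheme (default 1000).
#' @param bootstrap_multiple Bootstrap draw size as a multiple of n
#'   (default 2, i.e. draws of size 2n).
#' @param seed Master seed; every source of randomness derives from it.
#' @param alpha l1 mixing of the elastic net.
#' @param inner_folds,n_lambda,lambda_ratio Inner cross-validation used to
#'   choose the penalty on each training set (see [choose_lambda()]).
#' @param standardize Z-score features with training-split statistics.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(scheme = c("repeated_kfold", "bootstrap_2n"),
                            n_folds = 10L, n_repeats = 1000L,
                            bootstrap_multiple = 2, seed = 1L, alpha = 0.5,
                            inner_folds = 5L, n_lambda = 30L,
                            lambda_ratio = 1e-4, standardize = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(n_folds >= 2L, n_repeats >= 1L, bootstrap_multiple > 0)
  structure(list(scheme = scheme, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 bootstrap_multiple = bootstrap_multiple,
                 seed = as.integer(seed), alpha = alpha,
                 inner_folds = as.integer(inner_folds),
                 n_lambda = as.integer(n_lambda),
                 lambda_ratio = lambda_ratio, standardize = standardize),
            class = "ensemble_config")
}

# train on (Xtr, ytr) with inner-CV lambda choice; predict Xte.
# Returns list(pred, w) with w on the standardized scale. The compiled
# kernel mirrors choose_lambda() + elastic_net_fit(); only the inner fold
# labels consume the caller's RNG stream.
.fit_and_predict <- function(Xtr, ytr, Xte, config) {
  Xg <- if (config$standardize) .std_apply(Xtr, .std_stats(Xtr)) else Xtr
  grid <- lambda_grid(Xg, ytr, config$alpha, config$n_lambda,
                      config$lambda_ratio)
  inner <- fold_assignment(nrow(Xtr), min(config$inner_folds, nrow(Xtr)))
  # inner path fits carry a per-step sweep budget: warm starts along the
  # grid make 50 sweeps ample for ranking penalties by validation error
  fit <- cv_fit_predict(Xtr, ytr, Xte, inner, grid, config$alpha,
                        50L, 1e-4, 10000L, 1e-6, config$standardize)
  names(fit$w) <- colnames(Xtr)
  list(pred = as.numeric(fit$pred), w = fit$w)
}

.ensemble_result <- function(X, y, pred_sum, pred_sq, pred_n, w_sum, n_models,
                             config) {
  mean_pred <- ifelse(pred_n > 0, pred_sum / pred_n, NA_real_)
  var_pred <- ifelse(pred_n > 1,
                     pmax(0, (pred_sq - pred_n * mean_pred^2) / (pred_n - 1)),
                     NA_real_)
  never <- pred_n == 0
  if (any(never)) {
    warning(sum(never), " sample(s) never left out; prediction NA")
  }
  weights <- aggregate_weights(list(w_sum / n_models), colnames(X))
  ok <- !is.na(mean_pred)
  perf <- if (sum(ok) >= 3) cor(mean_pred[ok], y[ok]) else NA_real_
  structure(list(
    predictions = data.frame(
      mutant = if (is.null(rownames(X))) as.character(seq_along(y)) else rownames(X),
      observed = y, mean_pred = mean_pred, sd_pred = sqrt(var_pred),
      n_left_out = pred_n, row.names = NULL, stringsAsFactors = FALSE),
    weights = weights, performance_pcc = perf, config = config),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %s: n=%d, PCC(mean left-out prediction, observed)=%.3f\n",
              x$config$scheme, nrow(x$predictions), x$performance_pcc))
  sel <- x$weights[x$weights$selected, ]
  cat(sprintf("  %d/%d features selected; top: %s\n", nrow(sel),
              nrow(x$weights),
              paste(head(sel$feature, 3), collapse = ", ")))
  invisible(x)
}

#' Repeated k-fold cross-validation ensemble
#'
#' For each repeat, a fresh random partition into `n_folds` folds; each
#' sample is predicted once per repeat by the model not trained on it. The
#' final prediction per sample is the mean over repeats (its dispersion the
#' standard deviation over repeats), and feature weights are averaged over
#' all `n_folds * n_repeats` fitted models. Fully deterministic given
#' `config$seed`.
#'
#' @param X Feature matrix (mutant rownames, feature colnames; no `NA`).
#' @param y Targets (log-scale relative constants).
#' @param config An [ensemble_config()].
#' @return Object of class `ensemble_result` with `predictions` (per-sample
#'   mean, sd, count), `weights` (mean and max-normalized per feature) and
#'   `performance_pcc`.
#' @export
repeated_kfold_ensemble <- function(X, y, config = ensemble_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X) || anyNA(y)) stop("NA values in X or y; exclude unmeasurable samples first")
  if (n < config$n_folds) stop("need n >= n_folds")
  pred_sum <- pred_sq <- numeric(n)
  pred_n <- integer(n)
  w_sum <- numeric(ncol(X))
  n_models <- 0L
  with_local_seed(config$seed, {
    subseeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)
    for (r in seq_len(config$n_repeats)) {
      set.seed(subseeds[r])
      fold <- fold_assignment(n, config$n_folds)
      for (k in seq_len(config$n_folds)) {
        te <- fold == k
        fp <- .fit_and_predict(X[!te, , drop = FALSE], y[!te],
                               X[te, , drop = FALSE], config)
        pred_sum[te] <- pred_sum[te] + fp$pred
        pred_sq[te] <- pred_sq[te] + fp$pred^2
        pred_n[te] <- pred_n[te] + 1L
        w_sum <- w_sum + fp$w
        n_models <- n_models + 1L
      }
    }
  })
  .ensemble_result(X, y, pred_sum, pred_sq, pred_n, w_sum, n_models, config)
}

#' 2n bootstrap ensemble
#'
#' Each repeat draws `bootstrap_multiple * n` sample indices with
#' replacement, trains on the draw, and predicts the samples absent from it
#' (the out-of-bag set). Per-sample predictions are averaged over the
#' repeats in which the sample was left out. The result also records the
#' mean in-bag coverage (fraction of distinct original samples per draw),
#' whose expectation is [expected_bootstrap_coverage()].
#'
#' @inheritParams repeated_kfold_ensemble
#' @return An `ensemble_result`; the extra field `mean_coverage` holds the
#'   empirical in-bag coverage.
#' @export
bootstrap_ensemble <- function(X, y, config = ensemble_config("bootstrap_2n")) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (anyNA(X) || anyNA(y)) stop("NA values in X or y; exclude unmeasurable samples first")
  if (n < 3L) stop("need n >= 3")
  m <- round(config$bootstrap_multiple * n)
  pred_sum <- pred_sq <- numeric(n)
  pred_n <- integer(n)
  w_sum <- numeric(ncol(X))
  n_models <- 0L
  coverage <- numeric(config$n_repeats)
  with_local_seed(config$seed, {
    subseeds <- sample.int(.Machine$integer.max - 1L, config$n_repeats)
    for (r in seq_len(config$n_repeats)) {
      set.seed(subseeds[r])
      draw <- sample.int(n, m, replace = TRUE)
      inbag <- unique(draw)
      coverage[r] <- length(inbag) / n
      oob <- setdiff(seq_len(n), inbag)
      if (!length(oob)) {
        # degenerate draw containing every sample: nothing to predict
        fp <- .fit_and_predict(X[draw, , drop = FALSE], y[draw],
                               X[0, , drop = FALSE], config)
        w_sum <- w_sum + fp$w
        n_models <- n_models + 1L
        next
      }
      fp <- .fit_and_predict(X[draw, , drop = FALSE], y[draw],
                             X[oob, , drop = FALSE], config)
      pred_sum[oob] <- pred_sum[oob] + fp$pred
      pred_sq[oob] <- pred_sq[oob] + fp$pred^2
      pred_n[oob] <- pred_n[oob] + 1L
      w_sum <- w_sum + fp$w
      n_models <- n_models + 1L
    }
  })
  res <- .ensemble_result(X, y, pred_sum, pred_sq, pred_n, w_sum, n_models,
                          config)
  res$mean_coverage <- mean(coverage)
  res
}

#' Expected bootstrap coverage
#'
#' Expected fraction of distinct original samples appearing in a
#' with-replacement draw of size `m` from `n` samples:
#' `1 - (1 - 1/n)^m`. At `n = 80`, `m = 160` this is 0.8663, the
#' mean coverage of the 2n bootstrap scheme.
#'
#' @param n Sample count (>= 1).
#' @param m Draw size (>= 1).
#' @return Fraction in `(0, 1]`.
#' @export
expected_bootstrap_coverage <- function(n, m) {
  stopifnot(n >= 1, m >= 1)
  1 - (1 - 1 / n)^m
}

#' Average and normalize feature weights across models
#'
#' Mean weight per feature over all fitted models, then normalized by the
#' largest absolute mean weight so exactly one feature carries +/-1.00
#' (unless all means vanish). Features whose normalized magnitude falls
#' below `epsilon` are reported as not selected (`ns`).
#'
#' @param models List of weight vectors (or `enet_fit` objects) sharing one
#'   feature ordering.
#' @param features Feature names.
#' @param epsilon Selection threshold on the normalized magnitude (0.005,
#'   below two-decimal reporting precision).
#' @return Data frame: `feature`, `mean_weight`, `normalized`, `selected`.
#' @export
aggregate_weights <- function(models, features, epsilon = 0.005) {
  if (!length(models)) stop("no models to aggregate")
  W <- vapply(models, function(m) {
    w <- if (inherits(m, "enet_fit")) m$weights else m
    as.numeric(w)
  }, numeric(length(features)))
  mean_w <- if (is.null(dim(W))) W else rowMeans(W)
  mx <- max(abs(mean_w))
  if (mx == 0) {
    warning("all mean weights are zero; nothing selected")
    norm <- rep(0, length(mean_w))
  } else {
    norm <- mean_w / mx
  }
  out <- data.frame(feature = features, mean_weight = mean_w,
                    normalized = norm, selected = abs(norm) >= epsilon,
                    stringsAsFactors = FALSE)
  out[order(-abs(out$normalized)), ]
}

#' Format a multi-channel weight report
#'
#' Table-style report with one row per feature and one column per target
#' channel, normalized weights printed to two decimals and unselected
#' features as `"ns"`.
#'
#' @param channel_weights Named list of [aggregate_weights()] outputs.
#' @return Data frame of character columns.
#' @export
format_weight_table <- function(channel_weights) {
  feats <- unique(unlist(lapply(channel_weights, function(w) w$feature)))
  out <- data.frame(feature = feats, stringsAsFactors = FALSE)
  for (ch in names(channel_weights)) {
    w <- channel_weights[[ch]]
    i <- match(feats, w$feature)
    out[[ch]] <- ifelse(w$selected[i], sprintf("%.2f", w$normalized[i]), "ns")
  }
  out
}

#' Write ensemble outputs
#'
#' Per-sample predictions as CSV (observed, mean predicted, SD, left-out
#' count) and the full result (weights, performance, config) as JSON.
#'
#' @param result An `ensemble_result`.
#' @param pred_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the result.
#' @export
write_ensemble_result <- function(result, pred_path = NULL, json_path = NULL) {
  if (!is.null(pred_path)) {
    write.csv(result$predictions, pred_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(scheme = result$config$scheme,
           performance_pcc = result$performance_pcc,
           mean_coverage = result$mean_coverage,
           predictions = result$predictions, weights = result$weights),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(result)
}
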