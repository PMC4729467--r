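# Elastic-net regression solved by cyclic coordinate descent with
# soft-thresholding (compiled core in src/enet.cpp). The penalised objective
# is
#   (1/2n) sum_i (y_i - b - x_i.w)^2
#     + lambda * ( alpha sum_j |w_j| + (1-alpha)/2 sum_j w_j^2 ).

#' Elastic-net specification
#'
#' @param lambda Penalty strength (>= 0).
#' @param alpha l1 mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param max_iterations Coordinate-descent sweep budget.
#' @param tolerance Convergence threshold on the largest coefficient change
#'   in a sweep.
#' @param standardize Whether callers should z-score features before
#'   fitting (recorded here; [elastic_net_fit()] itself expects its inputs
#'   already on their final scale).
#' @return List of class `enet_spec`.
#' @export
enet_spec <- function(lambda, alpha = 0.5, max_iterations = 10000L,
                      tolerance = 1e-7, standardize = TRUE) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1)
  structure(list(lambda = lambda, alpha = alpha,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, standardize = standardize),
            class = "enet_spec")
}

#' Fit an elastic net by coordinate descent
#'
#' @param X Numeric feature matrix (callers standardize columns; no `NA`).
#' @param y Numeric targets.
#' @param spec An [enet_spec()].
#' @param intercept Fit an unpenalised intercept.
#' @return List of class `enet_fit`: `weights` (named if `X` has column
#'   names), `intercept`, `objective` (per-sweep trace, non-increasing),
#'   `converged`, `iterations`.
#' @export
elastic_net_fit <- function(X, y, spec, intercept = TRUE) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("NA values in X or y")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (nrow(X) != length(y)) stop("nrow(X) != length(y)")
  if (nrow(X) < 2L) stop("need n >= 2")
  fit <- enet_cd(X, as.numeric(y), spec$lambda, spec$alpha,
                 spec$max_iterations, spec$tolerance,
                 numeric(ncol(X)), if (intercept) mean(y) else 0,
                 intercept, TRUE)
  w <- as.numeric(fit$w)
  names(w) <- colnames(X)
  structure(list(weights = w, intercept = fit$b, objective = fit$objective,
                 converged = fit$converged, iterations = fit$iterations,
                 spec = spec),
            class = "enet_fit")
}

#' @export
predict.enet_fit <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' Smallest penalty zeroing every coefficient
#'
#' For the objective above (with an unpenalised intercept), all weights are
#' zero at the optimum iff `lambda * alpha >= max_j |x_j . (y - mean y)| / n`.
#'
#' @param X Feature matrix.
#' @param y Targets.
#' @param alpha l1 mixing; values below 0.001 are floored to keep the bound
#'   finite.
#' @return `lambda_max`.
#' @export
lambda_max <- function(X, y, alpha = 0.5) {
  a <- max(alpha, 1e-3)
  max(abs(crossprod(as.matrix(X), y - mean(y)))) / (nrow(X) * a)
}

#' Logarithmic penalty grid
#'
#' @inheritParams lambda_max
#' @param n_lambda Grid size.
#' @param ratio Smallest lambda as a fraction of `lambda_max`.
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(X, y, alpha = 0.5, n_lambda = 30L, ratio = 1e-4) {
  lmax <- lambda_max(X, y, alpha)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n_lambda))
}

# column statistics for leakage-free standardization
.std_stats <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}

.std_apply <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

#' Choose the penalty by inner cross-validation
#'
#' K-fold cross-validation over a warm-started logarithmic grid from
#' `lambda_max` down to `ratio * lambda_max`, minimising the validation
#' mean-squared error. Standardization statistics are recomputed from each
#' inner training split, so no information leaks from the validation part.
#' Fold assignment consumes the caller's RNG stream.
#'
#' @param X,y Training data (unstandardized).
#' @param alpha l1 mixing.
#' @param n_folds Inner folds (default 5).
#' @param n_lambda,ratio Grid shape.
#' @param standardize Z-score features inside each inner split.
#' @param path_tol Convergence tolerance for the inner path fits; looser
#'   than a final fit, since only the penalty ranking matters here.
#' @return List: `lambda` (the minimiser), `grid`, `cv_mse`.
#' @export
choose_lambda <- function(X, y, alpha = 0.5, n_folds = 5L, n_lambda = 30L,
                          ratio = 1e-4, standardize = TRUE, path_tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  grid <- lambda_grid(if (standardize) .std_apply(X, .std_stats(X)) else X,
                      y, alpha, n_lambda, ratio)
  fold <- fold_assignment(n, min(n_folds, n))
  err <- matrix(NA_real_, max(fold), length(grid))
  for (k in seq_len(max(fold))) {
    tr <- fold != k
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (standardize) {
      st <- .std_stats(Xtr)
      Xtr <- .std_apply(Xtr, st)
      Xte <- .std_apply(Xte, st)
    }
    path <- enet_path(Xtr, y[tr], grid, alpha, 2000L, path_tol, TRUE)
    pred <- Xte %*% path$W + matrix(path$b, nrow(Xte), length(grid),
                                    byrow = TRUE)
    err[k, ] <- colMeans((pred - y[!tr])^2)
  }
  mse <- colMeans(err)
  list(lambda = grid[which.min(mse)], grid = grid, cv_mse = mse)
}

#' Shuffled k-fold assignment
#'
#' Random partition of `n` samples into `k` folds; the remainder is spread
#' over the leading folds. Consumes the current RNG stream.
#'
#' @param n Sample count.
#' @param k Fold count.
#' @return Integer vector of fold labels in `1..k`.
#' @export
fold_assignment <- function(n, k) {
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), sizes)
  fold
}
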