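# Bagged ensemble schemes: partition bookkeeping, determinism, bootstrap
# coverage, weight aggregation and reporting.

test_that("repeated k-fold gives every sample one left-out prediction per repeat", {
  set.seed(30)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("M%02d", 1:20), paste0("f", 1:6)))
  y <- drop(X[, 1] + rnorm(20, sd = 0.2))
  res <- repeated_kfold_ensemble(X, y, ensemble_config(n_folds = 5,
                                                       n_repeats = 4, seed = 1))
  expect_true(all(res$predictions$n_left_out == 4L))
  expect_equal(res$predictions$mutant, rownames(X))
  expect_true(all(is.finite(res$predictions$sd_pred)))
})

test_that("noiseless sparse truth is predicted almost perfectly", {
  d <- generate_feature_regression_data(sim_config(
    seed = 31, n_mutants = 90,
    feature_truth = list(n_features = 59, support_size = 5,
                         weight_scale = 1, noise_sd = 0)))
  res <- repeated_kfold_ensemble(unclass(d$features), d$targets,
                                 ensemble_config(n_repeats = 3, seed = 2))
  expect_gt(res$performance_pcc, 0.99)
})

test_that("ensembles are bit-identical under a fixed master seed", {
  set.seed(32)
  X <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- drop(X[, 2] - X[, 5]) + rnorm(30, sd = 0.3)
  cfg <- ensemble_config(n_folds = 5, n_repeats = 3, seed = 99)
  expect_identical(repeated_kfold_ensemble(X, y, cfg),
                   repeated_kfold_ensemble(X, y, cfg))
  cfgb <- ensemble_config("bootstrap_2n", n_repeats = 3, seed = 99)
  expect_identical(bootstrap_ensemble(X, y, cfgb),
                   bootstrap_ensemble(X, y, cfgb))
})

test_that("bootstrap coverage matches its closed-form expectation", {
  expect_equal(expected_bootstrap_coverage(80, 160), 1 - (79 / 80)^160)
  # log-space closed form as an independent route to the same number
  expect_equal(expected_bootstrap_coverage(80, 160),
               1 - exp(160 * log1p(-1 / 80)), tolerance = 1e-12)
  expect_equal(expected_bootstrap_coverage(80, 160), 0.86636,
               tolerance = 1e-5)
  expect_equal(expected_bootstrap_coverage(1, 1), 1)
  # monotone in draw size, approaching 1
  cov <- vapply(c(40, 80, 160, 320, 2000), function(m) {
    expected_bootstrap_coverage(40, m)
  }, numeric(1))
  expect_true(all(diff(cov) > 0))
  expect_gt(cov[5], 1 - 1e-12)
  # empirical in-bag coverage over the ensemble run
  set.seed(33)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- drop(X[, 1]) + rnorm(40, sd = 0.3)
  res <- bootstrap_ensemble(X, y, ensemble_config("bootstrap_2n",
                                                  n_repeats = 150, seed = 3))
  expect_equal(res$mean_coverage, expected_bootstrap_coverage(40, 80),
               tolerance = 0.01)
  expect_true(all(res$predictions$n_left_out <= 150))
})

test_that("samples never left out are flagged as NA predictions", {
  # n = 3, draws of size 6: a single repeat usually covers everyone
  set.seed(34)
  X <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rnorm(3)
  res <- NULL
  for (s in 1:20) {
    cfg <- ensemble_config("bootstrap_2n", n_repeats = 1, seed = s)
    r <- suppressWarnings(bootstrap_ensemble(X, y, cfg))
    if (all(r$predictions$n_left_out == 0)) {
      res <- r
      break
    }
  }
  expect_false(is.null(res))
  expect_true(all(is.na(res$predictions$mean_pred)))
  expect_warning(bootstrap_ensemble(X, y, cfg), "never left out")
})

test_that("weight aggregation normalizes by the largest mean magnitude", {
  w <- aggregate_weights(list(c(-2, 1, 0), c(-2, 1, 0)), c("A", "B", "C"))
  expect_equal(w$normalized[w$feature == "A"], -1)
  expect_equal(w$normalized[w$feature == "B"], 0.5)
  expect_false(w$selected[w$feature == "C"])
  expect_equal(sum(abs(w$normalized) == 1), 1L)
  # a single model normalizes by its own largest weight
  single <- aggregate_weights(list(c(0.4, -0.8)), c("A", "B"))
  expect_equal(single$normalized, c(-1, 0.5),
               ignore_attr = TRUE)
  # scale invariance
  sc <- aggregate_weights(list(10 * c(-2, 1, 0)), c("A", "B", "C"))
  expect_equal(sc$normalized, w$normalized)
  expect_warning(z <- aggregate_weights(list(c(0, 0)), c("A", "B")),
                 "all mean weights")
  expect_false(any(z$selected))
  expect_error(aggregate_weights(list(), c("A")), "no models")
})

test_that("the weight report prints two decimals with ns markers", {
  wa <- aggregate_weights(list(c(-2, 1, 0.001)), c("A", "B", "C"))
  wb <- aggregate_weights(list(c(0.5, 0, 1)), c("A", "B", "C"))
  tab <- format_weight_table(list(kcat = wa, inv_KM = wb))
  expect_equal(sort(tab$feature), c("A", "B", "C"))
  expect_equal(tab$kcat[tab$feature == "A"], "-1.00")
  expect_equal(tab$kcat[tab$feature == "C"], "ns")
  expect_equal(tab$inv_KM[tab$feature == "B"], "ns")
})

test_that("k-fold and bootstrap schemes agree within sampling error", {
  d <- gen_sparse_regression(35, n = 60, p = 20, support = 3, r2 = 0.8)
  kf <- repeated_kfold_ensemble(unclass(d$features), d$targets,
                                ensemble_config(n_folds = 10, n_repeats = 10,
                                                seed = 4))
  bs <- bootstrap_ensemble(unclass(d$features), d$targets,
                           ensemble_config("bootstrap_2n", n_repeats = 30,
                                           seed = 4))
  expect_lt(abs(kf$performance_pcc - bs$performance_pcc), 0.15)
})

test_that("ensemble outputs serialise to CSV and JSON", {
  set.seed(36)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- drop(X[, 1]) + rnorm(20, sd = 0.2)
  res <- repeated_kfold_ensemble(X, y, ensemble_config(n_folds = 5,
                                                       n_repeats = 2, seed = 5))
  pred <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_ensemble_result(res, pred_path = pred, json_path = js)
  back <- read.csv(pred)
  expect_equal(back$mean_pred, res$predictions$mean_pred)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$performance_pcc, res$performance_pcc, tolerance = 1e-9)
})
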