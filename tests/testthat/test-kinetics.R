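# Kinetic-constant fitting: absorbance conversion, model selection,
# relative constants and the heatmap report.

test_that("absorbance traces convert to rates through the standard curve", {
  curve <- standard_curve(slope = 1e4)
  ts <- data.frame(mutant = "A", substrate_mM = 10, replicate = 1,
                   enzyme_mg_per_mL = 0.5, time_min = 0:9,
                   absorbance = 0.1 + 0.01 * (0:9))
  rates <- absorbance_to_rates(ts, curve)
  expect_equal(rates$rate_M_per_min, 0.01 / 1e4)
  expect_false(rates$clamped)

  flat <- ts; flat$absorbance <- 0.2
  expect_equal(absorbance_to_rates(flat, curve)$rate_M_per_min, 0)

  neg <- ts; neg$absorbance <- rev(ts$absorbance)
  expect_warning(r <- absorbance_to_rates(neg, curve), "clamped")
  expect_equal(r$rate_M_per_min, 0)
  expect_true(r$clamped)

  expect_error(absorbance_to_rates(ts[1:2, ], curve), ">= 3 time points")
  bad <- ts; bad$absorbance[3] <- NaN
  expect_error(absorbance_to_rates(bad, curve), "non-finite")
})

test_that("injected slopes are recovered within least-squares error", {
  curve <- standard_curve(slope = 5e3)
  set.seed(21)
  for (i in 1:5) {
    slope <- runif(1, 0.002, 0.02)
    tv <- 0:29
    ab <- 0.05 + slope * tv + rnorm(30, sd = 0.003)
    ts <- data.frame(mutant = "A", substrate_mM = 10, replicate = 1,
                     enzyme_mg_per_mL = 0.5, time_min = tv, absorbance = ab)
    se <- summary(lm(ab ~ tv))$coefficients["tv", "Std. Error"]
    got <- absorbance_to_rates(ts, curve)$rate_M_per_min
    expect_lt(abs(got * curve$slope - slope), 3 * se)
  }
})

test_that("noiseless wild-type parameters are recovered to 0.1%", {
  cfg <- sim_config(seed = 1, n_mutants = 1, noise_cv = 0,
                    truth_kinetics = data.frame(mutant = "WT", kcat = 880,
                                                KM = 5.0, Ki = NA))
  fit <- fit_kinetics(generate_rate_data(cfg))
  expect_equal(fit$fit_kind, "MM")
  expect_equal(fit$kcat, 880, tolerance = 1e-3)
  expect_equal(fit$KM, 5.0, tolerance = 1e-3)
  expect_equal(fit$kcat_over_KM, 1000 * fit$kcat / fit$KM)
})

test_that("far-below-KM data falls back to the first-order linear model", {
  # all tested S <= KM/100: no saturation observable
  cfg <- sim_config(seed = 2, n_mutants = 1, noise_cv = 0,
                    substrate_concs = c(0.5, 0.25, 0.12, 0.06, 0.02),
                    truth_kinetics = data.frame(mutant = "A", kcat = 500,
                                                KM = 50, Ki = NA))
  fit <- fit_kinetics(generate_rate_data(cfg))
  expect_equal(fit$fit_kind, "linear")
  expect_true(is.na(fit$kcat))
  expect_equal(fit$kcat_over_KM, 1000 * 500 / 50, tolerance = 0.01)
})

test_that("substrate inhibition is selected and Ki recovered at low noise", {
  cfg <- sim_config(seed = 5, n_mutants = 1, noise_cv = 0.02,
                    truth_kinetics = data.frame(mutant = "A", kcat = 800,
                                                KM = 4, Ki = 5))
  fit <- fit_kinetics(generate_rate_data(cfg))
  expect_equal(fit$fit_kind, "MM_substrate_inhibition")
  expect_equal(fit$Ki, 5, tolerance = 0.1)
})

test_that("uninhibited data rarely triggers the inhibition model", {
  wrong <- 0L
  for (s in 1:30) {
    cfg <- sim_config(seed = s, n_mutants = 1, noise_cv = 0.05,
                      truth_kinetics = data.frame(mutant = "A", kcat = 880,
                                                  KM = 5, Ki = NA))
    fit <- fit_kinetics(generate_rate_data(cfg))
    if (fit$fit_kind == "MM_substrate_inhibition") wrong <- wrong + 1L
  }
  expect_lt(wrong / 30, 0.1)
})

test_that("all-zero rates and sub-LOD efficiencies are flagged below_LOD", {
  obs <- data.frame(mutant = "dead", substrate_mM = c(100, 25, 6.25, 1.6),
                    replicate = 1, rate_M_per_min = 0, enzyme_mg_per_mL = 0.5)
  expect_equal(fit_kinetics(obs)$fit_kind, "below_LOD")
  # tiny but nonzero activity: kcat/KM under 10 M^-1 min^-1
  cfg <- sim_config(seed = 3, n_mutants = 1, noise_cv = 0,
                    truth_kinetics = data.frame(mutant = "A", kcat = 0.02,
                                                KM = 5, Ki = NA))
  fit <- fit_kinetics(generate_rate_data(cfg))
  expect_equal(fit$fit_kind, "below_LOD")
  expect_true(is.na(fit$kcat_over_KM))
})

test_that("fitting is invariant to observation order", {
  cfg <- sim_config(seed = 8, n_mutants = 1, noise_cv = 0.05,
                    truth_kinetics = data.frame(mutant = "A", kcat = 300,
                                                KM = 10, Ki = NA))
  rd <- generate_rate_data(cfg)
  f1 <- fit_kinetics(rd)
  f2 <- fit_kinetics(rd[rev(seq_len(nrow(rd))), ])
  expect_equal(f1$kcat, f2$kcat)
  expect_equal(f1$KM, f2$KM)
})

test_that("relative constants follow the log10 conventions of the heatmap", {
  wt <- fake_constants("WT", kcat = 880, KM = 5, kcat_over_KM = 171000)
  # wild type against itself sits at 0 on every channel
  self <- relative_constants(wt, wt)
  expect_equal(self$log10_kcat, 0)
  expect_equal(self$log10_inv_KM, 0)
  expect_equal(self$log10_kcat_over_KM, 0)
  # the best observed efficiency: log10(560000/171000)
  best <- fake_constants("best", kcat = 5000, KM = 8.9,
                         kcat_over_KM = 560000)
  expect_equal(relative_constants(best, wt)$log10_kcat_over_KM,
               log10(560000 / 171000), tolerance = 1e-12)
  expect_equal(round(relative_constants(best, wt)$log10_kcat_over_KM, 3),
               0.515)
  # a tenfold KM increase maps to -1 on the 1/KM channel
  worse <- fake_constants("worse", kcat = 880, KM = 50)
  expect_equal(relative_constants(worse, wt)$log10_inv_KM, -1)
})

test_that("relative constants are antisymmetric and flag partial fits", {
  set.seed(4)
  for (i in 1:5) {
    a <- fake_constants("a", kcat = 10^runif(1, 1, 4), KM = 10^runif(1, -0.2, 1.9))
    b <- fake_constants("b", kcat = 10^runif(1, 1, 4), KM = 10^runif(1, -0.2, 1.9))
    ab <- relative_constants(a, b)
    ba <- relative_constants(b, a)
    expect_equal(ab$log10_kcat, -ba$log10_kcat)
    expect_equal(ab$log10_inv_KM, -ba$log10_inv_KM)
    expect_equal(ab$log10_kcat_over_KM, -ba$log10_kcat_over_KM)
  }
  wt <- fake_constants("WT", kcat = 880, KM = 5)
  lin <- fake_constants("lin", fit_kind = "linear", kcat_over_KM = 2000)
  rl <- relative_constants(lin, wt)
  expect_false(rl$measurable[["kcat"]])
  expect_true(rl$measurable[["kcat_over_KM"]])
  lod <- fake_constants("lod", fit_kind = "below_LOD")
  expect_false(any(relative_constants(lod, wt)$measurable))
  expect_error(relative_constants(wt, lin), "saturating")
})

test_that("heatmap matrix masks unmeasurable cells and round-trips CSV", {
  wt <- fake_constants("WT", kcat = 880, KM = 5)
  ok <- fake_constants("ok", kcat = 88, KM = 10)
  dead <- fake_constants("dead", fit_kind = "below_LOD")
  rel <- list(relative_constants(ok, wt), relative_constants(dead, wt))
  hm <- build_heatmap_matrix(rel)
  expect_equal(dim(hm$values), c(2L, 3L))
  expect_false(any(hm$mask["ok", ]))
  expect_true(all(hm$mask["dead", ]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(hm, path)
  back <- read_heatmap_csv(path)
  expect_equal(back$values, hm$values)
  expect_equal(back$mask, hm$mask)
  expect_error(build_heatmap_matrix(list(rel[[1]], rel[[1]])), "duplicate")
})

test_that("insoluble mutants are annotated and skipped, not fit", {
  cfg <- sim_config(seed = 6, n_mutants = 2, noise_cv = 0)
  rd <- generate_rate_data(cfg)
  yields <- c(M001 = 1.0, M002 = 0.05)
  fits <- fit_all_kinetics(rd, yield = yields)
  expect_equal(fits$M002$fit_kind, "insoluble")
  expect_true(fits$M001$fit_kind %in% c("MM", "MM_substrate_inhibition", "linear"))
  tab <- kinetics_table(fits)
  expect_equal(nrow(tab), 2L)
})
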