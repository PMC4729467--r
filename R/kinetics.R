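# Kinetics module: converts raw observations into per-mutant kinetic
# constants with model selection (Michaelis-Menten, substrate inhibition,
# linear fallback), detection-limit flagging, and log-scale relative
# constants for heatmap reporting.

#' Standard curve for absorbance-to-concentration conversion
#'
#' @param slope Absorbance units per molar of product (> 0).
#' @param intercept Absorbance offset.
#' @param wavelength Wavelength in nm (4-nitrophenol absorbs at 420 nm).
#' @return Object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept = 0, wavelength = 420) {
  if (slope <= 0) stop("standard curve slope must be > 0")
  structure(list(slope = slope, intercept = intercept, wavelength = wavelength),
            class = "standard_curve")
}

#' Convert absorbance time series to rates
#'
#' For each well (grouped by mutant, substrate concentration and replicate),
#' the rate in M/min is the least-squares slope of absorbance versus time
#' divided by the standard-curve slope. Negative fitted slopes are clamped
#' to zero and flagged.
#'
#' @param timeseries Data frame with columns `mutant`, `substrate_mM`,
#'   `replicate`, `enzyme_mg_per_mL`, `time_min`, `absorbance`.
#' @param curve A [standard_curve()].
#' @return A `rate_dataset` data frame with an extra logical `clamped`
#'   column.
#' @export
absorbance_to_rates <- function(timeseries, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  need <- c("mutant", "substrate_mM", "replicate", "enzyme_mg_per_mL",
            "time_min", "absorbance")
  miss <- setdiff(need, names(timeseries))
  if (length(miss)) stop("timeseries missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(timeseries$absorbance))) stop("non-finite absorbances")
  key <- interaction(timeseries$mutant, timeseries$substrate_mM,
                     timeseries$replicate, drop = TRUE)
  rows <- lapply(split(timeseries, key), function(w) {
    if (nrow(w) < 3L) stop("need >= 3 time points per well")
    if (is.unsorted(w$time_min, strictly = TRUE)) {
      stop("time vector must be strictly increasing within a well")
    }
    sl <- coef(lm(absorbance ~ time_min, data = w))[["time_min"]]
    data.frame(mutant = w$mutant[1], substrate_mM = w$substrate_mM[1],
               replicate = w$replicate[1],
               rate_M_per_min = max(sl, 0) / curve$slope,
               enzyme_mg_per_mL = w$enzyme_mg_per_mL[1],
               clamped = sl < 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$clamped)) {
    warning(sum(out$clamped), " negative slope(s) clamped to zero")
  }
  class(out) <- c("rate_dataset", class(out))
  out
}

#' Model-selection rules for kinetic fitting
#'
#' @param lod Limit of detection for kcat/KM (M^-1 min^-1); fits below it
#'   are flagged `below_LOD`.
#' @param aicc_margin Substrate inhibition accepted only when it improves
#'   the small-sample-corrected information criterion by more than this.
#' @param km_saturation_factor "No clear saturation": fitted KM greater than
#'   this multiple of the largest tested concentration triggers the linear
#'   fallback.
#' @param km_rse_max Maximum relative standard error of KM before the linear
#'   fallback triggers.
#' @param n_starts Multi-start attempts (log-spaced perturbations of the
#'   initial guesses) for the nonlinear fits.
#' @param mw Enzyme molecular weight (g/mol) for the mg/mL to molar
#'   conversion.
#' @return List of class `kinetics_rules`.
#' @export
kinetics_rules <- function(lod = 10, aicc_margin = 2, km_saturation_factor = 2,
                           km_rse_max = 1, n_starts = 5, mw = 51573) {
  structure(list(lod = lod, aicc_margin = aicc_margin,
                 km_saturation_factor = km_saturation_factor,
                 km_rse_max = km_rse_max, n_starts = n_starts, mw = mw),
            class = "kinetics_rules")
}

.aicc <- function(rss, n, npar) {
  k <- npar + 1 # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1e-9)
}

# multi-start nonlinear least squares; returns best converged fit or NULL.
# Starting points are the supplied guesses perturbed by log-spaced factors,
# cycled per parameter so the attempts explore different directions.
.nls_multistart <- function(formula, data, start, lower, n_starts) {
  factors <- 10^seq(-0.6, 0.6, length.out = n_starts)
  best <- NULL
  for (i in seq_len(n_starts)) {
    st <- start
    for (j in seq_along(st)) {
      st[[j]] <- st[[j]] * factors[((i + j - 2L) %% n_starts) + 1L]
    }
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(formula, data = data, start = st,
                                         lower = lower,
                                         control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  best
}

#' Fit kinetic constants for one mutant
#'
#' Fits the Michaelis-Menten model `v = kcat E S / (KM + S)`, the substrate
#' inhibition model `v = kcat E S / (KM + S + S^2/Ki)`, and the first-order
#' linear model `v = (kcat/KM) E S` to the observed rates, then selects:
#' substrate inhibition only when it beats Michaelis-Menten by more than
#' `aicc_margin` information-criterion units; the linear fallback when no
#' clear saturation is seen (fitted KM beyond `km_saturation_factor` times
#' the largest tested concentration, KM relative standard error above
#' `km_rse_max`, or non-convergence); and `below_LOD` when the resulting
#' kcat/KM falls under the detection limit. Units: kcat min^-1, KM mM,
#' kcat/KM M^-1 min^-1 (the single mM-to-M factor of 1000 is applied there).
#'
#' @param observations Rows of a `rate_dataset` for a single mutant (a
#'   single enzyme concentration; replicates allowed).
#' @param rules A [kinetics_rules()].
#' @return Object of class `kinetic_constants`: fields `mutant`, `kcat`,
#'   `KM`, `Ki`, `kcat_over_KM`, `fit_kind`, `se` (named standard errors),
#'   `rss`, `aicc`, `n_obs`.
#' @export
fit_kinetics <- function(observations, rules = kinetics_rules()) {
  obs <- as.data.frame(observations)
  if (length(unique(obs$mutant)) != 1L) stop("one mutant at a time")
  if (length(unique(obs$enzyme_mg_per_mL)) != 1L) {
    stop("a single enzyme concentration per mutant is required")
  }
  S <- obs$substrate_mM
  v <- obs$rate_M_per_min
  if (length(unique(S[S > 0])) < 4L) {
    stop("need >= 4 distinct non-zero substrate concentrations")
  }
  E <- obs$enzyme_mg_per_mL[1] / rules$mw
  res <- list(mutant = obs$mutant[1], kcat = NA_real_, KM = NA_real_,
              Ki = NA_real_, kcat_over_KM = NA_real_, fit_kind = "below_LOD",
              se = c(kcat = NA_real_, KM = NA_real_, Ki = NA_real_,
                     kcat_over_KM = NA_real_),
              rss = NA_real_, aicc = NA_real_, n_obs = length(v))
  class(res) <- "kinetic_constants"
  if (all(v <= 0)) return(res)

  dat <- data.frame(S = S, v = v)
  kcat0 <- max(v) / E
  half <- max(v) / 2
  ord <- order(S)
  km0 <- tryCatch(stats::approx(v[ord], S[ord], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(S)
  fit_mm <- .nls_multistart(v ~ kcat * E * S / (KM + S), dat,
                            list(kcat = kcat0, KM = km0),
                            lower = c(1e-12, 1e-12), rules$n_starts)
  fit_si <- .nls_multistart(v ~ kcat * E * S / (KM + S + S^2 / Ki), dat,
                            list(kcat = kcat0, KM = km0, Ki = max(S)),
                            lower = c(1e-12, 1e-12, 1e-12), rules$n_starts)
  lin <- lm(v ~ 0 + S, data = dat)
  slope <- coef(lin)[["S"]]
  lin_eff <- 1000 * slope / E
  lin_se <- 1000 * summary(lin)$coefficients["S", "Std. Error"] / E

  choose_linear <- function(why) {
    res$fit_kind <<- "linear"
    res$kcat_over_KM <<- lin_eff
    res$se["kcat_over_KM"] <<- lin_se
    res$rss <<- sum(stats::resid(lin)^2)
    res$aicc <<- .aicc(res$rss, length(v), 1)
  }

  if (is.null(fit_mm) && is.null(fit_si)) {
    choose_linear("non-convergence")
  } else {
    n <- length(v)
    use_si <- if (is.null(fit_mm)) {
      TRUE
    } else if (is.null(fit_si)) {
      FALSE
    } else {
      .aicc(fit_si$rss, n, 3) < .aicc(fit_mm$rss, n, 2) - rules$aicc_margin
    }
    chosen <- if (use_si) fit_si else fit_mm
    cf <- coef(chosen$fit)
    ses <- tryCatch(summary(chosen$fit)$coefficients[, "Std. Error"],
                    error = function(e) rep(NA_real_, length(cf)))
    km_rse <- if (is.finite(ses[["KM"]]) && cf[["KM"]] > 0) {
      ses[["KM"]] / cf[["KM"]]
    } else {
      Inf
    }
    if (!use_si && (cf[["KM"]] > rules$km_saturation_factor * max(S) ||
                    km_rse > rules$km_rse_max)) {
      choose_linear("no clear saturation")
    } else {
      res$fit_kind <- if (use_si) "MM_substrate_inhibition" else "MM"
      res$kcat <- cf[["kcat"]]
      res$KM <- cf[["KM"]]
      if (use_si) res$Ki <- cf[["Ki"]]
      res$kcat_over_KM <- 1000 * res$kcat / res$KM
      res$se["kcat"] <- ses[["kcat"]]
      res$se["KM"] <- ses[["KM"]]
      if (use_si) res$se["Ki"] <- ses[["Ki"]]
      res$se["kcat_over_KM"] <- res$kcat_over_KM *
        sqrt((ses[["kcat"]] / cf[["kcat"]])^2 + (ses[["KM"]] / cf[["KM"]])^2)
      res$rss <- chosen$rss
      res$aicc <- .aicc(chosen$rss, n, if (use_si) 3 else 2)
    }
  }
  if (is.finite(res$kcat_over_KM) && res$kcat_over_KM < rules$lod) {
    res$fit_kind <- "below_LOD"
    res$kcat <- res$KM <- res$Ki <- res$kcat_over_KM <- NA_real_
    res$se[] <- NA_real_
  }
  res
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat(sprintf("<kinetic_constants> %s [%s] kcat=%s min^-1, KM=%s mM, kcat/KM=%s M^-1min^-1\n",
              x$mutant, x$fit_kind, signif(x$kcat, 3), signif(x$KM, 3),
              signif(x$kcat_over_KM, 3)))
  invisible(x)
}

#' Fit kinetic constants for every mutant in a dataset
#'
#' @param rates A `rate_dataset`.
#' @param rules A [kinetics_rules()].
#' @param yield Optional named vector of protein yields (mg/mL); mutants
#'   below `yield_lod` are marked `insoluble` and not fit.
#' @param yield_lod Solubility limit of detection (mg/mL).
#' @return Named list of [fit_kinetics()] results.
#' @export
fit_all_kinetics <- function(rates, rules = kinetics_rules(), yield = NULL,
                             yield_lod = 0.1) {
  out <- lapply(split(as.data.frame(rates), rates$mutant), function(obs) {
    id <- obs$mutant[1]
    if (!is.null(yield) && !is.na(yield[id]) && yield[id] < yield_lod) {
      res <- list(mutant = id, kcat = NA_real_, KM = NA_real_, Ki = NA_real_,
                  kcat_over_KM = NA_real_, fit_kind = "insoluble",
                  se = c(kcat = NA_real_, KM = NA_real_, Ki = NA_real_,
                         kcat_over_KM = NA_real_),
                  rss = NA_real_, aicc = NA_real_, n_obs = nrow(obs))
      class(res) <- "kinetic_constants"
      return(res)
    }
    fit_kinetics(obs, rules)
  })
  out[unique(rates$mutant)]
}

#' Tabulate fitted kinetic constants
#'
#' @param fits List of [fit_kinetics()] results.
#' @return Data frame with one row per mutant (constants, standard errors,
#'   fit kind and diagnostics).
#' @export
kinetics_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(mutant = f$mutant, fit_kind = f$fit_kind, kcat = f$kcat,
               KM = f$KM, Ki = f$Ki, kcat_over_KM = f$kcat_over_KM,
               se_kcat = f$se[["kcat"]], se_KM = f$se[["KM"]],
               se_kcat_over_KM = f$se[["kcat_over_KM"]], rss = f$rss,
               aicc = f$aicc, n_obs = f$n_obs, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
}

#' Log-scale constants relative to wild type
#'
#' log10(mutant/wild-type) for kcat and kcat/KM, and log10(wild-type
#' KM / mutant KM) for the 1/KM channel, so that a higher value is always a
#' "better" constant. Channels a mutant's fit kind cannot support are
#' flagged unmeasurable rather than numeric: a linear fit carries only
#' kcat/KM; below-detection and insoluble mutants carry nothing.
#'
#' @param mutant,wildtype [fit_kinetics()] results; the wild type must have
#'   a saturating (`MM`) fit.
#' @return Object of class `relative_constants`: numeric `log10_kcat`,
#'   `log10_inv_KM`, `log10_kcat_over_KM` plus a logical `measurable` vector
#'   and the mutant's `fit_kind`.
#' @export
relative_constants <- function(mutant, wildtype) {
  if (!wildtype$fit_kind %in% c("MM", "MM_substrate_inhibition")) {
    stop("wild-type reference must have a saturating Michaelis-Menten fit")
  }
  meas <- c(kcat = FALSE, inv_KM = FALSE, kcat_over_KM = FALSE)
  vals <- c(kcat = NA_real_, inv_KM = NA_real_, kcat_over_KM = NA_real_)
  if (mutant$fit_kind %in% c("MM", "MM_substrate_inhibition")) {
    vals["kcat"] <- log10(mutant$kcat / wildtype$kcat)
    vals["inv_KM"] <- log10(wildtype$KM / mutant$KM)
    vals["kcat_over_KM"] <- log10(mutant$kcat_over_KM / wildtype$kcat_over_KM)
    meas[] <- TRUE
  } else if (mutant$fit_kind == "linear") {
    vals["kcat_over_KM"] <- log10(mutant$kcat_over_KM / wildtype$kcat_over_KM)
    meas["kcat_over_KM"] <- TRUE
  }
  structure(list(mutant = mutant$mutant, fit_kind = mutant$fit_kind,
                 log10_kcat = vals[["kcat"]],
                 log10_inv_KM = vals[["inv_KM"]],
                 log10_kcat_over_KM = vals[["kcat_over_KM"]],
                 measurable = meas),
            class = "relative_constants")
}

#' Build the heatmap matrix of relative constants
#'
#' @param rel_list List of [relative_constants()] with unique mutant ids.
#' @return List with `values` (mutants x {kcat, inv_KM, kcat_over_KM} matrix
#'   of log10 ratios, `NA` where masked), `mask` (TRUE = unmeasurable) and
#'   `soluble` (annotation column).
#' @export
build_heatmap_matrix <- function(rel_list) {
  ids <- vapply(rel_list, function(r) r$mutant, character(1))
  if (anyDuplicated(ids)) stop("duplicate mutant ids")
  vals <- t(vapply(rel_list, function(r) {
    c(kcat = r$log10_kcat, inv_KM = r$log10_inv_KM,
      kcat_over_KM = r$log10_kcat_over_KM)
  }, numeric(3)))
  mask <- t(vapply(rel_list, function(r) !r$measurable, logical(3)))
  rownames(vals) <- rownames(mask) <- ids
  colnames(mask) <- colnames(vals)
  soluble <- vapply(rel_list, function(r) r$fit_kind != "insoluble", logical(1))
  names(soluble) <- ids
  list(values = vals, mask = mask, soluble = soluble)
}

#' Write / read the heatmap matrix CSV
#'
#' Masked cells are written as empty fields and read back as `NA` with the
#' mask reconstructed.
#'
#' @param hm Result of [build_heatmap_matrix()].
#' @param path CSV path.
#' @return `path` invisibly / the heatmap list.
#' @export
write_heatmap_csv <- function(hm, path) {
  df <- data.frame(mutant = rownames(hm$values), hm$values,
                   soluble = hm$soluble, row.names = NULL)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
read_heatmap_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, c("kcat", "inv_KM", "kcat_over_KM")])
  rownames(vals) <- df$mutant
  mask <- is.na(vals)
  soluble <- df$soluble
  names(soluble) <- df$mutant
  list(values = vals, mask = mask, soluble = soluble)
}
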