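# Synthetic-data module: generates every input the pipeline consumes --
# raw rate observations, toy structural model ensembles, and feature tables
# with a known sparse linear truth -- so all downstream stages are testable
# without external data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. A fixed `seed` makes
#' each generator a pure function of its configuration: the same config yields
#' bit-identical output.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_mutants Number of mutants to simulate.
#' @param substrate_concs Substrate concentrations in mM. Defaults to the
#'   seven-point pNPG dilution series used in the assay
#'   (100, 25, 6.25, 1.6, 0.4, 0.1, 0.02 mM); set `include_blank = TRUE` to
#'   append a 0 mM blank for an eight-point design.
#' @param n_replicates Technical replicates per (mutant, concentration);
#'   default 3 (triplicate assay).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal, mean-one) rate noise. 0 gives noiseless rates.
#' @param truth_kinetics Data frame with columns `mutant`, `kcat` (min^-1),
#'   `KM` (mM) and optionally `Ki` (mM, `NA` = no substrate inhibition).
#'   Defaults to [random_truth_kinetics()] over `n_mutants`.
#' @param feature_truth List with `n_features`, `support_size`,
#'   `weight_scale` and `noise_sd` controlling the sparse linear
#'   feature-regression truth (see [generate_feature_regression_data()]).
#' @param structure List with `n_models`, `n_residues`, `perturb_sd` (Angstrom
#'   coordinate jitter) and `energy_sd` controlling toy model ensembles.
#' @param enzyme_mg_per_ml Enzyme concentration used in the assay wells.
#' @param mw Enzyme molecular weight (g/mol) used to convert mg/mL to molar.
#' @param include_blank Append a 0 mM blank concentration.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_mutants = 90L,
                       substrate_concs = c(100, 25, 6.25, 1.6, 0.4, 0.1, 0.02),
                       n_replicates = 3L,
                       noise_cv = 0.05,
                       truth_kinetics = NULL,
                       feature_truth = list(n_features = 59L, support_size = 5L,
                                            weight_scale = 1, noise_sd = 0.5),
                       structure = list(n_models = 100L, n_residues = 30L,
                                        perturb_sd = 0.3, energy_sd = 5),
                       enzyme_mg_per_ml = 0.5,
                       mw = 51573,
                       include_blank = FALSE) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (any(substrate_concs <= 0)) {
    stop("all substrate concentrations must be > 0 (use include_blank for a 0 mM blank)")
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (n_replicates < 1L || n_mutants < 1L) stop("counts must be >= 1")
  if (enzyme_mg_per_ml <= 0 || mw <= 0) stop("enzyme concentration and mw must be > 0")
  if (include_blank) substrate_concs <- c(substrate_concs, 0)
  cfg <- list(seed = as.integer(seed), n_mutants = as.integer(n_mutants),
              substrate_concs = substrate_concs,
              n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
              truth_kinetics = truth_kinetics, feature_truth = feature_truth,
              structure = structure, enzyme_mg_per_ml = enzyme_mg_per_ml,
              mw = mw, include_blank = include_blank)
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate `expr` under a temporary RNG state so generators do not disturb
# (or depend on) the caller's random stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw per-mutant true kinetic constants
#'
#' Samples kcat and KM log-uniformly over the dynamic ranges observed across
#' the mutant panel (kcat 10--11,000 min^-1, KM 0.6--85 mM), independently of
#' each other, with an optional fraction of substrate-inhibited mutants.
#'
#' @param n_mutants Number of mutants.
#' @param seed Integer seed.
#' @param kcat_range,km_range Ranges sampled log-uniformly.
#' @param prop_inhibited Fraction of mutants given a finite Ki
#'   (log-uniform in `ki_range`).
#' @param ki_range Range for Ki when present (mM).
#' @return Data frame `mutant`, `kcat`, `KM`, `Ki` (`NA` where absent).
#' @export
random_truth_kinetics <- function(n_mutants, seed = 1L,
                                  kcat_range = c(10, 11000),
                                  km_range = c(0.6, 85),
                                  prop_inhibited = 0,
                                  ki_range = c(2, 50)) {
  with_local_seed(seed, {
    kcat <- exp(runif(n_mutants, log(kcat_range[1]), log(kcat_range[2])))
    km <- exp(runif(n_mutants, log(km_range[1]), log(km_range[2])))
    ki <- rep(NA_real_, n_mutants)
    n_inh <- round(prop_inhibited * n_mutants)
    if (n_inh > 0) {
      idx <- sample.int(n_mutants, n_inh)
      ki[idx] <- exp(runif(n_inh, log(ki_range[1]), log(ki_range[2])))
    }
    data.frame(mutant = sprintf("M%03d", seq_len(n_mutants)),
               kcat = kcat, KM = km, Ki = ki)
  })
}

#' Michaelis-Menten rate, with optional substrate inhibition
#'
#' v = kcat * E * S / (KM + S) without inhibition, or
#' v = kcat * E * S / (KM + S + S^2/Ki) with it. Units: S and KM in mM
#' (the ratio is unit-free), E molar, so v is in M/min.
#'
#' @param S Substrate concentration (mM), vectorised.
#' @param kcat Turnover number (min^-1).
#' @param KM Michaelis constant (mM).
#' @param E Enzyme concentration (M).
#' @param Ki Substrate-inhibition constant (mM) or `NA`/`NULL` for none.
#' @return Rate in M/min.
#' @export
mm_rate <- function(S, kcat, KM, E, Ki = NULL) {
  if (is.null(Ki) || is.na(Ki)) {
    kcat * E * S / (KM + S)
  } else {
    kcat * E * S / (KM + S + S^2 / Ki)
  }
}

#' Generate a synthetic rate dataset
#'
#' Simulates the plate assay: one observed rate per (mutant, substrate
#' concentration, replicate), with noiseless expectation given by [mm_rate()]
#' and multiplicative lognormal noise of coefficient of variation
#' `config$noise_cv`. The lognormal is parameterised to have mean exactly 1,
#' so noisy rates are unbiased and strictly positive.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `rate_dataset` with columns `mutant`,
#'   `substrate_mM`, `replicate`, `rate_M_per_min`, `enzyme_mg_per_mL`, and
#'   attributes `mw` and `truth` (the kinetics truth table used).
#' @export
generate_rate_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- config$truth_kinetics
  if (is.null(truth)) {
    truth <- random_truth_kinetics(config$n_mutants, seed = config$seed)
  }
  if (!all(c("mutant", "kcat", "KM") %in% names(truth))) {
    stop("truth_kinetics must have columns mutant, kcat, KM")
  }
  if (is.null(truth$Ki)) truth$Ki <- NA_real_
  if (any(truth$kcat <= 0) || any(truth$KM <= 0) ||
      any(!is.na(truth$Ki) & truth$Ki <= 0)) {
    stop("kinetic parameters must be positive")
  }
  E <- config$enzyme_mg_per_ml / config$mw
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      substrate_mM = config$substrate_concs,
                      mutant = truth$mutant,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("mutant", "substrate_mM", "replicate")]
  i <- match(grid$mutant, truth$mutant)
  v0 <- mm_rate(grid$substrate_mM, truth$kcat[i], truth$KM[i], E, NULL)
  inh <- !is.na(truth$Ki[i])
  if (any(inh)) {
    v0[inh] <- truth$kcat[i][inh] * E * grid$substrate_mM[inh] /
      (truth$KM[i][inh] + grid$substrate_mM[inh] +
         grid$substrate_mM[inh]^2 / truth$Ki[i][inh])
  }
  noise <- if (config$noise_cv > 0) {
    sdlog <- sqrt(log1p(config$noise_cv^2))
    with_local_seed(config$seed,
                    exp(rnorm(nrow(grid), mean = -sdlog^2 / 2, sd = sdlog)))
  } else {
    rep(1, nrow(grid))
  }
  out <- data.frame(mutant = grid$mutant, substrate_mM = grid$substrate_mM,
                    replicate = grid$replicate, rate_M_per_min = v0 * noise,
                    enzyme_mg_per_mL = config$enzyme_mg_per_ml)
  attr(out, "mw") <- config$mw
  attr(out, "truth") <- truth
  class(out) <- c("rate_dataset", class(out))
  out
}

#' Generate toy structural model ensembles
#'
#' For each mutant, builds `n_models` copies of an idealised helical
#' protein with a pyranose-like ligand docked beside it, applies independent
#' Gaussian coordinate jitter of standard deviation `perturb_sd` (Angstrom)
#' to each model, and attaches a scalar energy drawn from a normal
#' distribution (stand-in for an overall system score). `perturb_sd = 0`
#' yields identical models.
#'
#' @param config A [sim_config()]; the `structure` sub-list is used.
#' @return List of [model_ensemble()] objects, one per mutant.
#' @export
generate_structure_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- config$structure
  base <- toy_model(n_residues = st$n_residues)
  with_local_seed(config$seed + 1L, {
    lapply(seq_len(config$n_mutants), function(m) {
      id <- sprintf("M%03d", m)
      energies <- rnorm(st$n_models, mean = -600, sd = st$energy_sd)
      models <- lapply(seq_len(st$n_models), function(k) {
        mod <- base
        if (st$perturb_sd > 0) {
          n <- nrow(mod$atoms)
          mod$atoms$x <- mod$atoms$x + rnorm(n, sd = st$perturb_sd)
          mod$atoms$y <- mod$atoms$y + rnorm(n, sd = st$perturb_sd)
          mod$atoms$z <- mod$atoms$z + rnorm(n, sd = st$perturb_sd)
        }
        mod$energy <- energies[k]
        mod
      })
      model_ensemble(id, models)
    })
  })
}

#' Generate a feature table with sparse linear truth
#'
#' Draws an n x p matrix of independent standard-normal features, a sparse
#' coefficient vector (`support_size` nonzero entries of scale
#' `weight_scale`), and targets `y = X w + b + N(0, noise_sd^2)`.
#' The target is on the same log10 scale as the relative kinetic constants
#' the real pipeline regresses on.
#'
#' @param config A [sim_config()]; `n_mutants` and the `feature_truth`
#'   sub-list are used.
#' @return List with `features` (a `feature_table`), `targets` (numeric,
#'   named by mutant) and `truth` (list: `true_weights`, `true_intercept`,
#'   `true_support`).
#' @export
generate_feature_regression_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ft <- config$feature_truth
  p <- as.integer(ft$n_features)
  s <- as.integer(ft$support_size)
  if (s > p) stop("support_size must be <= n_features")
  n <- config$n_mutants
  with_local_seed(config$seed + 2L, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- feature_names(p)
    rownames(X) <- sprintf("M%03d", seq_len(n))
    support <- sort(sample.int(p, s))
    w <- numeric(p)
    w[support] <- ft$weight_scale * sample(c(-1, 1), s, replace = TRUE) *
      runif(s, 0.5, 1.5)
    names(w) <- colnames(X)
    b <- 0.25
    y <- drop(X %*% w) + b +
      if (ft$noise_sd > 0) rnorm(n, sd = ft$noise_sd) else 0
    names(y) <- rownames(X)
    tbl <- feature_table(X, provenance = rep("computed", p))
    truth <- list(true_weights = w, true_intercept = b,
                  true_support = colnames(X)[support])
    list(features = tbl, targets = y, truth = truth)
  })
}

#' Noise level achieving a target R-squared
#'
#' For independent standard-normal features and sparse weights `w`, the
#' signal variance is `sum(w^2)`; the Gaussian noise standard deviation that
#' makes `R^2 = var(signal)/(var(signal)+sd^2)` equal `r2` is returned.
#'
#' @param w True coefficient vector.
#' @param r2 Target fraction of target variance explained, in (0, 1).
#' @return Noise standard deviation.
#' @export
noise_sd_for_r2 <- function(w, r2) {
  stopifnot(r2 > 0, r2 < 1)
  sqrt(sum(w^2) * (1 - r2) / r2)
}

#' Write a rate dataset as CSV
#'
#' @param rates A `rate_dataset` (or compatible data frame).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_csv <- function(rates, path) {
  cols <- c("mutant", "substrate_mM", "replicate", "rate_M_per_min",
            "enzyme_mg_per_mL")
  write.csv(as.data.frame(rates)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a rate dataset from CSV
#'
#' @param path CSV written by [write_rate_csv()].
#' @param mw Enzyme molecular weight (g/mol) used downstream for the molar
#'   conversion.
#' @return A `rate_dataset` data frame.
#' @export
read_rate_csv <- function(path, mw = 51573) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mutant", "substrate_mM", "replicate", "rate_M_per_min",
            "enzyme_mg_per_mL")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("rate CSV missing columns: ", paste(miss, collapse = ", "))
  attr(out, "mw") <- mw
  class(out) <- c("rate_dataset", class(out))
  out
}
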