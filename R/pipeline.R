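# Pipeline orchestration: stages coupled only through CSV/JSON artifacts,
# a validated declarative config, deterministic seeds, and a run manifest
# written beside every stage's outputs.

.known_keys <- list(
  top = c("seed", "out_dir", "mw", "log_level", "simulate", "kinetics",
          "features", "ensemble"),
  simulate = c("n_mutants", "n_replicates", "noise_cv", "include_blank",
               "n_models", "n_residues", "perturb_sd", "energy_sd",
               "enzyme_mg_per_ml"),
  kinetics = c("lod", "aicc_margin", "km_saturation_factor", "km_rse_max",
               "n_starts", "yield_lod"),
  features = c("select_k", "n_points"),
  ensemble = c("scheme", "n_folds", "n_repeats", "bootstrap_multiple",
               "alpha", "inner_folds", "n_lambda", "lambda_ratio",
               "standardize"))

#' Pipeline configuration
#'
#' Builds and validates the declarative configuration driving
#' [run_pipeline()]. Unknown keys are rejected. Defaults mirror the study
#' design: triplicate rates at the seven-point dilution series, detection
#' limit 10 M^-1 min^-1, 10 lowest-energy models of 100, 10-fold
#' cross-validation repeated 1000 times.
#'
#' @param config Named list of overrides, or a path to a YAML file holding
#'   one.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "))
    }
  }
  check_keys(config, .known_keys$top, "top level")
  for (sec in c("simulate", "kinetics", "features", "ensemble")) {
    if (!is.null(config[[sec]])) check_keys(config[[sec]], .known_keys[[sec]], sec)
  }
  base <- list(seed = 1L, out_dir = "results", mw = 51573, log_level = "info",
               simulate = list(n_mutants = 90L, n_replicates = 3L,
                               noise_cv = 0.05, include_blank = FALSE,
                               n_models = 100L, n_residues = 30L,
                               perturb_sd = 0.3, energy_sd = 5,
                               enzyme_mg_per_ml = 0.5),
               kinetics = list(lod = 10, aicc_margin = 2,
                               km_saturation_factor = 2, km_rse_max = 1,
                               n_starts = 5, yield_lod = 0.1),
               features = list(select_k = 10L, n_points = 240L),
               ensemble = list(scheme = "repeated_kfold", n_folds = 10L,
                               n_repeats = 1000L, bootstrap_multiple = 2,
                               alpha = 0.5, inner_folds = 5L, n_lambda = 30L,
                               lambda_ratio = 1e-4, standardize = TRUE))
  for (k in names(config)) {
    if (is.list(base[[k]])) {
      for (kk in names(config[[k]])) base[[k]][[kk]] <- config[[k]][[kk]]
    } else {
      base[[k]] <- config[[k]]
    }
  }
  class(base) <- "pipeline_config"
  base
}

.log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(...)
}

# atomic writer: materialise via `writer(tmp)` then rename into place
.atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.write_manifest <- function(config, stage, outputs) {
  manifest <- list(stage = stage, seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   package_version = as.character(utils::packageVersion("kcatnet")),
                   outputs = basename(outputs))
  .atomic_write(file.path(config$out_dir, paste0("manifest_", stage, ".json")),
                function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE))
}

#' Run one pipeline stage
#'
#' Stages are independently invokable and couple only through the artifacts
#' under `config$out_dir`:
#' `simulate` writes `rates.csv`, `scores.csv`, `truth.json` and a
#' `structures/` directory of PDB model ensembles;
#' `fit-kinetics` turns `rates.csv` into `kinetics.csv` and `heatmap.csv`;
#' `extract-features` turns `structures/` + `scores.csv` into
#' `features.csv`; `screen` writes `screen.csv`; `train` writes per-channel
#' `predictions_<channel>.csv` and `ensemble_<channel>.json` plus
#' `weights.csv`; `report` writes `summary.json`. Outputs are written
#' atomically, with a stage manifest (config hash, seed, version) beside
#' them.
#'
#' @param stage One of `"simulate"`, `"fit-kinetics"`, `"extract-features"`,
#'   `"screen"`, `"train"`, `"report"`.
#' @param config A [pipeline_config()] (or list/YAML path coerced by it).
#' @return Invisibly, a character vector of the artifact paths written.
#' @export
run_pipeline <- function(stage = c("simulate", "fit-kinetics",
                                   "extract-features", "screen", "train",
                                   "report"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(stage,
                    "simulate" = .stage_simulate(config),
                    "fit-kinetics" = .stage_fit_kinetics(config),
                    "extract-features" = .stage_extract_features(config),
                    "screen" = .stage_screen(config),
                    "train" = .stage_train(config),
                    "report" = .stage_report(config))
  .write_manifest(config, stage, outputs)
  invisible(outputs)
}

.require_inputs <- function(config, files) {
  paths <- file.path(config$out_dir, files)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing stage input(s): ", paste(missing, collapse = ", "),
         " -- run the upstream stage first")
  }
  paths
}

.stage_simulate <- function(config) {
  sc <- config$simulate
  cfg <- sim_config(seed = config$seed, n_mutants = sc$n_mutants,
                    n_replicates = sc$n_replicates, noise_cv = sc$noise_cv,
                    structure = list(n_models = sc$n_models,
                                     n_residues = sc$n_residues,
                                     perturb_sd = sc$perturb_sd,
                                     energy_sd = sc$energy_sd),
                    enzyme_mg_per_ml = sc$enzyme_mg_per_ml, mw = config$mw,
                    include_blank = sc$include_blank)
  .log(config, "simulate: ", sc$n_mutants, " mutants, ", sc$n_models,
       " models each")
  rates <- generate_rate_data(cfg)
  ensembles <- generate_structure_set(cfg)
  out_rates <- file.path(config$out_dir, "rates.csv")
  .atomic_write(out_rates, function(p) write_rate_csv(rates, p))
  sdir <- file.path(config$out_dir, "structures")
  dir.create(sdir, showWarnings = FALSE)
  scores <- list()
  for (e in ensembles) {
    mdir <- file.path(sdir, e$mutant)
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(e$models)) {
      write_model_pdb(e$models[[i]], file.path(mdir, sprintf("model_%03d.pdb", i)))
    }
    scores[[e$mutant]] <- data.frame(
      mutant = e$mutant, model = seq_along(e$models),
      total_energy = vapply(e$models, function(m) m$energy, numeric(1)))
  }
  out_scores <- file.path(config$out_dir, "scores.csv")
  .atomic_write(out_scores, function(p) {
    write.csv(do.call(rbind, scores), p, row.names = FALSE)
  })
  out_truth <- file.path(config$out_dir, "truth.json")
  .atomic_write(out_truth, function(p) {
    jsonlite::write_json(attr(rates, "truth"), p, digits = NA, na = "null")
  })
  c(out_rates, out_scores, out_truth, sdir)
}

.stage_fit_kinetics <- function(config) {
  inp <- .require_inputs(config, "rates.csv")
  rates <- read_rate_csv(inp, mw = config$mw)
  kc <- config$kinetics
  rules <- kinetics_rules(lod = kc$lod, aicc_margin = kc$aicc_margin,
                          km_saturation_factor = kc$km_saturation_factor,
                          km_rse_max = kc$km_rse_max, n_starts = kc$n_starts,
                          mw = config$mw)
  fits <- fit_all_kinetics(rates, rules)
  .log(config, "fit-kinetics: ", length(fits), " mutants fit")
  tab <- kinetics_table(fits)
  out_kin <- file.path(config$out_dir, "kinetics.csv")
  .atomic_write(out_kin, function(p) write.csv(tab, p, row.names = FALSE))
  # reference = the mutant closest to the panel median efficiency among MM fits
  mm <- tab$fit_kind == "MM"
  if (!any(mm)) stop("no saturating fit available as wild-type reference")
  ref_id <- tab$mutant[mm][which.min(abs(log10(tab$kcat_over_KM[mm]) -
                                           median(log10(tab$kcat_over_KM[mm]))))]
  rel <- lapply(fits, relative_constants, wildtype = fits[[ref_id]])
  hm <- build_heatmap_matrix(rel)
  out_hm <- file.path(config$out_dir, "heatmap.csv")
  .atomic_write(out_hm, function(p) write_heatmap_csv(hm, p))
  c(out_kin, out_hm)
}

.stage_extract_features <- function(config) {
  .require_inputs(config, c("structures", "scores.csv"))
  scores <- read.csv(file.path(config$out_dir, "scores.csv"),
                     stringsAsFactors = FALSE)
  sdir <- file.path(config$out_dir, "structures")
  mutants <- sort(list.dirs(sdir, recursive = FALSE, full.names = FALSE))
  ensembles <- lapply(mutants, function(id) {
    pdbs <- sort(list.files(file.path(sdir, id), pattern = "\\.pdb$",
                            full.names = TRUE))
    en <- scores[scores$mutant == id, ]
    models <- lapply(seq_along(pdbs), function(i) {
      read_model_pdb(pdbs[i], energy = en$total_energy[en$model == i])
    })
    select_lowest_energy(model_ensemble(id, models),
                         k = min(config$features$select_k, length(models)))
  })
  .log(config, "extract-features: ", length(ensembles), " ensembles")
  tbl <- assemble_feature_table(ensembles, external_scores = scores,
                                n_points = config$features$n_points)
  out <- file.path(config$out_dir, "features.csv")
  # written directly: the provenance sidecar's name is derived from the
  # final path, so the pair cannot share one temp-and-rename
  write_feature_csv(tbl, out)
  out
}

.read_targets <- function(config) {
  hm <- read_heatmap_csv(file.path(config$out_dir, "heatmap.csv"))
  hm$values
}

.stage_screen <- function(config) {
  .require_inputs(config, c("features.csv", "heatmap.csv"))
  tbl <- read_feature_csv(file.path(config$out_dir, "features.csv"))
  targets <- .read_targets(config)
  rep <- single_feature_screen(tbl, targets)
  .log(config, "screen: ", nrow(rep), " feature-channel pairs")
  out <- file.path(config$out_dir, "screen.csv")
  .atomic_write(out, function(p) write_screen_csv(rep, p))
  out
}

.stage_train <- function(config) {
  .require_inputs(config, c("features.csv", "heatmap.csv"))
  tbl <- read_feature_csv(file.path(config$out_dir, "features.csv"))
  if (anyNA(tbl)) {
    bad <- which(is.na(unclass(tbl)), arr.ind = TRUE)
    stop("feature table contains NA cells: ",
         paste(sprintf("%s/%s", rownames(tbl)[bad[, 1]],
                       colnames(tbl)[bad[, 2]]), collapse = ", "))
  }
  targets <- .read_targets(config)
  ec <- config$ensemble
  outs <- character()
  wts <- list()
  for (ch in colnames(targets)) {
    y <- targets[, ch]
    ids <- intersect(rownames(tbl), names(y)[!is.na(y)])
    if (length(ids) < ec$n_folds) {
      .log(config, "train: skipping ", ch, " (too few measurable samples)")
      next
    }
    cfg <- ensemble_config(scheme = ec$scheme, n_folds = ec$n_folds,
                           n_repeats = ec$n_repeats,
                           bootstrap_multiple = ec$bootstrap_multiple,
                           seed = config$seed, alpha = ec$alpha,
                           inner_folds = ec$inner_folds,
                           n_lambda = ec$n_lambda,
                           lambda_ratio = ec$lambda_ratio,
                           standardize = ec$standardize)
    X <- unclass(tbl)[ids, , drop = FALSE]
    # constant columns carry no information and are dropped from training
    keep <- apply(X, 2, sd) > 0
    res <- if (ec$scheme == "repeated_kfold") {
      repeated_kfold_ensemble(X[, keep, drop = FALSE], y[ids], cfg)
    } else {
      bootstrap_ensemble(X[, keep, drop = FALSE], y[ids], cfg)
    }
    .log(config, "train[", ch, "]: n=", length(ids), " PCC=",
         round(res$performance_pcc, 3))
    pred_path <- file.path(config$out_dir, paste0("predictions_", ch, ".csv"))
    json_path <- file.path(config$out_dir, paste0("ensemble_", ch, ".json"))
    .atomic_write(pred_path, function(p) {
      write.csv(res$predictions, p, row.names = FALSE)
    })
    .atomic_write(json_path, function(p) {
      write_ensemble_result(res, json_path = p)
    })
    wts[[ch]] <- res$weights
    outs <- c(outs, pred_path, json_path)
  }
  if (length(wts)) {
    wpath <- file.path(config$out_dir, "weights.csv")
    .atomic_write(wpath, function(p) {
      write.csv(format_weight_table(wts), p, row.names = FALSE)
    })
    outs <- c(outs, wpath)
  }
  outs
}

.stage_report <- function(config) {
  summary <- list()
  kin <- file.path(config$out_dir, "kinetics.csv")
  if (file.exists(kin)) {
    tab <- read.csv(kin, stringsAsFactors = FALSE)
    summary$n_mutants <- nrow(tab)
    summary$fit_kinds <- as.list(table(tab$fit_kind))
  }
  for (ch in c("kcat", "inv_KM", "kcat_over_KM")) {
    jp <- file.path(config$out_dir, paste0("ensemble_", ch, ".json"))
    if (file.exists(jp)) {
      js <- jsonlite::read_json(jp)
      summary[[paste0("pcc_", ch)]] <- js$performance_pcc
    }
  }
  out <- file.path(config$out_dir, "summary.json")
  .atomic_write(out, function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
  })
  out
}
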