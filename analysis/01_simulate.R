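#!/usr/bin/env Rscript
# Stage 1: simulate the raw inputs of the study design -- triplicate rate
# observations at the seven-point substrate dilution series for a panel of
# mutants with known kinetic truth, plus a toy structural model ensemble
# (100 models per mutant, scored) mimicking the modelling stage.
#
# Everything downstream couples only through the files written to results/.

library(kcatnet)

cfg <- pipeline_config(list(
  seed = 1L, out_dir = "results",
  simulate = list(n_mutants = 40L, n_models = 20L, n_residues = 24L,
                  perturb_sd = 0.25, noise_cv = 0.05),
  features = list(select_k = 10L)))

paths <- run_pipeline("simulate", cfg)
rates <- read_rate_csv(file.path(cfg$out_dir, "rates.csv"))
cat(sprintf("simulated %d rate observations for %d mutants (%d models each)\n",
            nrow(rates), length(unique(rates$mutant)),
            cfg$simulate$n_models))
cat("artifacts:", paste(basename(paths), collapse = ", "), "\n")
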