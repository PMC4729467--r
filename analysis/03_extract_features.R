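#!/usr/bin/env Rscript
# Stage 3: per mutant, keep the 10 lowest-energy models of the ensemble and
# average the registered geometric features (non-local contacts, hydrogen
# bonds, ligand burial, packing) over them, merging the externally supplied
# score terms (here: the simulated total energy) with provenance tracking.

library(kcatnet)

cfg <- pipeline_config(list(seed = 1L, out_dir = "results",
                            features = list(select_k = 10L)))
run_pipeline("extract-features", cfg)

tbl <- read_feature_csv("results/features.csv")
prov <- attr(tbl, "provenance")
cat(sprintf("feature table: %d mutants x %d features (%d computed, %d external)\n",
            nrow(tbl), ncol(tbl), sum(prov == "computed"),
            sum(prov == "external")))
cat("feature ranges across mutants:\n")
rng <- t(apply(unclass(tbl), 2, range))
print(round(data.frame(min = rng[, 1], max = rng[, 2]), 3))
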