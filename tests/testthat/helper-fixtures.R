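# Fixture builders and independent brute-force oracles shared by the tests.

# minimal atoms data frame
make_atoms <- function(elety, resno, resid, x, y, z, element = NULL,
                       chain = "A", is_ligand = FALSE) {
  n <- length(elety)
  if (is.null(element)) element <- substr(gsub("[0-9]", "", elety), 1, 1)
  data.frame(eleno = seq_len(n), elety = elety, resno = resno, resid = resid,
             chain = rep_len(chain, n), x = x, y = y, z = z,
             element = element, is_ligand = rep_len(is_ligand, n),
             stringsAsFactors = FALSE)
}

# two single-atom glycine residues at a given sequence separation and
# spatial distance: known contact ground truth
two_residue_fixture <- function(separation = 9L, distance = 4.0) {
  structure_model(make_atoms(
    elety = c("CA", "CA"), resno = c(1L, 1L + separation),
    resid = "GLY", x = c(0, distance), y = c(0, 0), z = c(0, 0)))
}

# random compact chain of 1-2 heavy atoms per residue
random_fixture <- function(n_res = 20L, seed = 1L) {
  set.seed(seed)
  rows <- list()
  pos <- c(0, 0, 0)
  for (i in seq_len(n_res)) {
    step <- rnorm(3)
    pos <- pos + 3.8 * step / sqrt(sum(step^2))
    rows[[length(rows) + 1L]] <- make_atoms("CA", i, "GLY",
                                            pos[1], pos[2], pos[3])
    if (i %% 2 == 0) {
      off <- rnorm(3, sd = 0.8)
      rows[[length(rows) + 1L]] <- make_atoms("CB", i, "ALA",
                                              pos[1] + off[1], pos[2] + off[2],
                                              pos[3] + off[3])
    }
  }
  at <- do.call(rbind, rows)
  at$resid <- "GLY"
  at$eleno <- seq_len(nrow(at))
  structure_model(at)
}

# naive all-pairs contact oracle, independent of the package implementation
brute_contacts <- function(model, cutoff = 4.5, min_sep = 8L) {
  at <- model$atoms[model$atoms$element != "H" & !model$atoms$is_ligand, ]
  seen <- character()
  for (a in seq_len(nrow(at))) {
    for (b in seq_len(nrow(at))) {
      if (b <= a) next
      if (at$chain[a] != at$chain[b]) next
      if (abs(at$resno[a] - at$resno[b]) <= min_sep) next
      d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                  (at$z[a] - at$z[b])^2)
      if (d < cutoff) {
        seen <- union(seen, paste(sort(c(at$resno[a], at$resno[b])),
                                  collapse = "-"))
      }
    }
  }
  length(seen)
}

# uniformly random proper rotation
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# exhaustive objective-grid oracle for the elastic net: cyclic per-coordinate
# grid minimisation (step `step`) of the exact objective, intercept profiled
# out analytically (it is unpenalised)
grid_enet_oracle <- function(X, y, lambda, alpha, step = 1e-3, span = 3,
                             max_rounds = 200) {
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p)
  obj <- function(w) {
    b <- mean(y - X %*% w)
    r <- y - X %*% w - b
    sum(r^2) / (2 * n) + lambda * (alpha * sum(abs(w)) +
                                     (1 - alpha) / 2 * sum(w^2))
  }
  grid <- seq(-span, span, by = step)
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (j in seq_len(p)) {
      vals <- vapply(grid, function(g) {
        wj <- w; wj[j] <- g; obj(wj)
      }, numeric(1))
      best <- grid[which.min(vals)]
      if (abs(best - w[j]) > step / 2) {
        w[j] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(w = w, b = mean(y - X %*% w))
}

# enumeration oracle for the two-sided signed-rank p-value on already
# normalized differences
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(sums <= W + 1e-9), mean(sums >= W - 1e-9)))
}

# synthetic kinetic_constants object without fitting
fake_constants <- function(mutant, kcat = NA, KM = NA, Ki = NA,
                           fit_kind = "MM", kcat_over_KM = NULL) {
  if (is.null(kcat_over_KM)) {
    kcat_over_KM <- if (is.finite(kcat) && is.finite(KM)) 1000 * kcat / KM else NA_real_
  }
  structure(list(mutant = mutant, kcat = kcat, KM = KM, Ki = Ki,
                 kcat_over_KM = kcat_over_KM, fit_kind = fit_kind,
                 se = c(kcat = NA_real_, KM = NA_real_, Ki = NA_real_,
                        kcat_over_KM = NA_real_),
                 rss = NA_real_, aicc = NA_real_, n_obs = 21L),
            class = "kinetic_constants")
}

# sparse-truth regression data at a target R^2 (two-pass: draw the truth,
# then set the noise level from it)
gen_sparse_regression <- function(seed, n = 90L, p = 59L, support = 5L,
                                  r2 = 0.8) {
  base <- function(nsd) {
    generate_feature_regression_data(sim_config(
      seed = seed, n_mutants = n,
      feature_truth = list(n_features = p, support_size = support,
                           weight_scale = 1, noise_sd = nsd)))
  }
  d0 <- base(0)
  base(noise_sd_for_r2(d0$truth$true_weights, r2))
}
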