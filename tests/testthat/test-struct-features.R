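# Geometric feature operators against brute-force oracles and closed forms,
# plus model selection, table assembly and PDB round-trips.

test_that("lowest-energy selection is stable and validated", {
  mods <- lapply(1:20, function(i) {
    m <- toy_model(6, ligand = FALSE)
    m$energy <- 21 - i # energies 20..1 in input order
    m
  })
  ens <- select_lowest_energy(model_ensemble("m", mods), k = 5)
  expect_equal(sort(vapply(ens$models[ens$selection], function(m) m$energy,
                           numeric(1))), 1:5)
  # ties break by input order
  tied <- lapply(1:6, function(i) {
    m <- toy_model(6, ligand = FALSE); m$energy <- 7; m
  })
  expect_equal(select_lowest_energy(model_ensemble("t", tied), 3)$selection,
               1:3)
  expect_error(select_lowest_energy(model_ensemble("m", mods), 0), "k must")
  expect_error(select_lowest_energy(model_ensemble("m", mods), 21), "k must")
  noen <- model_ensemble("n", list(toy_model(6, ligand = FALSE)))
  expect_error(select_lowest_energy(noen, 1), "energy")
})

test_that("non-local contacts respect the strict >8 separation boundary", {
  expect_equal(nonlocal_contact_count(two_residue_fixture(9, 4.0)), 1L)
  expect_equal(nonlocal_contact_count(two_residue_fixture(8, 4.0)), 0L)
  expect_equal(nonlocal_contact_count(two_residue_fixture(9, 4.6)), 0L)
})

test_that("non-local contacts match the all-pairs brute-force oracle", {
  for (s in 1:10) {
    m <- random_fixture(n_res = 25, seed = s)
    expect_equal(nonlocal_contact_count(m), brute_contacts(m))
  }
})

test_that("hydrogen bond criteria: distance, angle, and heavy-atom fallback", {
  # idealised backbone N-H...O=C at 2.9 A, 180 degrees
  donor_pair <- function(ox, oy) {
    structure_model(make_atoms(
      elety = c("N", "H", "O"), resno = c(1, 1, 5), resid = "GLY",
      x = c(0, 1.0, ox), y = c(0, 0, oy), z = c(0, 0, 0),
      element = c("N", "H", "O")))
  }
  expect_equal(hydrogen_bonds(donor_pair(2.9, 0), "protein_all"), 1L)
  # beyond the 3.5 A cutoff
  expect_equal(hydrogen_bonds(donor_pair(4.0, 0), "protein_all"), 0L)
  # donor-H-acceptor angle 90 degrees at N-O 2.9 A
  expect_equal(hydrogen_bonds(donor_pair(1.0, 2.72), "protein_all"), 0L)
  # no hydrogens: heavy-atom distance plus typing decides
  no_h <- structure_model(make_atoms(
    elety = c("N", "O"), resno = c(1, 5), resid = "GLY",
    x = c(0, 2.9), y = 0, z = 0, element = c("N", "O")))
  expect_equal(hydrogen_bonds(no_h, "protein_all"), 1L)
  # polar contact scope uses the 3.8 A cutoff regardless of typing
  expect_equal(hydrogen_bonds(donor_pair(3.7, 0), "polar_contacts"), 1L)
  expect_equal(hydrogen_bonds(donor_pair(3.9, 0), "polar_contacts"), 0L)
})

test_that("unknown residues are skipped with a warning", {
  odd <- structure_model(make_atoms(
    elety = c("N", "O"), resno = c(1, 5), resid = c("XXX", "GLY"),
    x = c(0, 2.9), y = 0, z = 0, element = c("N", "O")))
  expect_warning(n <- hydrogen_bonds(odd, "protein_all"), "XXX")
  expect_equal(n, 0L)
})

test_that("SASA matches the closed form for an isolated atom and occludes", {
  lone <- structure_model(make_atoms("C1", 1, "LIG", 0, 0, 0,
                                     element = "C", is_ligand = TRUE))
  area <- sasa(lone, "all", probe = 1.4, n_points = 960)
  expect_equal(area, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)
  # two overlapping atoms: occlusion strictly reduces the total
  two <- structure_model(make_atoms(c("C1", "C2"), 1, "LIG",
                                    c(0, 2.0), 0, 0, element = "C",
                                    is_ligand = TRUE))
  expect_lt(sasa(two), 2 * area)
  # an atom caged by close neighbours is almost fully buried
  shell_pts <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                     z = c(-2, 0, 2)))
  shell_pts <- shell_pts[rowSums(shell_pts^2) > 0, ]
  cage <- structure_model(make_atoms(
    paste0("C", 1:(nrow(shell_pts) + 1)), 1, "LIG",
    c(0, shell_pts[, 1]), c(0, shell_pts[, 2]), c(0, shell_pts[, 3]),
    element = "C", is_ligand = TRUE))
  buried <- sasa(cage, subset = 1L, n_points = 960)
  expect_lt(buried / area, 0.01)
})

test_that("ligand burial fraction behaves at the extremes and stays in [0,1]", {
  far <- toy_model(16, ligand_offset = 50)
  expect_equal(delta_sasa_ligand(far), 0)
  near <- toy_model(16, ligand_offset = 3)
  d <- delta_sasa_ligand(near)
  expect_gt(d, 0)
  expect_lte(d, 1)
  # oracle: two direct SASA calls (independently canonicalized frames, so
  # agreement is up to sphere-sampling orientation)
  lig_only <- near
  lig_only$atoms <- lig_only$atoms[lig_only$atoms$is_ligand, ]
  expect_equal(d, 1 - sasa(near, "ligand") / sasa(lig_only, "all"),
               tolerance = 0.02)
  nol <- toy_model(10, ligand = FALSE)
  expect_error(delta_sasa_ligand(nol), "no ligand")
})

test_that("packing approaches 1 inside a dense lattice and is monotone", {
  # lattice spacing 2.0 < 2 * (r_C + margin): every shell point is occupied
  g <- expand.grid(x = seq(-12, 12, 2), y = seq(-12, 12, 2),
                   z = seq(-12, 12, 2))
  lat <- structure_model(make_atoms(
    paste0("C", seq_len(nrow(g))),
    resno = c(1L, rep(2L, nrow(g) - 1L)), resid = "ALA",
    x = g$x[order(rowSums(g^2))], y = g$y[order(rowSums(g^2))],
    z = g$z[order(rowSums(g^2))], element = "C"))
  # region = residue 1, the central atom: its 8 A shell lies inside the lattice
  expect_gt(packing_score(lat, region = 1L), 0.95)
  # removing pocket-filling ligand atoms strictly decreases packing
  m <- toy_model(16, ligand_offset = 2.5)
  with_l <- packing_score(m, region = 8L, include_ligand = TRUE)
  no_l <- packing_score(m, region = 8L, include_ligand = FALSE)
  expect_lt(no_l, with_l)
  expect_true(with_l >= 0 && with_l <= 1)
  expect_error(packing_score(m, region = 999L), "not found")
})

test_that("all geometric features are invariant under rigid transforms", {
  m <- toy_model(14)
  base <- compute_model_features(m, n_points = 120)
  set.seed(33)
  for (i in 1:3) {
    tm <- transform_model(m, random_rotation(), rnorm(3, sd = 20))
    expect_equal(compute_model_features(tm, n_points = 120), base,
                 tolerance = 1e-6)
  }
})

test_that("feature averaging over selected models is an honest mean", {
  cfg <- sim_config(seed = 13, n_mutants = 1,
                    structure = list(n_models = 4, n_residues = 12,
                                     perturb_sd = 0.25, energy_sd = 3))
  ens <- select_lowest_energy(generate_structure_set(cfg)[[1]], k = 3)
  tbl <- assemble_feature_table(list(ens), n_points = 120)
  oracle <- rowMeans(vapply(ens$selection, function(i) {
    compute_model_features(ens$models[[i]], n_points = 120)
  }, numeric(ncol(tbl))))
  expect_equal(unclass(tbl)[1, ], oracle)
  # identical models: the mean equals the single-model vector
  cfg0 <- sim_config(seed = 13, n_mutants = 1,
                     structure = list(n_models = 3, n_residues = 12,
                                      perturb_sd = 0, energy_sd = 3))
  ens0 <- select_lowest_energy(generate_structure_set(cfg0)[[1]], k = 3)
  tbl0 <- assemble_feature_table(list(ens0), n_points = 120)
  expect_equal(unclass(tbl0)[1, ],
               compute_model_features(ens0$models[[1]], n_points = 120))
})

test_that("external score terms merge with provenance and explicit NA", {
  cfg <- sim_config(seed = 14, n_mutants = 2,
                    structure = list(n_models = 3, n_residues = 10,
                                     perturb_sd = 0.1, energy_sd = 2))
  ens <- lapply(generate_structure_set(cfg), select_lowest_energy, k = 2)
  ext <- expand.grid(mutant = c("M001", "M002"), model = 1:3,
                     stringsAsFactors = FALSE)
  ext$total_energy <- seq_len(nrow(ext)) * 1.5
  tbl <- assemble_feature_table(ens, external_scores = ext, n_points = 120)
  prov <- attr(tbl, "provenance")
  expect_equal(unname(prov["total_energy"]), "external")
  expect_equal(unname(prov["nonlocal_contacts"]), "computed")
  # oracle for the external mean over the selected models
  sel <- ens[[1]]$selection
  expect_equal(unclass(tbl)["M001", "total_energy"],
               mean(ext$total_energy[ext$mutant == "M001" & ext$model %in% sel]))
  # a missing selected model yields NA with a warning
  expect_warning(
    tbl2 <- assemble_feature_table(ens, external_scores = ext[ext$model != sel[1] |
                                                                ext$mutant != "M001", ],
                                   n_points = 120),
    "missing")
  expect_true(is.na(unclass(tbl2)["M001", "total_energy"]))
  # name collisions between computed and external features are errors
  clash <- ext
  names(clash)[names(clash) == "total_energy"] <- "nonlocal_contacts"
  expect_error(assemble_feature_table(ens, external_scores = clash,
                                      n_points = 120), "collision")
})

test_that("models and feature tables round-trip through PDB and CSV", {
  m <- toy_model(8)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(m, pdb)
  back <- read_model_pdb(pdb, energy = -5)
  expect_equal(back$atoms$x, m$atoms$x, tolerance = 1e-3)
  expect_equal(back$atoms$resno, m$atoms$resno)
  expect_equal(back$atoms$is_ligand, m$atoms$is_ligand)
  expect_equal(back$energy, -5)
  expect_equal(nonlocal_contact_count(back), nonlocal_contact_count(m))

  X <- matrix(c(1.5, 2.5, 3.5, 4.5), 2, 2,
              dimnames = list(c("A", "B"), c("f1", "f2")))
  tbl <- feature_table(X, provenance = c("computed", "external"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(tbl, csv)
  got <- read_feature_csv(csv)
  expect_equal(unclass(got), unclass(tbl))
  expect_equal(attr(got, "provenance"), attr(tbl, "provenance"))
})
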