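# Structural feature extraction from model ensembles: lowest-energy model
# selection, geometric features (non-local contacts, hydrogen bonds, SASA,
# packing), merging with externally supplied score-term tables, and
# averaging across selected models.

#' Select the lowest-energy models of an ensemble
#'
#' Keeps the `k` models with the smallest supplied energies; ties are broken
#' stably by input order.
#'
#' @param ensemble A [model_ensemble()].
#' @param k Number of models to select (default 10, of typically 100).
#' @return The ensemble with its `selection` field set.
#' @export
select_lowest_energy <- function(ensemble, k = 10L) {
  stopifnot(inherits(ensemble, "model_ensemble"))
  n <- length(ensemble$models)
  if (k < 1L || k > n) stop("k must be in [1, number of models]")
  energies <- vapply(ensemble$models, function(m) m$energy, numeric(1))
  if (anyNA(energies)) stop("every model needs an energy before selection")
  ensemble$selection <- order(energies, seq_len(n))[seq_len(k)]
  ensemble
}

# ---- geometric features ----------------------------------------------------

# heavy (non-hydrogen) atoms, optionally protein-only
.heavy <- function(atoms, exclude_ligand = FALSE) {
  keep <- atoms$element != "H"
  if (exclude_ligand) keep <- keep & !atoms$is_ligand
  atoms[keep, , drop = FALSE]
}

#' Count non-local residue contacts
#'
#' Number of unordered residue pairs (same chain, sequence separation
#' strictly greater than `min_separation`) with any heavy-atom pair closer
#' than `cutoff`. The ligand is excluded.
#'
#' @param model A [structure_model()].
#' @param cutoff Heavy-atom contact distance (Angstrom); 4.5 is the
#'   conventional threshold.
#' @param min_separation Pairs must satisfy `|i - j| > min_separation`
#'   (default 8, i.e. "more than 8 sequence positions apart").
#' @return Integer count.
#' @export
nonlocal_contact_count <- function(model, cutoff = 4.5, min_separation = 8L) {
  at <- .heavy(model$atoms, exclude_ligand = TRUE)
  if (nrow(at) < 2L) return(0L)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  sep_ok <- outer(at$resno, at$resno, function(a, b) abs(a - b) > min_separation) &
    outer(at$chain, at$chain, "==")
  hit <- d < cutoff & sep_ok
  pairs <- unique(t(apply(which(hit, arr.ind = TRUE), 1L, function(ij) {
    sort(c(paste(at$chain[ij[1]], at$resno[ij[1]]),
           paste(at$chain[ij[2]], at$resno[ij[2]])))
  })))
  if (is.null(dim(pairs))) return(as.integer(length(pairs) > 0))
  nrow(pairs)
}

# side-chain donor atom names by residue; backbone N is a donor for all
# residues except proline
.sc_donors <- list(SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ",
                   ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
                   HIS = c("ND1", "NE2"), TRP = "NE1", CYS = "SG")
.known_res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
                "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
                "TYR", "VAL")

# donor/acceptor typing from atom names and residue templates; ligand
# oxygens and nitrogens are treated as both donors and acceptors
.hb_typing <- function(atoms) {
  donor <- rep(FALSE, nrow(atoms))
  acceptor <- rep(FALSE, nrow(atoms))
  prot <- !atoms$is_ligand
  unknown <- prot & !(atoms$resid %in% .known_res)
  if (any(unknown)) {
    warning("skipping residues of unknown type: ",
            paste(unique(atoms$resid[unknown]), collapse = ", "))
  }
  ok <- prot & !unknown
  donor[ok & atoms$elety == "N" & atoms$resid != "PRO"] <- TRUE
  for (res in names(.sc_donors)) {
    donor[ok & atoms$resid == res & atoms$elety %in% .sc_donors[[res]]] <- TRUE
  }
  acceptor[ok & atoms$element == "O"] <- TRUE
  acceptor[ok & atoms$resid == "HIS" & atoms$elety %in% c("ND1", "NE2")] <- TRUE
  lig <- atoms$is_ligand & atoms$element %in% c("O", "N")
  donor[lig] <- TRUE
  acceptor[lig] <- TRUE
  list(donor = donor, acceptor = acceptor)
}

#' Count hydrogen bonds or polar contacts
#'
#' Geometric criteria: donor--acceptor distance <= 3.5 Angstrom and, when the
#' donor carries an explicit hydrogen, a donor-H-acceptor angle >= 120
#' degrees for at least one such hydrogen; with no hydrogens in the model the
#' heavy-atom distance plus donor/acceptor typing alone decides. The
#' `polar_contacts` scope instead counts every N/O--N/O pair within the
#' polar-contact cutoff (3.8 Angstrom) regardless of typing. Pairs within a
#' single residue are never counted.
#'
#' @param model A [structure_model()].
#' @param scope `"protein_all"` (both partners protein), `"to_ligand"`
#'   (one partner protein, one ligand), or `"polar_contacts"`.
#' @param dist_cutoff,angle_cutoff,polar_cutoff Criteria knobs (Angstrom,
#'   degrees, Angstrom).
#' @return Integer count of unordered pairs.
#' @export
hydrogen_bonds <- function(model,
                           scope = c("protein_all", "to_ligand", "polar_contacts"),
                           dist_cutoff = 3.5, angle_cutoff = 120,
                           polar_cutoff = 3.8) {
  scope <- match.arg(scope)
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  res_key <- paste(at$chain, at$resno)
  if (scope == "polar_contacts") {
    polar <- which(at$element %in% c("N", "O"))
    if (length(polar) < 2L) return(0L)
    d <- as.matrix(stats::dist(xyz[polar, , drop = FALSE]))
    cnt <- 0L
    for (a in seq_along(polar)) {
      for (b in seq_along(polar)) {
        if (b <= a) next
        if (res_key[polar[a]] == res_key[polar[b]]) next
        if (d[a, b] <= polar_cutoff) cnt <- cnt + 1L
      }
    }
    return(cnt)
  }
  ty <- .hb_typing(at)
  hydro <- which(at$element == "H")
  cnt <- 0L
  for (i in which(ty$donor)) {
    for (j in which(ty$acceptor)) {
      if (i == j || res_key[i] == res_key[j]) next
      if (scope == "protein_all" && (at$is_ligand[i] || at$is_ligand[j])) next
      if (scope == "to_ligand" && (at$is_ligand[i] == at$is_ligand[j])) next
      # count each unordered partnership once even if both atoms are dual-typed
      if (ty$donor[j] && ty$acceptor[i] && j < i) next
      dv <- xyz[j, ] - xyz[i, ]
      if (sqrt(sum(dv^2)) > dist_cutoff) next
      if (length(hydro)) {
        # hydrogens bonded to this donor (within covalent range)
        hd <- hydro[sqrt(rowSums((xyz[hydro, , drop = FALSE] -
                                    matrix(xyz[i, ], length(hydro), 3,
                                           byrow = TRUE))^2)) < 1.3]
        if (length(hd)) {
          ok <- FALSE
          for (h in hd) {
            v1 <- xyz[i, ] - xyz[h, ]
            v2 <- xyz[j, ] - xyz[h, ]
            ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                       (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
            if (ang >= angle_cutoff) ok <- TRUE
          }
          if (!ok) next
        }
      }
      cnt <- cnt + 1L
    }
  }
  cnt
}

# deterministic golden-spiral unit vectors
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area
#'
#' Sphere-point (Shrake-Rupley style) sampling: each atom's accessible area
#' is the fraction of `n_points` deterministic golden-spiral points on its
#' probe-expanded sphere not occluded by any other atom, times the full
#' sphere area. Coordinates are first moved to a canonical molecular frame,
#' so the result is exactly invariant under rigid-body transforms of the
#' input.
#'
#' @param model A [structure_model()].
#' @param subset `"all"`, `"protein"`, `"ligand"`, `"hydrophobic"` (carbon
#'   and sulfur atoms), or a logical/integer index over atoms: the atoms
#'   whose areas are summed. All atoms of the model occlude.
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere sampling points per atom.
#' @return Total area in square Angstrom.
#' @export
sasa <- function(model, subset = "all", probe = 1.4, n_points = 960L) {
  at <- .heavy(model$atoms)
  if (!nrow(at)) stop("no heavy atoms")
  sel <- if (is.character(subset)) {
    switch(subset,
           all = rep(TRUE, nrow(at)),
           protein = !at$is_ligand,
           ligand = at$is_ligand,
           hydrophobic = at$element %in% c("C", "S") & !at$is_ligand,
           stop("unknown subset: ", subset))
  } else if (is.logical(subset)) {
    subset[model$atoms$element != "H"]
  } else {
    seq_len(nrow(model$atoms)) %in% subset & model$atoms$element != "H"
  }
  radii <- vdw_radius(at$element)
  xyz <- canonical_coords(as.matrix(at[, c("x", "y", "z")]))
  counts <- count_exposed_points(xyz, radii, fibonacci_sphere(n_points), probe)
  er <- radii + probe
  sum(4 * pi * er[sel]^2 * counts[sel] / n_points)
}

#' Fractional burial of the ligand surface on binding
#'
#' `1 - SASA(ligand in complex) / SASA(ligand isolated)`: 0 when the ligand
#' is fully exposed, approaching 1 when fully enclosed.
#'
#' @param model A [structure_model()] containing a ligand.
#' @inheritParams sasa
#' @return Fraction in `[0, 1]`.
#' @export
delta_sasa_ligand <- function(model, probe = 1.4, n_points = 960L) {
  if (!any(model$atoms$is_ligand)) stop("model has no ligand")
  at <- .heavy(model$atoms)
  lig <- at$is_ligand
  radii <- vdw_radius(at$element)
  # one canonical frame for both states, so a non-occluding protein leaves
  # the burial exactly zero
  xyz <- canonical_coords(as.matrix(at[, c("x", "y", "z")]))
  sphere <- fibonacci_sphere(n_points)
  er <- radii + probe
  in_complex <- count_exposed_points(xyz, radii, sphere, probe)[lig]
  alone <- count_exposed_points(xyz[lig, , drop = FALSE], radii[lig],
                                sphere, probe)
  area <- 4 * pi * er[lig]^2 / n_points
  complexed <- sum(area * in_complex)
  isolated <- sum(area * alone)
  if (isolated <= 0) stop("degenerate ligand: isolated SASA is zero")
  max(0, min(1, 1 - complexed / isolated))
}

#' Packing score (occupied-volume fraction)
#'
#' A cubic grid (0.7 Angstrom spacing, in the canonical molecular frame) is
#' laid over a shell within `shell` Angstrom of the region's heavy atoms; a
#' grid point is occupied if it falls inside any included atom's van der
#' Waals radius plus `margin`. The score is occupied/total grid points:
#' higher values mean fewer voids.
#'
#' @param model A [structure_model()].
#' @param region `"global"` or a residue number (the shell is then taken
#'   around that residue's heavy atoms).
#' @param include_ligand Count ligand atoms as occupiers (and region
#'   context).
#' @param spacing,shell,margin Grid spacing, shell radius and radius margin
#'   (Angstrom).
#' @return Fraction in `[0, 1]`.
#' @export
packing_score <- function(model, region = "global", include_ligand = TRUE,
                          spacing = 0.7, shell = 8, margin = 0.5) {
  at <- .heavy(model$atoms, exclude_ligand = !include_ligand)
  if (!nrow(at)) stop("no atoms to pack")
  xyz <- canonical_coords(as.matrix(at[, c("x", "y", "z")]))
  if (identical(region, "global")) {
    ridx <- seq_len(nrow(at))
  } else {
    ridx <- which(at$resno == region & !at$is_ligand)
    if (!length(ridx)) stop("region residue ", region, " not found")
  }
  rxyz <- xyz[ridx, , drop = FALSE]
  lo <- apply(rxyz, 2, min) - shell
  hi <- apply(rxyz, 2, max) + shell
  grid <- as.matrix(expand.grid(seq(lo[1], hi[1], by = spacing),
                                seq(lo[2], hi[2], by = spacing),
                                seq(lo[3], hi[3], by = spacing)))
  in_shell <- points_within(grid, rxyz, rep(shell, nrow(rxyz)))
  grid <- grid[in_shell, , drop = FALSE]
  if (!nrow(grid)) stop("empty packing region")
  occ <- points_within(grid, xyz, vdw_radius(at$element) + margin)
  sum(occ) / nrow(grid)
}

# ---- feature table ---------------------------------------------------------

#' Registered computed geometric features
#'
#' Returns the registry of features this package computes from coordinates,
#' as a data frame of name, description and the regions involved. Energy-type
#' score terms are never computed; they enter through an external score
#' table (provenance `"external"`).
#'
#' @param regions Named integer vector of residue numbers for regional
#'   packing features; `NULL` gives the three default site labels used by
#'   [default_regions()].
#' @return Data frame with columns `name`, `description`.
#' @export
feature_registry <- function(regions = NULL) {
  if (is.null(regions)) regions <- c(site_a = NA_integer_, site_b = NA_integer_,
                                     site_c = NA_integer_)
  base <- data.frame(
    name = c("nonlocal_contacts", "hbonds_total", "hbonds_to_ligand",
             "polar_contacts", "delta_sasa_ligand", "hydrophobic_sasa_per_res",
             "packing_no_ligand", "packing_with_ligand"),
    description = c(
      "count of residue pairs >8 apart in sequence with heavy atoms < 4.5 A",
      "protein-internal hydrogen bonds",
      "protein-ligand hydrogen bonds",
      "N/O-N/O pairs within 3.8 A",
      "fraction of ligand surface buried on binding",
      "carbon+sulfur SASA per residue, ligand absent",
      "global packing fraction, ligand absent",
      "global packing fraction, ligand present"),
    stringsAsFactors = FALSE)
  reg <- do.call(rbind, lapply(names(regions), function(nm) {
    data.frame(name = c(sprintf("packing_%s_no_ligand", nm),
                        sprintf("packing_%s_with_ligand", nm)),
               description = sprintf("packing within 8 A of residue %s, ligand %s",
                                     regions[[nm]], c("absent", "present")),
               stringsAsFactors = FALSE)
  }))
  rbind(base, reg)
}

#' Default regional-packing sites for a model
#'
#' Three residues spread along the chain (the quarter, mid and
#' three-quarter points of the protein's residue numbering), labelled
#' `site_a`, `site_b`, `site_c` -- stand-ins for naming catalytically
#' interesting residues when none are specified.
#'
#' @param model A [structure_model()].
#' @return Named integer vector of residue numbers.
#' @export
default_regions <- function(model) {
  resno <- sort(unique(model$atoms$resno[!model$atoms$is_ligand]))
  idx <- pmax(1L, round(length(resno) * c(0.25, 0.5, 0.75)))
  c(site_a = resno[idx[1]], site_b = resno[idx[2]], site_c = resno[idx[3]])
}

#' Feature names for a table of width p
#'
#' The computed registry names first, padded with generic filler columns
#' (stand-ins for score-term features) up to `p`.
#'
#' @param p Total number of features (e.g. 59).
#' @return Character vector of length `p`.
#' @export
feature_names <- function(p) {
  nm <- feature_registry()$name
  if (p <= length(nm)) return(nm[seq_len(p)])
  c(nm, sprintf("feat_%02d", seq_len(p - length(nm))))
}

#' Compute the registered feature vector for one model
#'
#' @param model A [structure_model()].
#' @param regions Named residue numbers for the regional packing features;
#'   `NULL` uses [default_regions()] of the model.
#' @param n_points Sphere points for SASA features.
#' @return Named numeric vector over the computed registry.
#' @export
compute_model_features <- function(model, regions = NULL, n_points = 240L) {
  if (is.null(regions)) regions <- default_regions(model)
  nres <- length(unique(model$atoms$resno[!model$atoms$is_ligand]))
  v <- c(
    nonlocal_contacts = as.numeric(nonlocal_contact_count(model)),
    hbonds_total = as.numeric(hydrogen_bonds(model, "protein_all")),
    hbonds_to_ligand = as.numeric(hydrogen_bonds(model, "to_ligand")),
    polar_contacts = as.numeric(hydrogen_bonds(model, "polar_contacts")),
    delta_sasa_ligand = delta_sasa_ligand(model, n_points = n_points),
    hydrophobic_sasa_per_res = {
      prot <- model
      prot$atoms <- prot$atoms[!prot$atoms$is_ligand, , drop = FALSE]
      sasa(prot, "hydrophobic", n_points = n_points) / nres
    },
    packing_no_ligand = packing_score(model, include_ligand = FALSE),
    packing_with_ligand = packing_score(model, include_ligand = TRUE)
  )
  for (nm in names(regions)) {
    v[sprintf("packing_%s_no_ligand", nm)] <-
      packing_score(model, regions[[nm]], include_ligand = FALSE)
    v[sprintf("packing_%s_with_ligand", nm)] <-
      packing_score(model, regions[[nm]], include_ligand = TRUE)
  }
  v
}

#' Construct a feature table
#'
#' @param x Numeric matrix, mutants x features, with dimnames.
#' @param provenance Character vector (`"computed"` or `"external"`) per
#'   feature column.
#' @return Object of class `feature_table` (a matrix with a `provenance`
#'   attribute).
#' @export
feature_table <- function(x, provenance = rep("computed", ncol(x))) {
  stopifnot(is.matrix(x), length(provenance) == ncol(x))
  if (is.null(colnames(x))) stop("feature table needs column names")
  names(provenance) <- colnames(x)
  attr(x, "provenance") <- provenance
  class(x) <- c("feature_table", class(x))
  x
}

#' Assemble the per-mutant feature table
#'
#' Each mutant's feature value is the mean over its selected models of the
#' per-model computed features, merged with columns of an optional external
#' score-term table (keyed by mutant and model index; averaged over the same
#' selected models). A selected model missing from the external table yields
#' an explicit `NA` with a warning; a name collision between computed and
#' external features is an error.
#'
#' @param ensembles List of [model_ensemble()]s with selections set.
#' @param external_scores Optional data frame with columns `mutant`, `model`
#'   and one column per score-term feature.
#' @param regions,n_points Passed to [compute_model_features()].
#' @return A [feature_table()].
#' @export
assemble_feature_table <- function(ensembles, external_scores = NULL,
                                   regions = NULL, n_points = 240L) {
  if (!length(ensembles)) stop("no ensembles")
  for (e in ensembles) {
    if (is.null(e$selection)) {
      stop("ensemble ", e$mutant, " has no selection; run select_lowest_energy()")
    }
  }
  rows <- lapply(ensembles, function(e) {
    per_model <- vapply(e$selection, function(i) {
      compute_model_features(e$models[[i]], regions = regions,
                             n_points = n_points)
    }, compute_model_features(e$models[[e$selection[1]]], regions = regions,
                              n_points = n_points) * 0)
    rowMeans(per_model)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(ensembles, function(e) e$mutant, character(1))
  prov <- rep("computed", ncol(X))
  if (!is.null(external_scores)) {
    extn <- setdiff(names(external_scores), c("mutant", "model"))
    clash <- intersect(extn, colnames(X))
    if (length(clash)) {
      stop("feature name collision with computed features: ",
           paste(clash, collapse = ", "))
    }
    ext <- matrix(NA_real_, nrow(X), length(extn),
                  dimnames = list(rownames(X), extn))
    for (e in ensembles) {
      sub <- external_scores[external_scores$mutant == e$mutant &
                               external_scores$model %in% e$selection, ,
                             drop = FALSE]
      if (nrow(sub) < length(e$selection)) {
        warning("external scores missing ", length(e$selection) - nrow(sub),
                " selected model(s) for ", e$mutant, "; NA recorded")
        next
      }
      ext[e$mutant, ] <- colMeans(as.matrix(sub[, extn, drop = FALSE]))
    }
    X <- cbind(X, ext)
    prov <- c(prov, rep("external", length(extn)))
  }
  feature_table(X, prov)
}

#' Write a feature table as CSV with a provenance sidecar
#'
#' @param tbl A [feature_table()].
#' @param path CSV output path; a `<path>.provenance.json` sidecar records
#'   per-feature provenance.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(tbl, path) {
  df <- data.frame(mutant = rownames(tbl), as.data.frame(unclass(tbl)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(attr(tbl, "provenance")),
                       paste0(path, ".provenance.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$mutant
  side <- paste0(path, ".provenance.json")
  if (file.exists(side)) {
    prov <- unlist(jsonlite::read_json(side))
    prov <- unname(prov[colnames(X)])
  } else {
    prov <- rep("computed", ncol(X))
  }
  feature_table(X, prov)
}
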