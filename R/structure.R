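# Structure containers and PDB input/output. Models hold atom-level
# coordinates for one protein plus (optionally) one ligand as a HETATM group,
# together with a supplied scalar energy used for lowest-energy selection.

#' Construct a structure model
#'
#' @param atoms Data frame with columns `eleno`, `elety` (atom name), `resno`
#'   (1-based residue index), `resid` (residue name), `chain`, `x`, `y`, `z`
#'   (Angstrom), `element`, `is_ligand` (logical).
#' @param energy Scalar score for the model (arbitrary units; supplied, not
#'   computed here).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, energy = NA_real_) {
  need <- c("eleno", "elety", "resno", "resid", "chain", "x", "y", "z",
            "element", "is_ligand")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }
  lig <- atoms[atoms$is_ligand, ]
  if (nrow(lig) && length(unique(paste(lig$chain, lig$resno))) > 1L) {
    stop("exactly one ligand group supported")
  }
  structure(list(atoms = atoms, energy = energy), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  np <- sum(!x$atoms$is_ligand)
  nl <- sum(x$atoms$is_ligand)
  cat(sprintf("<structure_model> %d protein atoms, %d ligand atoms, energy %s\n",
              np, nl, format(x$energy)))
  invisible(x)
}

#' Construct a model ensemble
#'
#' @param mutant Mutant identifier.
#' @param models List of [structure_model()] objects.
#' @param selection Integer indices of selected models (filled by
#'   [select_lowest_energy()]).
#' @return Object of class `model_ensemble`.
#' @export
model_ensemble <- function(mutant, models, selection = NULL) {
  stopifnot(is.character(mutant), length(mutant) == 1L)
  if (!all(vapply(models, inherits, logical(1), "structure_model"))) {
    stop("models must be structure_model objects")
  }
  if (!is.null(selection)) {
    stopifnot(all(selection >= 1L), all(selection <= length(models)))
  }
  structure(list(mutant = mutant, models = models, selection = selection),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %s: %d models, %s selected\n", x$mutant,
              length(x$models),
              if (is.null(x$selection)) "none" else length(x$selection)))
  invisible(x)
}

# Local helix frame offsets: (radial, tangential, axial) in Angstrom.
.backbone_offsets <- list(
  N  = c(-0.4, -1.1, -0.8),
  CA = c(0, 0, 0),
  C  = c(-0.3, 1.1, 0.8),
  O  = c(-1.0, 1.8, 1.2),
  CB = c(1.4, -0.4, 0.2)
)

#' Build an idealised toy protein-ligand model
#'
#' A helix-hairpin chain (N, CA, C, O, CB per residue; 100 degrees of twist
#' and 1.5 Angstrom of rise per residue on a 2.3 Angstrom radius, the second
#' half of the chain packed antiparallel against the first) with a
#' pyranose-like ligand (5 ring carbons, ring oxygen, and hydroxyl oxygens)
#' docked into the inter-helix groove. The hairpin gives sequence-distant
#' residue pairs in spatial contact. Toy geometry: adequate for exercising
#' contact, hydrogen-bond, surface-area and packing operators, not a model
#' of any real fold.
#'
#' @param n_residues Chain length.
#' @param ligand Include the ligand group.
#' @param ligand_offset Distance (Angstrom) from the first helix surface to
#'   the ligand centre; larger values move the ligand away from the protein.
#' @return A [structure_model()] (energy `NA`).
#' @export
toy_model <- function(n_residues = 30L, ligand = TRUE, ligand_offset = 3.0) {
  stopifnot(n_residues >= 2L)
  resnames <- rep(c("ALA", "SER", "LEU", "GLU", "THR", "GLY"),
                  length.out = n_residues)
  n1 <- ceiling(n_residues / 2)
  rows <- list()
  for (i in seq_len(n_residues)) {
    if (i <= n1) {
      th <- (i - 1) * 100 * pi / 180
      axis <- c(0, 0, 1.5 * (i - 1))
    } else {
      th <- -(i - n1 - 1) * 100 * pi / 180
      axis <- c(0, 5.6, 1.5 * (n1 - (i - n1)))
    }
    u <- c(cos(th), sin(th), 0)       # radial
    tg <- c(-sin(th), cos(th), 0)     # tangential
    ez <- c(0, 0, 1)
    ca <- 2.3 * u + axis
    atoms <- if (resnames[i] == "GLY") {
      .backbone_offsets[c("N", "CA", "C", "O")]
    } else {
      .backbone_offsets
    }
    for (a in names(atoms)) {
      off <- atoms[[a]]
      p <- ca + off[1] * u + off[2] * tg + off[3] * ez
      rows[[length(rows) + 1L]] <- data.frame(
        elety = a, resno = i, resid = resnames[i], chain = "A",
        x = p[1], y = p[2], z = p[3],
        element = substr(a, 1, 1), is_ligand = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  if (ligand) {
    mid <- 1.5 * (n1 - 1) / 2
    centre <- c(2.3 + ligand_offset, 2.8, mid)
    ring_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
    for (j in seq_along(ring_names)) {
      ang <- (j - 1) * pi / 3
      p <- centre + c(0, 1.45 * cos(ang), 1.45 * sin(ang))
      rows[[length(rows) + 1L]] <- data.frame(
        elety = ring_names[j], resno = n_residues + 1L, resid = "LIG",
        chain = "X", x = p[1], y = p[2], z = p[3],
        element = substr(ring_names[j], 1, 1), is_ligand = TRUE,
        stringsAsFactors = FALSE)
    }
    hyd <- c("O1", "O2", "O3", "O4")
    for (j in seq_along(hyd)) {
      ang <- (j - 1) * pi / 3 + pi / 6
      # hydroxyls splay outward, alternating toward/away from the helix
      p <- centre + c(if (j %% 2) -1.0 else 1.0, 2.6 * cos(ang), 2.6 * sin(ang))
      rows[[length(rows) + 1L]] <- data.frame(
        elety = hyd[j], resno = n_residues + 1L, resid = "LIG",
        chain = "X", x = p[1], y = p[2], z = p[3],
        element = "O", is_ligand = TRUE, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  structure_model(atoms[, c("eleno", "elety", "resno", "resid", "chain",
                            "x", "y", "z", "element", "is_ligand")])
}

#' Apply a rigid-body transform to a model
#'
#' @param model A [structure_model()].
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Length-3 translation (Angstrom).
#' @return Transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  model$atoms$x <- xyz[, 1] + translation[1]
  model$atoms$y <- xyz[, 2] + translation[2]
  model$atoms$z <- xyz[, 3] + translation[3]
  model
}

#' Write a model as a PDB file
#'
#' Standard ATOM/HETATM records (ligand atoms as HETATM), 1-based residue
#' numbering, via the bio3d writer.
#'
#' @param model A [structure_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  at <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$is_ligand, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, eleno = at$eleno,
                   elety = at$elety, chain = at$chain,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                   elesy = at$element)
  invisible(path)
}

#' Read a model from a PDB file
#'
#' HETATM records (excluding waters) form the ligand group. Insertion codes
#' are not supported and are rejected.
#'
#' @param path PDB file.
#' @param energy Scalar energy to attach (energies are metadata supplied
#'   alongside models, e.g. from a score table; PDB files do not carry them).
#' @return A [structure_model()].
#' @export
read_model_pdb <- function(path, energy = NA_real_) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported: ", path)
  }
  is_lig <- at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT"))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- gsub("[0-9']", "", substr(trimws(at$elety), 1, 1))
  }
  atoms <- data.frame(eleno = at$eleno, elety = trimws(at$elety),
                      resno = at$resno, resid = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      x = at$x, y = at$y, z = at$z,
                      element = toupper(trimws(elem)), is_ligand = is_lig,
                      stringsAsFactors = FALSE)
  structure_model(atoms, energy = energy)
}

# van der Waals radii (Angstrom) by element; unknown elements fall back to
# the default carbon-like radius with a warning.
.vdw_table <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(element, default = 1.70) {
  r <- .vdw_table[toupper(element)]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(element[is.na(r)]), collapse = ","),
            "; using default radius ", default)
    r[is.na(r)] <- default
  }
  unname(r)
}

# Canonical molecular frame: centre coordinates at the centroid and rotate
# onto the principal axes of the point cloud, with the sign of each axis
# fixed by the third moment of the projections (falling back to the largest
# projection when the skewness is degenerate) and handedness enforced.
# Any proper rigid-body transform of the input yields identical canonical
# coordinates, which makes grid- and sphere-sampled quantities exactly
# invariant under isometries.
canonical_coords <- function(xyz) {
  xyz <- as.matrix(xyz)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  axes <- ev$vectors # columns, decreasing eigenvalue
  for (k in 1:2) {
    pr <- xc %*% axes[, k]
    s3 <- sum(pr^3)
    s <- if (abs(s3) > 1e-8) sign(s3) else sign(pr[which.max(abs(pr))])
    if (s < 0) axes[, k] <- -axes[, k]
  }
  # right-handed third axis
  axes[, 3] <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
                 axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
                 axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  xc %*% axes
}
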