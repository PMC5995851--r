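# van der Waals radii (Angstrom) for SASA; Bondi-type set used by common
# accessibility programs. Override or extend via the `radii` argument.
default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                       P = 1.80, H = 1.20, SE = 1.90)

water_resids <- c("HOH", "WAT", "DOD", "H2O")

#' Atomic structure model
#'
#' Lightweight container for macromolecular coordinates: a data frame of
#' atoms with chain id, author residue numbering (+ insertion code),
#' residue and atom names, element symbol and xyz in Angstrom, plus
#' flags for heteroatoms and waters. Construct from a file with
#' [load_structure()] or directly from a data frame (synthetic fixtures).
#'
#' @param atoms Data frame with columns `chain`, `resno`, `ins`, `resid`,
#'   `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z`, and
#'   optionally `het` (logical) and `o` (occupancy).
#' @param source Provenance string.
#'
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "in-memory") {
  req <- c("chain", "resno", "ins", "resid", "elety", "elesy", "x", "y", "z")
  assert_that(all(req %in% names(atoms)),
              paste("`atoms` must contain columns:", paste(req, collapse = ", ")))
  assert_numeric(c(atoms$x, atoms$y, atoms$z), "coordinates")
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$water <- atoms$resid %in% water_resids
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  assert_that(!anyDuplicated(key),
              "duplicate (chain, residue, atom) keys after alternate-location resolution")
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure [%s]: %d atoms, chains %s, %d waters, %d het atoms\n",
              x$source, nrow(a), paste(unique(a$chain), collapse = ","),
              sum(a$water), sum(a$het & !a$water)))
  invisible(x)
}

#' Load a structure from a PDB or mmCIF file
#'
#' Parses via `bio3d` (`read.pdb`/`read.cif`), resolves alternate
#' locations to the highest-occupancy conformer, flags waters, and keeps
#' author residue numbering verbatim. Coordinates are in Angstrom.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A [structure_model()].
#' @export
load_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(switch(format,
           pdb = bio3d::read.pdb(path, verbose = FALSE),
           cif = bio3d::read.cif(path, verbose = FALSE))),
    error = function(e) stop_kaicdyn(
      sprintf("failed to parse %s as %s: %s", path, toupper(format),
              conditionMessage(e)),
      "kaicdyn_parse_error"))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0 || !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    stop_kaicdyn(sprintf("no valid atom records in %s (checked %d ATOM/HETATM rows)",
                         path, if (is.null(a)) 0L else nrow(a)),
                 "kaicdyn_parse_error")
  ins <- if (is.null(a$insert)) "" else ifelse(is.na(a$insert), "", a$insert)
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno, ins = ins, resid = a$resid,
    elety = a$elety,
    elesy = toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                           substr(gsub("[0-9']", "", a$elety), 1, 1), a$elesy)),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    o = ifelse(is.na(a$o), 1, a$o),
    alt = if (is.null(a$alt)) "" else ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE)
  # alternate locations: keep the highest-occupancy conformer per atom key
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  if (anyDuplicated(key)) {
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, ][!duplicated(key[ord]), ]
    atoms <- atoms[order(as.integer(rownames(atoms))), ]
  }
  atoms$alt <- NULL
  structure_model(atoms, source = basename(path))
}

#' Write a structure model to a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  assert_that(inherits(model, "structure_model"), "`model` must be a structure_model")
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, insert = a$ins,
                   chain = a$chain, elety = a$elety, elesy = a$elesy,
                   o = a$o, b = rep(0, nrow(a)))
  invisible(path)
}

#' Atom selection predicate
#'
#' @param atoms Atom names to keep (e.g. `c("N", "CA", "C", "O")`), or
#'   `NULL` for all.
#' @param chains Chain ids to keep, or `NULL` for all.
#' @param resno Residue numbers to keep, or `NULL` for all.
#' @param include_het Keep heteroatoms (default `FALSE`).
#' @param include_water Keep waters (default `FALSE`).
#' @return An object of class `atom_selection`.
#' @export
atom_selection <- function(atoms = NULL, chains = NULL, resno = NULL,
                           include_het = FALSE, include_water = FALSE) {
  structure(list(atoms = atoms, chains = chains, resno = resno,
                 include_het = include_het, include_water = include_water),
            class = "atom_selection")
}

#' Backbone atom selection (N, CA, C, O)
#' @inheritParams atom_selection
#' @return An `atom_selection` keeping protein backbone atoms.
#' @export
backbone_selection <- function(chains = NULL) {
  atom_selection(atoms = c("N", "CA", "C", "O"), chains = chains)
}

#' Apply a selection to a structure model
#'
#' @param model A [structure_model()].
#' @param sel An [atom_selection()]; `NULL` keeps everything except
#'   waters and heteroatoms.
#' @return The selected atoms as a data frame.
#' @export
select_atoms <- function(model, sel = NULL) {
  a <- model$atoms
  if (is.null(sel)) sel <- atom_selection()
  keep <- rep(TRUE, nrow(a))
  if (!sel$include_water) keep <- keep & !a$water
  if (!sel$include_het) keep <- keep & (!a$het | a$water & sel$include_water)
  if (!is.null(sel$atoms)) keep <- keep & a$elety %in% sel$atoms
  if (!is.null(sel$chains)) keep <- keep & a$chain %in% sel$chains
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  a[keep, , drop = FALSE]
}

#' Optimal rigid superposition and RMSD (Kabsch algorithm)
#'
#' Pairs atoms of two structures by (chain mapping, residue number +
#' insertion code, atom name) over the residues common to both, then
#' computes the least-squares optimal rotation and translation of `a`
#' onto `b` by singular value decomposition of the covariance matrix
#' (with the determinant correction that excludes reflections), and the
#' post-superposition RMSD.
#'
#' @param a,b [structure_model()] objects.
#' @param sel An [atom_selection()] applied to both structures; default
#'   backbone atoms (N, CA, C, O).
#' @param chain_map Named character vector mapping chains of `a` to
#'   chains of `b` (e.g. `c(A = "B")`). Default: first chain of `a` onto
#'   first chain of `b`.
#'
#' @return A list with `rotation` (3x3), `translation` (length 3; the
#'   transform maps centred `a` coordinates onto `b`), `rmsd` (Angstrom)
#'   and `n_atoms` (atoms paired).
#' @export
kabsch_rmsd <- function(a, b, sel = backbone_selection(), chain_map = NULL) {
  assert_that(inherits(a, "structure_model") && inherits(b, "structure_model"),
              "`a` and `b` must be structure_model objects")
  if (is.null(chain_map)) {
    chain_map <- setNames(unique(b$atoms$chain)[1], unique(a$atoms$chain)[1])
  }
  sa <- select_atoms(a, sel)
  sb <- select_atoms(b, sel)
  sa <- sa[sa$chain %in% names(chain_map), , drop = FALSE]
  sb <- sb[sb$chain %in% unname(chain_map), , drop = FALSE]
  key_a <- paste(unname(chain_map[sa$chain]), sa$resno, sa$ins, sa$elety)
  key_b <- paste(sb$chain, sb$resno, sb$ins, sb$elety)
  common <- intersect(key_a, key_b)
  if (length(common) == 0)
    stop_kaicdyn(sprintf(
      "no common atoms under chain mapping %s; %d atoms selected in a, %d in b",
      paste(names(chain_map), "->", unname(chain_map), collapse = ", "),
      nrow(sa), nrow(sb)),
      "kaicdyn_pairing_error")
  P <- as.matrix(sa[match(common, key_a), c("x", "y", "z")])
  Q <- as.matrix(sb[match(common, key_b), c("x", "y", "z")])
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- Qc - Pc %*% t(R)
  list(rotation = R, translation = as.numeric(cq - cp %*% t(R)),
       rmsd = sqrt(mean(rowSums(diff^2))), n_atoms = length(common))
}

# deterministic golden-spiral quadrature points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# core Shrake-Rupley: per-atom SASA for coordinate matrix xyz (n x 3) with
# vdW radii `rad`, probe radius `probe`, `n_points` quadrature points/atom.
# Neighbour search uses a cell list at the maximal contact cutoff.
shrake_rupley <- function(xyz, rad, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  rs <- rad + probe
  pts <- sphere_points(n_points)
  cutoff <- 2 * max(rs)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  bins <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb_keys <- paste(cell[i, 1] + offs[, 1], cell[i, 2] + offs[, 2],
                     cell[i, 3] + offs[, 3])
    cand <- unlist(bins[nb_keys], use.names = FALSE)
    cand <- cand[cand != i]
    if (length(cand)) {
      dx <- sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])
      d2 <- rowSums(dx^2)
      cand <- cand[d2 < (rs[i] + rs[cand])^2]
    }
    if (!length(cand)) { sasa[i] <- 4 * pi * rs[i]^2; next }
    P <- sweep(pts * rs[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in cand) {
      dx <- sweep(P[acc, , drop = FALSE], 2, xyz[j, ])
      acc[acc] <- rowSums(dx^2) > rs[j]^2
      if (!any(acc)) break
    }
    sasa[i] <- 4 * pi * rs[i]^2 * sum(acc) / n_points
  }
  sasa
}

sasa_atom_table <- function(model, include_het, radii) {
  a <- model$atoms
  keep <- !a$water & (include_het | !a$het)
  a <- a[keep, , drop = FALSE]
  assert_that(nrow(a) > 0, "no atoms left after het/water filtering")
  rad_table <- default_vdw_radii
  if (!is.null(radii)) rad_table[names(radii)] <- radii
  rad <- rad_table[a$elesy]
  if (any(is.na(rad))) {
    bad <- unique(a$elesy[is.na(rad)])
    stop_kaicdyn(sprintf(
      "no van der Waals radius for element(s) %s; supply `radii = c(%s = ...)`",
      paste(bad, collapse = ", "), bad[1]),
      "kaicdyn_radius_error")
  }
  list(atoms = a, rad = unname(rad))
}

#' Per-residue solvent-accessible surface area (Shrake--Rupley)
#'
#' Rolls a probe sphere (default 1.4 Angstrom, water) over every atom
#' using deterministic golden-spiral point quadrature (default 960
#' points/atom) and sums atomic SASA per residue (backbone plus side
#' chain). Waters are always excluded; other heteroatoms (e.g. bound
#' ATP) are excluded by default and can be included with
#' `include_het = TRUE` — both modes are worth reporting when comparing
#' against published values, since the treatment of nucleotides is often
#' unstated.
#'
#' @param model A [structure_model()].
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Quadrature points per atom (default 960).
#' @param include_het Include non-water heteroatoms as occluders and
#'   surface contributors.
#' @param radii Named numeric vector of van der Waals radii overriding or
#'   extending the built-in element table.
#'
#' @return An object of class `sasa_result`: a data frame with columns
#'   `chain`, `resno`, `ins`, `resid`, `sasa` (Angstrom^2); attributes
#'   `probe` and `n_points`.
#' @export
residue_sasa <- function(model, probe = 1.4, n_points = 960,
                         include_het = FALSE, radii = NULL) {
  assert_that(inherits(model, "structure_model"), "`model` must be a structure_model")
  assert_that(probe >= 0, "`probe` must be >= 0")
  tab <- sasa_atom_table(model, include_het, radii)
  sasa <- shrake_rupley(as.matrix(tab$atoms[, c("x", "y", "z")]),
                        tab$rad, probe, n_points)
  grp <- paste(tab$atoms$chain, tab$atoms$resno, tab$atoms$ins, sep = "\r")
  idx <- !duplicated(grp)
  out <- data.frame(chain = tab$atoms$chain[idx], resno = tab$atoms$resno[idx],
                    ins = tab$atoms$ins[idx], resid = tab$atoms$resid[idx],
                    sasa = as.numeric(tapply(sasa, factor(grp, levels = grp[idx]),
                                             sum)))
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  class(out) <- c("sasa_result", "data.frame")
  out
}

#' Interface burial of a residue upon assembly
#'
#' SASA of one residue computed twice with identical settings: in its
#' isolated chain and in the full assembly. The difference
#' `delta = isolated - assembly` is the area buried by the interfaces
#' the assembly forms around that residue; it is non-negative because
#' adding occluding atoms can only reduce accessibility.
#'
#' @param assembly A [structure_model()] of the full assembly (e.g. the
#'   hexamer).
#' @param chain Chain id of the residue.
#' @param resno Residue number (author numbering).
#' @param ins Insertion code (default `""`).
#' @inheritParams residue_sasa
#'
#' @return A list with `sasa_isolated`, `sasa_assembly` and `delta`
#'   (Angstrom^2).
#' @export
assembly_burial <- function(assembly, chain, resno, ins = "", probe = 1.4,
                            n_points = 960, include_het = FALSE, radii = NULL) {
  assert_that(inherits(assembly, "structure_model"),
              "`assembly` must be a structure_model")
  a <- assembly$atoms
  assert_that(chain %in% a$chain, sprintf("chain '%s' not present", chain))
  hit <- a$chain == chain & a$resno == resno & a$ins == ins
  if (!any(hit))
    stop_kaicdyn(sprintf("residue %s%s%s not found in chain %s",
                         resno, ins, "", chain),
                 "kaicdyn_selection_error")
  iso <- structure_model(a[a$chain == chain, , drop = FALSE],
                         source = paste0(assembly$source, ":", chain))
  res_of <- function(sr) {
    row <- sr[sr$chain == chain & sr$resno == resno & sr$ins == ins, ]
    assert_that(nrow(row) == 1L, "residue not present in SASA table")
    row$sasa
  }
  s_iso <- res_of(residue_sasa(iso, probe, n_points, include_het, radii))
  s_asm <- res_of(residue_sasa(assembly, probe, n_points, include_het, radii))
  list(sasa_isolated = s_iso, sasa_assembly = s_asm,
       delta = s_iso - s_asm)
}

#' Minimum distance from one atom to a selection
#'
#' Minimum Euclidean distance (Angstrom) from a named source atom to any
#' atom of a target chain or [atom_selection()] — e.g. from the Cb of a
#' probe residue to the closest atom of bound KaiB.
#'
#' @param model A [structure_model()].
#' @param chain,resno,atom Source atom address (author numbering).
#' @param ins Source insertion code (default `""`).
#' @param to Target: a chain id (character scalar) or an
#'   [atom_selection()].
#'
#' @return Minimum distance in Angstrom.
#' @export
min_distance <- function(model, chain, resno, atom, to, ins = "") {
  a <- model$atoms
  src <- a[a$chain == chain & a$resno == resno & a$ins == ins & a$elety == atom, ]
  if (nrow(src) != 1L)
    stop_kaicdyn(sprintf("source atom %s/%s%s/%s not found (or ambiguous)",
                         chain, resno, ins, atom),
                 "kaicdyn_selection_error")
  tgt <- if (inherits(to, "atom_selection")) select_atoms(model, to)
         else a[a$chain %in% to & !a$water, , drop = FALSE]
  assert_that(nrow(tgt) > 0, "target selection is empty")
  dx <- sweep(as.matrix(tgt[, c("x", "y", "z")]), 2,
              as.numeric(src[1, c("x", "y", "z")]))
  sqrt(min(rowSums(dx^2)))
}
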