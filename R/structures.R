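# Molecular structure containers and file readers/writers.

# Element-default PB radii (Angstrom) used when the input format carries none.
.default_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2,
                    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Standard atomic masses for the elements that occur in drug-like molecules.
.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904)

element_radius <- function(element) {
  r <- .default_radii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a molecule structure
#'
#' The common container for proteins and ligands: a table of atoms with
#' coordinates, element symbols, partial charges and radii, plus an optional
#' bond table.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `x`, `y`,
#'   `z`, `charge`, `radius`.  A logical `is_heavy` column is derived
#'   (element != "H") if absent.
#' @param bonds optional data.frame with columns `from`, `to`, `order`
#'   (atom serials and integer bond order).
#' @param id molecule identifier string.
#' @return An object of class `molecule_structure`.
#' @export
molecule_structure <- function(atoms, bonds = NULL, id = "mol") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("serial", "name", "element", "x", "y", "z", "charge", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atomic coordinates")
  if (any(atoms$element == "" | is.na(atoms$element)))
    stop("empty element symbols")
  if (any(!is.na(atoms$radius) & atoms$radius <= 0))
    stop("non-positive atomic radius")
  if (is.null(atoms$is_heavy))
    atoms$is_heavy <- toupper(atoms$element) != "H"
  if (!is.null(bonds)) {
    stopifnot(all(c("from", "to", "order") %in% names(bonds)))
    if (!all(c(bonds$from, bonds$to) %in% atoms$serial))
      stop("bond references atom serial not present in atom table")
  }
  structure(list(atoms = atoms, bonds = bonds, id = id),
            class = "molecule_structure")
}

#' @export
print.molecule_structure <- function(x, ...) {
  cat("<molecule_structure>", x$id, ":", nrow(x$atoms), "atoms (",
      sum(x$atoms$is_heavy), "heavy ),",
      if (is.null(x$bonds)) "no bond table" else paste(nrow(x$bonds), "bonds"),
      "\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param mol a `molecule_structure`.
#' @param heavy_only drop hydrogens.
#' @return numeric matrix with one row per atom, columns x/y/z (Angstrom).
#' @export
atom_coords <- function(mol, heavy_only = FALSE) {
  a <- mol$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Derive an element symbol from a PDB-style atom name, e.g. " CA " -> "C",
# "CL1" -> "CL".  Two-letter halogens are recognised; anything else takes the
# first alphabetic character.
.name_to_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "CA"),
               two, substr(nm, 1, 1))
  # protein atom names like "CA"/"NA" are alpha carbons / sodium only for
  # HETATMs; for safety prefer single letters C/N/O/S/P/H when they lead
  el[substr(nm, 1, 1) %in% c("C", "N", "O", "S", "P", "H") &
       !(two %in% c("CL", "BR"))] <-
    substr(nm, 1, 1)[substr(nm, 1, 1) %in% c("C", "N", "O", "S", "P", "H") &
                       !(two %in% c("CL", "BR"))]
  el
}

.from_bio3d <- function(pdb, id, has_pqr_fields) {
  a <- pdb$atom
  if (nrow(a) == 0) stop("empty structure: no atoms parsed")
  element <- a$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- .name_to_element(a$elety)
  element[is.na(element) | element == ""] <-
    .name_to_element(a$elety)[is.na(element) | element == ""]
  if (has_pqr_fields) {
    charge <- a$o
    radius <- a$b
  } else {
    warning("no charges/radii in input; using element-default radii and zero charge")
    charge <- rep(0, nrow(a))
    radius <- element_radius(element)
  }
  atoms <- data.frame(serial = a$eleno, name = a$elety, element = element,
                      x = a$x, y = a$y, z = a$z,
                      charge = charge, radius = radius,
                      stringsAsFactors = FALSE)
  molecule_structure(atoms, bonds = NULL, id = id)
}

.from_mol2 <- function(m, id) {
  a <- m$atom
  if (is.null(a) || nrow(a) == 0) stop("empty structure: no atoms parsed")
  element <- toupper(sub("\\..*$", "", a$elety))
  atoms <- data.frame(serial = a$eleno, name = a$elena, element = element,
                      x = a$x, y = a$y, z = a$z,
                      charge = if (is.null(a$charge)) 0 else a$charge,
                      radius = element_radius(element),
                      stringsAsFactors = FALSE)
  bonds <- NULL
  if (!is.null(m$bond) && nrow(m$bond) > 0) {
    ord <- suppressWarnings(as.integer(m$bond$type))
    ord[is.na(ord)] <- 1L # aromatic ("ar") and amide ("am") treated as order 1 ring/rigid bonds downstream
    bonds <- data.frame(from = m$bond$origin, to = m$bond$target, order = ord)
  }
  molecule_structure(atoms, bonds = bonds, id = id)
}

.from_sdf <- function(sdf, id) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0) stop("empty structure: no atoms parsed")
  element <- toupper(sub("_.*$", "", rownames(ab)))
  atoms <- data.frame(serial = seq_len(nrow(ab)),
                      name = rownames(ab), element = element,
                      x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      charge = 0, radius = element_radius(element),
                      stringsAsFactors = FALSE)
  bb <- ChemmineR::bondblock(sdf)
  bonds <- NULL
  if (!is.null(bb) && nrow(bb) > 0)
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  molecule_structure(atoms, bonds = bonds, id = id)
}

#' Read a molecular structure file
#'
#' Reads PDB, PQR, MOL2 or SDF files into a [molecule_structure()].  PQR input
#' populates per-atom partial charges and radii; plain PDB input falls back to
#' element-default radii and zero charge (with a warning) so that shape-only
#' workflows still run.  MOL2 and SDF input carry a bond table.
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"pqr"`, `"mol2"`, `"sdf"`, or `"auto"`
#'   (default; by file extension).
#' @param id molecule id; defaults to the file base name.
#' @return A `molecule_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr", "mol2", "sdf"),
                           id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "pqr", "mol2", "sdf", "sd"))
      stop("cannot infer format from extension '", ext, "'; pass format=")
    format <- if (ext == "sd") "sdf" else ext
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  switch(format,
         pdb  = .from_bio3d(bio3d::read.pdb(path), id, has_pqr_fields = FALSE),
         pqr  = .from_bio3d(bio3d::read.pqr(path), id, has_pqr_fields = TRUE),
         mol2 = .from_mol2(bio3d::read.mol2(path), id),
         sdf  = {
           set <- ChemmineR::read.SDFset(path)
           .from_sdf(set[[1]], id)
         })
}

#' Write a structure in the whitespace PQR dialect
#'
#' @param mol a `molecule_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(mol, path) {
  a <- mol$atoms
  lines <- sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
                   a$serial, substr(a$name, 1, 4), "LIG", "A", 1L,
                   a$x, a$y, a$z,
                   ifelse(is.na(a$charge), 0, a$charge),
                   ifelse(is.na(a$radius), element_radius(a$element), a$radius))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write one or more conformers as a multi-record SDF file
#'
#' @param mols a `molecule_structure` or a list of them (shared atom order).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule_structure")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms
    b <- mol$bonds
    nb <- if (is.null(b)) 0L else nrow(b)
    writeLines(c(mol$id, "  surfcomp", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nb), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nb > 0) {
      idx <- match(b$from, a$serial)
      jdx <- match(b$to, a$serial)
      writeLines(sprintf("%3d%3d%3d  0", idx, jdx, b$order), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
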