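# Conformer bookkeeping: multi-conformer sets, rotatable-bond counting and
# RMSD-based deduplication.

#' Construct a conformer set
#'
#' @param ligand_id ligand type identifier (e.g. `"AMP"`).
#' @param conformers list of [molecule_structure()] sharing atom order.
#' @return An object of class `conformer_set`.
#' @export
conformer_set <- function(ligand_id, conformers) {
  stopifnot(length(conformers) >= 1)
  n <- vapply(conformers, function(m) nrow(m$atoms), integer(1))
  if (length(unique(n)) != 1)
    stop("conformers differ in atom count")
  el <- vapply(conformers, function(m) paste(m$atoms$element, collapse = ""),
               character(1))
  if (length(unique(el)) != 1)
    stop("conformers differ in element sequence")
  structure(list(ligand_id = ligand_id, conformers = conformers),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat("<conformer_set>", x$ligand_id, ":", length(x$conformers),
      "conformers of", nrow(x$conformers[[1]]$atoms), "atoms\n")
  invisible(x)
}

#' @export
length.conformer_set <- function(x) length(x$conformers)

#' Read a multi-record SDF file as a conformer set
#'
#' @param path SDF file with one record per conformer.
#' @param ligand_id id for the set; defaults to the file base name.
#' @return A [conformer_set()].
#' @export
read_conformers <- function(path, ligand_id = NULL) {
  if (is.null(ligand_id)) ligand_id <- tools::file_path_sans_ext(basename(path))
  set <- ChemmineR::read.SDFset(path)
  if (length(set) == 0) stop("empty SDF file: ", path)
  confs <- lapply(seq_along(set@SDF), function(i)
    .from_sdf(set[[i]], id = paste0(ligand_id, "_c", i)))
  conformer_set(ligand_id, confs)
}

#' Count rotatable bonds
#'
#' A bond is rotatable when it is a single bond between two heavy atoms, does
#' not belong to a ring (i.e. it is a bridge of the heavy-atom bond graph),
#' and neither end is terminal (each end has at least two heavy neighbours).
#'
#' @param mol a `molecule_structure` with a bond table.
#' @return integer count.
#' @export
count_rotatable_bonds <- function(mol) {
  if (is.null(mol$bonds))
    stop("no bond table; read the molecule from a format with bonds (MOL2/SDF)")
  a <- mol$atoms
  heavy <- a$serial[a$is_heavy]
  b <- mol$bonds
  b <- b[b$from %in% heavy & b$to %in% heavy, , drop = FALSE]
  if (nrow(b) == 0) return(0L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(b$from), to = as.character(b$to)),
    directed = FALSE, vertices = data.frame(name = as.character(heavy)))
  deg <- igraph::degree(g)
  bridge_eids <- igraph::bridges(g)
  is_bridge <- rep(FALSE, nrow(b))
  is_bridge[as.integer(bridge_eids)] <- TRUE
  nonterminal <- deg[as.character(b$from)] >= 2 & deg[as.character(b$to)] >= 2
  sum(b$order == 1 & is_bridge & nonterminal)
}

# Best-fit (Kabsch-superposed) RMSD over heavy atoms of two conformers that
# share atom order.
conformer_rmsd <- function(ma, mb, heavy_only = TRUE) {
  xa <- atom_coords(ma, heavy_only = heavy_only)
  xb <- atom_coords(mb, heavy_only = heavy_only)
  bio3d::rmsd(as.vector(t(xa)), as.vector(t(xb)), fit = TRUE)
}

# RMSD threshold ladder keyed on rotatable-bond count.
.dedup_threshold <- function(n_rot) {
  if (n_rot <= 5) 0.5 else if (n_rot <= 10) 0.8 else 1.0
}

#' Deduplicate and cap a conformer set
#'
#' Greedy keep-first filtering: a conformer is dropped when its best-fit
#' heavy-atom RMSD to any already-kept conformer falls below a threshold that
#' depends on the ligand's flexibility -- 0.5 A for 0-5 rotatable bonds,
#' 0.8 A for 6-10, and 1.0 A for more than 10.  At most `max_keep` conformers
#' are retained.
#'
#' @param set a [conformer_set()].
#' @param max_keep maximum conformers retained (default 20).
#' @param threshold override the automatic RMSD cutoff (Angstrom).
#' @return A filtered `conformer_set`.
#' @export
filter_conformers <- function(set, max_keep = 20L, threshold = NULL) {
  stopifnot(inherits(set, "conformer_set"))
  if (is.null(threshold)) {
    first <- set$conformers[[1]]
    if (is.null(first$bonds)) {
      warning("no bond table; assuming a rigid ligand (0.5 A RMSD cutoff)")
      threshold <- 0.5
    } else {
      threshold <- .dedup_threshold(count_rotatable_bonds(first))
    }
  }
  kept <- list()
  for (cf in set$conformers) {
    if (length(kept) >= max_keep) break
    dup <- FALSE
    for (kc in kept) {
      if (conformer_rmsd(kc, cf) < threshold) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cf
  }
  conformer_set(set$ligand_id, kept)
}
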