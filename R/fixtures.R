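# Deterministic synthetic fixtures: toy molecules, complementary
# pocket-ligand pairs with known patch contacts, and active/decoy screening
# libraries.  Everything is a pure function of its spec (seeded), so tests
# and benchmarks need no external downloads.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' @param seed RNG seed; the same spec always yields bit-identical fixtures.
#' @param n_atoms atoms in generated ligand-sized molecules.
#' @param cavity_radius pocket cavity radius (Angstrom, >= 3).
#' @param noise_sigma positional jitter (Angstrom).
#' @param charge_pattern `"none"`, `"dipolar"` or `"random"`.
#' @param shape walk style for [make_molecule()]: `"blob"` (compact) or
#'   `"chain"` (extended).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_atoms = 20L, cavity_radius = 7.0,
                         noise_sigma = 0.2, charge_pattern = "dipolar",
                         shape = "blob") {
  stopifnot(n_atoms >= 1, cavity_radius >= 3)
  structure(list(seed = as.integer(seed), n_atoms = as.integer(n_atoms),
                 cavity_radius = cavity_radius, noise_sigma = noise_sigma,
                 charge_pattern = match.arg(charge_pattern,
                                            c("none", "dipolar", "random")),
                 shape = match.arg(shape, c("blob", "chain"))),
            class = "fixture_spec")
}

# Self-avoiding 1.5 A walk; blob walks branch from any placed atom, chain
# walks extend the last atom.  Optionally confined to an (axis-aligned)
# ellipsoid, which yields elongated, symmetry-free shapes.
.walk_positions <- function(n, shape, semi_axes = c(Inf, Inf, Inf)) {
  semi_axes <- rep_len(semi_axes, 3L)
  pos <- matrix(0, n, 3)
  parent <- integer(n)
  for (i in seq_len(n)[-1]) {
    for (try in 1:200) {
      base_i <- if (shape == "blob") sample.int(i - 1, 1) else i - 1L
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      cand <- pos[base_i, ] + 1.5 * dir
      d <- sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 3, byrow = TRUE))^2))
      if (min(d) >= 1.2 && sum((cand / semi_axes)^2) <= 1) break
    }
    pos[i, ] <- cand
    parent[i] <- base_i
  }
  list(pos = pos, parent = parent)
}

.assign_charges <- function(pos, pattern, magnitude = 0.3) {
  n <- nrow(pos)
  switch(pattern,
         none = rep(0, n),
         random = stats::runif(n, -0.5, 0.5),
         dipolar = ifelse(pos[, 3] > stats::median(pos[, 3]),
                          magnitude, -magnitude))
}

#' Generate a toy molecule
#'
#' A connected pseudo-molecule grown by a self-avoiding 1.5 A walk with a
#' C/N/O element cycle, element-default radii, optional charges and a bond
#' table along the walk.
#'
#' @param spec a [fixture_spec()].
#' @param id molecule id (default derived from the seed).
#' @return A `molecule_structure`.
#' @export
make_molecule <- function(spec, id = NULL) {
  if (is.null(id)) id <- paste0("mol_s", spec$seed)
  with_seed(spec$seed, {
    w <- .walk_positions(spec$n_atoms, spec$shape)
    pos <- w$pos
    if (spec$noise_sigma > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, spec$noise_sigma),
                          ncol = 3)
    el <- rep(c("C", "N", "O"), length.out = spec$n_atoms)
    atoms <- data.frame(serial = seq_len(spec$n_atoms),
                        name = paste0(el, seq_len(spec$n_atoms)),
                        element = el, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        charge = .assign_charges(pos, spec$charge_pattern),
                        radius = element_radius(el),
                        stringsAsFactors = FALSE)
    bonds <- if (spec$n_atoms > 1)
      data.frame(from = w$parent[-1], to = 2:spec$n_atoms, order = 1L)
    else NULL
    molecule_structure(atoms, bonds = bonds, id = id)
  })
}

#' Generate a complementary pocket-ligand pair
#'
#' Builds a toy complex: a shell of pseudo-atoms forming a hemispherical
#' cavity (the "protein") and a compact blob filling the cavity with a
#' surface gap of roughly 1.5-3 A (the "ligand"), with complementary
#' charges under the dipolar pattern (cavity wall positive, ligand
#' negative).  The full surface/patch/descriptor pipeline is then run on
#' both sides in the complex frame, and the native patch contacts at
#' `contact_cutoff` are recorded for recovery tests.
#'
#' @param spec a [fixture_spec()] (`cavity_radius >= 3`).
#' @param contact_cutoff native-contact cutoff (Angstrom, default 5).
#' @param params pipeline parameters, see [pipeline_params()].
#' @return list with `protein`, `ligand` (`molecule_structure`s), `pocket`
#'   and `ligand_patches` (descriptor-bearing `patch_set`s), `contacts`
#'   (a [contact_map()]) and `true_contacts` (its edge list).
#' @export
make_complementary_pair <- function(spec, contact_cutoff = 5.0,
                                    params = pipeline_params()) {
  stopifnot(spec$cavity_radius >= 3)
  pl <- with_seed(spec$seed, {
    # ligand: compact blob confined to an elongated ellipsoid inside the
    # cavity -- elongation breaks rotational symmetry, so the pocket groove
    # it imprints admits a well-defined patch correspondence
    ax <- pmax(c(spec$cavity_radius - 1.4, spec$cavity_radius - 2.8,
                 spec$cavity_radius - 3.4), 1.2)
    w <- .walk_positions(spec$n_atoms, "blob", semi_axes = ax)
    lpos <- w$pos
    lpos <- sweep(lpos, 2, colMeans(lpos))       # centre the blob in the cavity
    el <- rep(c("C", "N", "O"), length.out = spec$n_atoms)
    lcharge <- switch(spec$charge_pattern,
                      none = rep(0, spec$n_atoms),
                      random = stats::runif(spec$n_atoms, -0.5, 0.5),
                      dipolar = rep(-0.3, spec$n_atoms))
    ligand <- molecule_structure(
      data.frame(serial = seq_len(spec$n_atoms), name = paste0(el, seq_len(spec$n_atoms)),
                 element = el, x = lpos[, 1], y = lpos[, 2], z = lpos[, 3],
                 charge = lcharge, radius = element_radius(el),
                 stringsAsFactors = FALSE),
      bonds = data.frame(from = w$parent[-1], to = 2:spec$n_atoms, order = 1L),
      id = paste0("lig_s", spec$seed))

    # protein: single-layer wall that hugs the ligand surface at a gap of
    # ~2 A, with an opening (no atoms) at the top -- a snug complementary
    # pocket rather than a fixed sphere
    gap <- 2.0
    rw_nominal <- spec$cavity_radius + 1.7
    target_spacing <- 2.0
    n_sphere <- max(40L, round(4 * pi * rw_nominal^2 / target_spacing^2))
    dirs <- fibonacci_directions(n_sphere)
    dirs <- dirs[dirs[, 3] <= 0.55, , drop = FALSE]
    lrad <- element_radius(el)
    # outermost crossing of the ligand's Gaussian density isosurface along
    # each direction: the wall then tracks the true ligand surface at a
    # constant gap, giving locally parallel (complementary) surfaces
    tgrid <- seq(8, 0.2, by = -0.1)
    wall_r <- vapply(seq_len(nrow(dirs)), function(k) {
      ray <- outer(tgrid, dirs[k, ])
      rho <- rep(0, length(tgrid))
      for (i in seq_len(nrow(lpos))) {
        d2 <- rowSums(sweep(ray, 2, lpos[i, ])^2)
        rho <- rho + exp(-2.3 * (d2 - lrad[i]^2) / lrad[i]^2)
      }
      hit <- which(rho >= 1)
      ext <- if (length(hit)) tgrid[hit[1]] else 1.0
      min(max(ext + gap + 1.7, 4.2), rw_nominal + 1.5)
    }, numeric(1))
    wpos <- dirs * wall_r
    if (spec$noise_sigma > 0)
      wpos <- wpos + matrix(stats::rnorm(length(wpos), 0, spec$noise_sigma),
                            ncol = 3)
    nw <- nrow(wpos)
    wcharge <- switch(spec$charge_pattern,
                      none = rep(0, nw),
                      random = stats::runif(nw, -0.5, 0.5),
                      dipolar = rep(0.3, nw))
    protein <- molecule_structure(
      data.frame(serial = seq_len(nw), name = paste0("C", seq_len(nw)),
                 element = "C", x = wpos[, 1], y = wpos[, 2], z = wpos[, 3],
                 charge = wcharge, radius = 1.7, stringsAsFactors = FALSE),
      bonds = NULL, id = paste0("prot_s", spec$seed))
    list(protein = protein, ligand = ligand)
  })
  pocket <- pocket_patchset(pl$protein, center = pocket_center(pl$ligand),
                            params = params)
  ligp <- ligand_patchset(pl$ligand, params = params)
  cm <- contact_map(patch_centers(pocket), patch_centers(ligp),
                    cutoff = contact_cutoff)
  list(protein = pl$protein, ligand = pl$ligand,
       pocket = pocket, ligand_patches = ligp,
       contacts = cm, true_contacts = cm$edges, spec = spec)
}

#' Generate a labelled active/decoy screening library
#'
#' Actives are positional jitters of the cavity-filling ligand of a
#' complementary pair (each with `conformers_active` jittered conformers);
#' decoys share the atom count, element cycle and charge magnitudes but are
#' re-grown as extended chains (similar size, different shape).
#'
#' @param spec a [fixture_spec()].
#' @param n_actives,n_decoys library composition.
#' @param conformers_active,conformers_decoy conformers per entry.
#' @param jitter_sigma active jitter (Angstrom, <= 0.5).
#' @return list: `pair` (the generating [make_complementary_pair()] output)
#'   and `entries` -- a list whose elements carry `ligand_id`, `active` and
#'   a [conformer_set()].
#' @export
make_screening_set <- function(spec, n_actives = 5L, n_decoys = 45L,
                               conformers_active = 3L, conformers_decoy = 1L,
                               jitter_sigma = 0.3) {
  stopifnot(n_actives >= 1, n_decoys >= 1, jitter_sigma <= 0.5)
  pair <- make_complementary_pair(spec)
  base <- pair$ligand
  jitter_mol <- function(mol, sd, id) {
    a <- mol$atoms
    a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] +
      matrix(stats::rnorm(3 * nrow(a), 0, sd), ncol = 3)
    molecule_structure(a, bonds = mol$bonds, id = id)
  }
  entries <- with_seed(spec$seed + 10000L, {
    act <- lapply(seq_len(n_actives), function(i) {
      parent <- jitter_mol(base, jitter_sigma, sprintf("active_%02d", i))
      confs <- lapply(seq_len(conformers_active), function(j)
        jitter_mol(parent, jitter_sigma / 2, sprintf("active_%02d_c%d", i, j)))
      list(ligand_id = sprintf("active_%02d", i), active = TRUE,
           conformers = conformer_set(sprintf("active_%02d", i), confs))
    })
    dec <- lapply(seq_len(n_decoys), function(i) {
      w <- .walk_positions(spec$n_atoms, "chain")
      pos <- sweep(w$pos, 2, colMeans(w$pos))
      el <- rep(c("C", "N", "O"), length.out = spec$n_atoms)
      ch <- switch(spec$charge_pattern,
                   none = rep(0, spec$n_atoms),
                   random = stats::runif(spec$n_atoms, -0.5, 0.5),
                   dipolar = rep(-0.3, spec$n_atoms))
      mol <- molecule_structure(
        data.frame(serial = seq_len(spec$n_atoms),
                   name = paste0(el, seq_len(spec$n_atoms)), element = el,
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   charge = ch, radius = element_radius(el),
                   stringsAsFactors = FALSE),
        bonds = data.frame(from = w$parent[-1], to = 2:spec$n_atoms, order = 1L),
        id = sprintf("decoy_%02d", i))
      confs <- lapply(seq_len(conformers_decoy), function(j)
        jitter_mol(mol, jitter_sigma / 2, sprintf("decoy_%02d_c%d", i, j)))
      list(ligand_id = sprintf("decoy_%02d", i), active = FALSE,
           conformers = conformer_set(sprintf("decoy_%02d", i), confs))
    })
    c(act, dec)
  })
  list(pair = pair, entries = entries)
}

#' Build a rankable patch library from screening-set entries
#'
#' Runs the ligand surface/patch/descriptor pipeline on every conformer.
#'
#' @param entries the `entries` of [make_screening_set()].
#' @param params pipeline parameters, see [pipeline_params()].
#' @return library list as consumed by [rank_library()].
#' @export
build_library <- function(entries, params = pipeline_params()) {
  lapply(entries, function(entry) {
    confs <- lapply(entry$conformers$conformers, function(mol)
      tryCatch(ligand_patchset(mol, params = params),
               error = function(e) {
                 warning("conformer of ", entry$ligand_id, " skipped: ",
                         conditionMessage(e))
                 NULL
               }))
    list(ligand_id = entry$ligand_id, active = entry$active,
         conformers = Filter(Negate(is.null), confs))
  })
}

#' Write a fixture pair to disk
#'
#' PQR for the protein, SDF for the ligand, JSON for the recorded native
#' patch contacts.
#'
#' @param pair a [make_complementary_pair()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_fixture_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pqr(pair$protein, file.path(dir, "protein.pqr"))
  write_sdf(pair$ligand, file.path(dir, "ligand.sdf"))
  jsonlite::write_json(list(cutoff = pair$contacts$cutoff,
                            contacts = pair$true_contacts),
                       file.path(dir, "true_contacts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
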