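# Structure readers/writers, grids, and conformer bookkeeping.

test_that("PQR round-trip preserves coordinates, charges and radii", {
  mol <- make_molecule(fixture_spec(seed = 3, n_atoms = 6,
                                    charge_pattern = "random"))
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(mol, path)
  back <- read_structure(path, format = "pqr")
  expect_equal(atom_coords(back), atom_coords(mol), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$atoms$charge, mol$atoms$charge, tolerance = 1e-3)
  expect_equal(back$atoms$radius, mol$atoms$radius, tolerance = 1e-3)
  expect_true(all(back$atoms$is_heavy))
})

test_that("SDF multi-record files read as conformer sets with bonds", {
  spec <- fixture_spec(seed = 5, n_atoms = 8)
  m1 <- make_molecule(spec)
  m2 <- make_molecule(fixture_spec(seed = 6, n_atoms = 8))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(m1, m2), path)
  cs <- read_conformers(path, ligand_id = "TOY")
  expect_s3_class(cs, "conformer_set")
  expect_length(cs, 2)
  expect_equal(nrow(cs$conformers[[1]]$atoms), 8)
  expect_equal(cs$conformers[[1]]$atoms$element,
               cs$conformers[[2]]$atoms$element)
  expect_equal(atom_coords(cs$conformers[[1]]), atom_coords(m1),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(nrow(cs$conformers[[1]]$bonds), 7)
})

test_that("plain PDB input falls back to default radii with a warning", {
  mol <- single_atom()
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  C   LIG A   1       0.000   0.000",
                      "   0.000  1.00  0.00           C"),
               "END"), path)
  expect_warning(back <- read_structure(path, format = "pdb"),
                 "element-default")
  expect_equal(back$atoms$radius, 1.7)
  expect_equal(back$atoms$charge, 0)
})

test_that("OpenDX grids round-trip and reject corrupt files", {
  vals <- array(seq_len(24) / 10, dim = c(2, 3, 4))
  g <- scalar_grid3d(origin = c(-1, 0, 2), spacing = c(0.5, 0.5, 1), vals)
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx_grid(g, path)
  back <- read_dx_grid(path)
  expect_equal(back$dims, c(2L, 3L, 4L))
  expect_equal(back$origin, c(-1, 0, 2))
  expect_equal(back$spacing, c(0.5, 0.5, 1))
  expect_equal(back$values, g$values, tolerance = 1e-6)

  # truncate one value: corruption must be detected
  lines <- readLines(path)
  dataline <- max(grep("^[-0-9]", lines))
  lines[dataline] <- sub("\\s+\\S+$", "", lines[dataline])
  writeLines(lines, path)
  expect_error(read_dx_grid(path), "corrupt")
})

test_that("trilinear interpolation is exact for constant and linear fields", {
  ax <- seq(0, 2, by = 0.5)
  vals <- array(3.5, dim = c(5, 5, 5))
  g <- scalar_grid3d(c(0, 0, 0), 0.5, vals)
  p <- rbind(c(0.3, 1.1, 0.7), c(2, 2, 2), c(0, 0, 0))
  expect_equal(grid_interpolate(g, p), rep(3.5, 3))

  lin <- outer(outer(ax, 2 * ax, `+`), 3 * ax, `+`)
  gl <- scalar_grid3d(c(0, 0, 0), 0.5, lin)
  expect_equal(grid_interpolate(gl, p),
               p[, 1] + 2 * p[, 2] + 3 * p[, 3], tolerance = 1e-12)
  expect_error(grid_interpolate(gl, rbind(c(5, 0, 0))), "outside")
})

test_that("rotatable bond counting distinguishes chains, rings and terminals", {
  chain <- function(n, order = rep(1L, n - 1)) {
    el <- rep("C", n)
    molecule_structure(
      data.frame(serial = seq_len(n), name = paste0("C", seq_len(n)),
                 element = el, x = 1.5 * seq_len(n), y = 0, z = 0,
                 charge = 0, radius = 1.7),
      bonds = data.frame(from = seq_len(n - 1), to = 2:n, order = order),
      id = "chain")
  }
  expect_equal(count_rotatable_bonds(chain(2)), 0)  # ethane-like: terminal
  expect_equal(count_rotatable_bonds(chain(4)), 1)  # n-butane: one interior
  expect_equal(count_rotatable_bonds(chain(6)), 3)

  # benzene-like ring: all bonds cyclic
  ring <- molecule_structure(
    data.frame(serial = 1:6, name = paste0("C", 1:6), element = "C",
               x = cos(2 * pi * (0:5) / 6) * 1.4,
               y = sin(2 * pi * (0:5) / 6) * 1.4, z = 0,
               charge = 0, radius = 1.7),
    bonds = data.frame(from = 1:6, to = c(2:6, 1), order = 1L), id = "ring")
  expect_equal(count_rotatable_bonds(ring), 0)
  expect_error(count_rotatable_bonds(single_atom()), "bond")
})

test_that("conformer deduplication applies the flexibility-dependent cutoff", {
  spec <- fixture_spec(seed = 11, n_atoms = 8, noise_sigma = 0)
  base <- make_molecule(spec)
  # two identical conformers collapse to one
  cs <- conformer_set("dup", list(base, base))
  expect_length(filter_conformers(cs), 1)

  # jittered copy at RMSD ~0.9 A survives at the 1.0 A cutoff only when the
  # molecule is rigid enough; verify against the Kabsch oracle
  shift <- base
  shift$atoms$x <- shift$atoms$x + c(1.2, rep(0, 7))
  r <- kabsch_rmsd_oracle(atom_coords(base, TRUE), atom_coords(shift, TRUE))
  expect_equal(conformer_rmsd(base, shift), r, tolerance = 2e-3)
  cs2 <- conformer_set("pair", list(base, shift))
  kept_tight <- filter_conformers(cs2, threshold = r - 0.05)
  kept_loose <- filter_conformers(cs2, threshold = r + 0.05)
  expect_length(kept_tight, 2)
  expect_length(kept_loose, 1)
})

test_that("dedup caps the set at 20 and is idempotent", {
  mols <- lapply(1:25, function(s)
    make_molecule(fixture_spec(seed = 100 + s, n_atoms = 6)))
  cs <- conformer_set("many", mols)
  kept <- filter_conformers(cs)
  expect_lte(length(kept), 20)
  expect_equal(length(filter_conformers(kept)), length(kept))
})

test_that("dedup RMSD is invariant to rigid motion of one conformer", {
  base <- make_molecule(fixture_spec(seed = 21, n_atoms = 7))
  rot <- base
  xyz <- atom_coords(base)
  R <- with_seed(5, random_rotation())
  moved <- xyz %*% t(R)
  moved <- sweep(moved, 2, c(3, -2, 5), `+`)
  rot$atoms[, c("x", "y", "z")] <- moved
  expect_lt(conformer_rmsd(base, rot), 1e-6)
})
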