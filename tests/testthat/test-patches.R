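# Seed selection, patch segmentation, geodesics and APP vectors.

# A straight chain of surface points 1 A apart, with edges between
# consecutive points, doubles as a path-enumeration oracle.
chain_surface <- function(n = 12) {
  pts <- cbind(seq_len(n) - 1, 0, 0)
  normals <- matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE)
  edges <- data.frame(i = seq_len(n - 1), j = 2:n, length = 1)
  surface_point_cloud(pts, normals, edges, spacing = 1, source_id = "chain")
}

test_that("seed selection anchors to close atoms and enforces separation", {
  pair <- cached_pair()
  pk <- pair$pocket
  seeds <- pk$seeds
  p <- pk$surface$points[seeds, , drop = FALSE]
  if (length(seeds) > 1) {
    dmin <- min(stats::dist(p))
    expect_gte(dmin, 3.0)
  }
  # every seed is within d_atom of some heavy atom
  xyz <- atom_coords(pair$protein, heavy_only = TRUE)
  d2 <- outer(rowSums(p^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(p, xyz)
  expect_lte(max(sqrt(pmax(apply(d2, 1, min), 0))), 3.5 + 1e-9)
})

test_that("two atoms sharing a nearby surface point yield one seed", {
  surf <- chain_surface(5)
  mol <- molecule_structure(
    data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
               x = c(1.8, 2.2), y = 1, z = 0, charge = 0, radius = 1.7),
    id = "pairatoms")
  seeds <- select_seed_points(surf, mol, d_atom = 3.5, d_min = 3.0)
  expect_length(seeds, 1)
  expect_error(select_seed_points(surf, molecule_structure(
    data.frame(serial = 1L, name = "C1", element = "C", x = 0, y = 50, z = 0,
               charge = 0, radius = 1.7), id = "far")), "3.5")
})

test_that("patch membership follows geodesic distance on a chain", {
  surf <- chain_surface(12)
  ps <- segment_patches(surf, seeds = 1L, radius = 5.0)
  # points at 0..5 A along the chain: exactly 6 members
  expect_equal(sort(ps$patches[[1]]$point_ids), 1:6)
  # geodesic between chain ends via the path
  ps2 <- segment_patches(surf, seeds = c(1L, 8L), radius = 5.0)
  expect_equal(geodesic_matrix(ps2)[1, 2], 7)
  expect_equal(diag(geodesic_matrix(ps2)), c(0, 0))
})

test_that("patches stay within one connected component", {
  # two disjoint chains glued into one cloud
  pts <- rbind(cbind(0:4, 0, 0), cbind(0:4, 10, 0))
  normals <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  edges <- data.frame(i = c(1:4, 6:9), j = c(2:5, 7:10), length = 1)
  surf <- surface_point_cloud(pts, normals, edges, spacing = 1)
  ps <- segment_patches(surf, seeds = 1L, radius = 5.0)
  expect_true(all(ps$patches[[1]]$point_ids <= 5))
  # cross-component geodesics are infinite and flagged in APP's last bin
  ps2 <- segment_patches(surf, seeds = c(1L, 6L), radius = 5.0)
  expect_true(is.infinite(geodesic_matrix(ps2)[1, 2]))
  expect_warning(app <- app_vectors(ps2), "last")
  expect_equal(app[1, 40], 1)
})

test_that("geodesic dominates Euclidean and APP bins count the others", {
  pair <- cached_pair()
  ps <- pair$pocket
  g <- geodesic_matrix(ps)
  fin <- is.finite(g)
  expect_true(all(g[fin] >= ps$euclidean[fin] - 1e-6))
  app <- app_vectors(ps)
  expect_equal(dim(app), c(n_patches(ps), 40L))
  expect_true(all(rowSums(app) == n_patches(ps) - 1))
  # direct binning check on one pair
  ps2 <- segment_patches(chain_surface(10), seeds = c(1L, 6L), radius = 5)
  app2 <- app_vectors(ps2)
  expect_equal(app2[1, 6], 1)  # geodesic 5.0 -> bin index floor(5)+1
  expect_equal(sum(app2[1, ]), 1)
})

test_that("patch counts sit in the expected magnitude range", {
  pair <- cached_pair()
  expect_gte(n_patches(pair$pocket), 5)
  expect_lte(n_patches(pair$pocket), 60)
  expect_gte(n_patches(pair$ligand_patches), 5)
  expect_lte(n_patches(pair$ligand_patches), 60)
  # same ballpark as the published per-ligand-type averages
  hp <- huang_patch_summary()
  expect_true(n_patches(pair$ligand_patches) <
                3 * max(hp$avg_ligand_patches))
})

test_that("rigid motion leaves patch structure invariant", {
  mol <- make_molecule(fixture_spec(seed = 31, n_atoms = 8))
  p1 <- ligand_patchset(mol)

  # translation by multiples of the grid spacing: the surface discretization
  # commutes exactly, so patch structure is identical
  mov <- mol
  mov$atoms[, c("x", "y", "z")] <-
    sweep(atom_coords(mol), 2, c(2.0, -1.2, 0.8), `+`)
  p2 <- ligand_patchset(mov)
  expect_equal(n_patches(p1), n_patches(p2))
  expect_equal(geodesic_matrix(p1), geodesic_matrix(p2), tolerance = 1e-6)
  expect_equal(app_vectors(p1), app_vectors(p2))

  # arbitrary rotation: invariant up to surface re-discretization
  R <- with_seed(8, random_rotation())
  mov2 <- mol
  mov2$atoms[, c("x", "y", "z")] <- atom_coords(mol) %*% t(R)
  p3 <- ligand_patchset(mov2)
  expect_lte(abs(n_patches(p3) - n_patches(p1)), 2)
  g1 <- geodesic_matrix(p1); g3 <- geodesic_matrix(p3)
  expect_equal(mean(g3[is.finite(g3)]), mean(g1[is.finite(g1)]),
               tolerance = 0.1)
})
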