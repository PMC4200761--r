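# 3D Zernike descriptors: dimensionality, moment identities, invariances.

test_that("descriptor length counts (n, l) pairs with n - l even", {
  expect_equal(descriptor_length(0), 1)   # (0,0) only
  expect_equal(descriptor_length(2), 4)   # (0,0),(1,1),(2,0),(2,2)
  expect_equal(descriptor_length(15), 72)
  expect_error(descriptor_length(-1), "non-negative")
})

test_that("radial polynomials are orthonormal under the r^2 weight", {
  # exact monomial inner products; independent of the moment engine
  ip <- function(ca, cb) {
    s <- 0
    for (i in seq_along(ca$coef)) for (j in seq_along(cb$coef))
      s <- s + ca$coef[i] * cb$coef[j] / (ca$pow[i] + cb$pow[j] + 3)
    s
  }
  for (l in c(0, 3, 7)) {
    ns <- seq(l, 15, by = 2)
    for (n1 in ns) for (n2 in ns) {
      v <- ip(surfcomp:::.zernike_radial_coefs(n1, l),
              surfcomp:::.zernike_radial_coefs(n2, l))
      expect_equal(v, if (n1 == n2) 1 / 3 else 0, tolerance = 1e-6)
    }
  }
})

test_that("moments of a solid ball vanish for l > 0 and scale linearly", {
  dim <- 32L
  idx <- as.matrix(expand.grid(1:dim, 1:dim, 1:dim))
  U <- surfcomp:::.voxel_centers(idx, dim)
  keep <- sqrt(rowSums(U^2)) <= 0.95
  f <- structure(list(dim = dim, indices = idx[keep, ],
                      values = rep(1, sum(keep))),
                 class = "unit_sphere_function")
  mom <- zernike_moments(f, order = 8)
  Fv <- invariant_norms(mom)
  nl <- surfcomp:::nl_pairs(8)
  expect_lt(max(Fv[nl$l > 0]) / Fv[1], 0.05)
  # linearity: doubling the function doubles every moment exactly
  f2 <- f; f2$values <- 2 * f$values
  expect_equal(zernike_moments(f2, order = 8)$values, 2 * mom$values)
  # Omega_000 equals the brute-force voxel integral of f * conj(Z_000)
  r <- sqrt(rowSums(U[keep, ]^2))
  z000 <- surfcomp:::.zernike_radial_coefs(0, 0)$coef[1] * sqrt(1 / (4 * pi))
  direct <- 3 / (4 * pi) * (2 / dim)^3 * sum(z000 * rep(1, sum(keep)))
  expect_equal(Re(mom$values[1]), direct, tolerance = 1e-10)
  expect_equal(Im(mom$values[1]), 0, tolerance = 1e-12)
})

test_that("voxelization respects the unit-ball contract and channel split", {
  fx <- cap_patch_fixture()
  f <- voxelize_patch(fx$patch, fx$surface, channel = "shape")
  U <- surfcomp:::.voxel_centers(f$indices, f$dim)
  expect_lte(max(sqrt(rowSums(U^2))), 0.7 + sqrt(3) * 2 / f$dim)
  expect_lte(nrow(f$indices), length(fx$patch$point_ids))
  expect_true(all(f$values == 1))
  # all-negative potential leaves the positive channel empty
  neg_surface <- fx$surface
  neg_surface$potential <- -abs(neg_surface$potential) - 0.1
  fp <- voxelize_patch(fx$patch, neg_surface, channel = "elec_pos")
  expect_true(all(fp$values == 0))
  fn <- voxelize_patch(fx$patch, neg_surface, channel = "elec_neg")
  expect_true(all(fn$values > 0))
})

test_that("patch descriptors have the published dimensionality and are deterministic", {
  fx <- cap_patch_fixture()
  d <- patch_descriptor(fx$patch, fx$surface)
  expect_length(d$shape, 72)
  expect_length(d$elec_pos, 72)
  expect_length(d$elec_neg, 72)
  expect_equal(length(d$elec_pos) + length(d$elec_neg), 144)
  d2 <- patch_descriptor(fx$patch, fx$surface)
  expect_identical(d, d2)
  # zero potential: electrostatic channels vanish, shape does not
  flat <- fx$surface; flat$potential <- rep(0, nrow(flat$points))
  dz <- patch_descriptor(fx$patch, flat)
  expect_true(all(dz$elec_pos == 0) && all(dz$elec_neg == 0))
  expect_gt(sum(dz$shape), 0)
})

test_that("descriptors are rotation invariant within discretization error", {
  fx <- cap_patch_fixture()
  d0 <- patch_descriptor(fx$patch, fx$surface)
  rels <- with_seed(99, vapply(1:25, function(i) {
    R <- random_rotation()
    rot <- fx$surface
    rot$points <- fx$surface$points %*% t(R)
    d <- patch_descriptor(fx$patch, rot)
    sqrt(sum((d$shape - d0$shape)^2)) / sqrt(sum(d0$shape^2))
  }, numeric(1)))
  expect_lt(stats::median(rels), 0.05)
  expect_lt(max(rels), 0.15)
})

test_that("descriptors are invariant to uniform scaling and translation", {
  fx <- cap_patch_fixture()
  d0 <- patch_descriptor(fx$patch, fx$surface)
  big <- fx$surface; big$points <- fx$surface$points * 2.5
  db <- patch_descriptor(fx$patch, big)
  expect_lt(sqrt(sum((db$shape - d0$shape)^2)) / sqrt(sum(d0$shape^2)), 0.05)
  shifted <- fx$surface
  shifted$points <- sweep(fx$surface$points, 2, c(7, -4, 11), `+`)
  ds <- patch_descriptor(fx$patch, shifted)
  expect_equal(ds$shape, d0$shape, tolerance = 1e-12)
})
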