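# Shared fixtures and independent oracles for the test suite.

# Independent Kabsch superposition RMSD oracle (SVD-based, written apart from
# the bio3d-backed implementation path).
kabsch_rmsd_oracle <- function(xa, xb) {
  ca <- scale(xa, scale = FALSE)
  cb <- scale(xb, scale = FALSE)
  s <- svd(t(cb) %*% ca)               # H = P'Q with P moving, Q target
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((ca - cb %*% R)^2)))
}

# Exhaustive assignment oracle: minimum total cost over all injective row ->
# column maps (vectorized over the permutation list).
assignment_oracle <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  perm_rows <- function(n, r) {
    if (r == 1) return(matrix(seq_len(n), ncol = 1))
    sub <- perm_rows(n, r - 1)
    do.call(rbind, lapply(seq_len(n), function(v)
      cbind(v, sub[rowSums(sub == v) == 0, , drop = FALSE])))
  }
  p <- perm_rows(nc, nr)
  tot <- rowSums(matrix(cost[cbind(rep(seq_len(nr), each = nrow(p)),
                                   as.vector(p))],
                        nrow = nrow(p)))
  min(tot)
}

# Random rotation matrix from a quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
           2 * (q[2] * q[4] + q[1] * q[3]),
           2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
           2 * (q[3] * q[4] - q[1] * q[2]),
           2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
           1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
}

# Single-atom molecule (sphere surface fixture).
single_atom <- function(radius = 1.7, charge = 0) {
  molecule_structure(
    data.frame(serial = 1L, name = "C1", element = "C",
               x = 0, y = 0, z = 0, charge = charge, radius = radius),
    id = "atom")
}

# Small cached complementary pair so several test files can share one
# pipeline run.
.pair_cache <- new.env(parent = emptyenv())
cached_pair <- function(seed = 7L) {
  key <- paste0("s", seed)
  if (is.null(.pair_cache[[key]]))
    .pair_cache[[key]] <- make_complementary_pair(fixture_spec(seed = seed))
  .pair_cache[[key]]
}

# A hemispherical-cap point cloud with a synthetic potential, standing in
# for a surface patch in descriptor tests (no surface pipeline needed).
cap_patch_fixture <- function(n = 400, seed = 42) {
  with_seed(seed, {
    theta <- stats::runif(n, 0, pi / 2)
    phi <- stats::runif(n, 0, 2 * pi)
    pts <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta)) * 4
    pts <- pts + matrix(stats::rnorm(n * 3, 0, 0.1), ncol = 3)
    list(surface = list(points = pts, potential = pts[, 3] * 0.5),
         patch = list(id = 1L, seed = 1L, center = pts[1, ],
                      point_ids = seq_len(n)))
  })
}
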