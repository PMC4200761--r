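# Rotation-invariant 3D Zernike descriptors of surface patches.
#
# A patch is mapped into the unit ball (centroid-centred, farthest point at
# radius 0.7), voxelized on a cubic grid, and expanded in the Zernike-
# Canterakis basis Z_nlm(r, theta, phi) = R_nl(r) Y_lm(theta, phi) up to
# order n_max.  The per-(n, l) norms F_nl = sqrt(sum_m |Omega_nlm|^2) are
# invariant under rotation of the patch.

#' Number of (n, l) invariants for a given expansion order
#'
#' Counts pairs with `0 <= l <= n <= order` and `n - l` even; order 15 gives
#' the 72-component shape descriptor.
#'
#' @param order expansion order `n_max`.
#' @return integer count.
#' @export
descriptor_length <- function(order) {
  if (order < 0) stop("order must be non-negative")
  sum(seq.int(0L, order) %/% 2L + 1L)
}

# Table of (n, l) pairs, ordered n ascending then l ascending (memoized).
.zernike_cache <- new.env(parent = emptyenv())
nl_pairs <- function(order) {
  key <- paste0("nl", order)
  if (is.null(.zernike_cache[[key]]))
    .zernike_cache[[key]] <- do.call(rbind, lapply(0:order, function(n)
      data.frame(n = n, l = seq(n %% 2, n, by = 2))))
  .zernike_cache[[key]]
}

# Per-order basis bookkeeping: (n, l, m) index table, per-row radial
# coefficient sets, and the row -> (n, l) group map for norm collapsing.
.zernike_plan <- function(order) {
  key <- paste0("plan", order)
  if (is.null(.zernike_cache[[key]])) {
    nl <- nl_pairs(order)
    radial <- lapply(seq_len(nrow(nl)), function(i)
      .zernike_radial_coefs(nl$n[i], nl$l[i]))
    idx <- do.call(rbind, lapply(seq_len(nrow(nl)), function(i)
      data.frame(n = nl$n[i], l = nl$l[i], m = 0:nl$l[i], row = i)))
    .zernike_cache[[key]] <- list(nl = nl, radial = radial, idx = idx,
                                  group = idx$row, mult = ifelse(idx$m == 0, 1, 2))
  }
  .zernike_cache[[key]]
}

# Canterakis radial polynomial coefficients: R_nl(r) = sum_nu q_nu r^(l+2nu),
# orthogonalized so that \int_0^1 R_nl R_n'l r^2 dr = delta / 3.
.zernike_radial_coefs <- function(n, l) {
  k <- (n - l) %/% 2
  nu <- 0:k
  q <- ((-1)^k / 4^k) * sqrt((2 * l + 4 * k + 3) / 3) * choose(2 * k, k) *
    (-1)^nu * (choose(k, nu) * choose(2 * (k + l + nu) + 1, 2 * k)) /
    choose(k + l + nu, k)
  list(pow = l + 2 * nu, coef = q)
}

# Fully normalized associated Legendre functions \bar P_lm(x) for all
# 0 <= m <= l <= lmax, returned as a list indexed [[l+1]][[m+1]] of vectors.
# Normalization: \int |\bar P_lm(cos t) e^(i m phi)|^2 dOmega = 1.
.assoc_legendre_norm <- function(x, lmax) {
  sx <- sqrt(pmax(0, 1 - x^2))
  P <- lapply(0:lmax, function(l) vector("list", l + 1))
  P[[1]][[1]] <- rep(sqrt(1 / (4 * pi)), length(x))
  for (m in seq_len(lmax)) {
    P[[m + 1]][[m + 1]] <- -sqrt((2 * m + 1) / (2 * m)) * sx * P[[m]][[m]]
  }
  for (m in 0:(lmax - 1)) {
    P[[m + 2]][[m + 1]] <- sqrt(2 * m + 3) * x * P[[m + 1]][[m + 1]]
    if (m + 2 <= lmax) {
      for (l in (m + 2):lmax) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        P[[l + 1]][[m + 1]] <- a * (x * P[[l]][[m + 1]] - b * P[[l - 1]][[m + 1]])
      }
    }
  }
  P
}

# Core moment engine: complex Zernike moments for C value channels sampled
# at unit-ball coordinates U (Nv x 3), each sample carrying volume h^3.
# Returns index (n, l, m >= 0) plus real/imaginary sum matrices (rows index
# (n,l,m), columns channels).  Moments with m < 0 follow from conjugation
# for real-valued inputs.
.zernike_core <- function(U, Fv, order, h) {
  Fv <- cbind(Fv)
  plan <- .zernike_plan(order)
  r <- sqrt(rowSums(U^2))
  ct <- ifelse(r > 0, U[, 3] / r, 1)
  phi <- atan2(U[, 2], U[, 1])
  Pl <- .assoc_legendre_norm(ct, order)
  rpow <- outer(r, 0:order, `^`)
  cosm <- outer(phi, 0:order, function(p, m) cos(m * p))
  sinm <- outer(phi, 0:order, function(p, m) sin(m * p))
  idx <- plan$idx
  nb <- nrow(idx)
  nC <- ncol(Fv)
  nl <- plan$nl
  # group radial functions by degree l (shared across all m of that l);
  # conj(Y_lm) carries e^(-i m phi)
  scale <- 3 / (4 * pi) * h^3
  re <- matrix(0, nb, nC)
  im <- matrix(0, nb, nC)
  for (l in unique(nl$l)) {
    rows <- which(nl$l == l)
    Rl <- vapply(rows, function(i) {
      cf <- plan$radial[[i]]
      as.numeric(rpow[, cf$pow + 1, drop = FALSE] %*% cf$coef)
    }, numeric(nrow(U)))
    for (m in 0:l) {
      P <- Pl[[l + 1]][[m + 1]]
      tgt <- which(idx$l == l & idx$m == m)      # ordered like `rows`
      re[tgt, ] <- scale * crossprod(Rl, Fv * (P * cosm[, m + 1]))
      im[tgt, ] <- scale * crossprod(Rl, Fv * (-P * sinm[, m + 1]))
    }
  }
  list(index = idx[, c("n", "l", "m")], re = re, im = im)
}

#' Voxelize a patch channel into the unit ball
#'
#' Patch points are centred on their centroid and scaled so the farthest
#' point sits at radius 0.7, then binned into a cubic voxel grid spanning
#' `[-1, 1]^3`.  Channels: `shape` marks occupied voxels with 1;
#' `elec_pos` / `elec_neg` carry the positive part / magnitude of the
#' negative part of the surface potential (points in one voxel average).
#'
#' @param patch one element of a `patch_set`'s `patches` list.
#' @param surface the parent `surface_point_cloud`.
#' @param channel `"shape"`, `"elec_pos"` or `"elec_neg"`.
#' @param dim voxel grid dimension (default 64).
#' @return An object of class `unit_sphere_function` (sparse voxel list with
#'   `dim`, `indices`, `values`, `scale`, `offset`).
#' @export
voxelize_patch <- function(patch, surface, channel = c("shape", "elec_pos", "elec_neg"),
                           dim = 64L) {
  channel <- match.arg(channel)
  pts <- surface$points[patch$point_ids, , drop = FALSE]
  if (nrow(pts) < 3) stop("patch has fewer than 3 points")
  phi <- surface$potential[patch$point_ids]
  val <- switch(channel,
                shape = rep(1, nrow(pts)),
                elec_pos = pmax(phi, 0),
                elec_neg = pmax(-phi, 0))
  vox <- .voxel_bin(pts, val, dim, merge = if (channel == "shape") "max" else "mean")
  structure(list(dim = dim, indices = vox$indices, values = as.numeric(vox$values),
                 scale = vox$scale, offset = vox$offset, channel = channel),
            class = "unit_sphere_function")
}

# Shared voxel binning.  `val` may be a vector or a matrix (one column per
# channel); points landing in one voxel merge by mean (or max).
.voxel_bin <- function(pts, val, dim, merge = "mean", target_radius = 0.7) {
  val <- cbind(val)
  centroid <- colMeans(pts)
  u0 <- sweep(pts, 2, centroid)
  rmax <- sqrt(max(rowSums(u0^2)))
  if (rmax < 1e-9) stop("degenerate patch: all points identical")
  u <- u0 * (target_radius / rmax)
  h <- 2 / dim
  idx <- pmin(pmax(floor((u + 1) / h) + 1, 1), dim)
  key <- (idx[, 1] - 1) + dim * ((idx[, 2] - 1) + dim * (idx[, 3] - 1))
  ukey <- sort(unique(key))
  gi <- match(key, ukey)
  if (merge == "max") {
    out <- vapply(seq_len(ncol(val)), function(c)
      as.numeric(tapply(val[, c], gi, max)), numeric(length(ukey)))
  } else {
    out <- rowsum(val, gi) / tabulate(gi)
  }
  ui <- cbind(ukey %% dim, (ukey %/% dim) %% dim, ukey %/% (dim * dim)) + 1
  list(indices = ui, values = unname(cbind(out)),
       scale = target_radius / rmax, offset = centroid, h = h)
}

# Anti-aliased (trilinear-splat) voxel binning: each point distributes its
# channel values over its 8 neighbouring voxel centres with trilinear
# weights.  The first returned channel is the accumulated splat weight (an
# area-density shape function); further channels are splat-weighted means
# scaled by occupancy.  Splatting removes almost all of the orientation
# dependence that nearest-voxel binning leaves in the descriptors.
.voxel_splat <- function(pts, val, dim, target_radius = 0.7) {
  val <- cbind(val)
  centroid <- colMeans(pts)
  u0 <- sweep(pts, 2, centroid)
  rmax <- sqrt(max(rowSums(u0^2)))
  if (rmax < 1e-9) stop("degenerate patch: all points identical")
  u <- u0 * (target_radius / rmax)
  h <- 2 / dim
  g <- (u + 1) / h + 0.5               # voxel centres at integer coordinates
  i0 <- floor(g)
  fr <- g - i0
  np <- nrow(pts)
  keys <- vector("list", 8L)
  wts <- vector("list", 8L)
  k <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fr[, 1] else fr[, 1]
    wy <- if (dy == 0) 1 - fr[, 2] else fr[, 2]
    wz <- if (dz == 0) 1 - fr[, 3] else fr[, 3]
    ii <- pmin(pmax(i0[, 1] + dx, 1), dim)
    jj <- pmin(pmax(i0[, 2] + dy, 1), dim)
    kk <- pmin(pmax(i0[, 3] + dz, 1), dim)
    k <- k + 1L
    keys[[k]] <- (ii - 1) + dim * ((jj - 1) + dim * (kk - 1))
    wts[[k]] <- wx * wy * wz
  }
  key <- unlist(keys)
  wgt <- unlist(wts)
  V <- val[rep(seq_len(np), times = 8L), , drop = FALSE] * wgt
  ukey <- sort(unique(key))
  gi <- match(key, ukey)
  sums <- rowsum(cbind(wgt, V), gi)
  wsum <- sums[, 1]
  occ <- pmin(wsum, 1)
  out <- cbind(wsum,
               sums[, -1, drop = FALSE] / pmax(wsum, 1e-12) * occ)
  ui <- cbind(ukey %% dim, (ukey %/% dim) %% dim, ukey %/% (dim * dim)) + 1
  list(indices = ui, values = unname(out),
       scale = target_radius / rmax, offset = centroid, h = h)
}

# Unit-ball coordinates of voxel centres.
.voxel_centers <- function(indices, dim) {
  h <- 2 / dim
  -1 + (indices - 0.5) * h
}

#' 3D Zernike moments of a voxelized function
#'
#' @param f a `unit_sphere_function` from [voxelize_patch()].
#' @param order expansion order (default 15; at most 20 for numerical
#'   stability of the radial polynomials).
#' @return A `zernike_moments` object: index table of `(n, l, m >= 0)` and
#'   complex moment values (moments for `-m` are conjugates for real input).
#' @export
zernike_moments <- function(f, order = 15L) {
  if (order > 20) stop("orders above 20 are numerically unstable")
  if (nrow(f$indices) == 0) {
    warning("empty function: all moments zero")
    plan <- .zernike_plan(order)
    return(structure(list(index = plan$idx[, c("n", "l", "m")],
                          values = complex(real = rep(0, nrow(plan$idx)),
                                           imaginary = 0),
                          order = order),
                     class = "zernike_moments"))
  }
  U <- .voxel_centers(f$indices, f$dim)
  core <- .zernike_core(U, f$values, order, h = 2 / f$dim)
  structure(list(index = core$index,
                 values = complex(real = core$re[, 1], imaginary = core$im[, 1]),
                 order = order),
            class = "zernike_moments")
}

#' Rotation-invariant norms of Zernike moments
#'
#' `F_nl = sqrt(sum_m |Omega_nlm|^2)`, expanded over all `-l <= m <= l`
#' using conjugate symmetry, ordered by `n` ascending then `l` ascending.
#'
#' @param mom a `zernike_moments` object.
#' @return named numeric vector of length `descriptor_length(order)`.
#' @export
invariant_norms <- function(mom) {
  idx <- mom$index
  a2 <- Mod(mom$values)^2
  mult <- ifelse(idx$m == 0, 1, 2)
  key <- paste(idx$n, idx$l)
  sums <- tapply(a2 * mult, key, sum)
  nl <- nl_pairs(mom$order)
  out <- sqrt(as.numeric(sums[paste(nl$n, nl$l)]))
  names(out) <- paste0("F", nl$n, "_", nl$l)
  out
}

#' Shape and electrostatics Zernike descriptor of one patch
#'
#' Computes the three descriptor channels in one pass over a shared
#' voxelization: `shape` (72 invariants at order 15) plus `elec_pos` and
#' `elec_neg` (together the 144-component electrostatic descriptor).  With
#' `normalize = TRUE` (default) each channel is divided by its own `F_00`
#' so descriptors compare shape rather than size; molecular size enters the
#' total score through the pocket-size term instead.
#'
#' @param patch one element of a `patch_set`'s `patches` list.
#' @param surface the parent `surface_point_cloud`.
#' @param order expansion order (default 15).
#' @param dim voxel grid dimension (default 64).
#' @param normalize divide each channel by its `F_00` (when positive).
#' @param method `"splat"` (default; anti-aliased trilinear splatting, which
#'   suppresses the grid-orientation noise of hard binning) or `"nearest"`
#'   (one voxel per point).
#' @return An object of class `zernike_descriptor` with fields `shape`,
#'   `elec_pos`, `elec_neg` and `order`.
#' @export
patch_descriptor <- function(patch, surface, order = 15L, dim = 64L,
                             normalize = TRUE, method = c("splat", "nearest")) {
  method <- match.arg(method)
  pts <- surface$points[patch$point_ids, , drop = FALSE]
  if (nrow(pts) < 3) stop("patch has fewer than 3 points")
  phi <- surface$potential[patch$point_ids]
  vox <- if (method == "splat")
    .voxel_splat(pts, cbind(pmax(phi, 0), pmax(-phi, 0)), dim)
  else
    .voxel_bin(pts, cbind(rep(1, nrow(pts)), pmax(phi, 0), pmax(-phi, 0)),
               dim, merge = "mean")
  U <- .voxel_centers(vox$indices, dim)
  core <- .zernike_core(U, vox$values, order, h = 2 / dim)
  plan <- .zernike_plan(order)
  a2 <- core$re^2 + core$im^2
  Fmat <- sqrt(rowsum(a2 * plan$mult, plan$group))
  if (normalize) {
    for (c in 1:3) if (Fmat[1, c] > 0) Fmat[, c] <- Fmat[, c] / Fmat[1, c]
  }
  structure(list(shape = Fmat[, 1], elec_pos = Fmat[, 2], elec_neg = Fmat[, 3],
                 order = order),
            class = "zernike_descriptor")
}

#' Compute descriptors and APP vectors for every patch in a set
#'
#' @param patchset a `patch_set`.
#' @param order expansion order (default 15).
#' @param dim voxel grid dimension (default 64).
#' @param normalize per-channel `F_00` normalization (default TRUE).
#' @return The `patch_set` with `descriptors` (list of
#'   [patch_descriptor()] results) and `app` (P x 40 matrix) attached.
#' @export
compute_descriptors <- function(patchset, order = 15L, dim = 64L,
                                normalize = TRUE) {
  patchset$descriptors <- lapply(patchset$patches, patch_descriptor,
                                 surface = patchset$surface, order = order,
                                 dim = dim, normalize = normalize)
  patchset$app <- app_vectors(patchset)
  patchset
}
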