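# Molecular surface engine: Gaussian-density grid, isosurface point cloud
# with a connectivity graph, and surface electrostatics.

#' Construct a surface point cloud
#'
#' @param points N x 3 surface point coordinates (Angstrom).
#' @param normals N x 3 outward unit normals.
#' @param edges data.frame `i`, `j`, `length` describing the surface
#'   connectivity graph (Euclidean edge lengths, Angstrom).
#' @param potential per-point electrostatic potential (default 0).
#' @param area_weights per-point isosurface area contribution (Angstrom^2).
#' @param spacing generating grid spacing (Angstrom), kept for tolerances.
#' @param source_id identifier of the generating molecule.
#' @return An object of class `surface_point_cloud`.
#' @export
surface_point_cloud <- function(points, normals, edges,
                                potential = NULL, area_weights = NULL,
                                spacing = NA_real_, source_id = "surface") {
  points <- rbind(points)
  n <- nrow(points)
  if (is.null(potential)) potential <- rep(0, n)
  if (is.null(area_weights)) area_weights <- rep(NA_real_, n)
  nl <- sqrt(rowSums(normals^2))
  if (any(abs(nl - 1) > 1e-6)) stop("normals must be unit length")
  if (nrow(edges) > 0 && any(edges$length <= 0)) stop("edge lengths must be positive")
  g <- igraph::make_graph(edges = as.vector(t(cbind(edges$i, edges$j))),
                          n = n, directed = FALSE)
  igraph::E(g)$weight <- edges$length
  structure(list(points = points, normals = normals, potential = potential,
                 edges = edges, area_weights = area_weights, graph = g,
                 spacing = spacing, source_id = source_id),
            class = "surface_point_cloud")
}

#' @export
print.surface_point_cloud <- function(x, ...) {
  cat("<surface_point_cloud>", x$source_id, ":", nrow(x$points), "points,",
      nrow(x$edges), "edges, area",
      if (all(is.na(x$area_weights))) "NA" else sprintf("%.1f", sum(x$area_weights, na.rm = TRUE)),
      "A^2\n")
  invisible(x)
}

#' Total isosurface area estimate
#'
#' Sum of the per-point area contributions (each isosurface crossing projects
#' its grid face through the local normal).
#'
#' @param surface a `surface_point_cloud`.
#' @return scalar area (Angstrom^2).
#' @export
surface_area <- function(surface) sum(surface$area_weights, na.rm = TRUE)

#' Gaussian atom-density grid of a molecule
#'
#' The density is a sum of per-atom Gaussians
#' `rho(x) = sum_i exp(-kappa * (|x - x_i|^2 - r_i^2) / r_i^2)` with
#' `kappa = 2.3`, so the density of an isolated atom is ~1 at its van der
#' Waals radius; the molecular surface is the `rho = 1` isosurface.
#'
#' @param mol a `molecule_structure` (atoms need radii).
#' @param spacing grid spacing (Angstrom).
#' @param padding box padding beyond the atom extents (Angstrom, >= 4
#'   recommended so the density decays to ~0 at the box walls).
#' @param kappa Gaussian sharpness (default 2.3).
#' @return A [scalar_grid3d()] of densities.
#' @export
compute_density_grid <- function(mol, spacing = 0.6, padding = 4.0, kappa = 2.3) {
  if (spacing <= 0) stop("spacing must be positive")
  xyz <- atom_coords(mol)
  radii <- mol$atoms$radius
  radii[is.na(radii)] <- element_radius(mol$atoms$element[is.na(radii)])
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 2L)
  ax <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(dims[k]) - 1))
  rho <- array(0, dim = dims)
  for (i in seq_len(nrow(xyz))) {
    r2 <- radii[i]^2
    cut <- 2.2 * radii[i]                      # exp(-kappa*3.8) ~ 2e-4 beyond
    rng <- lapply(1:3, function(k) {
      w <- which(abs(ax[[k]] - xyz[i, k]) <= cut)
      if (length(w)) range(w) else NULL
    })
    if (any(vapply(rng, is.null, logical(1)))) next
    ix <- rng[[1]][1]:rng[[1]][2]
    iy <- rng[[2]][1]:rng[[2]][2]
    iz <- rng[[3]][1]:rng[[3]][2]
    dx2 <- (ax[[1]][ix] - xyz[i, 1])^2
    dy2 <- (ax[[2]][iy] - xyz[i, 2])^2
    dz2 <- (ax[[3]][iz] - xyz[i, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    rho[ix, iy, iz] <- rho[ix, iy, iz] + exp(-kappa * (d2 - r2) / r2)
  }
  scalar_grid3d(lo, spacing, rho)
}

# Central-difference gradient arrays of a grid (per axis, grid units).
.grid_gradient <- function(v, spacing) {
  d <- dim(v)
  g <- vector("list", 3)
  for (k in 1:3) {
    gk <- array(0, dim = d)
    n <- d[k]
    idx <- function(i) switch(k, list(i, TRUE, TRUE), list(TRUE, i, TRUE),
                              list(TRUE, TRUE, i))
    sub <- function(i) do.call(`[`, c(list(v), idx(i)))
    asn <- function(i, val) {
      args <- c(list(gk), idx(i), list(value = val))
      do.call(`[<-`, args)
    }
    gk <- asn(2:(n - 1), (sub(3:n) - sub(1:(n - 2))) / (2 * spacing[k]))
    gk <- asn(1, (sub(2) - sub(1)) / spacing[k])
    gk <- asn(n, (sub(n) - sub(n - 1)) / spacing[k])
    g[[k]] <- gk
  }
  g
}

#' Extract an isosurface point cloud from a density grid
#'
#' Surface points are placed on grid edges whose endpoint densities straddle
#' the iso level (linear interpolation).  Normals follow the descending
#' density gradient (outward).  Two surface points are graph-adjacent when
#' their host grid edges share a grid cube, which links points along the
#' surface and supports geodesic distances.
#'
#' @param grid a [scalar_grid3d()] of densities.
#' @param iso iso level (default 1.0).
#' @param source_id identifier carried on the result.
#' @return A [surface_point_cloud()].
#' @export
extract_surface_points <- function(grid, iso = 1.0, source_id = "surface") {
  v <- grid$values
  d <- grid$dims
  ax <- grid_axes(grid)
  inside <- v >= iso
  if (!any(inside) || all(inside))
    stop("density grid does not straddle iso=", iso, "; no surface")
  gg <- .grid_gradient(v, grid$spacing)

  verts <- list(); axis_of <- list(); base_of <- list()
  for (k in 1:3) {
    n <- d[k]
    lowidx <- function(a) switch(k,
      a[a[, 1] < d[1], , drop = FALSE], a[a[, 2] < d[2], , drop = FALSE],
      a[a[, 3] < d[3], , drop = FALSE])
    cross <- which(if (k == 1) xor(inside[-n, , , drop = FALSE], inside[-1, , , drop = FALSE])
                   else if (k == 2) xor(inside[, -n, , drop = FALSE], inside[, -1, , drop = FALSE])
                   else xor(inside[, , -n, drop = FALSE], inside[, , -1, drop = FALSE]),
                   arr.ind = TRUE)
    if (nrow(cross) == 0) { verts[[k]] <- NULL; next }
    i1 <- cross
    i2 <- cross; i2[, k] <- i2[, k] + 1L
    lin <- function(m) (m[, 1] + d[1] * ((m[, 2] - 1) + d[2] * (m[, 3] - 1)))
    v1 <- v[lin(i1)]; v2 <- v[lin(i2)]
    t <- (iso - v1) / (v2 - v1)
    p <- cbind(ax[[1]][i1[, 1]], ax[[2]][i1[, 2]], ax[[3]][i1[, 3]])
    p[, k] <- p[, k] + t * grid$spacing[k]
    gr <- vapply(1:3, function(kk) {
      g1 <- gg[[kk]][lin(i1)]; g2 <- gg[[kk]][lin(i2)]
      g1 + t * (g2 - g1)
    }, numeric(nrow(cross)))
    verts[[k]] <- list(pos = p, grad = rbind(gr), base = i1, tk = t)
  }
  pos <- do.call(rbind, lapply(verts, function(z) if (is.null(z)) NULL else z$pos))
  grad <- do.call(rbind, lapply(verts, function(z) if (is.null(z)) NULL else z$grad))
  base <- do.call(rbind, lapply(verts, function(z) if (is.null(z)) NULL else z$base))
  axis <- rep(1:3, times = vapply(verts, function(z) if (is.null(z)) 0L else nrow(z$pos), integer(1)))
  nv <- nrow(pos)
  gl <- sqrt(rowSums(grad^2))
  gl[gl < 1e-12] <- 1
  normals <- -grad / gl
  # per-point area: the grid face pierced by this crossing, projected through
  # the local normal component along the edge axis
  face <- c(grid$spacing[2] * grid$spacing[3],
            grid$spacing[1] * grid$spacing[3],
            grid$spacing[1] * grid$spacing[2])
  area_w <- face[axis] * abs(normals[cbind(seq_len(nv), axis)])

  # adjacency: vertices sharing a grid cube; an edge along axis k at base
  # (i,j,k) borders up to 4 cubes obtained by decrementing the other two axes
  off <- list(c(0L, 0L), c(-1L, 0L), c(0L, -1L), c(-1L, -1L))
  other_mat <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  oth <- other_mat[axis, , drop = FALSE]
  cid_tab <- NULL
  for (o in seq_len(4L)) {
    cube <- base
    cube[cbind(seq_len(nv), oth[, 1])] <- cube[cbind(seq_len(nv), oth[, 1])] + off[[o]][1]
    cube[cbind(seq_len(nv), oth[, 2])] <- cube[cbind(seq_len(nv), oth[, 2])] + off[[o]][2]
    ok <- cube[, 1] >= 1 & cube[, 2] >= 1 & cube[, 3] >= 1 &
      cube[, 1] <= d[1] - 1 & cube[, 2] <= d[2] - 1 & cube[, 3] <= d[3] - 1
    cid <- cube[, 1] + (d[1] - 1) * ((cube[, 2] - 1) + (d[2] - 1) * (cube[, 3] - 1))
    cid_tab <- rbind(cid_tab, cbind(cid[ok], which(ok)))
  }
  ord <- order(cid_tab[, 1], cid_tab[, 2])
  cid <- cid_tab[ord, 1]
  vid <- cid_tab[ord, 2]
  # all within-cube vertex pairs, vectorized over run offsets
  maxrun <- max(rle(cid)$lengths)
  if (maxrun < 2) stop("degenerate surface: no connectivity")
  pr <- do.call(rbind, lapply(seq_len(maxrun - 1), function(o) {
    i1 <- seq_len(length(cid) - o)
    same <- cid[i1] == cid[i1 + o]
    cbind(vid[i1][same], vid[i1 + o][same])
  }))
  if (is.null(pr) || nrow(pr) == 0) stop("degenerate surface: no connectivity")
  key <- pmin(pr[, 1], pr[, 2]) * (nv + 1) + pmax(pr[, 1], pr[, 2])
  pr <- pr[!duplicated(key), , drop = FALSE]
  len <- sqrt(rowSums((pos[pr[, 1], , drop = FALSE] - pos[pr[, 2], , drop = FALSE])^2))
  keep <- len > 1e-9
  edges <- data.frame(i = pr[keep, 1], j = pr[keep, 2], length = len[keep])
  surface_point_cloud(pos, normals, edges, area_weights = area_w,
                      spacing = min(grid$spacing), source_id = source_id)
}

#' Assign electrostatic potential to surface points
#'
#' Either evaluates a distance-screened Coulomb model from the molecule's
#' partial charges, `phi(x) = sum_i 332.06 q_i exp(-|x-x_i|/lambda) /
#' (eps |x-x_i|)` (kcal/mol/e), or interpolates an imported potential grid
#' (e.g. a Poisson-Boltzmann solution in OpenDX format) trilinearly at each
#' surface point.
#'
#' @param surface a `surface_point_cloud`.
#' @param mol the generating `molecule_structure` (for `coulomb_screened`).
#' @param mode `"coulomb_screened"` or `"from_grid"`.
#' @param grid potential [scalar_grid3d()] for `mode = "from_grid"`.
#' @param eps dielectric constant (default 80).
#' @param lambda screening length (Angstrom, default 8; `Inf` disables
#'   screening).
#' @return The surface with its `potential` field filled.
#' @export
assign_electrostatics <- function(surface, mol = NULL,
                                  mode = c("coulomb_screened", "from_grid"),
                                  grid = NULL, eps = 80, lambda = 8) {
  mode <- match.arg(mode)
  if (mode == "from_grid") {
    if (is.null(grid)) stop("mode='from_grid' requires a potential grid")
    surface$potential <- grid_interpolate(grid, surface$points)
    return(surface)
  }
  if (is.null(mol)) stop("mode='coulomb_screened' requires the molecule")
  q <- mol$atoms$charge
  q[is.na(q)] <- 0
  phi <- rep(0, nrow(surface$points))
  if (any(q != 0)) {
    xyz <- atom_coords(mol)
    p <- surface$points
    for (i in which(q != 0)) {
      dv <- sqrt((p[, 1] - xyz[i, 1])^2 + (p[, 2] - xyz[i, 2])^2 +
                   (p[, 3] - xyz[i, 3])^2)
      dv[dv < 1e-6] <- 1e-6
      damp <- if (is.finite(lambda)) exp(-dv / lambda) else 1
      phi <- phi + 332.06 * q[i] * damp / (eps * dv)
    }
  }
  surface$potential <- phi
  surface
}

# Induced sub-cloud on a vertex subset (renumbers points and edges).
surface_subset <- function(surface, keep_ids, source_id = surface$source_id) {
  keep_ids <- sort(unique(keep_ids))
  remap <- match(seq_len(nrow(surface$points)), keep_ids)
  e <- surface$edges
  sel <- e$i %in% keep_ids & e$j %in% keep_ids
  edges <- data.frame(i = remap[e$i[sel]], j = remap[e$j[sel]],
                      length = e$length[sel])
  surface_point_cloud(surface$points[keep_ids, , drop = FALSE],
                      surface$normals[keep_ids, , drop = FALSE],
                      edges,
                      potential = surface$potential[keep_ids],
                      area_weights = surface$area_weights[keep_ids],
                      spacing = surface$spacing, source_id = source_id)
}

#' Build a molecular surface in one call
#'
#' Convenience wrapper: density grid, isosurface extraction and (optionally)
#' screened-Coulomb electrostatics.
#'
#' @inheritParams compute_density_grid
#' @param iso iso level.
#' @param electrostatics logical; evaluate the screened-Coulomb potential.
#' @return A [surface_point_cloud()].
#' @export
molecular_surface <- function(mol, spacing = 0.6, iso = 1.0, padding = 4.0,
                              electrostatics = TRUE) {
  grid <- compute_density_grid(mol, spacing = spacing, padding = padding)
  surf <- extract_surface_points(grid, iso = iso, source_id = mol$id)
  if (electrostatics)
    surf <- assign_electrostatics(surf, mol, mode = "coulomb_screened")
  surf
}
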