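# Patch segmentation: seed selection, geodesic patch growth, seed-to-seed
# distance matrices and approximate-patch-position (APP) vectors.

#' Select patch seed points on a surface
#'
#' Heavy atoms lying within `d_atom` of the surface are visited in ascending
#' atom-to-surface distance (ties by atom serial); each contributes its
#' closest surface point as a seed unless that point falls within `d_min`
#' (Euclidean) of an already accepted seed.  This spreads seeds evenly while
#' anchoring them to atoms that actually touch the surface.
#'
#' @param surface a `surface_point_cloud`.
#' @param mol the generating `molecule_structure` (heavy atoms are used).
#' @param d_atom atom-to-surface inclusion cutoff (Angstrom, default 3.5).
#' @param d_min minimum seed separation (Angstrom, default 3.0).
#' @return integer vector of surface point ids.
#' @export
select_seed_points <- function(surface, mol, d_atom = 3.5, d_min = 3.0) {
  if (nrow(surface$points) == 0) stop("empty surface")
  xyz <- atom_coords(mol, heavy_only = TRUE)
  serial <- mol$atoms$serial[mol$atoms$is_heavy]
  if (nrow(xyz) == 0) stop("molecule has no heavy atoms")
  p <- surface$points
  closest <- integer(nrow(xyz))
  dist <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    d2 <- (p[, 1] - xyz[i, 1])^2 + (p[, 2] - xyz[i, 2])^2 + (p[, 3] - xyz[i, 3])^2
    closest[i] <- which.min(d2)
    dist[i] <- sqrt(d2[closest[i]])
  }
  sel <- dist <= d_atom
  if (!any(sel)) stop("no heavy atom within ", d_atom, " A of the surface")
  ord <- order(dist[sel], serial[sel])
  cand <- closest[sel][ord]
  seeds <- integer(0)
  for (s in cand) {
    if (length(seeds) == 0) { seeds <- s; next }
    dmin <- min(sqrt(rowSums((p[seeds, , drop = FALSE] -
                                matrix(p[s, ], length(seeds), 3, byrow = TRUE))^2)))
    if (dmin >= d_min) seeds <- c(seeds, s)
  }
  seeds
}

#' Segment a surface into seed-centered patches
#'
#' Each patch is the set of surface points whose geodesic (shortest-path)
#' distance along the surface graph from the seed is at most `radius`; the
#' patch is therefore a connected single surface region by construction.
#' Patches may overlap.  Setting `euclidean = TRUE` instead takes the
#' Euclidean ball around the seed restricted to the seed's connected
#' component (a faster approximation kept behind this flag).
#'
#' @param surface a `surface_point_cloud`.
#' @param seeds surface point ids from [select_seed_points()].
#' @param radius patch radius (Angstrom, default 5.0).
#' @param euclidean use the Euclidean-ball variant.
#' @return A `patch_set` object: per-patch members, the P x P seed-to-seed
#'   geodesic and Euclidean matrices.
#' @export
segment_patches <- function(surface, seeds, radius = 5.0, euclidean = FALSE) {
  if (length(seeds) == 0) stop("no seeds supplied")
  np <- nrow(surface$points)
  if (any(seeds < 1 | seeds > np)) stop("seed id outside surface point range")
  gd <- igraph::distances(surface$graph, v = seeds, algorithm = "dijkstra")
  patches <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    if (euclidean) {
      d <- sqrt(rowSums((surface$points -
                           matrix(surface$points[seeds[i], ], np, 3, byrow = TRUE))^2))
      members <- which(d <= radius & is.finite(gd[i, ]))
    } else {
      members <- which(gd[i, ] <= radius)
    }
    patches[[i]] <- list(id = i, seed = seeds[i],
                         center = surface$points[seeds[i], ],
                         point_ids = members)
  }
  geo <- gd[, seeds, drop = FALSE]
  dimnames(geo) <- NULL
  geo <- (geo + t(geo)) / 2                     # symmetrize exact ties
  sp <- surface$points[seeds, , drop = FALSE]
  euc <- as.matrix(stats::dist(sp))
  dimnames(euc) <- NULL
  structure(list(patches = patches, seeds = seeds, geodesic = geo,
                 euclidean = euc, surface = surface,
                 source = surface$source_id, radius = radius),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("<patch_set>", x$source, ":", length(x$patches), "patches, radius",
      x$radius, "A",
      if (!is.null(x$descriptors)) "(with descriptors)" else "", "\n")
  invisible(x)
}

#' Number of patches
#' @param x a `patch_set`.
#' @export
n_patches <- function(x) length(x$patches)

#' Seed-to-seed geodesic distance matrix
#'
#' Shortest-path distances over the surface connectivity graph between patch
#' seed points.  Pairs on disconnected components are `Inf`.
#'
#' @param patchset a `patch_set`.
#' @return P x P symmetric matrix (Angstrom), zero diagonal.
#' @export
geodesic_matrix <- function(patchset) patchset$geodesic

#' Approximate-patch-position (APP) vectors
#'
#' For each patch, its geodesic distances to the other patches are binned
#' into a histogram (bin width `bin_width`, `n_bins` bins; the last bin also
#' collects overflow and unreachable pairs).  The APP vector encodes whether
#' a patch sits in the middle or at the rim of the pocket/ligand.
#'
#' @param patchset a `patch_set`.
#' @param bin_width histogram bin width (Angstrom, default 1.0).
#' @param n_bins number of bins (default 40).
#' @return P x n_bins matrix of counts; each row sums to P - 1.
#' @export
app_vectors <- function(patchset, bin_width = 1.0, n_bins = 40L) {
  g <- patchset$geodesic
  P <- nrow(g)
  app <- matrix(0L, P, n_bins)
  if (any(is.infinite(g[upper.tri(g)])))
    warning("unreachable patch pairs: counted in the last APP bin")
  for (i in seq_len(P)) {
    d <- g[i, -i]
    b <- pmin(floor(d / bin_width), n_bins - 1) + 1
    b[is.infinite(d)] <- n_bins
    tb <- tabulate(b, nbins = n_bins)
    app[i, ] <- tb
  }
  app
}

#' Serialize a patch set to JSON lines
#'
#' One JSON object per line per patch: seed id, center, member ids, APP bins
#' and (when present) the descriptor channels.  A plain-text, diff-friendly
#' exchange format.
#'
#' @param patchset a `patch_set` (optionally carrying descriptors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patchset_jsonl <- function(patchset, path) {
  app <- app_vectors(patchset)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(patchset$patches)) {
    p <- patchset$patches[[i]]
    rec <- list(id = p$id, seed = p$seed,
                center = round(unname(p$center), 6),
                n_members = length(p$point_ids),
                app = app[i, ])
    if (!is.null(patchset$descriptors)) {
      d <- patchset$descriptors[[i]]
      rec$shape <- round(d$shape, 8)
      rec$elec_pos <- round(d$elec_pos, 8)
      rec$elec_neg <- round(d$elec_neg, 8)
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
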