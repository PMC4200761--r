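# Binding-pocket definition: center from the bound ligand, surface carved by
# ray casting from that center.

#' Pocket center from a bound ligand
#'
#' Mass-weighted mean of the ligand's heavy-atom coordinates (standard atomic
#' masses).
#'
#' @param ligand a `molecule_structure`.
#' @return length-3 numeric vector (Angstrom).
#' @export
pocket_center <- function(ligand) {
  a <- ligand$atoms[ligand$atoms$is_heavy, , drop = FALSE]
  if (nrow(a) == 0) stop("ligand has no heavy atoms")
  m <- element_mass(a$element)
  unname(colSums(as.matrix(a[, c("x", "y", "z")]) * m) / sum(m))
}

# Evenly distributed unit directions (Fibonacci sphere).
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Carve a pocket surface by ray casting
#'
#' Rays are cast from the pocket center along uniformly distributed
#' directions; for each ray the nearest surface point lying within a
#' perpendicular tolerance of the ray segment is retained (first-hit
#' semantics: pocket walls, not the far side of the protein).  The retained
#' set is dilated by one graph ring to close pinholes between rays.
#'
#' @param surface the protein `surface_point_cloud`.
#' @param center length-3 pocket center (Angstrom).
#' @param n_rays number of ray directions (default 1000).
#' @param max_range maximum hit distance along a ray (Angstrom, default 12).
#' @param tolerance perpendicular hit tolerance; defaults to 1.2 x the
#'   surface grid spacing.
#' @return A `pocket` object: the carved sub-surface plus the center and the
#'   ids of the retained points on the parent surface.
#' @export
ray_cast_pocket <- function(surface, center, n_rays = 1000, max_range = 12,
                            tolerance = NULL) {
  stopifnot(length(center) == 3)
  if (is.null(tolerance)) {
    tolerance <- 1.2 * surface$spacing
    if (!is.finite(tolerance)) tolerance <- 0.75
  }
  p <- sweep(surface$points, 2, center)
  r2 <- rowSums(p^2)
  if (!any(r2 <= max_range^2))
    stop("empty pocket: no surface point within max_range of the center")
  dirs <- fibonacci_directions(n_rays)
  hits <- integer(0)
  chunk <- 128L
  for (s in seq(1, n_rays, by = chunk)) {
    dd <- dirs[s:min(s + chunk - 1, n_rays), , drop = FALSE]
    tt <- p %*% t(dd)                       # N x chunk projections
    perp2 <- r2 - tt^2
    ok <- tt >= 0 & tt <= max_range & perp2 <= tolerance^2
    tt[!ok] <- Inf
    first <- apply(tt, 2, which.min)
    got <- is.finite(tt[cbind(first, seq_len(ncol(tt)))])
    hits <- c(hits, first[got])
  }
  hits <- unique(hits)
  if (length(hits) == 0)
    stop("empty pocket: no ray hit the surface within tolerance")
  nb <- unique(unlist(igraph::adjacent_vertices(surface$graph, hits)))
  ids <- sort(unique(c(hits, as.integer(nb))))
  sub <- surface_subset(surface, ids,
                        source_id = paste0(surface$source_id, "_pocket"))
  structure(list(center = as.numeric(center), surface = sub,
                 parent_ids = ids, n_rays = n_rays, max_range = max_range,
                 protein_id = surface$source_id),
            class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat("<pocket> of", x$protein_id, ":", nrow(x$surface$points),
      "surface points, center",
      paste(sprintf("%.2f", x$center), collapse = ","), "\n")
  invisible(x)
}
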