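# Regular scalar grids and the OpenDX scalar-grid file format.

#' Construct a 3D scalar grid
#'
#' @param origin 3-vector, coordinates of grid point (1,1,1) (Angstrom).
#' @param spacing 3-vector of positive grid spacings (Angstrom).
#' @param values numeric 3D array indexed `[ix, iy, iz]`.
#' @return An object of class `scalar_grid3d`.
#' @export
scalar_grid3d <- function(origin, spacing, values) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dim(values), values = values),
            class = "scalar_grid3d")
}

#' @export
print.scalar_grid3d <- function(x, ...) {
  cat("<scalar_grid3d>", paste(x$dims, collapse = "x"),
      "spacing", paste(signif(x$spacing, 3), collapse = "/"),
      "origin", paste(signif(x$origin, 4), collapse = ","), "\n")
  invisible(x)
}

# Axis coordinate vectors of a grid.
grid_axes <- function(grid) {
  lapply(1:3, function(k)
    grid$origin[k] + grid$spacing[k] * (seq_len(grid$dims[k]) - 1))
}

#' Read an OpenDX scalar grid
#'
#' Parses the "gridpositions counts" dialect written by Poisson-Boltzmann
#' solvers.  Data values follow the OpenDX convention (z fastest).
#'
#' @param path file path.
#' @return A [scalar_grid3d()].
#' @export
read_dx_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  cnt <- grep("object .* gridpositions counts", lines, value = TRUE)
  if (length(cnt) == 0) stop("not an OpenDX gridpositions file: ", path)
  dims <- as.integer(utils::tail(strsplit(trimws(cnt[1]), "\\s+")[[1]], 3))
  org <- grep("^\\s*origin", lines, value = TRUE)
  if (length(org) == 0) stop("OpenDX file lacks an origin record")
  origin <- as.numeric(utils::tail(strsplit(trimws(org[1]), "\\s+")[[1]], 3))
  deltas <- grep("^\\s*delta", lines, value = TRUE)
  if (length(deltas) < 3) stop("OpenDX file lacks three delta records")
  dmat <- t(vapply(deltas[1:3], function(s)
    as.numeric(utils::tail(strsplit(trimws(s), "\\s+")[[1]], 3)),
    numeric(3)))
  spacing <- c(dmat[1, 1], dmat[2, 2], dmat[3, 3])
  if (any(abs(dmat - diag(spacing)) > 1e-8))
    stop("only axis-aligned OpenDX grids are supported")
  dstart <- grep("object .* class array", lines)
  if (length(dstart) == 0) stop("OpenDX file lacks a data array")
  dend <- grep("attribute|object \"", lines)
  dend <- dend[dend > dstart[1]]
  body <- lines[(dstart[1] + 1):(if (length(dend)) min(dend) - 1 else length(lines))]
  vals <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  n <- prod(dims)
  if (length(vals) != n)
    stop("corrupt OpenDX grid: expected ", n, " values, found ", length(vals))
  # file order is z fastest: unflatten as (z,y,x) then permute to (x,y,z)
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  scalar_grid3d(origin, spacing, arr)
}

#' Write an OpenDX scalar grid
#'
#' @param grid a [scalar_grid3d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dx_grid <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by surfcomp",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1))) # z fastest
  n <- length(vals)
  pad <- ceiling(n / 3) * 3 - n
  m <- matrix(c(vals, rep(NA_real_, pad)), nrow = 3)
  rows <- apply(m, 2, function(v) paste(sprintf("%.6e", v[!is.na(v)]), collapse = " "))
  writeLines(rows, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field'), con)
  invisible(path)
}

#' Trilinear interpolation of a scalar grid
#'
#' @param grid a [scalar_grid3d()].
#' @param points N x 3 matrix of coordinates (Angstrom).
#' @return numeric vector of interpolated values.
#' @export
grid_interpolate <- function(grid, points) {
  points <- rbind(points)
  u <- sweep(sweep(points, 2, grid$origin), 2, grid$spacing, "/")
  i0 <- floor(u)
  frac <- u - i0
  # clamp the upper cell so points exactly on the far face interpolate
  for (k in 1:3) {
    hi <- i0[, k] == grid$dims[k] - 1 & frac[, k] < 1e-9
    i0[hi, k] <- i0[hi, k] - 1
    frac[hi, k] <- 1
  }
  if (any(i0 < 0) || any(sweep(i0, 2, grid$dims - 2, ">"))) {
    bad <- which(apply(i0 < 0, 1, any) | apply(sweep(i0, 2, grid$dims - 2, ">"), 1, any))
    stop("point(s) outside grid, e.g. (",
         paste(signif(points[bad[1], ], 5), collapse = ", "), ")")
  }
  v <- grid$values
  d <- grid$dims
  idx <- function(dx, dy, dz)
    (i0[, 1] + dx) + d[1] * ((i0[, 2] + dy) + d[2] * (i0[, 3] + dz)) + 1
  fx <- frac[, 1]; fy <- frac[, 2]; fz <- frac[, 3]
  v[idx(0, 0, 0)] * (1 - fx) * (1 - fy) * (1 - fz) +
    v[idx(1, 0, 0)] * fx * (1 - fy) * (1 - fz) +
    v[idx(0, 1, 0)] * (1 - fx) * fy * (1 - fz) +
    v[idx(0, 0, 1)] * (1 - fx) * (1 - fy) * fz +
    v[idx(1, 1, 0)] * fx * fy * (1 - fz) +
    v[idx(1, 0, 1)] * fx * (1 - fy) * fz +
    v[idx(0, 1, 1)] * (1 - fx) * fy * fz +
    v[idx(1, 1, 1)] * fx * fy * fz
}
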