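# Patch-pair distance terms and the auction-based pocket-ligand assignment.

#' Distance-score weights for patch matching
#'
#' The three weights multiply the descriptor difference (`pdist`), the
#' approximate-patch-position difference (`appd`) and the relative-geodesic
#' term (`grpd`).  They may be given directly or derived from the reduced
#' two-parameter form `(w1, w2, w3) = (a*b, a*(1-b), 1-a)`, which guarantees
#' `w1 + w2 + w3 = 1`.
#'
#' @param w1,w2,w3 non-negative weights.
#' @param a,b alternative reduced parameterization (overrides w1..w3).
#' @return An object of class `distance_weights`.
#' @export
distance_weights <- function(w1 = 0.35, w2 = 0.15, w3 = 0.5, a = NULL, b = NULL) {
  if (!is.null(a)) {
    stopifnot(!is.null(b), a >= 0, a <= 1, b >= 0, b <= 1)
    w1 <- a * b; w2 <- a * (1 - b); w3 <- 1 - a
  }
  if (any(c(w1, w2, w3) < 0)) stop("weights must be non-negative")
  structure(list(w1 = w1, w2 = w2, w3 = w3), class = "distance_weights")
}

#' Preset matching weights
#'
#' `"optimized"` is the grid-search optimum for pocket-ligand matching
#' (0.35, 0.15, 0.5); `"default"` is the legacy pocket-pocket preset
#' (0.32, 0.48, 0.2); `"shape_only"` uses the descriptor term alone.
#'
#' @param name preset name.
#' @return A [distance_weights()] object.
#' @export
matching_weights <- function(name = c("optimized", "default", "shape_only")) {
  name <- match.arg(name)
  switch(name,
         optimized  = distance_weights(a = 0.5, b = 0.7),
         default    = distance_weights(a = 0.8, b = 0.4),
         shape_only = distance_weights(1, 0, 0))
}

#' Descriptor distance between two patches
#'
#' Weighted sum of Euclidean distances between the shape descriptors and the
#' concatenated (positive + negative channel) electrostatic descriptors.
#' The channel weights 0.717 / 0.283 normalize the differing value ranges of
#' the two properties.
#'
#' @param a,b `zernike_descriptor` objects.
#' @param shape_w,elec_w channel weights.
#' @return non-negative scalar.
#' @export
pdist <- function(a, b, shape_w = 0.717, elec_w = 0.283) {
  if (length(a$shape) != length(b$shape) ||
      length(a$elec_pos) != length(b$elec_pos) ||
      length(a$elec_neg) != length(b$elec_neg))
    stop("descriptor length mismatch")
  ds <- sqrt(sum((a$shape - b$shape)^2))
  de <- sqrt(sum((c(a$elec_pos, a$elec_neg) - c(b$elec_pos, b$elec_neg))^2))
  shape_w * ds + elec_w * de
}

#' Approximate-patch-position distance
#'
#' Euclidean norm of the difference of two APP histograms.
#'
#' @param a,b APP vectors (equal length, typically 40 bins).
#' @return non-negative scalar.
#' @export
appd <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2))
}

# Cap for unreachable (infinite) geodesic entries, matching the APP range.
.geo_cap <- function(g, cap = 40) {
  if (any(is.infinite(g))) {
    warning("infinite geodesic distances capped at ", cap, " A")
    g[is.infinite(g)] <- cap
  }
  g
}

#' Geodesic relative position difference of a candidate pair
#'
#' Given already-matched pairs `m`, measures how consistently the candidate
#' pocket patch `a` and ligand patch `b` sit relative to them:
#' `(1/n) * sum over (a', b') in m of |G2_A(a, a') - G2_B(b, b')|`.
#' Returns 0 when `m` is empty (the term is ignored in the first auction
#' round).
#'
#' @param a pocket patch index; `b` ligand patch index.
#' @param m matrix/data.frame of matched pairs (pocket index, ligand index),
#'   possibly empty.
#' @param G2_A,G2_B seed-to-seed geodesic matrices of the two patch sets.
#' @return non-negative scalar.
#' @export
grpd <- function(a, b, m, G2_A, G2_B) {
  m <- rbind(m)
  if (is.null(m) || nrow(m) == 0) return(0)
  ga <- .geo_cap(G2_A[a, m[, 1]])
  gb <- .geo_cap(G2_B[b, m[, 2]])
  mean(abs(ga - gb))
}

#' Combined patch-pair distance score
#'
#' `w1 * pdist + w2 * appd + w3 * grpd`.
#'
#' @param w a [distance_weights()] object.
#' @param pdist,appd,grpd the three term values.
#' @return scalar score (lower = more compatible pair).
#' @export
distance_score <- function(w, pdist, appd, grpd = 0) {
  w$w1 * pdist + w$w2 * appd + w$w3 * grpd
}

#' Minimum-cost one-to-one assignment by epsilon-scaling auction
#'
#' Solves the rectangular assignment problem (rows <= columns; every row is
#' assigned a distinct column minimizing total cost).  Costs are scaled to
#' integers (factor 1e6) and a forward auction with epsilon scaling is run
#' (epsilon starts at half the largest scaled cost and is divided by 5 until
#' below `1/(n+1)`), which is optimal for the scaled integer costs.
#'
#' @param cost numeric matrix, `nrow(cost) <= ncol(cost)`, finite entries.
#' @param scale_factor integer scaling of the costs.
#' @return integer vector: assigned column for each row.
#' @export
auction_assign <- function(cost, scale_factor = 1e6) {
  cost <- rbind(cost)
  if (any(!is.finite(cost))) stop("cost matrix has non-finite entries")
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr > nc) stop("cost matrix must have nrow <= ncol (transpose first)")
  # pad with zero-cost dummy rows: the square optimum restricted to the real
  # rows is exactly the rectangular optimum
  benefit <- -round(cost * scale_factor)
  if (nr < nc) benefit <- rbind(benefit, matrix(0, nc - nr, nc))
  n <- nc
  price <- rep(0, n)
  eps <- max(abs(benefit)) / 2
  if (eps == 0) eps <- 1
  assign_row <- rep(NA_integer_, n)
  repeat {
    assign_row[] <- NA_integer_
    owner <- rep(NA_integer_, n)
    queue <- seq_len(n)
    while (length(queue) > 0) {
      i <- queue[[1]]; queue <- queue[-1]
      vals <- benefit[i, ] - price
      j <- which.max(vals)
      bv <- vals[j]
      sv <- if (n > 1) max(vals[-j]) else bv - eps
      price[j] <- price[j] + (bv - sv) + eps
      if (!is.na(owner[j])) {
        assign_row[owner[j]] <- NA_integer_
        queue <- c(queue, owner[j])
      }
      owner[j] <- i
      assign_row[i] <- j
    }
    if (eps < 1 / (n + 1)) break
    eps <- eps / 5
  }
  assign_row[seq_len(nr)]
}

# Pairwise pdist matrix between two descriptor lists.
.pdist_matrix <- function(da, db, shape_w = 0.717, elec_w = 0.283) {
  fa <- t(vapply(da, function(d) c(d$shape, d$elec_pos, d$elec_neg),
                 numeric(length(da[[1]]$shape) * 3)))
  fb <- t(vapply(db, function(d) c(d$shape, d$elec_pos, d$elec_neg),
                 numeric(length(db[[1]]$shape) * 3)))
  ns <- length(da[[1]]$shape)
  d2 <- function(x, y) {
    # squared Euclidean cross-distances via the Gram trick
    outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  }
  ds <- sqrt(pmax(d2(fa[, 1:ns, drop = FALSE], fb[, 1:ns, drop = FALSE]), 0))
  de <- sqrt(pmax(d2(fa[, -(1:ns), drop = FALSE], fb[, -(1:ns), drop = FALSE]), 0))
  shape_w * ds + elec_w * de
}

# Pairwise appd matrix.
.appd_matrix <- function(appa, appb) {
  d2 <- outer(rowSums(appa^2), rowSums(appb^2), `+`) - 2 * tcrossprod(appa, appb)
  sqrt(pmax(d2, 0))
}

# grpd matrix for all (pocket, ligand) pairs given matched pairs m.
.grpd_matrix <- function(G2A, G2B, m) {
  nA <- nrow(G2A); nB <- nrow(G2B)
  if (is.null(m) || nrow(m) == 0) return(matrix(0, nA, nB))
  G2A <- .geo_cap(G2A); G2B <- .geo_cap(G2B)
  acc <- matrix(0, nA, nB)
  for (k in seq_len(nrow(m)))
    acc <- acc + abs(outer(G2A[, m[k, 1]], G2B[, m[k, 2]], `-`))
  acc / nrow(m)
}

#' Match pocket patches to ligand patches
#'
#' Two-phase auction search.  Phase 1 assigns patches using descriptor and
#' APP terms only (the relative-geodesic term is ignored while no pairs are
#' known).  Phase 2 recomputes the full three-term cost using the previous
#' round's pairs as context and re-runs the auction, iterating until the
#' pair set is stable (at most `max_iter` rounds).  Every patch of the
#' smaller side is matched, so `N = min(n_A, n_B)`.
#'
#' The `"sequential"` mode instead grows the matching one pair at a time,
#' always adding the currently cheapest compatible pair (greedy; kept for
#' comparison).
#'
#' @param pocket a `patch_set` with descriptors (see [compute_descriptors()]).
#' @param ligand a `patch_set` with descriptors.
#' @param w a [distance_weights()] object.
#' @param max_iter phase-2 iteration cap.
#' @param mode `"iterative"` (default) or `"sequential"`.
#' @return A `patch_matching` object: data.frame `pairs` with columns
#'   `pocket`, `ligand`, `pdist`, `appd`, `grpd`, `total`, plus the weights
#'   and `N`.
#' @export
match_patches <- function(pocket, ligand, w = matching_weights("optimized"),
                          max_iter = 5L, mode = c("iterative", "sequential")) {
  mode <- match.arg(mode)
  if (is.null(pocket$descriptors) || is.null(ligand$descriptors))
    stop("patch sets need descriptors; run compute_descriptors() first")
  nA <- n_patches(pocket); nB <- n_patches(ligand)
  if (nA == 0 || nB == 0) stop("empty patch set")
  PD <- .pdist_matrix(pocket$descriptors, ligand$descriptors)
  AD <- .appd_matrix(pocket$app, ligand$app)
  G2A <- pocket$geodesic; G2B <- ligand$geodesic

  cost_for <- function(m) w$w1 * PD + w$w2 * AD + w$w3 * .grpd_matrix(G2A, G2B, m)

  solve_phase <- function(cost) {
    if (nB <= nA) {
      cols <- auction_assign(t(cost))          # rows = ligand side
      cbind(pocket = cols, ligand = seq_len(nB))
    } else {
      cols <- auction_assign(cost)
      cbind(pocket = seq_len(nA), ligand = cols)
    }
  }

  if (mode == "sequential") {
    m <- matrix(integer(0), 0, 2)
    freeA <- seq_len(nA); freeB <- seq_len(nB)
    while (length(freeA) > 0 && length(freeB) > 0) {
      cost <- cost_for(m)[freeA, freeB, drop = FALSE]
      k <- arrayInd(which.min(cost), dim(cost))
      m <- rbind(m, c(freeA[k[1]], freeB[k[2]]))
      freeA <- freeA[-k[1]]; freeB <- freeB[-k[2]]
    }
    pairs <- m
  } else {
    pairs <- solve_phase(w$w1 * PD + w$w2 * AD)  # phase 1: grpd ignored
    for (it in seq_len(max_iter)) {
      nxt <- solve_phase(cost_for(pairs))
      if (nrow(nxt) == nrow(pairs) &&
          all(nxt[order(nxt[, 2]), ] == pairs[order(pairs[, 2]), ])) break
      pairs <- nxt
    }
  }
  GR <- .grpd_matrix(G2A, G2B, pairs)
  ij <- cbind(pairs[, 1], pairs[, 2])
  df <- data.frame(pocket = pairs[, 1], ligand = pairs[, 2],
                   pdist = PD[ij], appd = AD[ij], grpd = GR[ij])
  df$total <- w$w1 * df$pdist + w$w2 * df$appd + w$w3 * df$grpd
  df <- df[order(df$pocket, df$ligand), ]
  rownames(df) <- NULL
  structure(list(pairs = df, N = nrow(df), weights = w,
                 n_pocket = nA, n_ligand = nB),
            class = "patch_matching")
}

#' @export
print.patch_matching <- function(x, ...) {
  cat("<patch_matching>", x$N, "pairs (pocket", x$n_pocket, "x ligand",
      x$n_ligand, "), mean total", sprintf("%.4f", mean(x$pairs$total)), "\n")
  invisible(x)
}

#' Write a matching as TSV
#'
#' @param m a `patch_matching`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matching_tsv <- function(m, path) {
  df <- m$pairs
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
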