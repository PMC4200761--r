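# Pocket-ligand complementarity scores: per-conformer totals, library
# ranking and the per-ligand-type pocket score.

#' Total-score weights
#'
#' Weights of the three components of the pocket-ligand total score
#' (descriptor term, relative-geodesic term, size term).  The default
#' (0.8, 0.0, 0.1) is the grid-search optimum for active/decoy
#' discrimination on a virtual-screening training set.
#'
#' @param w1,w2,w3 non-negative component weights.
#' @return An object of class `total_weights`.
#' @export
total_weights <- function(w1 = 0.8, w2 = 0.0, w3 = 0.1) {
  if (any(c(w1, w2, w3) < 0)) stop("weights must be non-negative")
  structure(list(w1 = w1, w2 = w2, w3 = w3), class = "total_weights")
}

#' Average descriptor distance of a matching
#'
#' Mean `pdist` over the matched patch pairs.  An optional coverage penalty
#' (`coverage = TRUE`) multiplies by `n_A / N`, penalizing ligands whose
#' patches cover only part of the pocket.
#'
#' @param m a `patch_matching`.
#' @param coverage apply the pocket-coverage factor.
#' @return scalar (lower = better descriptor agreement).
#' @export
avg_zd <- function(m, coverage = FALSE) {
  if (m$N < 1) stop("empty matching")
  v <- mean(m$pairs$pdist)
  if (coverage) v <- v * m$n_pocket / m$N
  v
}

# Shared combinatorial form of avg_grpd / rdp: mean absolute difference of
# within-side center distances over all unordered couples of matched pairs.
.pairwise_layout_diff <- function(m, DA, DB, what) {
  if (m$N < 2) {
    warning(what, ": fewer than 2 matched pairs; returning 0")
    return(0)
  }
  a <- m$pairs$pocket; b <- m$pairs$ligand
  da <- .geo_cap(DA[a, a, drop = FALSE])
  db <- .geo_cap(DB[b, b, drop = FALSE])
  diff <- abs(da - db)
  sum(diff[upper.tri(diff)]) * 2 / (m$N * (m$N - 1))
}

#' Average geodesic relative position difference
#'
#' `(2 / (N (N - 1))) * sum over couples (i < j) of
#' |G2_A(a_i, a_j) - G2_B(b_i, b_j)|`: how congruent the geodesic layouts of
#' the matched patches are on the two surfaces.
#'
#' @param m a `patch_matching`.
#' @param G2_A,G2_B seed-to-seed geodesic matrices of pocket and ligand.
#' @return scalar (0 for perfectly congruent layouts).
#' @export
avg_grpd <- function(m, G2_A, G2_B) .pairwise_layout_diff(m, G2_A, G2_B, "avg_grpd")

#' Relative Euclidean distance of matched patches
#'
#' Same combinatorial form as [avg_grpd()] but over straight-line (L2)
#' center distances; used by the legacy pocket-style total score.
#'
#' @param m a `patch_matching`.
#' @param L2_A,L2_B seed-to-seed Euclidean matrices of pocket and ligand.
#' @return scalar.
#' @export
rdp <- function(m, L2_A, L2_B) .pairwise_layout_diff(m, L2_A, L2_B, "rdp")

#' Pocket-ligand size difference
#'
#' `|n_A - n_B| / max(n_A, n_B)`: the relative difference in patch counts.
#'
#' @param n_A,n_B patch counts of pocket and ligand.
#' @return scalar in `[0, 1)`.
#' @export
pocket_sd <- function(n_A, n_B) {
  if (n_A < 1 || n_B < 1) stop("patch counts must be >= 1")
  abs(n_A - n_B) / max(n_A, n_B)
}

#' Pocket-ligand total score
#'
#' `w1 * avgZd + w2 * avgGrpd + w3 * pocketSd`; lower is better.
#'
#' @param avgZd,avgGrpd,pocketSd component values.
#' @param w a [total_weights()] object.
#' @return scalar score.
#' @export
totalscore_pl <- function(avgZd, avgGrpd, pocketSd, w = total_weights()) {
  w$w1 * avgZd + w$w2 * avgGrpd + w$w3 * pocketSd
}

#' Pocket-style total score
#'
#' Fixed-weight combination `0.06 * avgZd + 0.14 * rdp + 0.8 * pocketSd`
#' used with descriptor-only matching; lower is better.
#'
#' @param avgZd,rdp,pocketSd component values.
#' @return scalar score.
#' @export
totalscore_ps <- function(avgZd, rdp, pocketSd) {
  0.06 * avgZd + 0.14 * rdp + 0.8 * pocketSd
}

#' Score one ligand conformer against a pocket
#'
#' Runs the patch matching and assembles the score components.  Mode `"pl"`
#' matches with the three-term distance score and combines
#' avgZd/avgGrpd/pocketSd; mode `"ps"` matches with the descriptor distance
#' only and combines avgZd/rdp/pocketSd with fixed weights.
#'
#' @param pocket pocket `patch_set` with descriptors.
#' @param ligand conformer `patch_set` with descriptors.
#' @param mode `"pl"` or `"ps"`.
#' @param dist_w [distance_weights()] for the matching (mode `"pl"`).
#' @param total_w [total_weights()] for the combination (mode `"pl"`).
#' @return A `score_breakdown` list: components, `total`, `matching`.
#' @export
score_conformer <- function(pocket, ligand, mode = c("pl", "ps"),
                            dist_w = matching_weights("optimized"),
                            total_w = total_weights()) {
  mode <- match.arg(mode)
  if (mode == "ps") dist_w <- distance_weights(1, 0, 0)
  m <- match_patches(pocket, ligand, w = dist_w)
  zd <- avg_zd(m)
  sd <- pocket_sd(m$n_pocket, m$n_ligand)
  if (mode == "pl") {
    gr <- if (m$N >= 2) avg_grpd(m, pocket$geodesic, ligand$geodesic) else 0
    total <- totalscore_pl(zd, gr, sd, total_w)
    out <- list(mode = "pl", avgZd = zd, avgGrpd = gr, pocketSd = sd,
                total = total, matching = m)
  } else {
    rd <- if (m$N >= 2) rdp(m, pocket$euclidean, ligand$euclidean) else 0
    total <- totalscore_ps(zd, rd, sd)
    out <- list(mode = "ps", avgZd = zd, rdp = rd, pocketSd = sd,
                total = total, matching = m)
  }
  structure(out, class = "score_breakdown")
}

#' Rank a ligand library against a pocket
#'
#' Scores every conformer of every ligand and ranks ligands by their final
#' score: the mean of the 10 best (lowest) conformer totals (all conformers
#' when fewer than 10).  Ties rank by ligand id.
#'
#' @param pocket pocket `patch_set` with descriptors.
#' @param library list of entries, each a list with `ligand_id`, `conformers`
#'   (list of descriptor-bearing `patch_set`s) and optional `active` flag.
#' @param mode,dist_w,total_w passed to [score_conformer()].
#' @param top_n number of best conformers averaged (default 10).
#' @return A `screening_result` data.frame: `ligand_id`, `final_score`,
#'   `rank`, `n_conformers_scored`, `active`.
#' @export
rank_library <- function(pocket, library, mode = "pl",
                         dist_w = matching_weights("optimized"),
                         total_w = total_weights(), top_n = 10L) {
  stopifnot(length(library) >= 1)
  rows <- lapply(library, function(entry) {
    totals <- numeric(0)
    for (cf in entry$conformers) {
      if (is.null(cf) || n_patches(cf) == 0) {
        warning("conformer with no patches skipped for ", entry$ligand_id)
        next
      }
      sb <- score_conformer(pocket, cf, mode = mode,
                            dist_w = dist_w, total_w = total_w)
      totals <- c(totals, sb$total)
    }
    if (length(totals) == 0) return(NULL)
    best <- sort(totals)[seq_len(min(top_n, length(totals)))]
    data.frame(ligand_id = entry$ligand_id,
               final_score = mean(best),
               n_conformers_scored = length(totals),
               active = isTRUE(entry$active))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$final_score, df$ligand_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("screening_result", "data.frame")
  df
}

#' Per-ligand-type pocket score over ranked conformers
#'
#' Given all database conformers ranked by total score (ascending, best
#' first), each of the `k` top ranks contributes a linearly decreasing
#' reward `k - i + 1` to its ligand type; each type's reward sum is
#' normalized by the number of its conformers in the database.  The type
#' with the highest pocket score is the predicted binder.
#'
#' @param conformer_scores data.frame with columns `ligand_type` and `total`
#'   (one row per database conformer).
#' @param k number of top ranks rewarded (default 20; capped at the table
#'   size).
#' @return named numeric vector of per-type scores, descending.
#' @export
pocket_score <- function(conformer_scores, k = 20L) {
  stopifnot(is.data.frame(conformer_scores),
            all(c("ligand_type", "total") %in% names(conformer_scores)))
  if (nrow(conformer_scores) == 0) stop("empty conformer database")
  df <- conformer_scores[order(conformer_scores$total), ]
  k <- min(k, nrow(df))
  n_type <- table(conformer_scores$ligand_type)
  reward <- numeric(length(n_type))
  names(reward) <- names(n_type)
  for (i in seq_len(k)) {
    ty <- as.character(df$ligand_type[i])
    reward[ty] <- reward[ty] + (k - i + 1)
  }
  score <- reward / as.numeric(n_type)
  sort(score, decreasing = TRUE)
}

#' Write a screening result as TSV
#'
#' @param result a `screening_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screening_tsv <- function(result, path) {
  df <- as.data.frame(result)[, c("ligand_id", "final_score", "rank",
                                  "n_conformers_scored", "active")]
  df$final_score <- sprintf("%.6f", df$final_score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
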