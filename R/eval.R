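# Benchmark machinery: native-contact maps and match success rates,
# weight grid searches, enrichment factors and ROC AUC.

#' Native-contact map between pocket and ligand patches
#'
#' In a complex structure, a pocket patch and a ligand patch form a native
#' contact when their patch centers lie within `cutoff` of each other.
#'
#' @param pocket_centers P x 3 matrix of pocket patch centers (complex frame).
#' @param ligand_centers Q x 3 matrix of ligand patch centers (same frame).
#' @param cutoff contact distance cutoff (Angstrom; typically 3-6, default 5).
#' @return A `contact_map` object with the center matrices, the cutoff and
#'   the data.frame of contact edges.
#' @export
contact_map <- function(pocket_centers, ligand_centers, cutoff = 5.0) {
  pocket_centers <- rbind(pocket_centers)
  ligand_centers <- rbind(ligand_centers)
  d2 <- outer(rowSums(pocket_centers^2), rowSums(ligand_centers^2), `+`) -
    2 * tcrossprod(pocket_centers, ligand_centers)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  edges <- data.frame(pocket = hit[, 1], ligand = hit[, 2])
  structure(list(pocket_centers = pocket_centers,
                 ligand_centers = ligand_centers,
                 cutoff = cutoff, edges = edges),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map>", nrow(x$pocket_centers), "x", nrow(x$ligand_centers),
      "patches,", nrow(x$edges), "contacts at", x$cutoff, "A\n")
  invisible(x)
}

#' Maximum attainable number of native contacts
#'
#' Size of a maximum one-to-one bipartite matching on the contact graph:
#' the largest set of contacts in which no patch is used twice.  A greedy
#' nearest-first variant (always <= the maximum) is available for
#' comparison.
#'
#' @param cm a [contact_map()].
#' @param method `"maximum"` (default, bipartite matching) or `"greedy"`.
#' @return integer count.
#' @export
max_native_contacts <- function(cm, method = c("maximum", "greedy")) {
  method <- match.arg(method)
  e <- cm$edges
  if (nrow(e) == 0) return(0L)
  if (method == "greedy") {
    d <- sqrt(rowSums((cm$pocket_centers[e$pocket, , drop = FALSE] -
                         cm$ligand_centers[e$ligand, , drop = FALSE])^2))
    e <- e[order(d), ]
    usedp <- logical(nrow(cm$pocket_centers))
    usedl <- logical(nrow(cm$ligand_centers))
    cnt <- 0L
    for (r in seq_len(nrow(e))) {
      if (!usedp[e$pocket[r]] && !usedl[e$ligand[r]]) {
        usedp[e$pocket[r]] <- TRUE; usedl[e$ligand[r]] <- TRUE
        cnt <- cnt + 1L
      }
    }
    return(cnt)
  }
  np <- nrow(cm$pocket_centers)
  nq <- nrow(cm$ligand_centers)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("p", e$pocket), to = paste0("l", e$ligand)),
    directed = FALSE,
    vertices = data.frame(name = c(paste0("p", seq_len(np)),
                                   paste0("l", seq_len(nq))),
                          type = c(rep(FALSE, np), rep(TRUE, nq))))
  igraph::max_bipartite_match(g)$matching_size
}

#' Match success rate of a matching against the native contacts
#'
#' Fraction of the maximum attainable native contacts that the matching
#' recovers: matched pairs whose patch centers lie within the contact
#' cutoff, divided by [max_native_contacts()].  Bounded by 1 because both
#' the matching and the contact bound are one-to-one.
#'
#' @param m a `patch_matching` (or a 2-column matrix of pairs).
#' @param cm a [contact_map()].
#' @return scalar in `[0, 1]`, or `NA` (with a warning) when no contact is
#'   attainable.
#' @export
match_success_rate <- function(m, cm) {
  mx <- max_native_contacts(cm)
  if (mx == 0) {
    warning("no attainable native contacts; success rate undefined")
    return(NA_real_)
  }
  pairs <- if (inherits(m, "patch_matching"))
    cbind(m$pairs$pocket, m$pairs$ligand) else rbind(m)
  d <- sqrt(rowSums((cm$pocket_centers[pairs[, 1], , drop = FALSE] -
                       cm$ligand_centers[pairs[, 2], , drop = FALSE])^2))
  sum(d <= cm$cutoff + 1e-12) / mx
}

#' Grid of reduced-parameter distance weights
#'
#' Enumerates `(a, b)` on a regular grid and maps each point to
#' `(w1, w2, w3) = (a*b, a*(1-b), 1-a)`; every triple sums to 1.
#'
#' @param step grid step in `(0, 1]` (default 0.1).
#' @return data.frame with columns `a`, `b`, `w1`, `w2`, `w3`.
#' @export
weight_grid <- function(step = 0.1) {
  if (step <= 0 || step > 1) stop("step must be in (0, 1]")
  ab <- expand.grid(b = seq(0, 1, by = step), a = seq(0, 1, by = step))
  data.frame(a = ab$a, b = ab$b,
             w1 = ab$a * ab$b, w2 = ab$a * (1 - ab$b), w3 = 1 - ab$a)[
               order(ab$a, ab$b), c("a", "b", "w1", "w2", "w3")]
}

#' Optimize matching weights on complex structures
#'
#' Exhaustive evaluation of the [weight_grid()]: for every candidate weight
#' triple, every complex is re-matched and the mean match success rate
#' computed; the argmax is returned (ties resolved towards smaller
#' `(a, b)`).
#'
#' @param complexes list of entries, each with `pocket` and `ligand`
#'   (descriptor-bearing `patch_set`s) and `contacts` (a [contact_map()]).
#' @param step grid step (default 0.1).
#' @return list: `weights` (best [distance_weights()]), `a`, `b`,
#'   `success_rate`, and the full `grid` with mean rates.
#' @export
optimize_distance_weights <- function(complexes, step = 0.1) {
  grid <- weight_grid(step)
  rates <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- distance_weights(grid$w1[g], grid$w2[g], grid$w3[g])
    rs <- vapply(complexes, function(cx) {
      m <- match_patches(cx$pocket, cx$ligand, w = w)
      match_success_rate(m, cx$contacts)
    }, numeric(1))
    rates[g] <- mean(rs, na.rm = TRUE)
  }
  grid$success_rate <- rates
  best <- which.max(rates)            # grid ordered by (a, b): first max wins ties
  list(weights = distance_weights(grid$w1[best], grid$w2[best], grid$w3[best]),
       a = grid$a[best], b = grid$b[best],
       success_rate = rates[best], grid = grid)
}

#' Enrichment factor at a ranking depth
#'
#' Fraction of actives within the top `level_pct` percent of the ranked
#' library, normalized by the overall active fraction.  1 corresponds to a
#' random ranking; EF at 100% is exactly 1.
#'
#' @param result a `screening_result` (needs `rank` and `active`).
#' @param level_pct depth in percent (e.g. 1, 10, 20).
#' @return scalar enrichment factor.
#' @export
enrichment_factor <- function(result, level_pct) {
  n <- nrow(result)
  n_act <- sum(result$active)
  if (n_act == 0) stop("no actives in the screening result")
  top <- ceiling(level_pct / 100 * n)
  hits <- sum(result$active[order(result$rank)][seq_len(top)])
  (hits / top) / (n_act / n)
}

#' Rank-based ROC AUC of a screening result
#'
#' Probability that a randomly chosen active outranks (has a lower score
#' than) a randomly chosen decoy; ties count one half.  Equivalent to the
#' normalized Mann-Whitney U statistic and invariant under monotone score
#' transforms.
#'
#' @param result a `screening_result` (needs `final_score` and `active`).
#' @return scalar in `[0, 1]`.
#' @export
roc_auc <- function(result) {
  act <- result$active
  if (all(act) || !any(act)) stop("AUC needs both actives and decoys")
  r <- rank(result$final_score, ties.method = "average")
  n1 <- sum(act); n0 <- sum(!act)
  u <- n1 * n0 + n1 * (n1 + 1) / 2 - sum(r[act])
  u / (n1 * n0)
}

#' Optimize total-score weights on training screening sets
#'
#' The matching (and hence the per-conformer components avgZd, avgGrpd,
#' pocketSd) does not depend on the total-score weights, so the components
#' are computed once per conformer and the 11^3 weight grid is then swept
#' cheaply: for every triple the ligands are re-ranked and the mean ROC AUC
#' over the training sets is evaluated.  Ties resolve to the smallest
#' `(w1, w2, w3)` lexicographically.
#'
#' @param training list of sets, each a list with `pocket` (descriptor-
#'   bearing `patch_set`) and `library` (as for [rank_library()], with
#'   `active` flags).
#' @param dist_w matching weights used throughout.
#' @param step weight grid step (default 0.1).
#' @param top_n conformers averaged per ligand (default 10).
#' @return list: `weights` (best [total_weights()]), `auc`, and the swept
#'   `grid` with mean AUCs.
#' @export
optimize_total_weights <- function(training, dist_w = matching_weights("optimized"),
                                   step = 0.1, top_n = 10L) {
  comp <- lapply(training, function(set) {
    lapply(set$library, function(entry) {
      mat <- t(vapply(entry$conformers, function(cf) {
        m <- match_patches(set$pocket, cf, w = dist_w)
        zd <- avg_zd(m)
        gr <- if (m$N >= 2) avg_grpd(m, set$pocket$geodesic, cf$geodesic) else 0
        sd <- pocket_sd(m$n_pocket, m$n_ligand)
        c(zd, gr, sd)
      }, numeric(3)))
      list(ligand_id = entry$ligand_id, active = isTRUE(entry$active),
           components = mat)
    })
  })
  ws <- seq(0, 1, by = step)
  grid <- expand.grid(w3 = ws, w2 = ws, w1 = ws)[, c("w1", "w2", "w3")]
  grid <- grid[order(grid$w1, grid$w2, grid$w3), ]
  aucs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    wv <- as.numeric(grid[g, ])
    set_aucs <- vapply(comp, function(set) {
      fs <- vapply(set, function(entry) {
        totals <- entry$components %*% wv
        mean(sort(totals)[seq_len(min(top_n, length(totals)))])
      }, numeric(1))
      act <- vapply(set, function(entry) entry$active, logical(1))
      roc_auc(data.frame(final_score = fs, active = act))
    }, numeric(1))
    aucs[g] <- mean(set_aucs)
  }
  grid$auc <- aucs
  best <- which.max(aucs)             # grid sorted lexicographically: first max
  list(weights = total_weights(grid$w1[best], grid$w2[best], grid$w3[best]),
       auc = aucs[best], grid = grid)
}
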