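# Contact maps, success rates, weight grids, enrichment and AUC.

test_that("maximum native contacts is a one-to-one bipartite bound", {
  # 2x2 all within cutoff -> 2
  cm <- contact_map(rbind(c(0, 0, 0), c(1, 0, 0)),
                    rbind(c(0, 1, 0), c(1, 1, 0)), cutoff = 5)
  expect_equal(max_native_contacts(cm), 2)
  # one ligand patch near three pocket patches -> 1
  cm2 <- contact_map(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                     rbind(c(1, 1, 0)), cutoff = 5)
  expect_equal(max_native_contacts(cm2), 1)
  # nothing within cutoff -> 0
  cm3 <- contact_map(rbind(c(0, 0, 0)), rbind(c(10, 0, 0)), cutoff = 5)
  expect_equal(max_native_contacts(cm3), 0)
  # greedy variant never exceeds the maximum
  pair <- cached_pair()
  expect_lte(max_native_contacts(pair$contacts, method = "greedy"),
             max_native_contacts(pair$contacts))
})

test_that("match success rate counts in-cutoff matched pairs over the bound", {
  pc <- rbind(c(0, 0, 0), c(10, 0, 0))
  lc <- rbind(c(1, 0, 0), c(11, 0, 0))
  cm <- contact_map(pc, lc, cutoff = 5)
  expect_equal(match_success_rate(cbind(1:2, 1:2), cm), 1)
  expect_equal(match_success_rate(cbind(1:2, 2:1), cm), 0)  # crossed: 9/11 A apart
  expect_equal(match_success_rate(cbind(1, 1), cm), 0.5)
  expect_warning(v <- match_success_rate(cbind(1, 1),
                                         contact_map(pc, lc + 100, cutoff = 5)),
                 "undefined")
  expect_true(is.na(v))
})

test_that("success rate stays within [0, 1] under arbitrary pairings", {
  pair <- cached_pair()
  cm <- pair$contacts
  nA <- nrow(cm$pocket_centers); nB <- nrow(cm$ligand_centers)
  with_seed(55, for (i in 1:25) {
    k <- min(nA, nB)
    sr <- match_success_rate(cbind(sample(nA, k), sample(nB, k)), cm)
    expect_gte(sr, 0); expect_lte(sr, 1)
  })
})

test_that("the weight grid spans 121 simplex triples including both presets", {
  g <- weight_grid(0.1)
  expect_equal(nrow(g), 121)
  expect_true(all(abs(g$w1 + g$w2 + g$w3 - 1) < 1e-12))
  expect_true(any(abs(g$w1 - 0.35) < 1e-9 & abs(g$w2 - 0.15) < 1e-9 &
                    abs(g$w3 - 0.5) < 1e-9))
  expect_true(any(abs(g$w1 - 0.32) < 1e-9 & abs(g$w2 - 0.48) < 1e-9 &
                    abs(g$w3 - 0.2) < 1e-9))
  expect_error(weight_grid(0), "step")
})

test_that("enrichment factor follows its definition and equals 1 at 100%", {
  res <- data.frame(rank = 1:100, active = c(rep(TRUE, 10), rep(FALSE, 90)),
                    final_score = seq(0.1, 10, length.out = 100))
  class(res) <- c("screening_result", "data.frame")
  expect_equal(enrichment_factor(res, 10), 10)     # all actives on top
  expect_equal(enrichment_factor(res, 100), 1)
  worst <- res; worst$active <- rev(res$active)
  expect_equal(enrichment_factor(worst, 10), 0)
  expect_error(enrichment_factor(transform(res, active = FALSE), 10), "active")
})

test_that("random rankings have expected enrichment near 1", {
  base <- data.frame(active = c(rep(TRUE, 10), rep(FALSE, 90)))
  efs <- with_seed(7, replicate(1000, {
    shuffled <- base[sample(nrow(base)), , drop = FALSE]
    shuffled$rank <- seq_len(nrow(shuffled))
    class(shuffled) <- c("screening_result", "data.frame")
    enrichment_factor(shuffled, 20)
  }))
  expect_equal(mean(efs), 1, tolerance = 0.1)
})

test_that("rank AUC matches its probabilistic definition and pROC", {
  res <- data.frame(final_score = c(0.1, 0.2, 0.8, 0.9),
                    active = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(res), 1)
  res$active <- rev(res$active)
  expect_equal(roc_auc(res), 0)
  tied <- data.frame(final_score = rep(0.5, 6),
                     active = rep(c(TRUE, FALSE), 3))
  expect_equal(roc_auc(tied), 0.5)
  # monotone transform invariance + cross-check against pROC
  with_seed(23, {
    sc <- stats::runif(40)
    lab <- stats::runif(40) < 0.3
    if (any(lab) && any(!lab)) {
      r1 <- roc_auc(data.frame(final_score = sc, active = lab))
      r2 <- roc_auc(data.frame(final_score = exp(3 * sc), active = lab))
      expect_equal(r1, r2)
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = lab, predictor = sc, direction = ">", quiet = TRUE)))
      expect_equal(r1, as.numeric(ref), tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(data.frame(final_score = 1:3, active = rep(TRUE, 3))),
               "decoys")
})

test_that("distance-weight optimization returns the grid argmax with tie-break", {
  # constructed complex where only a grpd-heavy triple recovers the contact:
  # use a real fixture and check argmax consistency instead of a tautology
  pair <- cached_pair()
  cx <- list(list(pocket = pair$pocket, ligand = pair$ligand_patches,
                  contacts = pair$contacts))
  opt <- optimize_distance_weights(cx, step = 0.5)
  expect_equal(opt$success_rate, max(opt$grid$success_rate))
  first_max <- which.max(opt$grid$success_rate)
  expect_equal(opt$a, opt$grid$a[first_max])
  expect_equal(opt$b, opt$grid$b[first_max])
  expect_equal(nrow(weight_grid(0.5)), 9)
})

test_that("total-weight optimization sweeps the 11^3 grid by component reuse", {
  pair <- cached_pair()
  lib <- list(list(ligand_id = "act", active = TRUE,
                   conformers = list(pair$ligand_patches)),
              list(ligand_id = "dec", active = FALSE,
                   conformers = list(pair$pocket)))
  # coarse grid for speed; structure checks only
  opt <- optimize_total_weights(list(list(pocket = pair$pocket, library = lib)),
                                step = 0.5)
  expect_equal(nrow(opt$grid), 27)
  expect_equal(opt$auc, max(opt$grid$auc))
  full <- optimize_total_weights(list(list(pocket = pair$pocket, library = lib)),
                                 step = 0.1)
  expect_equal(nrow(full$grid), 1331)
  expect_gte(full$auc, opt$auc)
})
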