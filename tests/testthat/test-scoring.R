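# Total-score components, library ranking and pocket score.

fake_matching <- function(pockets, ligands, pdists,
                          n_pocket = max(pockets), n_ligand = max(ligands)) {
  structure(list(pairs = data.frame(pocket = pockets, ligand = ligands,
                                    pdist = pdists, appd = 0, grpd = 0,
                                    total = pdists),
                 N = length(pockets), weights = matching_weights("optimized"),
                 n_pocket = n_pocket, n_ligand = n_ligand),
            class = "patch_matching")
}

test_that("avgZd is the mean pair pdist, with an optional coverage factor", {
  m <- fake_matching(1:2, 1:2, c(0.2, 0.4), n_pocket = 10)
  expect_equal(avg_zd(m), 0.3)
  expect_equal(avg_zd(m, coverage = TRUE), 0.3 * 10 / 2)
  expect_equal(avg_zd(fake_matching(1, 1, 0.7)), 0.7)
  expect_equal(avg_zd(fake_matching(1:3, 1:3, c(0, 0, 0))), 0)
})

test_that("avgGrpd and rdp measure layout congruence over pair couples", {
  G2A <- matrix(c(0, 5, 5, 0), 2)
  G2B <- matrix(c(0, 3, 3, 0), 2)
  m <- fake_matching(1:2, 1:2, c(0, 0))
  expect_equal(avg_grpd(m, G2A, G2B), 2)
  expect_equal(rdp(m, G2A, G2B), 2)
  expect_equal(avg_grpd(m, G2A, G2A), 0)           # congruent layouts
  expect_warning(v <- avg_grpd(fake_matching(1, 1, 0), G2A, G2B), "fewer")
  expect_equal(v, 0)
  # symmetric roles of the two sides
  expect_equal(rdp(m, G2B, G2A), rdp(m, G2A, G2B))
})

test_that("avgGrpd matches a brute-force couple enumeration", {
  with_seed(17, {
    n <- 5
    G2A <- as.matrix(stats::dist(matrix(stats::runif(12, 0, 10), 6)))
    G2B <- as.matrix(stats::dist(matrix(stats::runif(10, 0, 10), 5)))
    a <- sample(6, n); b <- sample(5, n)
    m <- fake_matching(a, b, rep(0, n), n_pocket = 6, n_ligand = 5)
    acc <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      acc <- acc + abs(G2A[a[i], a[j]] - G2B[b[i], b[j]])
    expect_equal(avg_grpd(m, G2A, G2B), acc * 2 / (n * (n - 1)))
  })
})

test_that("pocket size difference is relative and bounded", {
  expect_equal(pocket_sd(7, 7), 0)
  expect_equal(pocket_sd(20, 10), 0.5)
  expect_equal(pocket_sd(10, 20), 0.5)
  with_seed(4, for (i in 1:20) {
    n <- sample(1:50, 2)
    v <- pocket_sd(n[1], n[2])
    expect_gte(v, 0); expect_lt(v, 1)
  })
  expect_error(pocket_sd(0, 5), ">= 1")
})

test_that("total scores combine components with the stated weights", {
  expect_equal(totalscore_pl(0.5, 0, 0.2, total_weights(0.8, 0, 0.1)), 0.42)
  expect_equal(totalscore_pl(0.5, 0.3, 0.2, total_weights(1, 0, 0)), 0.5)
  # monotone in each component
  base <- totalscore_pl(0.5, 0.3, 0.2)
  expect_gt(totalscore_pl(0.6, 0.3, 0.2), base)
  expect_equal(totalscore_ps(0, 0, 0), 0)
  expect_equal(totalscore_ps(1, 1, 1), 1)        # 0.06 + 0.14 + 0.8
  expect_equal(totalscore_ps(1, 0, 0), 0.06)
})

test_that("library ranking averages the ten best conformers and orders ascending", {
  pair <- cached_pair()
  ligp <- pair$ligand_patches
  # a ligand with 12 identical conformers: final score equals any single score
  lib <- list(list(ligand_id = "L1", active = TRUE,
                   conformers = rep(list(ligp), 12)),
              list(ligand_id = "L2", active = FALSE,
                   conformers = list(ligp)))
  res <- rank_library(pair$pocket, lib)
  expect_s3_class(res, "screening_result")
  expect_equal(sort(res$rank), 1:2)
  expect_equal(res$n_conformers_scored[res$ligand_id == "L1"], 12)
  # identical conformers: both ligands tie in score; ranks break by id
  expect_equal(res$final_score[1], res$final_score[2], tolerance = 1e-9)
  expect_equal(res$ligand_id[res$rank == 1], "L1")
})

test_that("pocket score rewards top ranks normalized per type", {
  db <- data.frame(ligand_type = c("L1", "L1", "L2"),
                   total = c(0.1, 0.2, 0.3))
  sc <- pocket_score(db, k = 3)
  expect_equal(unname(sc["L1"]), (3 + 2) / 2)
  expect_equal(unname(sc["L2"]), 1 / 1)
  expect_equal(names(sc)[1], "L1")
  # all-top-k of one type wins regardless of the other's size
  db2 <- data.frame(ligand_type = c(rep("A", 3), rep("B", 5)),
                    total = c(1:3 / 10, 5:9 / 10))
  expect_equal(names(pocket_score(db2, k = 3))[1], "A")
  expect_error(pocket_score(db2[0, ], k = 3), "empty")
  # k larger than the table falls back to the full list
  expect_silent(pocket_score(db, k = 50))
})
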