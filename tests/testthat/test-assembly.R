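test_that("cophenetic distances are path sums forming a metric", {
  d2 <- cophenetic_distances(tree_ab())
  expect_equal(d2["A", "B"], 2)

  d3 <- cophenetic_distances(tree_abc())
  expect_equal(d3["A", "C"], 4)
  expect_equal(d3["A", "B"], 2)
  expect_equal(unname(diag(d3)), c(0, 0, 0))
  # triangle inequality on all triples
  ids <- rownames(d3)
  for (i in ids) for (j in ids) for (k in ids) {
    expect_lte(d3[i, j], d3[i, k] + d3[k, j] + 1e-12)
  }
})

test_that("beta-MNTD matches hand values and the brute-force loop", {
  d <- cophenetic_distances(tree_ab())
  # identical samples: every nearest-taxon distance is 0
  x <- c(A = 3, B = 1)
  expect_equal(beta_mntd(x, d, y = x), 0)
  # disjoint singletons on the 2-tip tree
  expect_equal(beta_mntd(c(A = 5, B = 0), d, y = c(A = 0, B = 2)), 2)

  # weighted 4-taxon fixture against the independent loop
  tr <- tree_4tip()
  d4 <- cophenetic_distances(tr)
  xa <- c(t1 = 5, t2 = 0, t3 = 2, t4 = 1)
  xb <- c(t1 = 0, t2 = 3, t3 = 0, t4 = 4)
  expect_equal(beta_mntd(xa, d4, y = xb),
               brute_beta_mntd(xa, xb, d4), tolerance = 1e-14)
  expect_equal(beta_mntd(xa, d4, weighted = FALSE, y = xb),
               brute_beta_mntd(xa, xb, d4, weighted = FALSE),
               tolerance = 1e-14)
})

test_that("all-pairs beta-MNTD agrees with the pairwise form and with picante", {
  tr <- simulate_tree(12, seed = 4)
  d <- cophenetic_distances(tr)
  m <- withr::with_seed(2, matrix(stats::rpois(12 * 5, 3), 12, 5,
    dimnames = list(tr$tip.label, paste0("s", 1:5))))
  mine <- as.matrix(beta_mntd(m, d))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(mine[i, j], beta_mntd(m[, i], d, y = m[, j]),
                 tolerance = 1e-12)
  }
  pic <- as.matrix(picante::comdistnt(t(m), d, abundance.weighted = TRUE))
  expect_equal(unname(mine), unname(pic[rownames(mine), colnames(mine)]),
               tolerance = 1e-12)
})

test_that("exhaustive betaNTI null matches brute-force enumeration of all 24 relabelings", {
  tr <- tree_4tip()
  d <- cophenetic_distances(tr)
  m <- matrix(c(10L, 5L, 0L, 0L,
                0L, 0L, 8L, 2L), 4,
              dimnames = list(tr$tip.label, c("s1", "s2")))

  res <- beta_nti(m, tr, mode = "exhaustive")

  # independent enumeration with the pairwise reference implementation
  perms <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    perms <- rbind(perms, c(a, b, cc, setdiff(1:4, c(a, b, cc))))
  }
  nulls <- apply(perms, 1, function(pp) {
    dp <- d[pp, pp]
    dimnames(dp) <- dimnames(d)
    brute_beta_mntd(m[, 1], m[, 2], dp)
  })
  sd_pop <- sqrt(mean((nulls - mean(nulls))^2))
  expect_equal(res$reps, 24)
  expect_equal(res$null_mean[1, 2], mean(nulls), tolerance = 1e-12)
  expect_equal(res$null_sd[1, 2], sd_pop, tolerance = 1e-12)
  expect_equal(res$bnti[1, 2],
               (brute_beta_mntd(m[, 1], m[, 2], d) - mean(nulls)) / sd_pop,
               tolerance = 1e-12)

  # sampled mode converges to the exhaustive answer
  samp <- beta_nti(m, tr, reps = 999, seed = 9, mode = "sampled")
  expect_lt(abs(samp$bnti[1, 2] - res$bnti[1, 2]), 0.05)
})

test_that("a star tree with equal branch lengths gives a degenerate null", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  m <- matrix(c(4L, 2L, 0L, 0L,
                0L, 0L, 3L, 5L), 4,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_warning(res <- beta_nti(m, star, reps = 99, seed = 1),
                 "zero null variance")
  expect_true(is.na(res$bnti[1, 2]))
})

test_that("tables are pruned to the tree with a report", {
  tr <- tree_abc()
  m <- matrix(c(3L, 1L, 2L, 4L,
                1L, 2L, 0L, 1L), 4,
              dimnames = list(c("A", "B", "C", "zzz"), c("s1", "s2")))
  expect_message(res <- beta_nti(m, tr, reps = 49, seed = 1),
                 "dropped 1")
  expect_equal(res$n_dropped, 1)
})

test_that("Raup-Crick hits its ceiling and floor on constructed extremes", {
  # extreme bimodal pair: observed BC far above anything the
  # occupancy/abundance null produces
  m <- matrix(1L, 2, 2, dimnames = list(c("f1", "f2"), c("x", "y")))
  m[1, 1] <- 2000L   # x dominated by f1
  m[2, 2] <- 2000L   # y dominated by f2
  rc_hi <- as.matrix(raup_crick(m, reps = 199, seed = 7))
  expect_equal(rc_hi["x", "y"], 1)

  # identical even-abundance pair inside a diverse pool: more similar
  # than chance assembly, strongly negative
  pool <- withr::with_seed(21, matrix(rpois(30 * 6, 8) + 1L, 30, 6))
  pool[, 2] <- pool[, 1]
  rownames(pool) <- sprintf("f%02d", 1:30)
  colnames(pool) <- sprintf("s%d", 1:6)
  rc_lo <- as.matrix(raup_crick(pool, reps = 999, seed = 8))
  expect_lte(rc_lo["s1", "s2"], -0.9)

  # range invariant across all pairs
  expect_true(all(abs(as.matrix(rc_lo)) <= 1))
  expect_error(raup_crick(m[, 1, drop = FALSE]), "2 samples")
})

test_that("the five process rules map exactly, including boundaries", {
  mk <- function(b, r) {
    bm <- matrix(c(NA, b, b, NA), 2,
                 dimnames = list(c("s1", "s2"), c("s1", "s2")))
    rm_ <- matrix(c(0, r, r, 0), 2, dimnames = dimnames(bm))
    classify_processes(bm, rm_)$process
  }
  expect_identical(mk(3.0, 0.1), "heterogeneous selection")
  expect_identical(mk(-2.5, 0.99), "homogeneous selection")
  expect_identical(mk(0.0, 0.99), "dispersal limitation")
  expect_identical(mk(0.0, -0.99), "homogenizing dispersal")
  expect_identical(mk(0.0, 0.0), "undominated")
  # strict thresholds: boundary values fall to the weaker side
  expect_identical(mk(2.0, 0.0), "undominated")
  expect_identical(mk(-2.0, 0.0), "undominated")
  expect_identical(mk(2.0, 0.99), "dispersal limitation")
  expect_identical(mk(0.0, 0.95), "undominated")
  expect_identical(mk(0.0, -0.95), "undominated")
  # missing betaNTI propagates as NA
  expect_true(is.na(mk(NA, 0.5)))
})

test_that("process fractions sum to one per stratum and ignore ordering", {
  proc <- tibble::tibble(
    sample_i = c("a", "a", "b"),
    sample_j = c("b", "c", "c"),
    bnti = c(3, 0, 0), rc_bray = c(0, 0.99, 0),
    process = c("heterogeneous selection", "dispersal limitation",
                "undominated")
  )
  md <- tibble::tibble(sample_id = c("a", "b", "c"),
                       stage = c("S1", "S1", "S2"))
  fr <- process_fractions(proc, md)
  for (p in unique(fr$pairing)) {
    sub <- fr[fr$pairing == p, ]
    if (sum(sub$n) > 0) expect_equal(sum(sub$fraction), 1, tolerance = 1e-9)
  }
  expect_equal(fr$fraction[fr$pairing == "S1" &
                             fr$process == "heterogeneous selection"], 1)
  # permuting the rows leaves the fractions unchanged
  fr2 <- process_fractions(proc[c(3, 1, 2), ], md)
  expect_equal(dplyr::arrange(fr, pairing, process),
               dplyr::arrange(fr2, pairing, process))
})

test_that("known assembly processes are recovered from simulated communities", {
  het <- simulate_assembly(assembly_scenario("heterogeneous_selection",
                                             seed = 11))
  bn_het <- suppressWarnings(beta_nti(het$table, het$tree, reps = 299,
                                      seed = 5))
  v <- bn_het$bnti[upper.tri(bn_het$bnti)]
  expect_gt(mean(v > 2, na.rm = TRUE), 0.5)

  neu <- simulate_assembly(assembly_scenario("neutral_drift", seed = 11))
  bn_neu <- suppressWarnings(beta_nti(neu$table, neu$tree, reps = 299,
                                      seed = 5))
  w <- bn_neu$bnti[upper.tri(bn_neu$bnti)]
  expect_gt(mean(abs(w) < 2, na.rm = TRUE), 0.6)
})
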