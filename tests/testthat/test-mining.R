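test_that("a single edge yields exactly its three sub-patterns", {
  g <- parse_cfg_glycan("Aa1-4B")
  mined <- mine_frequent_subtrees(list(g), 1.0)
  expect_equal(mined$code, sort(c("A", "B", "B(a1-4>A)")))
  expect_equal(mined$support, rep(1, 3))
})

test_that("support thresholds behave as ceilings on glycan counts", {
  gs <- lapply(c("Aa1-4B", "Aa1-4B", "Ca1-2B"), parse_cfg_glycan)
  mined <- mine_frequent_subtrees(gs, 0.5)  # need 2 of 3
  expect_true(all(mined$count >= 2))
  expect_true("B(a1-4>A)" %in% mined$code)
  expect_false("B(a1-2>C)" %in% mined$code)
  # ceiling beyond n: impossible threshold still legal input
  expect_error(mine_frequent_subtrees(gs, 0), "fraction")
  expect_error(mine_frequent_subtrees(gs, 1.5), "fraction")
})

test_that("embedding multiplicity does not inflate per-glycan support", {
  # two identical branches: one glycan, support must still be 1 glycan
  g <- parse_cfg_glycan("Aa1-2(Aa1-3)B")
  mined <- mine_frequent_subtrees(list(g, parse_cfg_glycan("D")), 0.5)
  row <- mined[mined$code == "A", ]
  expect_equal(row$count, 1L)
})

test_that("the Fig.-2-style trio mines the restricted discriminating motif", {
  ae <- fig2_fixture()
  cap <- build_capability_map(ae$glycans)
  aug <- lapply(ae$glycans, add_restricted_linkages, cap = cap)
  mined <- mine_frequent_subtrees(aug, 1 / 3)
  expect_true("GalNAc(b1-3>Gal(*3,6>X))" %in% mined$code)
  # restricted nodes never stand alone and never root a pattern
  expect_false(any(startsWith(mined$code, "X")))
})

test_that("miner equals the exhaustive enumeration oracle on random sets", {
  set.seed(61)
  for (rep in 1:6) {
    gs <- random_small_collection(8, augment = TRUE)
    truth <- oracle_pattern_counts(gs)
    for (ms in c(0.2, 0.5, 1.0)) {
      mined <- mine_frequent_subtrees(gs, ms)
      need <- ceiling(ms * length(gs))
      keep <- truth[truth >= need]
      expect_equal(sort(mined$code), sort(names(keep)))
      expect_equal(mined$count[order(mined$code)],
                   unname(keep[sort(names(keep))]))
    }
  }
})

test_that("candidate mining unions global and positive-set subtrees", {
  # planted motif in 45% of the 10 positives would be elsewhere too rare
  set.seed(77)
  pos <- lapply(1:10, function(i) {
    if (i <= 5) parse_cfg_glycan("Qa1-2R") else random_small_collection(1, augment = FALSE)[[1]]
  })
  neg <- c(lapply(1:2, function(i) parse_cfg_glycan("Qa1-2R")),
           random_small_collection(88, augment = FALSE))
  gs <- c(pos, neg)
  cand <- mine_candidate_motifs(gs, positive = 1:10,
                                global_min_support = 0.10,
                                positive_min_support = 0.40)
  row <- cand[cand$code == "R(a1-2>Q)", ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$provenance, "positive")
  # support reported over the full collection
  expect_equal(row$count, 7L)
  # provenance "both" for patterns frequent in both sets
  expect_true(all(cand$provenance %in% c("global", "positive", "both")))
  expect_false(anyDuplicated(cand$code) > 0)

  expect_warning(out <- mine_candidate_motifs(gs, positive = integer(0)),
                 "no positive")
  expect_true(all(out$provenance == "global"))
})

test_that("identical glycans at full support recover every subtree once", {
  gs <- lapply(rep("Aa1-4B", 4), parse_cfg_glycan)
  cand <- mine_candidate_motifs(gs, positive = 1:4,
                                global_min_support = 1, positive_min_support = 1)
  expect_equal(sort(cand$code), sort(c("A", "B", "B(a1-4>A)")))
  expect_true(all(cand$provenance == "both"))
})

test_that("feature matrices agree with direct containment checks", {
  ae <- fig2_fixture()
  cap <- build_capability_map(ae$glycans)
  aug <- lapply(ae$glycans, add_restricted_linkages, cap = cap)
  disc <- parse_motif_text("(*3,6)Gal b1-3GalNAc")
  mat <- compute_feature_matrix(aug, list(disc), labels = c(1, 0, 0))
  expect_equal(unname(mat[, 1]), c(1L, 0L, 0L))
  expect_equal(attr(mat, "labels"), c(1, 0, 0))

  empty <- compute_feature_matrix(aug, character(0))
  expect_equal(dim(empty), c(3L, 0L))

  # dual route: mined occurrence lists versus contains_motif, random sets
  set.seed(83)
  for (rep in 1:4) {
    gs <- random_small_collection(10, augment = TRUE)
    mined <- mine_frequent_subtrees(gs, 0.2)
    mat <- compute_feature_matrix(gs, mined$code)
    from_occ <- glycanmotifs:::matrix_from_occ(length(gs), mined$occ)
    expect_equal(unname(mat), from_occ)
    # every mined motif's column mean meets the mining threshold
    expect_true(all(colMeans(mat) >= 0.2))
  }
})

test_that("mining is deterministic", {
  set.seed(19)
  gs <- random_small_collection(12, augment = TRUE)
  a <- mine_frequent_subtrees(gs, 0.25)
  b <- mine_frequent_subtrees(gs, 0.25)
  expect_identical(a, b)
})
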