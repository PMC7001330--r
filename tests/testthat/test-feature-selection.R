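test_that("anomeric augmentation adds only variants observed in the data", {
  # the motif hangs only from alpha linkages here
  gs <- lapply(c("Galb1-3GalNAca1-6Man", "Galb1-3GalNAca1-3Man", "Man"),
               parse_cfg_glycan)
  pool <- augment_with_parent_anomer("GalNAc(b1-3>Gal)", gs)
  pans <- pool$parent_anomer[pool$code == "GalNAc(b1-3>Gal)"]
  expect_setequal(pans[!is.na(pans)], c("a", "ab"))
  expect_true(any(is.na(pool$parent_anomer)))

  # motif only ever at glycan roots: no variants possible
  gs2 <- lapply(c("Galb1-3GalNAc", "Man"), parse_cfg_glycan)
  pool2 <- augment_with_parent_anomer("GalNAc(b1-3>Gal)", gs2)
  expect_true(all(is.na(pool2$parent_anomer[pool2$code == "GalNAc(b1-3>Gal)"])))

  # the ABA-style target Gal b1-3GalNAc alpha is representable
  gs3 <- lapply(c("Galb1-3GalNAca1-3Glc", "Glc"), parse_cfg_glycan)
  pool3 <- augment_with_parent_anomer("GalNAc(b1-3>Gal)", gs3)
  j <- which(pool3$code == "GalNAc(b1-3>Gal)" &
               !is.na(pool3$parent_anomer) & pool3$parent_anomer == "a")
  expect_length(j, 1L)
  m <- decode_canonical_code(pool3$code[j], pool3$parent_anomer[j])
  expect_equal(write_motif_text(m), "Gal β1-3GalNAc α")
})

test_that("the augmentation occurrence matrix matches direct containment", {
  set.seed(15)
  gs <- random_small_collection(12, augment = TRUE)
  mined <- mine_frequent_subtrees(gs, 0.25)
  pool <- augment_with_parent_anomer(mined$code[mined$size >= 1][1:min(5, nrow(mined))], gs)
  mat <- attr(pool, "matrix")
  direct <- compute_feature_matrix(gs, pool)
  expect_equal(unname(mat), unname(direct))
})

test_that("a second mRMR round prefers a strictly more predictive variant", {
  # binding requires the alpha-linked form of the motif
  set.seed(44)
  base <- c("Galb1-3GalNAca1-3Man", "Galb1-3GalNAcb1-3Man")
  texts <- c(rep(base[1], 12), rep(base[2], 12),
             replicate(26, write_glycan_text(random_glycan(max_depth = 2))))
  gs <- lapply(texts, parse_cfg_glycan)
  y <- c(rep(1, 12), rep(0, 38))
  pool <- augment_with_parent_anomer("GalNAc(b1-3>Gal)", gs)
  sel <- second_round_mrmr(pool, gs, y, 3)
  expect_equal(sel$parent_anomer[1], "a")
  expect_equal(sel$code[1], "GalNAc(b1-3>Gal)")

  # feature budget larger than the pool returns the whole pool
  sel_all <- second_round_mrmr(pool, gs, y, 100)
  expect_equal(nrow(sel_all), nrow(pool))
})

test_that("MCC follows its closed form with the zero-marginal convention", {
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(10, 0, 10, 0), 0)
  expect_equal(mcc(90, 80, 20, 10),
               7000 / sqrt(110 * 100 * 100 * 90), tolerance = 1e-12)
  expect_equal(mcc(90, 80, 20, 10), 0.70353, tolerance = 1e-5)
})

test_that("L1 selection keeps an informative feature and drops pure noise", {
  set.seed(21)
  n <- 120
  y <- rep(c(1, 0), c(30, 90))
  X <- matrix(rbinom(n * 10, 1, 0.4), n, 10)
  X[, 4] <- ifelse(runif(n) < 0.95, y, 1 - y)
  res <- l1_select(X, y, seed = 2)
  expect_true(4L %in% res$selected)
  expect_true(all(abs(res$coef) > 1e-8))
  expect_true(all(res$selected %in% seq_len(10)))
  # strongest regularisation in the grid zeroes everything
  full <- glycanmotifs:::fit_weighted_logistic(X, y, C = 1e-4, alpha = 1)
  expect_true(all(abs(full$coef) < 1e-8))
})

test_that("ties in cross-validated MCC resolve to the smallest C", {
  set.seed(33)
  n <- 60
  y <- rep(c(1, 0), c(20, 40))
  X <- cbind(y, rbinom(n, 1, 0.5))  # perfectly separating feature
  res <- l1_select(X, y, seed = 6)
  top <- max(res$cv_mcc)
  winners <- which(res$cv_mcc >= top - 1e-12)
  expect_equal(unname(res$c_best), sort(default_c_grid())[winners[1]])
})

test_that("L1 selection is stable under duplicating a sample pair", {
  set.seed(52)
  n <- 100
  y <- rep(c(1, 0), c(25, 75))
  X <- matrix(rbinom(n * 6, 1, 0.5), n, 6)
  X[, 2] <- ifelse(runif(n) < 0.85, y, 1 - y)
  base <- l1_select(X, y, seed = 9)
  dup <- c(seq_len(n), which(y == 1)[1], which(y == 0)[1])
  again <- l1_select(X[dup, ], y[dup], seed = 9)
  expect_true(2L %in% base$selected)
  expect_true(2L %in% again$selected)
})

test_that("VIF pruning removes exactly the perfectly collinear columns", {
  set.seed(64)
  a <- rbinom(50, 1, 0.5)
  b <- rbinom(50, 1, 0.5)
  # identical pair: exactly one goes
  res <- vif_prune(cbind(a, a, b), relevance = c(2, 1, 3))
  expect_length(res$keep, 2L)
  expect_true(1L %in% res$keep)  # higher relevance copy retained
  expect_false(2L %in% res$keep)
  expect_true(all(is.finite(res$vif)))

  # orthogonal balanced columns keep VIF 1
  x1 <- rep(c(1, 0, 1, 0), 10)
  x2 <- rep(c(1, 1, 0, 0), 10)
  res2 <- vif_prune(cbind(x1, x2))
  expect_equal(res2$vif, c(1, 1))

  # exact linear combination x3 = x1 + x2 (disjoint supports)
  u <- rep(c(1, 0, 0), 12)
  v <- rep(c(0, 1, 0), 12)
  res3 <- vif_prune(cbind(u, v, u + v), relevance = c(3, 2, 1))
  expect_length(res3$keep, 2L)
  expect_false(3L %in% res3$keep)

  # never removes the last feature
  cnst <- matrix(1, 20, 1)
  res4 <- vif_prune(cnst)
  expect_equal(res4$keep, 1L)
})
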