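fig2_trees <- function() {
  lapply(c("Galb1-3GalNAc", "Neu5Aca2-3Galb1-3GalNAc", "Neu5Aca2-6Galb1-3GalNAc"),
         parse_cfg_glycan)
}

test_that("capability map collects occupied positions per residue label", {
  gs <- fig2_trees()
  cap <- build_capability_map(gs)
  expect_equal(cap$Gal, c(3L, 6L))
  expect_equal(cap$GalNAc, 3L)
  expect_null(cap$Neu5Ac)

  duo <- list(parse_cfg_glycan("Aa1-4B"))
  cap2 <- build_capability_map(duo)
  expect_equal(cap2$B, 4L)
  expect_null(cap2$A)

  # unknown '?' positions never certify capability
  cap3 <- build_capability_map(list(parse_cfg_glycan("Gala1-?GlcNAc")))
  expect_null(cap3$GlcNAc)
})

test_that("restricted-linkage augmentation fills capable unoccupied positions", {
  gs <- fig2_trees()
  cap <- build_capability_map(gs)
  aug <- lapply(gs, add_restricted_linkages, cap = cap)
  expect_equal(canonical_code(aug[[1]]), "GalNAc(b1-3>Gal(*3,6>X))")
  expect_equal(canonical_code(aug[[2]]), "GalNAc(b1-3>Gal(*6>X)(a2-3>Neu5Ac))")
  expect_equal(canonical_code(aug[[3]]), "GalNAc(b1-3>Gal(*3>X)(a2-6>Neu5Ac))")

  # every capable position occupied -> identity
  g <- parse_cfg_glycan("Neu5Aca2-3Galb1-3GalNAc")
  cap_small <- build_capability_map(list(g))
  expect_equal(canonical_code(add_restricted_linkages(g, cap_small)),
               canonical_code(g))

  # idempotence
  once <- add_restricted_linkages(gs[[1]], cap)
  twice <- add_restricted_linkages(once, cap)
  expect_equal(canonical_code(twice), canonical_code(once))
})

test_that("canonical codes are invariant to child order and label-sensitive", {
  a <- glycan_tree(c("GlcNAc", "Gal", "Fuc"), c(0L, 1L, 1L),
                   c(NA, "b1-4", "a1-3"))
  b <- glycan_tree(c("GlcNAc", "Fuc", "Gal"), c(0L, 1L, 1L),
                   c(NA, "a1-3", "b1-4"))
  expect_equal(canonical_code(a), canonical_code(b))
  expect_false(canonical_code(parse_cfg_glycan("Galb1-3GalNAc")) ==
                 canonical_code(parse_cfg_glycan("Galb1-4GalNAc")))
})

test_that("canonical code equality matches the isomorphism oracle", {
  set.seed(23)
  n_checked <- 0L
  for (i in 1:150) {
    gs <- random_small_collection(2, augment = (i %% 2 == 0))
    a <- gs[[1]]
    b <- gs[[2]]
    expect_equal(canonical_code(a) == canonical_code(b),
                 oracle_isomorphic(a, b))
    # shuffled child order must stay isomorphic
    perm <- sample(seq_along(a$label))
    inv <- order(perm)
    pp <- a$parent[perm]
    nz <- pp != 0L
    pp[nz] <- inv[pp[nz]]
    shuf <- glycan_tree(a$label[perm], pp, a$elab[perm])
    expect_equal(canonical_code(shuf), canonical_code(a))
    expect_true(oracle_isomorphic(shuf, a))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 150L)
})

test_that("decode inverts canonical codes", {
  set.seed(31)
  for (i in 1:25) {
    g <- random_small_collection(1, augment = TRUE)[[1]]
    cd <- canonical_code(g)
    expect_equal(canonical_code(decode_canonical_code(cd)), cd)
  }
  expect_error(decode_canonical_code("Gal(b1-3>"), "malformed")
})

test_that("containment honours labels, restricted sets and parent anomers", {
  gs <- fig2_trees()
  cap <- build_capability_map(gs)
  aug <- lapply(gs, add_restricted_linkages, cap = cap)

  gal <- glycan_motif("Gal", 0L)
  expect_true(all(vapply(aug, contains_motif, logical(1), m = gal)))

  disc <- parse_motif_text("(*3,6)Gal b1-3GalNAc")
  expect_equal(vapply(aug, contains_motif, logical(1), m = disc),
               c(TRUE, FALSE, FALSE))
  # restricted sets compare by equality, not subset
  sub <- parse_motif_text("(*6)Gal b1-3GalNAc")
  expect_false(contains_motif(aug[[1]], sub))
  expect_true(contains_motif(aug[[3]], parse_motif_text("(*3)Gal b1-3GalNAc")))

  # parent-anomer constraints
  root_gal <- parse_cfg_glycan("GlcNAcb1-4Gal")  # Gal is the root
  expect_false(contains_motif(root_gal, glycan_motif("Gal", 0L, parent_anomer = "a")))
  expect_true(contains_motif(parse_cfg_glycan("Galb1-4GlcNAc"),
                             glycan_motif("Gal", 0L, parent_anomer = "b")))
  expect_false(contains_motif(parse_cfg_glycan("Galb1-4GlcNAc"),
                              glycan_motif("Gal", 0L, parent_anomer = "a")))
  expect_true(contains_motif(parse_cfg_glycan("Galb1-4GlcNAc"),
                             glycan_motif("Gal", 0L, parent_anomer = "ab")))
  # unknown '?' anomer satisfies only the alpha/beta-agnostic constraint
  unk <- parse_cfg_glycan("Gal?1-4GlcNAc")
  expect_false(contains_motif(unk, glycan_motif("Gal", 0L, parent_anomer = "a")))
  expect_true(contains_motif(unk, glycan_motif("Gal", 0L, parent_anomer = "ab")))
})

test_that("every augmented glycan contains itself as a motif", {
  set.seed(7)
  gs <- random_small_collection(12, augment = TRUE)
  for (g in gs) expect_true(contains_motif(g, as_motif(g)))
})

test_that("extending a motif can only shrink its occurrence set", {
  set.seed(41)
  for (rep in 1:8) {
    gs <- random_small_collection(10, augment = TRUE)
    mined <- mine_frequent_subtrees(gs, 0.1)
    codes <- mined$code
    for (j in seq_len(nrow(mined))) {
      m <- decode_canonical_code(mined$code[j])
      occ <- which(vapply(gs, contains_motif, logical(1), m = m))
      expect_equal(occ, mined$occ[[j]])
      # compare against each sub-pattern obtained by dropping one leaf
      leaves <- setdiff(seq_along(m$label), m$parent)
      for (lf in leaves) {
        if (length(m$label) == 1L) next
        keep <- setdiff(seq_along(m$label), lf)
        idx <- match(m$parent[keep], keep)
        sub <- glycan_motif(m$label[keep],
                            ifelse(is.na(idx), 0L, idx),
                            ifelse(is.na(idx), NA, m$elab[keep]))
        occ_sub <- which(vapply(gs, contains_motif, logical(1), m = sub))
        expect_true(all(occ %in% occ_sub))
      }
    }
  }
})
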