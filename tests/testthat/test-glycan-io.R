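test_that("CFG strings parse into the expected rooted trees", {
  g <- parse_cfg_glycan("Galb1-3GalNAc")
  expect_equal(canonical_code(g), "GalNAc(b1-3>Gal)")
  expect_equal(g$label[glycanmotifs:::tree_root(g)], "GalNAc")

  expect_equal(canonical_code(parse_cfg_glycan("Man")), "Man")
  expect_equal(length(parse_cfg_glycan("Man")$label), 1L)

  g <- parse_cfg_glycan("Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAcb-Sp0")
  expect_equal(g$spacer, "Sp0")
  expect_equal(g$root_anomer, "b")
  expect_equal(canonical_code(g), "GlcNAc(a1-3>Fuc)(b1-4>Gal(a2-3>Neu5Ac))")
  # re-serialising reproduces an equivalent string
  expect_equal(canonical_code(parse_cfg_glycan(write_glycan_text(g))),
               canonical_code(g))
})

test_that("parser accepts unknown anomers/positions and Greek letters", {
  g <- parse_cfg_glycan("Gal?1-?GlcNAc")
  expect_equal(canonical_code(g), "GlcNAc(?1-?>Gal)")
  expect_equal(canonical_code(parse_cfg_glycan("Galβ1-3GalNAc")),
               "GalNAc(b1-3>Gal)")
  # covalent modifications stay inside the residue label
  g <- parse_cfg_glycan("Gal6Sb1-4GlcNAc")
  expect_true("Gal6S" %in% g$label)
})

test_that("malformed glycan strings raise parse errors", {
  expect_error(parse_cfg_glycan(""), class = "glycan_parse_error")
  expect_error(parse_cfg_glycan("Galb1-3(GalNAc"), class = "glycan_parse_error")
  expect_error(parse_cfg_glycan("Galb1-3GalNAc)"), class = "glycan_parse_error")
  expect_error(parse_cfg_glycan("Galb1-"), class = "glycan_parse_error")
  expect_error(parse_cfg_glycan("Galb1-3"), regexp = "dangling")
  err <- tryCatch(parse_cfg_glycan("Gal!!x"), glycan_parse_error = identity)
  expect_match(conditionMessage(err), "offset")
})

test_that("spacer stripping never changes the residue count", {
  base <- c("Galb1-3GalNAc", "Neu5Aca2-3Galb1-4(Fuca1-3)GlcNAc", "Man")
  for (s in base) {
    with_sp <- parse_cfg_glycan(paste0(s, "b-Sp8"))
    without <- parse_cfg_glycan(s)
    expect_equal(length(with_sp$label), length(without$label))
    expect_equal(with_sp$spacer, "Sp8")
  }
})

test_that("motif text round trips and matches the published notation style", {
  # terminal GlcNAc restricted at 3,4,6 and alpha-linked to its parent
  m <- glycan_motif(c("GlcNAc", "X"), c(0L, 1L), c(NA, "*3,4,6"),
                    parent_anomer = "a")
  expect_equal(write_motif_text(m), "(*3,4,6)GlcNAc α")
  expect_equal(write_motif_text(m, ascii = TRUE), "(*3,4,6)GlcNAc a")

  expect_equal(write_motif_text(parse_motif_text("Man")), "Man")

  m <- parse_motif_text("(*2,3,4,6)Gal β1-3GalNAc")
  expect_equal(write_motif_text(m), "(*2,3,4,6)Gal β1-3GalNAc")

  m <- parse_motif_text("Man a1-3(Man a1-6)(*2,4)Man a")
  expect_equal(write_motif_text(m), "Man α1-3(Man α1-6)(*2,4)Man α")
  expect_equal(m$parent_anomer, "a")

  m <- parse_motif_text("(*4,6)GalNAc α/β")
  expect_equal(m$parent_anomer, "ab")
  expect_equal(write_motif_text(m), "(*4,6)GalNAc α/β")
})

test_that("motif parse/write is an identity on random motifs", {
  set.seed(11)
  for (i in 1:40) {
    gs <- random_small_collection(3, augment = TRUE)
    m <- as_motif(gs[[1]], parent_anomer = sample(c(NA, "a", "b", "ab"), 1))
    txt <- write_motif_text(m)
    back <- parse_motif_text(txt)
    expect_equal(canonical_code(back), canonical_code(m), info = txt)
    expect_equal(back$parent_anomer, m$parent_anomer, info = txt)
  }
})

test_that("restricted position lists are emitted sorted ascending", {
  m <- glycan_motif(c("Gal", "X"), c(0L, 1L), c(NA, "*6,3"))
  expect_equal(write_motif_text(m, ascii = TRUE), "(*3,6)Gal")
})

test_that("array tables read, validate and report row-level problems", {
  fp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("glycan_text,rfu,extra",
               "Galb1-3GalNAc,50000,a",
               "Neu5Aca2-3Galb1-3GalNAc,100,b",
               "Neu5Aca2-6Galb1-3GalNAc,120,c"), fp)
  ae <- read_array_table(fp)
  expect_s3_class(ae, "array_experiment")
  expect_equal(length(ae), 3L)
  expect_equal(ae$table$extra, c("a", "b", "c"))

  writeLines("glycan_text,rfu", fp)
  expect_error(read_array_table(fp), "no rows")

  writeLines(c("glycan_text,rfu", "Gal,NA"), fp)
  expect_error(read_array_table(fp), "row")

  writeLines(c("structure,rfu", "Gal,10"), fp)
  expect_error(read_array_table(fp), "glycan_text")

  writeLines(c("glycan_text,rfu", "Gal,10", "not a glycan!!,20"), fp)
  expect_error(read_array_table(fp), "row\\(s\\): 2")
  expect_warning(ae <- read_array_table(fp, on_parse_error = "skip"), "skipped")
  expect_equal(length(ae), 1L)
})

test_that("models serialise losslessly and reject bad payloads", {
  ae <- simulate_array(n_glycans = 120, seed = 3)
  cls <- assign_binding_classes(ae$table$rfu)
  keep <- which(cls != "intermediate")
  y <- as.integer(cls[keep] == "positive")
  cap <- build_capability_map(ae$glycans)
  aug <- lapply(ae$glycans[keep], add_restricted_linkages, cap = cap)
  model <- fit_motif_model(aug, y, cap, seed = 5)

  txt <- serialise_model(model)
  back <- deserialise_model(txt)
  probe <- c("Galb1-3GalNAc", "Neu5Aca2-3Galb1-3GalNAc", "Manb1-4Glc")
  expect_equal(predict_binding(back, probe), predict_binding(model, probe))
  expect_equal(back$motifs$code, model$motifs$code)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$seed, model$seed)

  expect_error(deserialise_model("{not json"), "corrupted")
  tampered <- sub('"format_version": "1"', '"format_version": "99"', txt)
  expect_error(deserialise_model(tampered), "version")
})

test_that("an empty model predicts the intercept probability everywhere", {
  model <- structure(
    list(motifs = data.frame(code = character(0), parent_anomer = character(0),
                             text = character(0), coef = numeric(0)),
         coef = numeric(0), intercept = -1.2, C = 100,
         capability_map = build_capability_map(list(parse_cfg_glycan("Galb1-3GalNAc"))),
         config = list(), seed = 1, selection = list()),
    class = "trained_model")
  p <- predict_binding(model, c("Man", "Galb1-3GalNAc"))
  expect_equal(p, rep(plogis(-1.2), 2))
  rt <- deserialise_model(serialise_model(model))
  expect_equal(predict_binding(rt, "Man"), plogis(-1.2))
})
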