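B62 <- substitutionMatrix()

test_that("rectangular matrix keeps the best hit per cell with composite-side spans", {
  fx <- makeFixture(nSequences = 0, seed = 12, fusionTrios = 1)
  q <- fx$records[c("FUS1A", "FUS1B")]
  r <- fx$records["FUS1C"]
  cells <- buildRectMatrix(q, r, minScore = 60, matrix = B62)
  expect_equal(nrow(cells), 2L)
  a <- cells[cells$component_id == "FUS1A", ]
  b <- cells[cells$component_id == "FUS1B", ]
  expect_lte(a$s_start, 5); expect_gte(b$s_start, 105)  # disjoint spans
  expect_lt(a$s_end, b$s_start)
  # below-threshold search yields an empty matrix
  none <- buildRectMatrix(q, r, minScore = 1e5, matrix = B62)
  expect_equal(nrow(none), 0L)
})

test_that("pairs-list input and id-collision prefixing are honoured", {
  fx <- makeFixture(nSequences = 3, lengthRange = c(60, 80), seed = 44,
                    fusionTrios = 1)
  e <- crossSearch(fx$records, fx$records, B62, minScore = 60)
  cells <- buildRectMatrix(fx$records, fx$records, edges = e, minScore = 60)
  expect_true(all(startsWith(cells$component_id, "q:")))
  expect_true(all(startsWith(cells$composite_id, "r:")))
  expect_true("r:FUS1C" %in% cells$composite_id)
})

test_that("planted trios are detected, overlap and homology filters reject impostors", {
  fx <- makeFixture(nSequences = 0, seed = 5, fusionTrios = 1)
  q <- fx$records[c("FUS1A", "FUS1B", "FUS1C")]
  r <- fx$records["FUS1C"]
  names(r) <- "REF_COMPOSITE"
  cells <- buildRectMatrix(q, r, minScore = 60, matrix = B62)
  fus <- detectFusions(cells, q, B62, shuffles = 30, seed = 5)
  # composite's full-length self-hit overlaps both components -> dropped;
  # the two true components survive as one candidate
  expect_identical(unique(fus$composite_id), "REF_COMPOSITE")
  expect_setequal(fus$component_id, c("FUS1A", "FUS1B"))
  expect_lt(fus$s_end[1], fus$s_start[2])

  # overlap arithmetic: spans 1-100 and 21-120 overlap 80% of the shorter
  cells2 <- data.frame(component_id = c("u", "v"),
                       composite_id = "comp",
                       score = c(300, 300),
                       s_start = c(1L, 21L), s_end = c(100L, 120L),
                       stringsAsFactors = FALSE)
  qq <- aaset(c(u = random_protein_seeded(100, 1),
                v = random_protein_seeded(100, 2)))
  expect_equal(nrow(detectFusions(cells2, qq, B62, maxComponentOverlap = 0.1,
                                  validateComponents = FALSE)), 0L)
  cells2$s_start[2] <- 111L; cells2$s_end[2] <- 210L
  expect_equal(nrow(detectFusions(cells2, qq, B62, maxComponentOverlap = 0.1,
                                  validateComponents = FALSE)), 2L)
  expect_error(detectFusions(cells2, qq, B62, maxComponentOverlap = 2), "0, 1")
})

test_that("homologous components hitting disjoint spans are rejected only when validation is on", {
  base <- random_protein_seeded(100, 31)
  mutated <- local({
    set.seed(32)
    chars <- strsplit(base, "")[[1]]
    pos <- sample(100, 10)
    chars[pos] <- vapply(chars[pos], function(c0)
      sample(setdiff(protfam::homopolymerTargets(), c0), 1), character(1))
    paste(chars, collapse = "")
  })
  linker <- random_protein_seeded(10, 33)
  decoy <- aaset(c(DCOMP = paste0(base, linker, mutated)))
  q <- aaset(c(DUPA = base, DUPB = mutated))
  cells <- buildRectMatrix(q, decoy, minScore = 60, matrix = B62)
  expect_equal(nrow(cells), 2L)
  with_val <- detectFusions(cells, q, B62, shuffles = 40, seed = 2)
  expect_equal(nrow(with_val), 0L)                  # internal repeat, not fusion
  without_val <- detectFusions(cells, q, B62, validateComponents = FALSE)
  expect_equal(nrow(without_val), 2L)
})

test_that("k planted trios among background are recovered exactly with no false positives", {
  fx <- makeFixture(nSequences = 50, lengthRange = c(80, 160), seed = 2024,
                    fusionTrios = 3)
  cells <- buildRectMatrix(fx$records, fx$records, minScore = 60, matrix = B62)
  fus <- detectFusions(cells, setNames(fx$records,
                                       paste0("q:", names(fx$records))),
                       B62, shuffles = 30, seed = 11)
  expect_setequal(unique(fus$composite_id),
                  paste0("r:", c("FUS1C", "FUS2C", "FUS3C")))
  for (k in 1:3) {
    comp <- fus[fus$composite_id == paste0("r:", sprintf("FUS%dC", k)), ]
    expect_setequal(comp$component_id,
                    paste0("q:", sprintf("FUS%d%s", k, c("A", "B"))))
  }
})

test_that("component order permutation does not change the reported candidates", {
  fx <- makeFixture(nSequences = 0, seed = 7, fusionTrios = 2)
  q <- fx$records[c("FUS1A", "FUS1B", "FUS2A", "FUS2B")]
  r <- fx$records[c("FUS1C", "FUS2C")]
  cells <- buildRectMatrix(q, r, minScore = 60, matrix = B62)
  ref <- detectFusions(cells, q, B62, shuffles = 20, seed = 1)
  for (i in 1:3) {
    perm <- cells[sample(nrow(cells)), , drop = FALSE]
    expect_identical(detectFusions(perm, q, B62, shuffles = 20, seed = 1), ref)
  }
})

test_that("composites are only reported from the reference side", {
  fx <- makeFixture(nSequences = 0, seed = 19, fusionTrios = 1)
  comps <- fx$records[c("FUS1A", "FUS1B")]
  composite <- fx$records["FUS1C"]
  # composite in reference: candidate found
  found <- detectFusions(buildRectMatrix(comps, composite, minScore = 60,
                                         matrix = B62),
                         comps, B62, shuffles = 20, seed = 3)
  expect_equal(length(unique(found$composite_id)), 1L)
  # swapped roles: components cannot be composites
  swapped <- detectFusions(buildRectMatrix(composite, comps, minScore = 60,
                                           matrix = B62),
                           composite, B62, shuffles = 20, seed = 3)
  expect_equal(nrow(swapped), 0L)
})
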