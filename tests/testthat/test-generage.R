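B62 <- substitutionMatrix()

test_that("hit matrix construction sets passing cells plus an axiomatic diagonal", {
  e <- rbind(edge_row("A", "B", evalue = 1e-20),
             edge_row("C", "A", evalue = 1))      # fails threshold
  m <- buildHitMatrix(e, ids = c("A", "B", "C"), maxEvalue = 1e-5)
  expect_true(m["A", "B"]); expect_false(m["B", "A"])
  expect_false(m["C", "A"])
  expect_true(all(diag(m)))
  expect_equal(sum(m), 3L + 1L)                   # diagonal + one hit
  prov <- attr(m, "provenance")
  expect_identical(prov["A", "B"], "search_hit")
  expect_identical(prov["A", "A"], "diagonal")
  expect_error(buildHitMatrix(e, ids = c("A", "B")), "unknown id")
  none <- buildHitMatrix(e[0, ], ids = c("A", "B"))
  expect_true(all(none == (diag(2) > 0)))
})

test_that("symmetrification corrects identical-sequence false negatives and clears random one-way hits", {
  ident <- random_protein_seeded(100, 1)
  recs <- aaset(c(A = ident, B = ident, C = random_protein_seeded(100, 2)))
  e <- rbind(edge_row("A", "B", evalue = 1e-40),   # one-way only
             edge_row("A", "C", evalue = 1e-40))   # one-way, unrelated pair
  m <- buildHitMatrix(e, names(recs))
  sym <- symmetrifyMatrix(m, recs, B62, shuffles = 40, seed = 7)
  expect_true(sym["A", "B"] && sym["B", "A"])      # false negative corrected
  expect_false(sym["A", "C"] || sym["C", "A"])     # false positive removed
  expect_true(all(sym == t(sym)))
  prov <- attr(sym, "provenance")
  expect_identical(prov["B", "A"], "sw_validated")
  expect_identical(prov["A", "C"], "cleared")
  # missing sequence for an asymmetric pair is an error
  expect_error(symmetrifyMatrix(m, recs[c("A", "B")], B62, shuffles = 10),
               "no sequence")
})

test_that("symmetrification is idempotent and symmetric over random matrices", {
  set.seed(1234)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    ids <- sprintf("P%02d", seq_len(n))
    recs <- aaset(setNames(vapply(seq_len(n), function(i)
      random_protein(40), character(1)), ids))
    m <- matrix(runif(n * n) < 0.35, n, n, dimnames = list(ids, ids))
    diag(m) <- TRUE
    once <- symmetrifyMatrix(m, recs, B62, shuffles = 15, seed = rep)
    expect_true(all(once == t(once)))
    twice <- symmetrifyMatrix(once, recs, B62, shuffles = 15, seed = rep)
    expect_identical(once, twice)
  }
})

test_that("multi-domain calls are exactly the transitivity violations with witnesses", {
  ids <- c("A", "B", "C")
  path_m <- matrix(FALSE, 3, 3, dimnames = list(ids, ids))
  diag(path_m) <- TRUE
  path_m["A", "B"] <- path_m["B", "A"] <- TRUE
  path_m["B", "C"] <- path_m["C", "B"] <- TRUE
  calls <- detectMultiDomain(path_m)
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$protein, "B")
  expect_identical(c(calls$witness_x, calls$witness_y), c("A", "C"))
  tri <- path_m; tri["A", "C"] <- tri["C", "A"] <- TRUE
  expect_equal(nrow(detectMultiDomain(tri)), 0L)
  asym <- path_m; asym["A", "C"] <- TRUE
  expect_error(detectMultiDomain(asym), "symmetric")
})

test_that("clustering keeps multi-domain proteins out of core families and re-attaches them", {
  ids <- c("A", "B", "C")
  m <- matrix(FALSE, 3, 3, dimnames = list(ids, ids)); diag(m) <- TRUE
  m["A", "B"] <- m["B", "A"] <- TRUE
  m["B", "C"] <- m["C", "B"] <- TRUE
  fams <- rageCluster(m)
  expect_equal(nFamilies(fams), 2L)
  expect_setequal(unlist(families(fams)), c("A", "C"))
  ann <- familyAnnotations(fams)
  expect_identical(unique(ann$protein), "B")
  expect_setequal(ann$family, c(1L, 2L))           # B annotated into both
  # triangle: one family of three, no annotations
  tri <- m; tri["A", "C"] <- tri["C", "A"] <- TRUE
  fams2 <- rageCluster(tri)
  expect_equal(nFamilies(fams2), 1L)
  expect_setequal(families(fams2)[[1]], ids)
  expect_equal(nrow(familyAnnotations(fams2)), 0L)
  # no off-diagonal hits: all singletons
  solo <- diag(3) > 0; dimnames(solo) <- list(ids, ids)
  expect_equal(nFamilies(rageCluster(solo)), 3L)
})

test_that("planted fusion composite is called multi-domain from fixture searches", {
  fx <- makeFixture(nSequences = 4, lengthRange = c(60, 90), seed = 64,
                    fusionTrios = 1)
  e <- allVsAll(fx$records, B62, minScore = 60)
  m <- buildHitMatrix(e, names(fx$records), maxEvalue = 1)
  sym <- symmetrifyMatrix(m, fx$records, B62, shuffles = 30, seed = 64)
  calls <- detectMultiDomain(sym)
  expect_identical(unique(calls$protein), "FUS1C")
  expect_identical(c(calls$witness_x[1], calls$witness_y[1]),
                   c("FUS1A", "FUS1B"))
  fams <- rageCluster(sym, calls)
  expect_true(all(c("FUS1A", "FUS1B") %in% unlist(families(fams))))
  expect_false("FUS1C" %in% unlist(families(fams)))
})
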