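B62 <- substitutionMatrix()

test_that("homopolymer segment matches hand-derivable cases", {
  expect_equal(homopolymerSegment("QQQQQQQQ", "Q", B62),
               list(score = 40L, start = 1L, end = 8L))
  # single W flanked by Y (+2 vs W) extends the segment: 11 + 2 = 13
  seg <- homopolymerSegment("ACDEFGHIKLMNPQRSTVWY", "W", B62)
  expect_equal(seg$score, 13L)
  expect_equal(c(seg$start, seg$end), c(19L, 20L))
  expect_equal(homopolymerSegment("AAAA", "W", B62),
               list(score = 0L, start = NA_integer_, end = NA_integer_))
  expect_equal(homopolymerSegment("AQAQAQAQAQAQAQAQAQAQ", "Q", B62)$score, 41L)
  expect_equal(homopolymerSegment("AQAQAQAQAQAQAQAQAQAQ", "A", B62)$score, 31L)
})

test_that("homopolymer segment equals the exhaustive all-segments oracle", {
  set.seed(202)
  for (rep in 1:120) {
    s <- random_protein(sample(1:50, 1))
    r <- sample(homopolymerTargets(), 1)
    got <- homopolymerSegment(s, r, B62)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    want <- oracle_segment(unname(B62[chars, r]))
    expect_equal(got$score, as.integer(want$score), info = paste(s, r))
    if (want$score > 0) {
      # equal score on the reported span
      expect_equal(sum(B62[chars[got$start:got$end], r]), want$score)
    }
  }
})

test_that("detection finds implanted tracts and alternating bias, and respects the threshold", {
  fx <- makeFixture(nSequences = 3, lengthRange = c(120, 120), seed = 9,
                    lcrImplants = list(list(record = 2, start = 40, end = 59,
                                            residue = "Q")))
  regions <- detectLowComplexity(fx$records, B62, threshold = 40)
  qreg <- regions[regions$residue == "Q" & regions$record_id == "SYN0002", ]
  expect_equal(nrow(qreg), 1L)
  expect_true(qreg$start <= 40 && qreg$end >= 59)  # covers the implant
  expect_gte(qreg$score, 40)

  expect_equal(nrow(detectLowComplexity("ACDEFGHIKLMNPQRSTVWY", B62, 40)), 0L)

  alt <- detectLowComplexity("AQAQAQAQAQAQAQAQAQAQ", B62, 40)
  expect_equal(nrow(alt), 1L)
  expect_identical(alt$residue, "Q")
  expect_error(detectLowComplexity("MKV", B62, threshold = 0), "positive")
})

test_that("selective masking replaces only the offending residue and preserves length", {
  x <- aaset(c(p = "AQAQAQAQAQAQAQAQAQAQ"))
  res <- maskLowComplexity(x, B62, 40)
  masked <- as.character(res$records[[1]])
  expect_equal(nchar(masked), 20L)
  orig <- strsplit("AQAQAQAQAQAQAQAQAQAQ", "")[[1]]
  out <- strsplit(masked, "")[[1]]
  expect_true(all(orig[out == "X"] == "Q"))   # selectivity
  expect_true(all(out[orig == "A"] == "A"))   # bystanders survive
  # whole-sequence homopolymer masks totally
  tot <- maskLowComplexity(aaset(c(h = strrep("A", 12))), B62, 40)
  expect_identical(as.character(tot$records[[1]]), strrep("X", 12))
  # empty region list leaves the record unchanged
  unchanged <- maskSequences(x, detectLowComplexity("MKV", B62, 40))
  expect_identical(as.character(unchanged), as.character(x))
})

test_that("masking properties hold on random fixtures: sub-multiset, monotone threshold, fixed point", {
  fx <- makeFixture(nSequences = 6, lengthRange = c(90, 140), seed = 31,
                    lcrImplants = list(
                      list(record = 1, start = 10, end = 34, residue = "S"),
                      list(record = 3, start = 50, end = 77, residue = "E"),
                      list(record = 5, start = 5, end = 24, residue = "K")))
  res <- maskLowComplexity(fx$records, B62, 40)
  for (i in seq_along(fx$records)) {
    a <- table(strsplit(as.character(fx$records[[i]]), "")[[1]])
    b <- table(strsplit(gsub("X", "", as.character(res$records[[i]])), "")[[1]])
    expect_true(all(b <= a[names(b)]))        # unmasked residues are a sub-multiset
    expect_equal(nchar(as.character(res$records[[i]])),
                 nchar(as.character(fx$records[[i]])))
  }
  lo <- detectLowComplexity(fx$records, B62, 40)
  hi <- detectLowComplexity(fx$records, B62, 60)
  expect_lte(nrow(hi), nrow(lo))
  key <- function(d) paste(d$record_id, d$residue, d$start, d$end)
  expect_true(all(key(hi) %in% key(lo)))      # no new regions at higher threshold
  # fixed point: masked output has nothing left to detect at the same threshold
  expect_equal(nrow(detectLowComplexity(res$records, B62, 40)), 0L)
})

test_that("mask report aggregates counts consistently with the region table", {
  fx <- makeFixture(nSequences = 4, lengthRange = c(100, 100), seed = 13,
                    lcrImplants = list(
                      list(record = 1, start = 11, end = 30, residue = "Q"),
                      list(record = 2, start = 21, end = 45, residue = "N")))
  res <- maskLowComplexity(fx$records, B62, 40)
  rep <- res$report
  expect_s4_class(rep, "MaskReport")
  expect_gte(sum(regionCounts(rep)), 2)
  expect_equal(sum(maskedRegions(rep)$n_masked >= 0), nrow(maskedRegions(rep)))
  # masked fraction equals observed X fraction of the masked output
  n_x <- sum(vapply(as.character(res$records),
                    function(s) sum(strsplit(s, "")[[1]] == "X"), numeric(1)))
  expect_equal(maskedFraction(rep), n_x / sum(Biostrings::width(fx$records)))
  empty <- maskReport(fx$records, detectLowComplexity("MKV", B62, 40))
  expect_equal(maskedFraction(empty), 0)
  expect_equal(length(regionCounts(empty)), 0L)
})
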