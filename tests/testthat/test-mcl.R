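triangle_edges <- function(ids, score = 100) {
  do.call(rbind, lapply(utils::combn(ids, 2, simplify = FALSE), function(p)
    rbind(edge_row(p[1], p[2], bitscore = score),
          edge_row(p[2], p[1], bitscore = score))))
}

test_that("graph building applies thresholds, the weight rules and the max-direction collapse", {
  e <- rbind(edge_row("A", "B", evalue = 1e-50, bitscore = 185),
             edge_row("B", "A", evalue = 1e-30, bitscore = 120),
             edge_row("A", "C", evalue = 0, bitscore = 300),
             edge_row("C", "D", evalue = 0.5, bitscore = 20),
             edge_row("E", "E", evalue = 1e-99, bitscore = 500))
  g <- buildGraph(e, maxEvalue = 1e-5, weighting = "neglog_evalue")
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2L)                       # C-D fails threshold, E-E self dropped
  w_ab <- el$weight[(el$from == "A" & el$to == "B") | (el$from == "B" & el$to == "A")]
  expect_equal(w_ab, 50)                           # -log10(1e-50), max of directions
  w_ac <- el$weight[(el$from == "A" & el$to == "C") | (el$from == "C" & el$to == "A")]
  expect_equal(w_ac, 200)                          # cap for evalue 0
  g2 <- buildGraph(e, minScore = 150, weighting = "bitscore")
  el2 <- igraph::as_data_frame(g2)
  expect_equal(sort(el2$weight), c(185, 300))
  expect_equal(igraph::vcount(buildGraph(e[0, , drop = FALSE])), 0L)
})

test_that("disjoint dense groups are recovered exactly and a single vertex is a singleton family", {
  e <- rbind(triangle_edges(c("a", "b", "c")), triangle_edges(c("x", "y", "z")))
  fams <- mclCluster(buildGraph(e, weighting = "bitscore"))
  expect_equal(nFamilies(fams), 2L)
  expect_setequal(vapply(families(fams), paste, character(1), collapse = ","),
                  c("a,b,c", "x,y,z"))
  g1 <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices("solo")
  f1 <- mclCluster(g1)
  expect_equal(nFamilies(f1), 1L)
  expect_identical(families(f1)[[1]], "solo")
  expect_error(mclCluster(g1, inflation = 0.5), ">= 1")
})

test_that("planted partition with k=4 dense groups is recovered exactly", {
  set.seed(88)
  groups <- split(sprintf("v%02d", 1:20), rep(1:4, each = 5))
  e <- do.call(rbind, lapply(groups, triangle_edges))
  fams <- mclCluster(buildGraph(e, weighting = "bitscore"), inflation = 2)
  expect_equal(nFamilies(fams), 4L)
  got <- lapply(families(fams), sort)
  want <- lapply(groups, sort)
  expect_setequal(vapply(got, paste, character(1), collapse = ","),
                  vapply(want, paste, character(1), collapse = ","))
})

test_that("inflation granularity is monotone and r=1 merges connected components", {
  # two dense groups joined by a single weak bridge
  e <- rbind(triangle_edges(c("a", "b", "c"), 100),
             triangle_edges(c("x", "y", "z"), 100),
             edge_row("c", "x", bitscore = 5),
             edge_row("x", "c", bitscore = 5))
  g <- buildGraph(e, weighting = "bitscore")
  n_fine <- nFamilies(mclCluster(g, inflation = 5))
  n_coarse <- nFamilies(mclCluster(g, inflation = 1.4))
  expect_gte(n_fine, n_coarse)
  expect_equal(nFamilies(mclCluster(g, inflation = 1)), 1L)
})

test_that("family partition is invariant under edge-order permutation", {
  set.seed(99)
  e <- rbind(triangle_edges(c("a", "b", "c")),
             triangle_edges(c("p", "q", "r")),
             edge_row("c", "p", bitscore = 40), edge_row("p", "c", bitscore = 40))
  fam_of <- function(edges) {
    f <- mclCluster(buildGraph(edges, weighting = "bitscore"))
    vapply(families(f), paste, character(1), collapse = ",")
  }
  ref <- fam_of(e)
  for (i in 1:5)
    expect_identical(fam_of(e[sample(nrow(e)), , drop = FALSE]), ref)
})

test_that("clustering outputs are exactly three files with the documented schemas", {
  e <- rbind(triangle_edges(c("a", "b", "c")), triangle_edges(c("x", "y", "z")))
  g <- buildGraph(e, weighting = "bitscore")
  fams <- mclCluster(g)
  prefix <- file.path(tempdir(), "clusttest")
  paths <- writeClusterOutputs(g, fams, prefix)
  expect_length(paths, 3L)
  expect_true(all(file.exists(paths)))
  # visualization file: one line per undirected edge, 3 tab fields
  viz <- readLines(paths[1])
  expect_equal(length(viz), igraph::ecount(g))
  expect_true(all(lengths(strsplit(viz, "\t")) == 3L))
  # raw cluster file: one family per line
  expect_equal(length(readLines(paths[2])), nFamilies(fams))
  # families table: header + one row per family; member_count conserves vertices
  fam_tab <- read.delim(paths[3])
  expect_identical(names(fam_tab), c("family_id", "member_count", "members"))
  expect_equal(fam_tab$family_id, seq_len(nFamilies(fams)))
  expect_equal(sum(fam_tab$member_count), igraph::vcount(g))
})

test_that("family numbering is by decreasing size with deterministic ties", {
  e <- rbind(triangle_edges(c("m", "n", "o", "p")),  # size-4 clique
             triangle_edges(c("a", "b", "c")),
             triangle_edges(c("x", "y", "z")))
  fams <- mclCluster(buildGraph(e, weighting = "bitscore"))
  sz <- unname(familySizes(fams))
  expect_equal(sz, sort(sz, decreasing = TRUE))
  three <- families(fams)[sz == 3]
  expect_identical(three[[1]][1], "a")  # tie broken by smallest member id
})
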