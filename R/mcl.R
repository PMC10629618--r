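# Similarity-graph construction and native Markov clustering (MCL).
# A pairs-list is thresholded and collapsed into an undirected weighted
# graph; MCL then alternates expansion (matrix power) and inflation
# (entry-wise power + column renormalization) on the column-stochastic
# transition matrix until the flow stabilizes, and reads protein
# families off the attractor structure of the limit matrix.

#' Build a similarity graph from a pairs-list
#'
#' Edges failing the thresholds are dropped, self-hits are discarded
#' (self-loops are re-added at the matrix stage), and the two directions
#' of a pair are collapsed into one undirected edge carrying the larger
#' weight. Weights are `-log10(evalue)` (capped at `evalueCap`, also
#' used when `evalue == 0`) or the raw `bitscore` column.
#'
#' @param edges pairs-list data.frame ([parsePairsList()] /
#'   [allVsAll()]).
#' @param maxEvalue drop edges with `evalue` above this (NULL = keep
#'   all).
#' @param minScore drop edges with `bitscore` below this (NULL = keep
#'   all).
#' @param weighting `"neglog_evalue"` or `"bitscore"`.
#' @param evalueCap weight cap for vanishing E-values (default 200).
#' @return an undirected weighted [igraph::igraph] graph.
#' @export
buildGraph <- function(edges, maxEvalue = NULL, minScore = NULL,
                       weighting = c("neglog_evalue", "bitscore"),
                       evalueCap = 200) {
  weighting <- match.arg(weighting)
  keep <- rep(TRUE, nrow(edges))
  if (!is.null(maxEvalue)) keep <- keep & edges$evalue <= maxEvalue
  if (!is.null(minScore)) keep <- keep & edges$bitscore >= minScore
  keep <- keep & edges$qseqid != edges$sseqid
  e <- edges[keep, , drop = FALSE]
  if (!nrow(e))
    return(igraph::make_empty_graph(0, directed = FALSE))
  w <- switch(weighting,
    neglog_evalue = pmin(ifelse(e$evalue <= 0, evalueCap,
                                -log10(e$evalue)), evalueCap),
    bitscore = e$bitscore)
  stopifnot(all(w >= 0))
  a <- pmin(e$qseqid, e$sseqid)
  b <- pmax(e$qseqid, e$sseqid)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(w, key, max)
  ab <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  igraph::graph_from_data_frame(
    data.frame(from = ab[, 1], to = ab[, 2], weight = as.numeric(agg),
               stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Markov clustering of a similarity graph
#'
#' Native MCL: self-loops are added with weight equal to each vertex's
#' maximum incident edge weight (at least 1, a standard regularization
#' for aperiodicity), the weighted adjacency matrix is column-normalized,
#' and the process iterates expansion (`M^expansion`), inflation
#' (entry-wise power `inflation` followed by column renormalization) and
#' pruning of entries below `prune` (followed by renormalization) until
#' the largest entry change drops below `eps` or `maxIter` is reached
#' (warning; clusters are then read from the current state). Families
#' are the member sets of the attractor rows of the limit matrix;
#' attractor systems sharing members are merged, and any vertex claimed
#' by no attractor row is assigned to the family of its strongest
#' column entry. Families are numbered from 1 by decreasing size, ties
#' broken by smallest member id.
#'
#' @param graph undirected weighted graph from [buildGraph()].
#' @param inflation inflation parameter, `>= 1` (default 2; larger
#'   values give finer-grained families).
#' @param expansion matrix-power exponent (default 2).
#' @param prune entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param maxIter iteration cap (default 100).
#' @param eps convergence tolerance on the max entry change
#'   (default 1e-6).
#' @return a [FamilySet-class] with `method = "mcl"`.
#' @examples
#' g <- igraph::make_graph(~ a-b, b-c, a-c, x-y, y-z, x-z)
#' igraph::E(g)$weight <- 1
#' nFamilies(mclCluster(g))  # two disjoint triangles -> 2 families
#' @export
mclCluster <- function(graph, inflation = 2, expansion = 2L,
                       prune = 1e-5, maxIter = 100L, eps = 1e-6) {
  if (inflation < 1) stopf("inflation must be >= 1")
  n <- igraph::vcount(graph)
  if (n == 0L)
    return(methods::new("FamilySet", families = list(), method = "mcl"))
  ids <- igraph::V(graph)$name %||% as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(graph, attr = if (n > 1 &&
         "weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
         sparse = FALSE)
  if (is.null(rownames(A))) dimnames(A) <- list(ids, ids)
  A <- A[ids, ids, drop = FALSE] * 1.0
  diag(A) <- pmax(apply(A, 1, max), 1)
  M <- normalize_columns(A)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Mx <- M
    for (k in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    Mx <- normalize_columns(Mx)
    Mx[Mx < prune] <- 0
    Mx <- normalize_columns(Mx)
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < eps) break
    if (iter >= maxIter) {
      warnf("MCL did not converge in %d iterations (delta %.2e); clusters read from current state",
            maxIter, delta)
      break
    }
  }
  fams <- clusters_from_limit(M, ids)
  methods::new("FamilySet", families = order_families(fams), method = "mcl")
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  if (any(cs == 0)) stopf("internal error: zero column in stochastic matrix")
  M <- sweep(M, 2, cs, "/")
  stopifnot(all(abs(colSums(M) - 1) < 1e-9))
  M
}

# Interpret the (near-)limit matrix: attractors are rows with positive
# diagonal mass; each attractor claims the vertices with positive entries
# in its row; attractor systems sharing a member are one cluster.
clusters_from_limit <- function(M, ids) {
  n <- length(ids)
  attractors <- which(diag(M) > 0)
  if (!length(attractors)) attractors <- which(rowSums(M) > 0)
  B <- M[attractors, , drop = FALSE] > 0
  overlap <- ((B %*% t(B)) > 0) * 1  # attractors sharing >= 1 member
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(overlap, mode = "undirected",
                                        diag = FALSE))$membership
  fams <- lapply(sort(unique(comp)), function(cl) {
    members <- which(colSums(B[comp == cl, , drop = FALSE]) > 0)
    ids[members]
  })
  assigned <- unlist(fams, use.names = FALSE)
  leftover <- setdiff(ids, assigned)
  for (v in leftover) {
    j <- match(v, ids)
    owner <- which.max(M[, j])
    hit <- which(vapply(fams, function(f) ids[owner] %in% f, logical(1)))
    if (length(hit)) fams[[hit[1]]] <- c(fams[[hit[1]]], v)
    else fams[[length(fams) + 1L]] <- v
  }
  fams
}

# Deterministic family numbering: decreasing size, ties by smallest
# member id; members sorted within each family.
order_families <- function(fams) {
  if (!length(fams)) return(list())
  fams <- lapply(fams, function(f) sort(unique(f)))
  ord <- order(-lengths(fams), vapply(fams, `[`, character(1), 1))
  fams[ord]
}

#' Write clustering outputs
#'
#' Emits the three standard files: `<prefix>.pairs.tsv`, the weighted
#' edge list `id1<TAB>id2<TAB>weight` loadable by network viewers
#' (one line per undirected edge); `<prefix>.mcl`, the raw cluster
#' output with one family per line, members whitespace-separated; and
#' `<prefix>.families.tsv`, the human-readable table
#' `family_id<TAB>member_count<TAB>members(comma)` with family ids
#' incremental from 1 (header line included).
#'
#' @param graph the clustered similarity graph.
#' @param families a [FamilySet-class].
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
writeClusterOutputs <- function(graph, families, prefix) {
  paths <- paste0(prefix, c(".pairs.tsv", ".mcl", ".families.tsv"))
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  write.table(el[, c("from", "to", "weight")], paths[1], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(vapply(families(families), paste, character(1), collapse = " "),
             paths[2])
  fam_df <- data.frame(
    family_id = seq_len(nFamilies(families)),
    member_count = unname(familySizes(families)),
    members = vapply(families(families), paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  write.table(fam_df, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(paths)
}
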