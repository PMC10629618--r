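# Hit-matrix clustering with multi-domain detection. A thresholded
# pairs-list becomes a binary square matrix; one-way (asymmetric) hits
# are validated by an explicit Smith-Waterman shuffle test that either
# corrects the false negative (both directions set) or removes the false
# positive (both cleared). Multi-domain proteins are flagged as
# transitivity violations — a protein similar to two proteins that are
# not similar to each other — and are kept out of the single-linkage
# core families, then re-attached to every family holding one of their
# neighbours, so a two-domain protein cannot chain two unrelated
# families into one.

#' Build a binary hit matrix from a pairs-list
#'
#' Cell (q, s) is TRUE iff some edge q -> s passes the E-value
#' threshold; the diagonal is TRUE by convention (self-similarity is
#' axiomatic) and never validated.
#'
#' @param edges pairs-list data.frame.
#' @param ids complete vertex id set (unique); edges referencing unknown
#'   ids are an error.
#' @param maxEvalue inclusion threshold on the `evalue` column
#'   (default 1e-5).
#' @return logical matrix with dimnames `ids` and a `provenance`
#'   attribute (character matrix: `"diagonal"`, `"search_hit"` or `""`).
#' @export
buildHitMatrix <- function(edges, ids, maxEvalue = 1e-5) {
  if (anyDuplicated(ids)) stopf("duplicate ids")
  unknown <- setdiff(unique(c(edges$qseqid, edges$sseqid)), ids)
  if (length(unknown))
    stopf("edges reference unknown id '%s'", unknown[1])
  n <- length(ids)
  m <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  prov <- matrix("", n, n, dimnames = list(ids, ids))
  pass <- edges[edges$evalue <= maxEvalue, , drop = FALSE]
  if (nrow(pass)) {
    idx <- cbind(match(pass$qseqid, ids), match(pass$sseqid, ids))
    m[idx] <- TRUE
    prov[idx] <- "search_hit"
  }
  diag(m) <- TRUE
  diag(prov) <- "diagonal"
  attr(m, "provenance") <- prov
  m
}

#' Symmetrify a hit matrix by Smith-Waterman validation
#'
#' For every asymmetric pair (hit in one direction only) the two
#' sequences are aligned and tested with the shuffle-null z-score
#' ([shuffleZTest()]): a significant pair has both directions set (a
#' corrected false negative), an insignificant pair has both cleared
#' (a removed false positive). Symmetric pairs are untouched, so the
#' operation is idempotent and its output is always symmetric.
#'
#' @param mat logical matrix from [buildHitMatrix()].
#' @param records named `AAStringSet` holding a sequence for every id in
#'   an asymmetric pair.
#' @param matrix,gapOpen,gapExtend alignment parameters.
#' @param shuffles,zMin shuffle-null parameters (defaults 100 and 10).
#' @param seed integer folded into the deterministic per-pair seeds.
#' @return symmetric logical matrix (provenance updated with
#'   `"sw_validated"` / `"cleared"`).
#' @export
symmetrifyMatrix <- function(mat, records, matrix = substitutionMatrix(),
                             gapOpen = 11, gapExtend = 1, shuffles = 100L,
                             zMin = 10, seed = 0L) {
  ids <- rownames(mat)
  if (is.null(ids) || nrow(mat) != ncol(mat))
    stopf("hit matrix must be square with id dimnames")
  prov <- attr(mat, "provenance") %||%
    matrix("", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  asym <- which(mat != t(mat), arr.ind = TRUE)
  asym <- asym[asym[, 1] < asym[, 2], , drop = FALSE]
  for (k in seq_len(nrow(asym))) {
    i <- asym[k, 1]; j <- asym[k, 2]
    a <- ids[i]; b <- ids[j]
    miss <- setdiff(c(a, b), names(records))
    if (length(miss))
      stopf("no sequence available for id '%s' in asymmetric pair (%s, %s)",
            miss[1], a, b)
    res <- shuffleZTest(records[[a]], records[[b]], matrix, gapOpen,
                        gapExtend, shuffles, zMin, seed)
    val <- res$significant
    mat[i, j] <- val; mat[j, i] <- val
    prov[i, j] <- prov[j, i] <- if (val) "sw_validated" else "cleared"
  }
  attr(mat, "provenance") <- prov
  mat
}

#' Detect multi-domain proteins as transitivity violations
#'
#' In a validated (symmetric) hit matrix, protein p is called
#' multi-domain iff it has two neighbours x, y that are not similar to
#' each other; all witness pairs are reported, calls sorted by id.
#'
#' @param mat symmetric logical hit matrix.
#' @return data.frame with columns `protein`, `witness_x`, `witness_y`
#'   (witnesses ordered `x < y`).
#' @export
detectMultiDomain <- function(mat) {
  ids <- rownames(mat)
  if (!isTRUE(all(mat == t(mat))))
    stopf("hit matrix must be symmetric; run symmetrifyMatrix() first")
  rows <- list()
  for (p in seq_along(ids)) {
    nb <- which(mat[p, ])
    nb <- nb[nb != p]
    if (length(nb) < 2L) next
    for (xi in seq_len(length(nb) - 1L)) for (yi in seq(xi + 1L, length(nb))) {
      x <- nb[xi]; y <- nb[yi]
      if (!mat[x, y])
        rows[[length(rows) + 1L]] <- data.frame(
          protein = ids[p],
          witness_x = min(ids[x], ids[y]),
          witness_y = max(ids[x], ids[y]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(protein = character(0), witness_x = character(0),
                      witness_y = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$protein, out$witness_x, out$witness_y), , drop = FALSE]
}

#' Single-linkage families with multi-domain re-attachment
#'
#' Core families are the connected components of the validated matrix
#' restricted to non-multi-domain proteins. Each multi-domain protein is
#' then annotated as an additional member of every core family that
#' contains at least one of its neighbours (without bridging those
#' families); multi-domain proteins with no neighbour family are listed
#' as unassigned.
#'
#' @param mat symmetric logical hit matrix.
#' @param multidomain data.frame from [detectMultiDomain()].
#' @return a [FamilySet-class] with `method = "generage"`; multi-domain
#'   memberships are in `familyAnnotations()`.
#' @export
rageCluster <- function(mat, multidomain = detectMultiDomain(mat)) {
  ids <- rownames(mat)
  if (!isTRUE(all(mat == t(mat))))
    stopf("hit matrix must be symmetric; run symmetrifyMatrix() first")
  md <- unique(multidomain$protein)
  core <- setdiff(ids, md)
  fams <- list()
  if (length(core)) {
    sub <- mat[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub * 1, mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
    fams <- lapply(sort(unique(memb)), function(cl) core[memb == cl])
  }
  fams <- order_families(fams)
  ann <- list()
  unassigned <- character(0)
  for (p in md) {
    nb <- ids[mat[p, ] & ids != p]
    hit <- which(vapply(fams, function(f) any(nb %in% f), logical(1)))
    if (length(hit))
      ann[[length(ann) + 1L]] <- data.frame(protein = p, family = hit,
                                            stringsAsFactors = FALSE)
    else unassigned <- c(unassigned, p)
  }
  ann <- if (length(ann)) do.call(rbind, ann) else
    data.frame(protein = character(0), family = integer(0),
               stringsAsFactors = FALSE)
  methods::new("FamilySet", families = fams, unassigned = sort(unassigned),
               annotations = ann, method = "generage")
}

#' Write multi-domain calls
#'
#' Tab-separated `protein_id  witness_x  witness_y`, no header.
#'
#' @param calls data.frame from [detectMultiDomain()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMultiDomain <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
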