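# Gene-fusion (Rosetta Stone) detection. A rectangular hit matrix maps
# query-species proteins (fusion components) onto reference-species
# proteins (candidate composites). A composite is reported when at least
# two components hit it at essentially distinct regions and the
# components themselves are not homologous to each other (homologous
# components hitting twice indicate an internal repeat, not a fusion).

#' Build a rectangular component-vs-composite hit matrix
#'
#' Cells are the best-scoring hit of each query (component) on each
#' reference (composite) protein, with the hit's span on the composite.
#' Hits can come from a supplied pairs-list (rows whose `qseqid` is a
#' query id and `sseqid` a reference id) or from the internal
#' [crossSearch()] when `edges` is NULL. Query and reference id spaces
#' must be disjoint; colliding ids are made unambiguous by prefixing
#' `q:` / `r:`.
#'
#' @param query,reference named `AAStringSet` collections; components
#'   are sought in `query`, composites in `reference`.
#' @param edges optional pairs-list data.frame; NULL triggers an
#'   internal search.
#' @param maxEvalue,minScore inclusion thresholds (either or both).
#' @param matrix,gapOpen,gapExtend internal-search parameters.
#' @return data.frame of cells: `component_id`, `composite_id`, `score`,
#'   `s_start`, `s_end`; attributes `query_ids` and `reference_ids`.
#' @export
buildRectMatrix <- function(query, reference, edges = NULL,
                            maxEvalue = NULL, minScore = 30,
                            matrix = substitutionMatrix(),
                            gapOpen = 11, gapExtend = 1) {
  if (is.null(names(query)) || is.null(names(reference)))
    stopf("query and reference collections must be named")
  clash <- intersect(names(query), names(reference))
  if (length(clash)) {
    names(query) <- paste0("q:", names(query))
    names(reference) <- paste0("r:", names(reference))
    if (!is.null(edges)) {
      edges$qseqid <- paste0("q:", edges$qseqid)
      edges$sseqid <- paste0("r:", edges$sseqid)
    }
    if (length(intersect(names(query), names(reference))))
      stopf("id collision between query and reference persists after prefixing")
  }
  if (is.null(edges))
    edges <- crossSearch(query, reference, matrix, gapOpen, gapExtend,
                         minScore %||% 0)
  keep <- edges$qseqid %in% names(query) & edges$sseqid %in% names(reference)
  e <- edges[keep, , drop = FALSE]
  if (!is.null(maxEvalue)) e <- e[e$evalue <= maxEvalue, , drop = FALSE]
  if (!is.null(minScore)) e <- e[e$bitscore >= minScore, , drop = FALSE]
  cells <- data.frame(component_id = character(0), composite_id = character(0),
                      score = numeric(0), s_start = integer(0),
                      s_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(e)) {
    key <- paste(e$qseqid, e$sseqid, sep = "\r")
    best <- tapply(seq_len(nrow(e)), key, function(i) i[which.max(e$bitscore[i])])
    e <- e[as.integer(best), , drop = FALSE]
    cells <- data.frame(component_id = e$qseqid, composite_id = e$sseqid,
                        score = e$bitscore, s_start = e$sstart,
                        s_end = e$send, stringsAsFactors = FALSE)
    cells <- cells[order(cells$composite_id, cells$component_id), , drop = FALSE]
    rownames(cells) <- NULL
  }
  attr(cells, "query_ids") <- names(query)
  attr(cells, "reference_ids") <- names(reference)
  cells
}

# Overlap of two 1-based inclusive spans as a fraction of the shorter.
span_overlap_fraction <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2) + 1L)
  ov / min(e1 - s1 + 1L, e2 - s2 + 1L)
}

#' Detect gene-fusion candidates
#'
#' For every composite with two or more component hits, component pairs
#' are discarded when (1) their composite-side spans overlap by more
#' than `maxComponentOverlap` (as a fraction of the shorter span), or
#' (2) `validateComponents` is on and the components are homologous to
#' each other under the shuffle-null test. Components that survive in at
#' least one pair are reported; composites retaining >= 2 such
#' components are the fusion candidates, sorted by composite id with
#' components sorted by span start.
#'
#' @param cells rectangular matrix cells from [buildRectMatrix()].
#' @param query named `AAStringSet` of the component collection (needed
#'   for component-component validation).
#' @param matrix,gapOpen,gapExtend alignment parameters.
#' @param maxComponentOverlap tolerated span-overlap fraction
#'   (default 0.1).
#' @param validateComponents exclude mutually homologous component
#'   pairs (default TRUE).
#' @param shuffles,zMin,seed shuffle-null parameters as in
#'   [shuffleZTest()].
#' @return data.frame of retained components of candidate composites:
#'   `composite_id`, `component_id`, `s_start`, `s_end`, `score`.
#' @export
detectFusions <- function(cells, query, matrix = substitutionMatrix(),
                          gapOpen = 11, gapExtend = 1,
                          maxComponentOverlap = 0.1,
                          validateComponents = TRUE, shuffles = 100L,
                          zMin = 10, seed = 0L) {
  if (maxComponentOverlap < 0 || maxComponentOverlap > 1)
    stopf("maxComponentOverlap must be in [0, 1]")
  out <- list()
  for (comp in unique(cells$composite_id)) {
    cc <- cells[cells$composite_id == comp, , drop = FALSE]
    if (nrow(cc) < 2L) next
    k <- nrow(cc)
    ok_pair <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (span_overlap_fraction(cc$s_start[i], cc$s_end[i],
                                cc$s_start[j], cc$s_end[j]) >
          maxComponentOverlap) next
      if (validateComponents) {
        a <- cc$component_id[i]; b <- cc$component_id[j]
        miss <- setdiff(c(a, b), names(query))
        if (length(miss))
          stopf("no sequence for component '%s'", miss[1])
        homologous <- shuffleZTest(query[[a]], query[[b]], matrix, gapOpen,
                                   gapExtend, shuffles, zMin,
                                   seed)$significant
        if (homologous) next
      }
      ok_pair[i, j] <- ok_pair[j, i] <- TRUE
    }
    retained <- which(rowSums(ok_pair) > 0)
    if (length(retained) >= 2L) {
      sel <- cc[retained, , drop = FALSE]
      sel <- sel[order(sel$s_start, sel$component_id), , drop = FALSE]
      out[[length(out) + 1L]] <- sel
    }
  }
  if (!length(out))
    return(data.frame(composite_id = character(0), component_id = character(0),
                      s_start = integer(0), s_end = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$composite_id, res$s_start, res$component_id),
             c("composite_id", "component_id", "s_start", "s_end", "score"),
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write fusion candidates
#'
#' One line per composite:
#' `composite_id<TAB>n_components<TAB>component:start-end:score(;...)`.
#'
#' @param fusions data.frame from [detectFusions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFusions <- function(fusions, path) {
  if (!nrow(fusions)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- vapply(split(fusions, fusions$composite_id), function(d) {
    comp <- sprintf("%s:%d-%d:%g", d$component_id, d$s_start, d$s_end,
                    d$score)
    sprintf("%s\t%d\t%s", d$composite_id[1], nrow(d),
            paste(comp, collapse = ";"))
  }, character(1))
  writeLines(unname(lines[order(names(lines))]), path)
  invisible(path)
}
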