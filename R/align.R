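# Local alignment layer. Optimal Smith-Waterman alignment with affine
# gaps is delegated to Biostrings::pairwiseAlignment (a gap of length L
# costs gapOpen + L * gapExtend, the BLAST convention); this file owns
# the scoring-matrix plumbing, the all-vs-all / cross-search drivers that
# emit 12-column pairs-lists, and the shuffle-null significance test
# shared by the hit-matrix validation and fusion stages.

#' Substitution matrix with ambiguity fallback
#'
#' Returns an integer score matrix over the 20 standard residues plus
#' the tolerated extra letters (B, Z, J, U, O, X) and `*`. Standard
#' residue pairs take their values from the named matrix (BLOSUM62
#' packaged via Biostrings); every pair involving an extra letter scores
#' the fallback value. In particular `X` scores the fallback against
#' everything, which keeps masked sequences inert in later searches.
#'
#' @param name matrix name (`"BLOSUM62"`) or path to an NCBI-format
#'   matrix file.
#' @param fallback score for pairs involving non-standard letters
#'   (default -1).
#' @return symmetric integer matrix with dimnames.
#' @export
substitutionMatrix <- function(name = "BLOSUM62", fallback = -1L) {
  if (file.exists(name)) {
    base <- readNcbiMatrix(name)
  } else {
    env <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = env)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = env))
      stopf("unknown substitution matrix '%s'", name)
    base <- get(name, envir = env)
  }
  letters_all <- c(AA_STANDARD_20, AA_EXTRA, "*")
  m <- matrix(as.integer(fallback), nrow = length(letters_all),
              ncol = length(letters_all),
              dimnames = list(letters_all, letters_all))
  std <- intersect(AA_STANDARD_20, rownames(base))
  if (length(std) < 20L)
    stopf("matrix '%s' does not define all 20 standard residues", name)
  m[AA_STANDARD_20, AA_STANDARD_20] <-
    as.integer(base[AA_STANDARD_20, AA_STANDARD_20])
  if (any(m != t(m))) stopf("substitution matrix is not symmetric")
  attr(m, "name") <- if (file.exists(name)) basename(name) else name
  m
}

#' Read a substitution matrix in NCBI text format
#'
#' `#` comment lines are skipped; the first remaining line is the column
#' header of residue letters, each following line starts with the row
#' letter.
#'
#' @param path path to the matrix file.
#' @return symmetric integer matrix.
#' @export
readNcbiMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stopf("no matrix content in %s", path)
  cols <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "[[:space:]]+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(cols))))
  dimnames(vals) <- list(rn, cols)
  vals
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps: a gap of length L costs
#' `gapOpen + L * gapExtend`. The score floor is 0 (an empty alignment);
#' spans are 1-based inclusive and empty (`NA`) when the score is 0.
#'
#' @param a,b residue strings (or `AAString`s); non-empty.
#' @param matrix substitution matrix from [substitutionMatrix()].
#' @param gapOpen,gapExtend positive gap costs (defaults 11 and 1, the
#'   BLASTP convention).
#' @return a `localAlignment` list: `score`, `qStart`, `qEnd`, `sStart`,
#'   `sEnd`, `length` (alignment columns), `identity` (fraction),
#'   `mismatch`, `gapOpenings`.
#' @examples
#' swAlign("HEAGAWGHEE", "HEAGAWGHEE")$score  # 62 under BLOSUM62
#' @export
swAlign <- function(a, b, matrix = substitutionMatrix(),
                    gapOpen = 11, gapExtend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stopf("swAlign() requires non-empty sequences")
  if (gapOpen <= 0 || gapExtend <= 0) stopf("gap costs must be positive")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = matrix, gapOpening = gapOpen,
    gapExtension = gapExtend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    out <- list(score = 0, qStart = NA_integer_, qEnd = NA_integer_,
                sStart = NA_integer_, sEnd = NA_integer_, length = 0L,
                identity = NA_real_, mismatch = 0L, gapOpenings = 0L)
  } else {
    pat <- Biostrings::pattern(pa)
    sbj <- Biostrings::subject(pa)
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    gapruns <- function(s) sum(gregexpr("-+", s)[[1]] > 0)
    out <- list(
      score = sc,
      qStart = Biostrings::start(pat), qEnd = Biostrings::end(pat),
      sStart = Biostrings::start(sbj), sEnd = Biostrings::end(sbj),
      length = nchar(ap),
      identity = Biostrings::pid(pa) / 100,
      mismatch = Biostrings::nmismatch(pa),
      gapOpenings = gapruns(ap) + gapruns(as_)
    )
  }
  class(out) <- "localAlignment"
  out
}

#' @export
print.localAlignment <- function(x, ...) {
  cat(sprintf("local alignment: score %g", x$score))
  if (x$score > 0)
    cat(sprintf(", query %d-%d vs subject %d-%d, %d cols, %.1f%% id",
                x$qStart, x$qEnd, x$sStart, x$sEnd, x$length,
                100 * x$identity))
  cat("\n")
  invisible(x)
}

# Align a set of patterns against one subject in a single vectorized
# call; returns scores and subject/pattern spans.
sw_batch <- function(patterns, subject, matrix, gapOpen, gapExtend) {
  patterns <- Biostrings::AAStringSet(as.character(patterns))  # drop mcols
  pa <- Biostrings::pairwiseAlignment(
    patterns, Biostrings::AAString(as.character(subject)), type = "local",
    substitutionMatrix = matrix, gapOpening = gapOpen,
    gapExtension = gapExtend)
  list(
    score = Biostrings::score(pa),
    qStart = Biostrings::start(Biostrings::pattern(pa)),
    qEnd = Biostrings::end(Biostrings::pattern(pa)),
    sStart = Biostrings::start(Biostrings::subject(pa)),
    sEnd = Biostrings::end(Biostrings::subject(pa)),
    pid = Biostrings::pid(pa),
    nmismatch = Biostrings::nmismatch(pa),
    ncols = Biostrings::nchar(pa)
  )
}

# Monotone placeholder E-value for internally computed scores; the
# internal search is not Karlin-Altschul calibrated (see allVsAll docs).
pseudo_evalue <- function(score) 10^(-score / 10)

edge_frame <- function(q, s, b) {
  data.frame(
    qseqid = q, sseqid = s,
    pident = round(b$pid, 2),
    length = as.integer(b$ncols),
    mismatch = as.integer(b$nmismatch),
    gapopen = 0L,
    qstart = as.integer(b$qStart), qend = as.integer(b$qEnd),
    sstart = as.integer(b$sStart), send = as.integer(b$sEnd),
    evalue = pseudo_evalue(b$score),
    bitscore = b$score,
    stringsAsFactors = FALSE
  )
}

#' All-vs-all local alignment search
#'
#' Aligns every unordered pair of records and emits both directed hits
#' for pairs scoring at least `minScore`, as a 12-column pairs-list
#' data.frame compatible with [parsePairsList()]. The `bitscore` column
#' carries the raw Smith-Waterman score; the `evalue` column carries the
#' monotone placeholder `10^(-score/10)` — it is not a calibrated
#' Karlin-Altschul E-value, and thresholds on internally generated
#' pairs-lists should be expressed as minimum scores.
#'
#' @param records named `AAStringSet` with unique ids.
#' @param matrix,gapOpen,gapExtend alignment parameters.
#' @param minScore minimum raw score for a reported hit.
#' @param includeSelf also emit self-hits (default FALSE).
#' @return data.frame of similarity edges.
#' @export
allVsAll <- function(records, matrix = substitutionMatrix(),
                     gapOpen = 11, gapExtend = 1, minScore = 30,
                     includeSelf = FALSE) {
  ids <- names(records)
  if (is.null(ids) || anyDuplicated(ids))
    stopf("allVsAll() requires unique record ids")
  n <- length(records)
  out <- list()
  for (i in seq_len(n)) {
    js <- if (i < n) seq(i + 1L, n) else integer(0)
    if (length(js)) {
      b <- sw_batch(records[js], records[[i]], matrix, gapOpen, gapExtend)
      keep <- which(b$score >= minScore & b$score > 0)
      for (k in keep) {
        bk <- lapply(b, `[`, k)
        # pattern = records[js[k]] (query j), subject = record i
        out[[length(out) + 1L]] <- edge_frame(ids[js[k]], ids[i], bk)
        swapped <- bk
        swapped$qStart <- bk$sStart; swapped$qEnd <- bk$sEnd
        swapped$sStart <- bk$qStart; swapped$sEnd <- bk$qEnd
        out[[length(out) + 1L]] <- edge_frame(ids[i], ids[js[k]], swapped)
      }
    }
    if (includeSelf) {
      b <- sw_batch(records[i], records[[i]], matrix, gapOpen, gapExtend)
      if (b$score >= minScore)
        out[[length(out) + 1L]] <- edge_frame(ids[i], ids[i], lapply(b, `[`, 1))
    }
  }
  if (!length(out)) return(empty_edges())
  do.call(rbind, out)
}

#' Cross search: query collection vs reference collection
#'
#' Aligns every query against every reference record and emits
#' query-to-reference hits scoring at least `minScore` in the 12-column
#' dialect (same E-value placeholder caveat as [allVsAll()]).
#'
#' @param query,reference named `AAStringSet` collections.
#' @inheritParams allVsAll
#' @return data.frame of similarity edges (query ids in `qseqid`).
#' @export
crossSearch <- function(query, reference, matrix = substitutionMatrix(),
                        gapOpen = 11, gapExtend = 1, minScore = 30) {
  if (is.null(names(query)) || is.null(names(reference)))
    stopf("crossSearch() requires named collections")
  out <- list()
  for (j in seq_along(reference)) {
    b <- sw_batch(query, reference[[j]], matrix, gapOpen, gapExtend)
    keep <- which(b$score >= minScore & b$score > 0)
    for (k in keep)
      out[[length(out) + 1L]] <- edge_frame(names(query)[k],
                                            names(reference)[j],
                                            lapply(b, `[`, k))
  }
  if (!length(out)) return(empty_edges())
  do.call(rbind, out)
}

empty_edges <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Shuffle-null significance of a local alignment
#'
#' Scores the real pair, then `shuffles` random permutations of the
#' second sequence (seeded deterministically from the two sequences, so
#' the test is order-invariant and reproducible), and returns the
#' z-score `(S - mean) / sd` of the real score against that null. A pair
#' is called significant when `z >= zMin`.
#'
#' @param a,b residue strings.
#' @param matrix,gapOpen,gapExtend alignment parameters.
#' @param shuffles number of shuffles in the null (default 100).
#' @param zMin significance threshold on the z-score (default 10).
#' @param seed integer offset folded into the per-pair seed.
#' @return list: `score`, `z`, `significant`, `nullMean`, `nullSd`.
#' @export
shuffleZTest <- function(a, b, matrix = substitutionMatrix(),
                         gapOpen = 11, gapExtend = 1, shuffles = 100L,
                         zMin = 10, seed = 0L) {
  a <- as.character(a); b <- as.character(b)
  real <- swAlign(a, b, matrix, gapOpen, gapExtend)$score
  key <- paste(sort(c(a, b)), collapse = "|")
  chars <- strsplit(b, "", fixed = TRUE)[[1]]
  null_scores <- with_seed(seed_from_key(key, seed), {
    shuffled <- vapply(seq_len(shuffles), function(i)
      paste(sample(chars), collapse = ""), character(1))
    sw_batch(Biostrings::AAStringSet(shuffled), a, matrix,
             gapOpen, gapExtend)$score
  })
  mu <- mean(null_scores)
  sdev <- stats::sd(null_scores)
  z <- if (sdev > 0) (real - mu) / sdev
       else if (real > mu) Inf else 0
  list(score = real, z = z, significant = is.finite(zMin) && z >= zMin,
       nullMean = mu, nullSd = sdev)
}
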