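# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately share no code with the package implementation.

# Affine-gap local alignment score by explicit three-state dynamic
# programming (Gotoh). A gap of length L costs open + L * ext. Returns
# the optimal local score with floor 0.
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M  <- matrix(0,   n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (horizontal)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext), Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext), Iy[i + 1, j] - ext)
      M[i + 1, j + 1] <- max(0,
        max(M[i, j], Ix[i, j], Iy[i, j]) + mat[A[i], B[j]])
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive maximum-scoring contiguous segment: enumerate every
# (start, end) pair. Floor 0 with an empty span.
oracle_segment <- function(scores) {
  n <- length(scores)
  best <- list(score = 0, start = NA_integer_, end = NA_integer_)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + scores[j]
      if (acc > best$score) best <- list(score = acc, start = i, end = j)
    }
  }
  best
}

random_protein <- function(n) {
  paste(sample(protfam::homopolymerTargets(), n, replace = TRUE),
        collapse = "")
}

# Same, but under a private seed so the caller's RNG stream is untouched.
random_protein_seeded <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  random_protein(n)
}

aaset <- function(...) {
  x <- c(...)
  out <- Biostrings::AAStringSet(unname(x))
  names(out) <- names(x)
  out
}

# Small synthetic pairs-list with controllable values.
edge_row <- function(q, s, evalue = 1e-20, bitscore = 100, qs = 1, qe = 50,
                     ss = 1, se = 50, pident = 90) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = qe - qs + 1L,
             mismatch = 2L, gapopen = 0L, qstart = qs, qend = qe,
             sstart = ss, send = se, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

write_pairs_file <- function(edges, path) {
  protfam::writePairsList(edges, path)
  path
}
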