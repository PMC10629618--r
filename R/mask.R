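# Selective low-complexity masking. The detector compares a sequence
# against all 20 residue homopolymers under Smith-Waterman with infinite
# gap penalties: with unbounded gap cost no optimal alignment can contain
# a gap, so the alignment against an unbounded homopolymer of residue r
# reduces exactly to the maximum-scoring contiguous segment of the
# position scores s_i = matrix(seq[i], r). That reduction (a Kadane-style
# maximum subarray) is what is implemented; it is checked against an
# exhaustive all-segments oracle in the tests.

#' Homopolymer comparison targets
#'
#' The residues whose homopolymers the detector scores against: all 20
#' standard amino acids, in the alphabetical order used for tie-breaks.
#'
#' @return character vector of 20 residue letters.
#' @export
homopolymerTargets <- function() AA_STANDARD_20

#' Best homopolymer segment of a sequence
#'
#' Maximum-scoring contiguous segment of `residues` scored positionwise
#' against the homopolymer of `targetResidue` (local-alignment floor 0:
#' when every segment scores negatively the score is 0 with an empty
#' span). Among equal-scoring segments the one with the earliest end and
#' then the earliest start is reported, so results are deterministic.
#'
#' @param residues residue string.
#' @param targetResidue single standard residue letter.
#' @param matrix substitution matrix from [substitutionMatrix()].
#' @return list `score` (integer), `start`, `end` (1-based inclusive;
#'   `NA` when score is 0).
#' @examples
#' homopolymerSegment("QQQQQQQQ", "Q")$score  # 40 under BLOSUM62
#' @export
homopolymerSegment <- function(residues, targetResidue, matrix = substitutionMatrix()) {
  residues <- as.character(residues)
  if (!nzchar(residues)) stopf("empty sequence")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  if (!targetResidue %in% colnames(matrix))
    stopf("unknown target residue '%s'", targetResidue)
  if (any(!chars %in% rownames(matrix)))
    stopf("sequence contains residue '%s' absent from the matrix",
          setdiff(chars, rownames(matrix))[1])
  best_segment(unname(matrix[chars, targetResidue]))
}

# Vectorized maximum subarray with 0 floor; earliest maximal segment.
# prefix p_i = sum(sc[1..i]); best segment ending at i has score
# p_i - min_{j<i} p_j, realised from argmin j + 1.
best_segment <- function(sc) {
  n <- length(sc)
  p <- cumsum(sc)
  prev <- c(0, p[-n])             # prefix before position i
  cm <- cummin(prev)              # running minimum prefix
  ending <- p - cm
  best <- max(ending)
  if (best <= 0)
    return(list(score = 0L, start = NA_integer_, end = NA_integer_))
  end <- which(ending == best)[1L]  # earliest maximal end
  # earliest argmin of prev within 1..end gives the segment start
  start <- which(prev[seq_len(end)] == cm[end])[1L]
  list(score = as.integer(best), start = as.integer(start),
       end = as.integer(end))
}

#' Detect low-complexity regions by iterative homopolymer comparison
#'
#' Multiple-pass detection: each pass scores the current working
#' sequence against all 20 homopolymers, and if the best segment reaches
#' `threshold` the region is recorded (coordinates on the original
#' sequence), the offending residue's occurrences inside the span are
#' masked in the working copy, and the pass repeats; detection stops
#' when the best score falls below `threshold`. Per-pass masking lets
#' weaker tracts of other residue types surface after a dominant tract
#' is removed. Ties between residue types are broken alphabetically.
#'
#' @param records a named `AAStringSet` (or single residue string).
#' @param matrix substitution matrix; the mask character must score
#'   non-positively against every homopolymer (true of the default
#'   fallback `X`), which makes detection a fixed point on fully masked
#'   output.
#' @param threshold positive integer segment-score threshold
#'   (default 40).
#' @param maskChar working-copy mask character (default `"X"`).
#' @return data.frame with columns `record_id`, `residue`, `start`,
#'   `end`, `score`, `pass`.
#' @export
detectLowComplexity <- function(records, matrix = substitutionMatrix(),
                                threshold = 40L, maskChar = "X") {
  if (threshold <= 0) stopf("threshold must be positive")
  if (is.character(records) && is.null(names(records)))
    names(records) <- sprintf("seq%d", seq_along(records))
  seqs <- as.character(records)
  ids <- names(seqs) %||% names(records)
  rows <- list()
  for (ri in seq_along(seqs)) {
    chars <- strsplit(seqs[ri], "", fixed = TRUE)[[1]]
    pass <- 1L
    repeat {
      sc_all <- matrix[chars, AA_STANDARD_20, drop = FALSE]
      best <- list(score = 0L)
      best_res <- NA_character_
      for (r in AA_STANDARD_20) {       # alphabetical tie-break
        seg <- best_segment(unname(sc_all[, r]))
        if (seg$score > best$score) { best <- seg; best_res <- r }
      }
      if (best$score < threshold || is.na(best_res)) break
      rows[[length(rows) + 1L]] <- data.frame(
        record_id = ids[ri], residue = best_res,
        start = best$start, end = best$end,
        score = best$score, pass = pass, stringsAsFactors = FALSE)
      span <- seq(best$start, best$end)
      chars[span][chars[span] == best_res] <- maskChar
      pass <- pass + 1L
    }
  }
  if (!length(rows))
    return(data.frame(record_id = character(0), residue = character(0),
                      start = integer(0), end = integer(0),
                      score = integer(0), pass = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Selectively mask detected regions
#'
#' Within each region only the occurrences of that region's offending
#' residue are replaced by `maskChar`; every other position — including
#' other residues inside the span — is left untouched, so sequence
#' length is always preserved.
#'
#' @param records a named `AAStringSet`.
#' @param regions data.frame from [detectLowComplexity()] (produced from
#'   these records).
#' @param maskChar replacement character (default `"X"`).
#' @return an `AAStringSet` of the same shape with masked residues.
#' @export
maskSequences <- function(records, regions, maskChar = "X") {
  seqs <- as.character(records)
  ids <- names(seqs)
  for (k in seq_len(nrow(regions))) {
    i <- match(regions$record_id[k], ids)
    if (is.na(i)) stopf("region %d references unknown record '%s'",
                        k, regions$record_id[k])
    if (regions$start[k] < 1 || regions$end[k] > nchar(seqs[i]))
      stopf("region %d out of bounds for record '%s'", k, regions$record_id[k])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    span <- seq(regions$start[k], regions$end[k])
    chars[span][chars[span] == regions$residue[k]] <- maskChar
    seqs[i] <- paste(chars, collapse = "")
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  if (methods::is(records, "XStringSet"))
    S4Vectors::mcols(out)$description <- descriptions(records)
  out
}

#' Detect and mask low-complexity regions in one step
#'
#' @inheritParams detectLowComplexity
#' @return list with `records` (masked `AAStringSet`), `regions`
#'   (detection table) and `report` (a [MaskReport-class]).
#' @examples
#' aa <- Biostrings::AAStringSet(c(p1 = "AQAQAQAQAQAQAQAQAQAQ"))
#' res <- maskLowComplexity(aa, threshold = 40)
#' as.character(res$records)
#' @export
maskLowComplexity <- function(records, matrix = substitutionMatrix(),
                              threshold = 40L, maskChar = "X") {
  regions <- detectLowComplexity(records, matrix, threshold, maskChar)
  masked <- maskSequences(records, regions, maskChar)
  list(records = masked, regions = regions,
       report = maskReport(records, regions))
}

#' Summarize detected low-complexity regions
#'
#' Aggregates region counts per residue type, span lengths and the total
#' and fractional number of positions that selective masking replaces
#' (each position counted once even under overlapping regions).
#'
#' @param records the unmasked `AAStringSet` the regions refer to.
#' @param regions data.frame from [detectLowComplexity()].
#' @return a [MaskReport-class] object.
#' @export
maskReport <- function(records, regions) {
  seqs <- as.character(records)
  ids <- names(seqs)
  masked_by_record <- lapply(seqs, function(s) logical(nchar(s)))
  n_masked <- integer(nrow(regions))
  for (k in seq_len(nrow(regions))) {
    i <- match(regions$record_id[k], ids)
    if (is.na(i)) stopf("region %d references unknown record '%s'",
                        k, regions$record_id[k])
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    span <- seq(regions$start[k], regions$end[k])
    hit <- span[chars[span] == regions$residue[k]]
    n_masked[k] <- length(hit)
    masked_by_record[[i]][hit] <- TRUE
  }
  regions$n_masked <- n_masked
  methods::new("MaskReport",
    regions = regions,
    nRecords = length(seqs),
    totalResidues = as.integer(sum(nchar(seqs))),
    maskedPositions = as.integer(sum(vapply(masked_by_record, sum, numeric(1))))
  )
}

#' Write a low-complexity region table
#'
#' Tab-separated `record_id  residue  start  end  score  pass`,
#' 1-based inclusive, no header.
#'
#' @param regions data.frame from [detectLowComplexity()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegions <- function(regions, path) {
  write.table(regions[, c("record_id", "residue", "start", "end",
                          "score", "pass")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
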