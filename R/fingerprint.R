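# MD5 sequence fingerprinting: identical canonical residue strings map to
# identical 32-character digests, giving an exact-identity join key for
# cross-mapping identifiers between sequence collections. MD5 is used as
# an identity map, not for security; its published weaknesses do not
# affect this use and digests of the residue bytes alone (no header, no
# terminator) keep the contract minimal.

#' MD5 fingerprint of protein sequences
#'
#' Digests the ASCII bytes of the canonicalized residue string (see
#' [canonicalizeResidues()]); the record id and description never enter
#' the digest, so records with identical residues always share a
#' fingerprint.
#'
#' @param x an `AAStringSet` or character vector of residue strings.
#' @return character vector of 32-character lowercase hex digests.
#' @examples
#' seqFingerprint(c("MKV", " mkv ", "MKV*"))  # all identical
#' @export
seqFingerprint <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  canon <- canonicalizeResidues(x)
  vapply(canon, function(s) digest::digest(s, algo = "md5", serialize = FALSE),
         character(1), USE.NAMES = FALSE)
}

#' Index a sequence collection by fingerprint
#'
#' Groups record ids by sequence fingerprint, preserving insertion order
#' within groups and first-seen order across groups. Records whose
#' residues differ but whose digests collide (never observed in
#' practice) are reported with a warning rather than silently merged.
#'
#' @param records a named `AAStringSet`.
#' @return named list: fingerprint -> character vector of record ids.
#' @export
fingerprintIndex <- function(records) {
  if (!length(records)) return(stats::setNames(list(), character(0)))
  if (is.null(names(records))) stopf("records must be named")
  fp <- seqFingerprint(records)
  canon <- canonicalizeResidues(as.character(records))
  grp <- split(seq_along(fp), factor(fp, levels = unique(fp)))
  for (g in grp) {
    if (length(unique(canon[g])) > 1L)
      warnf("MD5 collision between distinct sequences: %s",
            paste(names(records)[g], collapse = ", "))
  }
  lapply(grp, function(i) names(records)[i])
}

#' Cross-match two sequence collections by fingerprint
#'
#' One row per fingerprint present in either set; rows populated on both
#' sides are the sequences shared (identically) between the collections.
#' The fingerprint set is symmetric in A and B.
#'
#' @param setA,setB named `AAStringSet` collections.
#' @return data.frame with columns `fingerprint`, `n_a`, `n_b`, `ids_a`,
#'   `ids_b` (comma-joined id lists, `""` if absent) and `shared`.
#' @examples
#' a <- Biostrings::AAStringSet(c(x = "MKV"))
#' b <- Biostrings::AAStringSet(c(y = "MKV", z = "GGS"))
#' crossMatch(a, b)
#' @export
crossMatch <- function(setA, setB) {
  ia <- fingerprintIndex(setA)
  ib <- fingerprintIndex(setB)
  fps <- unique(c(names(ia), names(ib)))
  ids_a <- lapply(fps, function(f) ia[[f]] %||% character(0))
  ids_b <- lapply(fps, function(f) ib[[f]] %||% character(0))
  data.frame(
    fingerprint = fps,
    n_a = lengths(ids_a),
    n_b = lengths(ids_b),
    ids_a = vapply(ids_a, paste, character(1), collapse = ","),
    ids_b = vapply(ids_b, paste, character(1), collapse = ","),
    shared = lengths(ids_a) > 0L & lengths(ids_b) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Write a fingerprint index or cross-match table
#'
#' The index form is `fingerprint<TAB>id`, one line per record; the
#' cross form is `fingerprint<TAB>ids_A(comma)<TAB>ids_B(comma)`.
#'
#' @param x a [fingerprintIndex()] list or [crossMatch()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFingerprints <- function(x, path) {
  if (is.data.frame(x)) {
    write.table(x[, c("fingerprint", "ids_a", "ids_b")], path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(fingerprint = rep(names(x), lengths(x)),
                     id = unlist(x, use.names = FALSE))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
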