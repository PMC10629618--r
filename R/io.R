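# FASTA and pairs-list I/O. Coordinates are 1-based inclusive at every
# file interface (BLAST tabular convention); sequences are held as
# AAStringSet with ids in names() and free-text descriptions in
# mcols()$description.

#' Read a protein FASTA file
#'
#' Parses `>id description` definition lines: the id is the first
#' whitespace-delimited token after `>`, the remainder (if any) the
#' description. Sequence lines belonging to one record are concatenated
#' with all whitespace removed and input order is preserved. Duplicate
#' ids are permitted with a warning; stages that index by id fail there.
#'
#' @param path path to a FASTA file (plain text or gzip).
#' @return an [Biostrings::AAStringSet] with record ids as names and a
#'   `description` metadata column.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 a toy protein", "MKVLA", ">p2", "GGSGG"), f)
#' aa <- readFasta(f)
#' names(aa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep)) stopf("empty FASTA file: %s", path)
  first <- which(keep)[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stopf("malformed FASTA %s: line %d does not start with '>'", path, first)
  lines <- lines[keep]
  is_hdr <- startsWith(lines, ">")
  grp <- cumsum(is_hdr)
  headers <- trimws(sub("^>", "", lines[is_hdr]))
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 trimws(sub("^[^[:space:]]+[[:space:]]+", "", headers)), "")
  if (any(!nzchar(ids)))
    stopf("record %d has an empty identifier", which(!nzchar(ids))[1])
  n <- length(ids)
  seq_lines <- lines[!is_hdr]
  seq_grp <- grp[!is_hdr]
  seqs <- character(n)
  if (length(seq_lines)) {
    joined <- vapply(split(seq_lines, factor(seq_grp, levels = seq_len(n))),
                     function(x) paste(x, collapse = ""), character(1))
    seqs[as.integer(names(joined))] <- joined
  }
  seqs <- gsub("[[:space:]]", "", seqs)
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stopf("record %d (%s) has an empty sequence", empty[1], ids[empty[1]])
  if (anyDuplicated(ids))
    warnf("duplicate record ids in %s: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- ids
  S4Vectors::mcols(x)$description <- desc
  x
}

#' Write a protein FASTA file
#'
#' Headers are `>id` or `>id description` (description taken from
#' `mcols(x)$description` when present); sequence lines are wrapped at 60
#' columns so outputs are byte-stable.
#'
#' @param x an `AAStringSet` (or named character vector of residues).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stopf("all records must be named to write FASTA")
  desc <- descriptions(x)
  out <- x
  names(out) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
  Biostrings::writeXStringSet(out, filepath = path, width = 60L)
  invisible(path)
}

#' Record descriptions of a sequence set
#'
#' @param x an `AAStringSet`.
#' @return character vector of descriptions ("" where absent).
#' @export
descriptions <- function(x) {
  mc <- S4Vectors::mcols(x)
  if (!is.null(mc) && "description" %in% names(mc)) {
    d <- as.character(mc$description)
    d[is.na(d)] <- ""
    d
  } else rep("", length(x))
}

#' Canonicalize residue strings
#'
#' Uppercases, removes all internal whitespace and strips a single
#' trailing stop (`*`). Internal stops, empty results and characters
#' outside the accepted amino-acid alphabet (20 standard letters plus
#' B, Z, J, U, O, X) are rejected. Idempotent.
#'
#' @param residues character vector of residue strings.
#' @return character vector of canonical residue strings.
#' @examples
#' canonicalizeResidues(c("mkv", "MKV*", " M K V "))
#' @export
canonicalizeResidues <- function(residues) {
  residues <- as.character(residues)
  out <- toupper(gsub("[[:space:]]", "", residues))
  out <- sub("\\*$", "", out)
  bad <- grep("\\*", out)
  if (length(bad))
    stopf("internal stop '*' in residue string %d", bad[1])
  if (any(!nzchar(out)))
    stopf("residue string %d is empty after canonicalization",
          which(!nzchar(out))[1])
  ok <- paste0(c(AA_STANDARD_20, AA_EXTRA), collapse = "")
  bad <- grep(sprintf("[^%s]", ok), out)
  if (length(bad)) {
    ch <- sub(sprintf(".*?([^%s]).*", ok), "\\1", out[bad[1]])
    stopf("residue string %d contains invalid character '%s'", bad[1], ch)
  }
  out
}

#' Parse a BLAST tabular pairs-list
#'
#' Reads the 12-column tab-separated dialect (BLAST `-outfmt 6`):
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Self-hits are retained (downstream
#' stages decide what to do with them). Subject coordinates given in
#' reverse orientation are normalized to `sstart <= send`.
#'
#' @param path path to the pairs-list file.
#' @param dialect `"blast12"` (plain) or `"blast12_commented"`
#'   (`#`-prefixed lines skipped).
#' @return data.frame of similarity edges, one row per hit, with a
#'   `source_line` attribute mapping rows to input line numbers.
#' @export
parsePairsList <- function(path, dialect = c("blast12", "blast12_commented")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("pairs-list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  if (dialect == "blast12_commented")
    keep <- keep & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- lineno[keep]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), 2), cols[1:2]), stringsAsFactors = FALSE)
    for (nm in cols[-(1:2)]) df[[nm]] <- numeric(0)
    attr(df, "source_line") <- integer(0)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1]
    stopf("pairs-list %s line %d: expected 12 tab-separated fields, got %d",
          path, lineno[i], nf[i])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2], stringsAsFactors = FALSE)
  for (k in 3:12) {
    v <- suppressWarnings(as.numeric(m[, k]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stopf("pairs-list %s line %d: non-numeric value '%s' in column %s",
            path, lineno[i], m[i, k], cols[k])
    }
    df[[cols[k]]] <- v
  }
  for (nm in c("length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send"))
    df[[nm]] <- as.integer(df[[nm]])
  flip <- df$sstart > df$send
  if (any(flip)) {
    tmp <- df$sstart[flip]; df$sstart[flip] <- df$send[flip]; df$send[flip] <- tmp
  }
  flip <- df$qstart > df$qend
  if (any(flip)) {
    tmp <- df$qstart[flip]; df$qstart[flip] <- df$qend[flip]; df$qend[flip] <- tmp
  }
  if (any(df$evalue < 0)) stopf("negative E-value in %s", path)
  attr(df, "source_line") <- lineno
  df
}

#' Write a pairs-list in the 12-column tabular dialect
#'
#' @param edges data.frame as produced by [parsePairsList()] or
#'   [allVsAll()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePairsList <- function(edges, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  miss <- setdiff(cols, names(edges))
  if (length(miss)) stopf("edges lack columns: %s", paste(miss, collapse = ", "))
  write.table(edges[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
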