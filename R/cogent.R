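# CoGenT-style identifier encoding: a genome collection's undisciplined
# identifier space is re-encoded as `Code-tag-vv-nnnnnn` (4-letter
# species code, free alphanumeric assembly tag, 2-digit collection
# version starting at 01, 6-digit serial starting at 000000), with the
# full original header preserved as the description so nothing is lost.

#' Render CoGenT-style identifiers
#'
#' @param speciesCode 4-letter token with an initial capital (e.g.
#'   `"Taeg"` for *Taeniopygia guttata*).
#' @param assemblyTag alphanumeric token (no `-`).
#' @param version integer 1-99 (rendered 2-digit zero-padded).
#' @param serial integer 0-999999 (rendered 6-digit zero-padded);
#'   vectorized.
#' @return character vector of rendered ids.
#' @examples
#' cogentId("Taeg", "2p1", 1, 0:1)
#' @export
cogentId <- function(speciesCode, assemblyTag, version, serial) {
  check_catalog_fields(speciesCode, assemblyTag, version)
  if (any(serial < 0 | serial > 999999))
    stopf("serial out of range 0-999999")
  sprintf("%s-%s-%02d-%06d", speciesCode, assemblyTag,
          as.integer(version), as.integer(serial))
}

check_catalog_fields <- function(speciesCode, assemblyTag, version) {
  if (!grepl("^[A-Z][A-Za-z]{3}$", speciesCode))
    stopf("species code '%s' must be 4 letters with an initial capital",
          speciesCode)
  if (!grepl("^[A-Za-z0-9]+$", assemblyTag))
    stopf("assembly tag '%s' must be alphanumeric (no '-')", assemblyTag)
  version <- suppressWarnings(as.integer(version))
  if (is.na(version) || version < 1L || version > 99L)
    stopf("version must be an integer in 1-99")
  invisible(TRUE)
}

#' Decode CoGenT-style identifiers
#'
#' Inverse of [cogentId()]: `decode(encode(x))` is the identity for
#' every valid identifier.
#'
#' @param ids character vector of rendered identifiers.
#' @return data.frame with columns `species_code`, `assembly_tag`,
#'   `version`, `serial` (integers).
#' @examples
#' decodeCogentId("Taeg-2p1-01-000000")
#' @export
decodeCogentId <- function(ids) {
  parts <- strsplit(ids, "-", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stopf("identifier '%s' does not have 4 '-'-separated fields",
          ids[bad[1]])
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  if (any(!grepl("^[0-9]{2}$", m[, 3])))
    stopf("identifier '%s' has a non-numeric or malformed version field",
          ids[which(!grepl("^[0-9]{2}$", m[, 3]))[1]])
  if (any(!grepl("^[0-9]{6}$", m[, 4])))
    stopf("identifier '%s' has a non-numeric or malformed serial field",
          ids[which(!grepl("^[0-9]{6}$", m[, 4]))[1]])
  data.frame(species_code = m[, 1], assembly_tag = m[, 2],
             version = as.integer(m[, 3]), serial = as.integer(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Suggest a species code from a binomial name
#'
#' Helper only — the catalog remains authoritative (collision handling
#' across taxonomies is policy, not mechanism). The rule reproduces the
#' conventional example `Taeniopygia guttata` -> `Taeg`: the first three
#' letters of the genus (title-cased) plus the first letter of the
#' species epithet (lower-cased).
#'
#' @param binomial e.g. `"Taeniopygia guttata"`.
#' @return 4-letter species code suggestion.
#' @export
suggestSpeciesCode <- function(binomial) {
  parts <- strsplit(trimws(binomial), "[[:space:]]+")[[1]]
  if (length(parts) < 2L) stopf("need a binomial 'Genus species' name")
  paste0(toupper(substr(parts[1], 1, 1)),
         tolower(substr(parts[1], 2, 3)),
         tolower(substr(parts[2], 1, 1)))
}

#' Re-encode a sequence collection with CoGenT-style identifiers
#'
#' Each record's id becomes `Code-tag-vv-nnnnnn` with serials
#' consecutive from 000000 in input order; the complete original header
#' (id plus description) is preserved as the new description. Residues
#' are untouched.
#'
#' @param records a named `AAStringSet` (non-empty).
#' @param speciesCode,assemblyTag,version catalog fields (see
#'   [cogentId()]).
#' @return an `AAStringSet` with re-encoded ids.
#' @examples
#' aa <- Biostrings::AAStringSet(c(NP_000001.1 = "MKV"))
#' S4Vectors::mcols(aa)$description <- "example protein"
#' names(encodeCollection(aa, "Taeg", "2p1", 1))
#' @export
encodeCollection <- function(records, speciesCode, assemblyTag, version = 1L) {
  if (!length(records)) stopf("cannot encode an empty collection")
  if (length(records) > 999999L)
    stopf("collection exceeds the 6-digit serial space (999,999 records)")
  check_catalog_fields(speciesCode, assemblyTag, version)
  old_ids <- names(records)
  if (is.null(old_ids)) stopf("records must be named")
  desc <- descriptions(records)
  out <- Biostrings::AAStringSet(as.character(records))
  names(out) <- cogentId(speciesCode, assemblyTag, version,
                         seq_along(records) - 1L)
  S4Vectors::mcols(out)$description <-
    trimws(paste(old_ids, desc))
  out
}

#' Read a genome-encoding catalog
#'
#' Tab-separated columns `source_path`, `species_code`, `assembly_tag`,
#' `version` (header optional). The (code, tag, version) triple must be
#' unique across the catalog.
#'
#' @param path catalog TSV path.
#' @return data.frame of catalog entries.
#' @export
readCatalog <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("source_path", "species_code",
                                 "assembly_tag", "version"))
  if (nrow(df) && df$source_path[1] == "source_path") df <- df[-1, , drop = FALSE]
  df$version <- as.integer(df$version)
  key <- paste(df$species_code, df$assembly_tag, df$version)
  if (anyDuplicated(key))
    stopf("duplicate catalog entry: %s", key[duplicated(key)][1])
  for (i in seq_len(nrow(df)))
    check_catalog_fields(df$species_code[i], df$assembly_tag[i], df$version[i])
  df
}

#' Build a concatenated reference database from a catalog
#'
#' Reads each source FASTA, re-encodes it with its catalog entry, and
#' concatenates the collections in catalog order into one reference
#' FASTA plus a manifest TSV of `(species_code, assembly_tag, version,
#' record_count, source_path)`. Global id uniqueness is enforced; a
#' duplicate rendered id aborts naming both sources.
#'
#' @param catalog data.frame from [readCatalog()] (or of the same shape).
#' @param out output FASTA path.
#' @param manifest output manifest TSV path (default `<out>.manifest.tsv`).
#' @return the manifest data.frame, invisibly.
#' @export
buildReference <- function(catalog, out,
                           manifest = paste0(out, ".manifest.tsv")) {
  key <- paste(catalog$species_code, catalog$assembly_tag, catalog$version)
  if (anyDuplicated(key))
    stopf("duplicate catalog entry: %s", key[duplicated(key)][1])
  collections <- vector("list", nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    recs <- readFasta(catalog$source_path[i])
    collections[[i]] <- encodeCollection(recs, catalog$species_code[i],
                                         catalog$assembly_tag[i],
                                         catalog$version[i])
  }
  all_ids <- unlist(lapply(collections, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    dup <- all_ids[duplicated(all_ids)][1]
    src <- catalog$source_path[vapply(collections,
                                      function(x) dup %in% names(x), logical(1))]
    stopf("duplicate encoded id '%s' across sources: %s",
          dup, paste(src, collapse = " and "))
  }
  merged <- do.call(c, collections)
  S4Vectors::mcols(merged)$description <-
    unlist(lapply(collections, descriptions), use.names = FALSE)
  writeFasta(merged, out)
  mf <- data.frame(
    species_code = catalog$species_code,
    assembly_tag = catalog$assembly_tag,
    version = catalog$version,
    record_count = vapply(collections, length, integer(1)),
    source_path = catalog$source_path,
    stringsAsFactors = FALSE
  )
  write.table(mf, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mf)
}
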