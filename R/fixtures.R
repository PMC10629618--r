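# Seeded synthetic proteome generator. Background sequences are drawn
# uniformly over the 20 standard residues (a null model under which two
# independent sequences are unrelated with overwhelming probability);
# biased tracts, homologous family triples and fusion trios are implanted
# on top so ground truth is exact and machine-readable.

random_residues <- function(n) {
  paste(sample(AA_STANDARD_20, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic protein fixture with known ground truth
#'
#' Produces a reproducible random proteome plus optional implanted
#' features, each recorded in a truth table
#' (`kind  record_id  start  end  detail`, 1-based inclusive):
#' \describe{
#'   \item{low-complexity implants}{`lcrImplants` is a list of
#'     `list(record=, start=, end=, residue=)`; the span is overwritten
#'     with the named residue (truth kind `"lcr"`).}
#'   \item{family triples}{for each triple a base sequence and two copies
#'     with ~10\% point substitutions are appended (ids `FAMk_1..3`,
#'     truth kind `"family"`, detail = family label).}
#'   \item{fusion trios}{for each trio two unrelated components `FUSkA`,
#'     `FUSkB` and a composite `FUSkC` = A-segment + linker + B-segment
#'     are appended; truth kind `"fusion_component"` rows give each
#'     component's span on the composite (detail = component id), plus a
#'     `"fusion_composite"` row spanning the composite.}
#' }
#' Identical seeds yield byte-identical output.
#'
#' @param nSequences number of background sequences.
#' @param lengthRange integer length range for background sequences.
#' @param seed integer seed; required for reproducibility.
#' @param lcrImplants list of low-complexity implant specs (see above).
#' @param fusionTrios number of fusion trios to append.
#' @param familyTriples number of homologous triples to append.
#' @return list with `records` (an `AAStringSet`) and `truth`
#'   (data.frame `kind`, `record_id`, `start`, `end`, `detail`).
#' @examples
#' fx <- makeFixture(nSequences = 5, seed = 1, fusionTrios = 1)
#' fx$truth
#' @export
makeFixture <- function(nSequences = 30L, lengthRange = c(80L, 160L),
                        seed, lcrImplants = list(), fusionTrios = 0L,
                        familyTriples = 0L) {
  if (missing(seed)) stopf("makeFixture() requires an explicit seed")
  stopifnot(nSequences >= 0, length(lengthRange) == 2L,
            lengthRange[1] >= 1, lengthRange[1] <= lengthRange[2])
  with_seed(seed, {
    rng <- seq(lengthRange[1], lengthRange[2])
    lens <- rng[sample.int(length(rng), nSequences, replace = TRUE)]
    seqs <- vapply(lens, random_residues, character(1))
    ids <- sprintf("SYN%04d", seq_len(nSequences))
    truth <- list()

    for (im in lcrImplants) {
      need <- c("record", "start", "end", "residue")
      if (!all(need %in% names(im)))
        stopf("lcr implant needs fields: %s", paste(need, collapse = ", "))
      i <- im$record
      if (i < 1 || i > nSequences) stopf("implant record %d out of range", i)
      if (im$start < 1 || im$end > nchar(seqs[i]) || im$start > im$end)
        stopf("implant span %d-%d exceeds record %d (length %d)",
              im$start, im$end, i, nchar(seqs[i]))
      substr(seqs[i], im$start, im$end) <-
        strrep(im$residue, im$end - im$start + 1L)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "lcr", record_id = ids[i], start = im$start, end = im$end,
        detail = im$residue, stringsAsFactors = FALSE)
    }

    for (k in seq_len(familyTriples)) {
      base <- random_residues(120L)
      fam_ids <- sprintf("FAM%d_%d", k, 1:3)
      members <- c(base, mutate_sequence(base, 0.10),
                   mutate_sequence(base, 0.10))
      ids <- c(ids, fam_ids)
      seqs <- c(seqs, members)
      for (j in 1:3)
        truth[[length(truth) + 1L]] <- data.frame(
          kind = "family", record_id = fam_ids[j], start = 1L,
          end = nchar(members[j]), detail = sprintf("FAM%d", k),
          stringsAsFactors = FALSE)
    }

    for (k in seq_len(fusionTrios)) {
      a <- random_residues(120L)
      b <- random_residues(120L)
      linker <- random_residues(10L)
      a_seg <- substr(a, 1L, 100L)
      b_seg <- substr(b, 1L, 100L)
      comp <- paste0(a_seg, linker, b_seg)
      trio_ids <- sprintf("FUS%d%s", k, c("A", "B", "C"))
      ids <- c(ids, trio_ids)
      seqs <- c(seqs, a, b, comp)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "fusion_component", record_id = trio_ids[3], start = 1L,
        end = 100L, detail = trio_ids[1], stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "fusion_component", record_id = trio_ids[3], start = 111L,
        end = 210L, detail = trio_ids[2], stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        kind = "fusion_composite", record_id = trio_ids[3], start = 1L,
        end = nchar(comp), detail = sprintf("%s+%s", trio_ids[1], trio_ids[2]),
        stringsAsFactors = FALSE)
    }

    records <- Biostrings::AAStringSet(seqs)
    names(records) <- ids
    S4Vectors::mcols(records)$description <-
      rep("synthetic fixture", length(records))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(kind = character(0), record_id = character(0),
                 start = integer(0), end = integer(0),
                 detail = character(0), stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

# Point-substitute a fraction of positions with random other residues.
mutate_sequence <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n_mut <- max(1L, round(rate * length(chars)))
  pos <- sample(length(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_STANDARD_20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Write a fixture truth table
#'
#' Tab-separated `kind  record_id  start  end  detail`, 1-based inclusive
#' coordinates, with a header line.
#'
#' @param truth data.frame from [makeFixture()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
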