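#' FamilySet: a partition of sequence identifiers into protein families
#'
#' Container for the result of a clustering stage (Markov clustering or
#' hit-matrix single-linkage clustering). Families are numbered
#' incrementally from 1, ordered by decreasing member count with ties
#' broken by the lexicographically smallest member id. Multi-domain
#' proteins re-attached to several core families (single-linkage route)
#' are carried separately in `annotations` so that `families` itself
#' always remains a disjoint collection.
#'
#' @slot families list of character vectors; element `i` holds the member
#'   ids of family `i`.
#' @slot unassigned character vector of ids not placed in any family
#'   (e.g. multi-domain proteins without a neighbour family).
#' @slot annotations data.frame with columns `protein` and `family` giving
#'   additional (non-exclusive) family memberships of multi-domain
#'   proteins; zero rows for Markov clustering results.
#' @slot method character scalar naming the producing algorithm.
#'
#' @exportClass FamilySet
setClass("FamilySet",
  representation(
    families    = "list",
    unassigned  = "character",
    annotations = "data.frame",
    method      = "character"
  ),
  prototype(
    families    = list(),
    unassigned  = character(0),
    annotations = data.frame(protein = character(0), family = integer(0),
                             stringsAsFactors = FALSE),
    method      = NA_character_
  )
)

setValidity("FamilySet", function(object) {
  msgs <- character(0)
  mem <- unlist(object@families, use.names = FALSE)
  if (anyDuplicated(mem))
    msgs <- c(msgs, "family members are not disjoint")
  if (length(intersect(mem, object@unassigned)))
    msgs <- c(msgs, "unassigned ids overlap family members")
  if (nrow(object@annotations) &&
      !all(c("protein", "family") %in% names(object@annotations)))
    msgs <- c(msgs, "annotations must have columns 'protein' and 'family'")
  if (length(msgs)) msgs else TRUE
})

#' MaskReport: statistics and geometry of detected low-complexity regions
#'
#' Aggregates the regions found by [detectLowComplexity()] over a sequence
#' collection: the per-region table plus totals needed for the masked
#' fraction. Positions are only counted once even when regions overlap.
#'
#' @slot regions data.frame with columns `record_id`, `residue`, `start`,
#'   `end`, `score`, `pass`, `n_masked` (1-based inclusive coordinates on
#'   the unmasked sequence).
#' @slot nRecords number of records surveyed.
#' @slot totalResidues total residue count of the surveyed records.
#' @slot maskedPositions number of distinct positions that selective
#'   masking replaces.
#'
#' @exportClass MaskReport
setClass("MaskReport",
  representation(
    regions         = "data.frame",
    nRecords        = "integer",
    totalResidues   = "integer",
    maskedPositions = "integer"
  )
)

setValidity("MaskReport", function(object) {
  r <- object@regions
  need <- c("record_id", "residue", "start", "end", "score", "pass", "n_masked")
  if (!all(need %in% names(r)))
    return(paste("regions must have columns:", paste(need, collapse = ", ")))
  if (nrow(r) && any(r$start > r$end))
    return("region start > end")
  if (object@maskedPositions > object@totalResidues)
    return("masked positions exceed total residues")
  TRUE
})
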