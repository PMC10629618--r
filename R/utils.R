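# Internal helpers shared across modules.

#' @importFrom methods new validObject is
#' @importFrom stats sd
#' @importFrom utils read.table write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Deterministic small integer seed derived from a character key; independent
# of input order when the key is built from a sorted id pair. Kept < 2^31.
seed_from_key <- function(key, base = 0L) {
  h <- digest::digest(key, algo = "md5", serialize = FALSE)
  (strtoi(substr(h, 1, 7), base = 16L) + as.integer(base)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The 20 standard amino-acid residues, alphabetical (tie-break order for
# homopolymer targets).
AA_STANDARD_20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity/extended letters tolerated on input; scored via matrix fallback.
AA_EXTRA <- c("B", "Z", "J", "U", "O", "X")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
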