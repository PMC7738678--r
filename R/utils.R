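# Ordinal repeat states, lowest to highest.
REPEAT_CLASSES <- c("ABSENT", "PROTO", "PRIMITIVE", "VARIABLE")

# 20-letter IUPAC amino-acid alphabet (X handled separately as ambiguity).
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Ordinal repeat classes
#'
#' The four states a RUNX2 QA repeat domain can take, in ordinal order:
#' `ABSENT` (no flanking motifs detectable), `PROTO` (flanks present but at
#' least one of polyQ/polyA missing), `PRIMITIVE` (both runs present but
#' short or interrupted), `VARIABLE` (long uninterrupted runs whose length
#' varies across a clade).
#'
#' @return Character vector of length 4, lowest state first.
#' @export
#' @examples
#' repeat_classes()
repeat_classes <- function() REPEAT_CLASSES

# ordinal rank of a repeat class; errors on unknown labels
class_rank <- function(x) {
  r <- match(x, REPEAT_CLASSES)
  if (anyNA(r)) {
    stop("unknown repeat class: ", paste(unique(x[is.na(r)]), collapse = ", "))
  }
  r
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
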