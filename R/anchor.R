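# Flank-motif anchoring. The QA repeat domain is defined as the region
# between a conserved N-terminal MSDVS and C-terminal VPRLR motif, sitting
# at the protein N terminus immediately upstream of the RUNT domain. The
# motifs are only "mostly" conserved across vertebrates (the C flank even
# occurs as the transposed spelling VRPLR), so matching is Hamming-distance
# based with a configurable mismatch budget.

#' Find approximate motif matches by Hamming distance
#'
#' Scans every window of `seq` of the motif's length and keeps windows
#' within `max_mismatch` substitutions. `X` (ambiguity) in the sequence
#' always counts as a mismatch. No profile/HMM scoring: plain Hamming only.
#'
#' @param seq Amino-acid string.
#' @param motif Motif string, length >= 3.
#' @param max_mismatch Maximum substitutions tolerated; must be smaller
#'   than the motif length.
#' @return A `data.frame` with columns `start` (0-based window offset),
#'   `mismatches`, `matched` (the window text), sorted by
#'   (mismatches, start). Empty (zero rows) when the motif is longer than
#'   the sequence or nothing matches.
#' @export
#' @examples
#' find_motif("AAMSDVSQQ", "MSDVS", max_mismatch = 0)
find_motif <- function(seq, motif, max_mismatch = 2L) {
  stopifnot(is.character(seq), length(seq) == 1L,
            is.character(motif), length(motif) == 1L)
  m <- nchar(motif)
  if (m < 3) stop("motif length must be >= 3")
  if (max_mismatch >= m) stop("max_mismatch must be smaller than the motif length")
  empty <- data.frame(start = integer(), mismatches = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  L <- nchar(seq)
  if (m > L) return(empty)
  s <- strsplit(toupper(seq), "")[[1]]
  mo <- strsplit(toupper(motif), "")[[1]]
  nwin <- L - m + 1L
  mism <- integer(nwin)
  for (k in seq_len(m)) {
    sk <- s[k:(k + nwin - 1L)]
    mism <- mism + as.integer(sk != mo[k] | sk == "X")
  }
  keep <- which(mism <= max_mismatch)
  if (!length(keep)) return(empty)
  hits <- data.frame(start = keep - 1L,
                     mismatches = mism[keep],
                     matched = substring(toupper(seq), keep, keep + m - 1L),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$mismatches, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

anchor_not_found <- function(meta, missing) {
  structure(c(meta, list(missing = missing)), class = "anchor_not_found")
}

#' Excise the candidate QA region between the flanking motifs
#'
#' Searches the first `config$window` residues for the N and C flank
#' motifs, picks the lowest-mismatch N hit and then the lowest-mismatch C
#' hit downstream of it (ties broken leftmost). When the best N hit has no
#' downstream C hit, the next-best N hit is tried before giving up. The
#' excision is lossless: re-inserting `inner_seq` between the matched flank
#' texts reconstructs the original substring.
#'
#' @param record One protein record: a list or single data-frame row with
#'   at least `seq`, and optionally `id`, `taxon`, `clade`.
#' @param config A [qa_config()] (fields `n_motif`, `c_motif`,
#'   `max_mismatch`, `window`).
#' @return An `anchored_region` (fields `id`, `taxon`, `clade`, `seq`,
#'   `n_hit`, `c_hit`, `inner_seq`, `inner_start` 0-based), or an
#'   `anchor_not_found` object whose `missing` field names which flank(s)
#'   failed (`"N"`, `"C"`, or both); the latter maps to class `ABSENT`
#'   downstream.
#' @export
extract_qa_region <- function(record, config = qa_config()) {
  seq <- toupper(record$seq)
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  meta <- list(id = record$id %||% NA_character_,
               taxon = record$taxon %||% NA_character_,
               clade = record$clade %||% NA_character_,
               seq = seq)
  searchable <- substr(seq, 1L, config$window)
  n_hits <- find_motif(searchable, config$n_motif, config$max_mismatch)
  c_hits <- find_motif(searchable, config$c_motif, config$max_mismatch)
  if (nrow(n_hits) == 0 && nrow(c_hits) == 0) {
    return(anchor_not_found(meta, c("N", "C")))
  }
  if (nrow(n_hits) == 0) return(anchor_not_found(meta, "N"))
  if (nrow(c_hits) == 0) return(anchor_not_found(meta, "C"))
  nm <- nchar(config$n_motif)
  for (i in seq_len(nrow(n_hits))) {
    n_end <- n_hits$start[i] + nm
    cand <- c_hits[c_hits$start >= n_end, , drop = FALSE]
    if (nrow(cand) == 0) next
    n_hit <- as.list(n_hits[i, ])
    n_hit$motif <- config$n_motif
    c_hit <- as.list(cand[1L, ])
    c_hit$motif <- config$c_motif
    # inner region is [n_end, c_start) in 0-based half-open coordinates
    inner <- substr(seq, n_end + 1L, c_hit$start)
    return(structure(
      c(meta, list(n_hit = n_hit, c_hit = c_hit,
                   inner_seq = inner, inner_start = n_end)),
      class = "anchored_region"))
  }
  anchor_not_found(meta, "C")
}
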