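# polyQ/polyA run detection with interruption tolerance, and the domain
# composition statistics built on it (Q:A ratio, codon-level repeat purity).
#
# A "run" is a maximal window of the anchored inner region that
#   * starts and ends on the run residue,
#   * contains at least one stretch of >= min_seed consecutive residues,
#   * has every interruption stretch of length <= max_gap, and
#   * has (interruptions / span) <= max_interrupt_frac.
# Maximality is exact (no greedy extension order-dependence): candidate
# runs are enumerated over homopolymer block ranges and windows contained
# in a larger valid window are dropped.

#' Detect polyQ or polyA runs with interruptions
#'
#' @param inner_seq The anchored inter-motif region (amino-acid string).
#' @param residue `"Q"` or `"A"`.
#' @param min_seed Minimum seed length of consecutive `residue` (>= 2).
#' @param max_gap Maximum length of one interruption stretch that can be
#'   bridged (0 disables interruption tolerance entirely).
#' @param max_interrupt_frac Maximum fraction of the run span occupied by
#'   interruptions.
#' @return A list of `repeat_run` objects sorted by start, each with
#'   `residue`, `start`, `end` (0-based half-open into `inner_seq`),
#'   `count` (positions equal to `residue`), and `interruptions` (a
#'   `data.frame` of run-relative `offset` and `residue`). Empty list when
#'   no seed exists. `X` is never a run member, so ambiguity characters
#'   terminate or interrupt runs.
#' @export
#' @examples
#' detect_run("QQHQQQPQQ", "Q", max_gap = 1)
detect_run <- function(inner_seq, residue, min_seed = 2L, max_gap = 1L,
                       max_interrupt_frac = 0.34) {
  stopifnot(is.character(residue), nchar(residue) == 1L)
  if (!residue %in% c("Q", "A")) stop("residue must be 'Q' or 'A'")
  if (min_seed < 2) stop("min_seed must be >= 2")
  if (max_gap < 0 || max_interrupt_frac < 0 || max_interrupt_frac > 1) {
    stop("invalid interruption tolerance")
  }
  ch <- strsplit(toupper(inner_seq), "")[[1]]
  L <- length(ch)
  if (L == 0) return(list())
  r <- rle(ch == residue)
  ends <- cumsum(r$lengths)          # 0-based half-open block ends
  starts <- ends - r$lengths         # 0-based block starts
  bi <- which(r$values)
  if (!length(bi)) return(list())
  bstart <- starts[bi]
  bend <- ends[bi]
  blen <- r$lengths[bi]
  nb <- length(bi)
  gaps <- if (nb > 1) bstart[-1] - bend[-nb] else integer(0)
  chain <- cumsum(c(1L, as.integer(gaps > max_gap)))
  runs <- list()
  for (cid in unique(chain)) {
    idx <- which(chain == cid)
    k <- length(idx)
    valid <- matrix(FALSE, k, k)
    for (i in seq_len(k)) {
      for (j in i:k) {
        sel <- idx[i:j]
        span <- bend[idx[j]] - bstart[idx[i]]
        interr <- span - sum(blen[sel])
        valid[i, j] <- interr / span <= max_interrupt_frac &&
          max(blen[sel]) >= min_seed
      }
    }
    for (i in seq_len(k)) {
      for (j in i:k) {
        if (!valid[i, j]) next
        contained <- FALSE
        for (i2 in seq_len(i)) {
          for (j2 in j:k) {
            if ((i2 < i || j2 > j) && valid[i2, j2]) contained <- TRUE
          }
        }
        if (contained) next
        s0 <- bstart[idx[i]]
        e0 <- bend[idx[j]]
        pos <- s0:(e0 - 1L)
        is_int <- ch[pos + 1L] != residue
        runs[[length(runs) + 1L]] <- structure(
          list(residue = residue, start = s0, end = e0,
               count = as.integer(sum(!is_int)),
               interruptions = data.frame(
                 offset = pos[is_int] - s0,
                 residue = ch[pos[is_int] + 1L],
                 stringsAsFactors = FALSE)),
          class = "repeat_run")
      }
    }
  }
  runs[order(vapply(runs, `[[`, integer(1), "start"))]
}

run_interrupted <- function(run) {
  !is.null(run) && nrow(run$interruptions) > 0
}

#' Q:A composition ratio
#'
#' Defined as `q_count / a_count` when both counts are positive and
#' undefined (`NA`) otherwise — a domain lacking one of the runs (e.g. the
#' chondrichthyan polyA-only proto-domain) has no ratio. Full precision is
#' kept internally; report tables round to 2 decimals.
#'
#' @param q_count,a_count Non-negative integer residue counts.
#' @return A real, or `NA_real_` when undefined.
#' @export
#' @examples
#' qa_ratio(31, 5)  # 6.2
#' qa_ratio(7, 16)  # 0.4375, printed 0.44 in reports
qa_ratio <- function(q_count, a_count) {
  stopifnot(length(q_count) == 1L, length(a_count) == 1L)
  if (is.na(q_count) || is.na(a_count) || q_count < 0 || a_count < 0) {
    stop("repeat counts must be non-negative numbers")
  }
  if (q_count > 0 && a_count > 0) q_count / a_count else NA_real_
}

#' Codon-level repeat purity
#'
#' Purity of a homopolymeric run's codons: the fraction occupied by the
#' modal codon. `CAG CAG CAG CAG` scores 1.0; the alternating low-purity
#' `CAG CAA CAG CAA` scores 0.5. High-purity repeats are the ones prone to
#' replication slippage.
#'
#' @param codons Character vector of codons (length >= 1, each 3 nt).
#' @return Purity in \[0, 1\].
#' @export
#' @examples
#' codon_purity(c("CAG", "CAG", "CAG", "CAG"))
#' codon_purity(c("CAG", "CAA", "CAG", "CAA"))
codon_purity <- function(codons) {
  if (length(codons) < 1) stop("need at least one codon")
  codons <- toupper(codons)
  if (any(nchar(codons) != 3)) stop("codons must be 3 nucleotides each")
  as.numeric(max(table(codons)) / length(codons))
}

# Codons underlying the counted (residue-matching) positions of a run.
# Validates the CDS pairing: length must be 3x the protein and each codon
# must translate to the run residue.
run_codons <- function(region, run, cds_seq, id = region$id) {
  if (is.null(run)) return(NULL)
  if (nchar(cds_seq) != 3L * nchar(region$seq)) {
    stop("CDS length does not match protein length for record '", id, "'")
  }
  off <- run$start:(run$end - 1L)
  ch <- substring(region$inner_seq, off + 1L, off + 1L)
  p0 <- region$inner_start + off[ch == run$residue]   # 0-based protein pos
  codons <- substring(cds_seq, 3L * p0 + 1L, 3L * p0 + 3L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (any(is.na(aa)) || any(aa != run$residue)) {
    stop("CDS does not translate to the protein run for record '", id, "'")
  }
  codons
}

#' Assemble a QA domain from an anchored region
#'
#' Chooses the highest-count Q run (ties to the earlier run), then the
#' highest-count A run starting at or after the Q run's end — QA order is
#' invariant in every repeat structure observed, so the polyA is always
#' sought downstream of the polyQ; only when no Q run exists is the global
#' best A run taken. The spacer is the residue stretch strictly between
#' the chosen runs (a single glutamic acid in mammals).
#'
#' @param region An `anchored_region` from [extract_qa_region()]. An
#'   `anchor_not_found` object is passed through unchanged.
#' @param config A [qa_config()] supplying the run-detection thresholds.
#' @param cds_seq Optional in-frame CDS string paired with the protein;
#'   when supplied, codon purities of the chosen runs are computed.
#' @return A `qa_domain`: `id`, `taxon`, `clade`, `n_hit`, `c_hit`,
#'   `inner_seq`, `q_run`, `a_run` (either may be `NULL`), `spacer`,
#'   `q_count`, `a_count`, `ratio` (`NA` when undefined), `purity_q`,
#'   `purity_a` (`NA` without CDS or run).
#' @export
assemble_domain <- function(region, config = qa_config(), cds_seq = NULL) {
  if (inherits(region, "anchor_not_found")) return(region)
  stopifnot(inherits(region, "anchored_region"))
  inner <- region$inner_seq
  qruns <- detect_run(inner, "Q", config$min_seed, config$max_gap,
                      config$max_interrupt_frac)
  aruns <- detect_run(inner, "A", config$min_seed, config$max_gap,
                      config$max_interrupt_frac)
  pick <- function(runs) {
    if (!length(runs)) return(NULL)
    counts <- vapply(runs, `[[`, integer(1), "count")
    runs[[which.max(counts)]]   # runs sorted by start: earliest wins ties
  }
  q_run <- pick(qruns)
  a_pool <- if (!is.null(q_run)) {
    Filter(function(r) r$start >= q_run$end, aruns)
  } else {
    aruns
  }
  a_run <- pick(a_pool)
  q_count <- if (is.null(q_run)) 0L else q_run$count
  a_count <- if (is.null(a_run)) 0L else a_run$count
  spacer <- if (!is.null(q_run) && !is.null(a_run)) {
    substr(inner, q_run$end + 1L, a_run$start)
  } else {
    ""
  }
  purity_q <- purity_a <- NA_real_
  if (!is.null(cds_seq)) {
    if (!is.null(q_run)) purity_q <- codon_purity(run_codons(region, q_run, cds_seq))
    if (!is.null(a_run)) purity_a <- codon_purity(run_codons(region, a_run, cds_seq))
  }
  structure(list(id = region$id, taxon = region$taxon, clade = region$clade,
                 n_hit = region$n_hit, c_hit = region$c_hit,
                 inner_seq = inner, inner_start = region$inner_start,
                 seq = region$seq,
                 q_run = q_run, a_run = a_run, spacer = spacer,
                 q_count = q_count, a_count = a_count,
                 ratio = qa_ratio(q_count, a_count),
                 purity_q = purity_q, purity_a = purity_a),
            class = "qa_domain")
}

#' @export
print.qa_domain <- function(x, ...) {
  cat(sprintf("QA domain [%s]: %d Q : %d A, ratio %s, spacer '%s'\n",
              x$id %||% "?", x$q_count, x$a_count,
              ifelse(is.na(x$ratio), "NA", format(round(x$ratio, 2))),
              x$spacer))
  invisible(x)
}
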