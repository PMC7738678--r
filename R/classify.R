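# Two-stage repeat-state classification.
#
# Per sequence: ABSENT (no anchors) < PROTO (flanks only) < PRIMITIVE
# (both runs present but short or interrupted) < candidate-VARIABLE (long,
# uninterrupted runs). "Variable length" is intrinsically a clade-level
# property — one sequence cannot show between-species length variation —
# so candidate-VARIABLE is only confirmed at the clade stage, when the
# clade's Q or A count range spans at least var_min_span; otherwise the
# clade is demoted to PRIMITIVE (e.g. galliforms, whose high 6.0 Q:A ratio
# is conserved across the order).

#' Classify one sequence's repeat state
#'
#' @param x A `qa_domain` or `anchor_not_found` object.
#' @param short_run_max Runs of this many residues or fewer count as
#'   "short" (default 5: the longest composition treated as
#'   primitive-range, the caecilian 2 Q:3-5 A domain, fits under it, while
#'   interrupted anuran tracts reach PRIMITIVE via the interruption gate).
#' @return One of `repeat_classes()`. `"VARIABLE"` here means
#'   candidate-VARIABLE, pending clade-level confirmation by
#'   [classify_clade()].
#' @export
classify_sequence <- function(x, short_run_max = 5L) {
  if (inherits(x, "anchor_not_found")) return("ABSENT")
  stopifnot(inherits(x, "qa_domain"))
  if (is.null(x$q_run) || is.null(x$a_run)) return("PROTO")
  short <- x$q_count <= short_run_max || x$a_count <= short_run_max
  interrupted <- run_interrupted(x$q_run) || run_interrupted(x$a_run)
  if (short || interrupted) "PRIMITIVE" else "VARIABLE"
}

#' Summarize and classify a clade
#'
#' The clade class is the maximum member class, except that
#' candidate-VARIABLE must be confirmed by between-member length variation:
#' the Q-count or A-count range must span at least `var_min_span`. A
#' single-member clade keeps candidate-VARIABLE by convention but is
#' flagged low-confidence.
#'
#' @param members Data frame with columns `class`, `q_count`, `a_count`
#'   (counts may be `NA` for ABSENT members), one row per sequence.
#' @param clade Display name for the clade.
#' @param var_min_span Minimum count-range span confirming VARIABLE
#'   (default 2).
#' @return A `clade_summary`: `clade`, `n`, `clade_class`, `q_range`,
#'   `a_range`, `ratio_range` (each `c(NA, NA)` when no member carries the
#'   run), `demoted` (candidate-VARIABLE demoted to PRIMITIVE for lack of
#'   span), `low_confidence` (n = 1 VARIABLE convention).
#' @export
classify_clade <- function(members, clade = NA_character_, var_min_span = 2L) {
  if (!is.data.frame(members) || nrow(members) == 0) {
    stop("empty clade: at least one member required")
  }
  stopifnot(all(c("class", "q_count", "a_count") %in% names(members)))
  top <- REPEAT_CLASSES[max(class_rank(members$class))]
  qv <- members$q_count[!is.na(members$q_count) & members$q_count > 0]
  av <- members$a_count[!is.na(members$a_count) & members$a_count > 0]
  both <- !is.na(members$q_count) & !is.na(members$a_count) &
    members$q_count > 0 & members$a_count > 0
  rv <- members$q_count[both] / members$a_count[both]
  demoted <- FALSE
  low_confidence <- FALSE
  if (top == "VARIABLE") {
    if (nrow(members) == 1) {
      low_confidence <- TRUE
    } else {
      span_q <- if (length(qv)) diff(range(qv)) else 0
      span_a <- if (length(av)) diff(range(av)) else 0
      if (max(span_q, span_a) < var_min_span) {
        top <- "PRIMITIVE"
        demoted <- TRUE
      }
    }
  }
  rng <- function(v) if (length(v)) range(v) else c(NA_real_, NA_real_)
  structure(list(clade = clade, n = nrow(members), clade_class = top,
                 q_range = rng(qv), a_range = rng(av), ratio_range = rng(rv),
                 demoted = demoted, low_confidence = low_confidence),
            class = "clade_summary")
}

#' Per-sequence classification table
#'
#' @param domains List of `qa_domain` / `anchor_not_found` objects (one per
#'   input record, as produced by [profile_records()]).
#' @param config A [qa_config()].
#' @return Data frame with columns `id`, `taxon`, `clade`, `q_count`,
#'   `a_count`, `ratio`, `interrupted`, `class`; `NA` counts for ABSENT
#'   rows, one row per input domain.
#' @export
classify_table <- function(domains, config = qa_config()) {
  rows <- lapply(domains, function(d) {
    cls <- classify_sequence(d, short_run_max = config$short_run_max)
    if (inherits(d, "anchor_not_found")) {
      data.frame(id = d$id %||% NA_character_,
                 taxon = d$taxon %||% NA_character_,
                 clade = d$clade %||% NA_character_,
                 q_count = NA_integer_, a_count = NA_integer_,
                 ratio = NA_real_, interrupted = NA, class = cls,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = d$id %||% NA_character_,
                 taxon = d$taxon %||% NA_character_,
                 clade = d$clade %||% NA_character_,
                 q_count = d$q_count, a_count = d$a_count,
                 ratio = d$ratio,
                 interrupted = run_interrupted(d$q_run) ||
                   run_interrupted(d$a_run),
                 class = cls, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clade summaries over a classification table
#'
#' @param class_table Output of [classify_table()].
#' @param var_min_span See [classify_clade()].
#' @return Data frame, one row per clade: `clade`, `n`, `class`, count and
#'   ratio ranges, `demoted`, `low_confidence`. Rows without a clade label
#'   are grouped under `"unassigned"`.
#' @export
summarize_clades <- function(class_table, var_min_span = 2L) {
  cl <- ifelse(is.na(class_table$clade), "unassigned", class_table$clade)
  out <- lapply(unique(cl), function(g) {
    s <- classify_clade(class_table[cl == g, , drop = FALSE], clade = g,
                        var_min_span = var_min_span)
    data.frame(clade = s$clade, n = s$n, class = s$clade_class,
               q_min = s$q_range[1], q_max = s$q_range[2],
               a_min = s$a_range[1], a_max = s$a_range[2],
               ratio_min = round(s$ratio_range[1], 2),
               ratio_max = round(s$ratio_range[2], 2),
               demoted = s$demoted, low_confidence = s$low_confidence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.clade_summary <- function(x, ...) {
  cat(sprintf("Clade %s (n=%d): %s%s | Q %s-%s, A %s-%s\n",
              x$clade, x$n, x$clade_class,
              if (x$demoted) " (demoted)" else if (x$low_confidence) " (low confidence)" else "",
              x$q_range[1], x$q_range[2], x$a_range[1], x$a_range[2]))
  invisible(x)
}
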