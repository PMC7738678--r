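# End-to-end composition of the pipeline stages
# (extract -> profile -> classify -> map -> regress) plus the validated
# configuration bundle every stage reads its thresholds from.

#' Pipeline configuration
#'
#' All tunable thresholds in one validated bundle. Unknown keys are
#' rejected by name; every value is range-checked.
#'
#' Fields: `n_motif`/`c_motif` (flank motifs, default MSDVS/VPRLR),
#' `max_mismatch` (Hamming budget per flank, default 2), `window` (motif
#' search restricted to the first K residues, default 120), `min_seed`,
#' `max_gap`, `max_interrupt_frac` (run detection), `short_run_max`
#' (classification short-run gate, default 5), `var_min_span` (clade-level
#' VARIABLE confirmation span, default 2), `ordered` (parsimony mode),
#' `leaf_age_tol` (tip-age snap tolerance in Ma).
#'
#' @param ... Named overrides of the defaults above.
#' @return A validated `qa_config` list.
#' @export
#' @examples
#' qa_config(max_mismatch = 1)
qa_config <- function(...) {
  defaults <- list(n_motif = "MSDVS", c_motif = "VPRLR",
                   max_mismatch = 2L, window = 120L,
                   min_seed = 2L, max_gap = 1L, max_interrupt_frac = 0.34,
                   short_run_max = 5L, var_min_span = 2L,
                   ordered = FALSE, leaf_age_tol = 0.5)
  user <- list(...)
  if (length(user) && (is.null(names(user)) || any(!nzchar(names(user))))) {
    stop("all config entries must be named")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  stopifnot(nchar(cfg$n_motif) >= 3, nchar(cfg$c_motif) >= 3)
  if (cfg$max_mismatch < 0 ||
      cfg$max_mismatch >= min(nchar(cfg$n_motif), nchar(cfg$c_motif))) {
    stop("max_mismatch must be in [0, motif length)")
  }
  if (cfg$window < nchar(cfg$n_motif) + nchar(cfg$c_motif)) {
    stop("window too small to hold both motifs")
  }
  if (cfg$min_seed < 2) stop("min_seed must be >= 2")
  if (cfg$max_gap < 0) stop("max_gap must be >= 0")
  if (cfg$max_interrupt_frac < 0 || cfg$max_interrupt_frac > 1) {
    stop("max_interrupt_frac must be in [0, 1]")
  }
  if (cfg$short_run_max < 0) stop("short_run_max must be >= 0")
  if (cfg$var_min_span < 0) stop("var_min_span must be >= 0")
  stopifnot(is.logical(cfg$ordered), length(cfg$ordered) == 1)
  if (cfg$leaf_age_tol < 0) stop("leaf_age_tol must be >= 0")
  structure(cfg, class = "qa_config")
}

#' Profile every protein record into a QA domain
#'
#' Runs [extract_qa_region()] then [assemble_domain()] on each record,
#' pairing CDS sequences by id when available.
#'
#' @param records Protein records data frame (see
#'   [read_protein_fasta()]).
#' @param cds Optional CDS data frame (see [read_coding_fasta()]).
#' @param config A [qa_config()].
#' @return Named list (by record id) of `qa_domain` /
#'   `anchor_not_found` objects, input order preserved.
#' @export
profile_records <- function(records, cds = NULL, config = qa_config()) {
  stopifnot(is.data.frame(records))
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- as.list(records[i, , drop = FALSE])
    region <- extract_qa_region(rec, config)
    cds_seq <- if (!is.null(cds)) {
      j <- match(rec$id, cds$id)
      if (is.na(j)) NULL else cds$cds[j]
    }
    assemble_domain(region, config, cds_seq = cds_seq)
  })
  names(out) <- records$id
  out
}

#' Map repeat classes onto a dated tree
#'
#' Tip labels are reconciled against the classification table in order:
#' record id, then taxon name, then clade label (which maps the tip to the
#' clade-level class from [summarize_clades()]). Unmatched tips are listed
#' in a reconciliation message and dropped, not a crash.
#'
#' @param tree A `dated_tree`.
#' @param class_table Output of [classify_table()].
#' @param clade_summary Optional output of [summarize_clades()] for
#'   clade-label tips.
#' @param config A [qa_config()] (`ordered` selects the parsimony mode).
#' @return List with `report` ([fitch_reconstruct()] output), `ages`
#'   ([emergence_ages()] table) and `dropped` (unmatched tip labels).
#' @export
map_emergence <- function(tree, class_table, clade_summary = NULL,
                          config = qa_config()) {
  stopifnot(inherits(tree, "dated_tree"))
  tips <- tree$phylo$tip.label
  state <- rep(NA_character_, length(tips))
  j <- match(tips, class_table$id)
  state[!is.na(j)] <- class_table$class[j[!is.na(j)]]
  k <- is.na(state)
  j <- match(tips[k], class_table$taxon)
  state[k][!is.na(j)] <- class_table$class[j[!is.na(j)]]
  if (!is.null(clade_summary)) {
    k <- is.na(state)
    j <- match(tips[k], clade_summary$clade)
    state[k][!is.na(j)] <- clade_summary$class[j[!is.na(j)]]
  }
  dropped <- tips[is.na(state)]
  if (length(dropped)) {
    message("tip(s) without matching records, dropped: ",
            paste(dropped, collapse = ", "))
    if (length(dropped) == length(tips)) {
      stop("no tree tip could be matched to the classified records")
    }
    state_map <- setNames(state, tips)
    phy <- ape::drop.tip(tree$phylo, dropped)
    tree <- as_dated_tree(phy, leaf_age_tol = config$leaf_age_tol)
    tips <- phy$tip.label
    state <- unname(state_map[tips])   # drop.tip may reorder tips
  }
  report <- fitch_reconstruct(tree, setNames(state, tips),
                              ordered = config$ordered)
  list(report = report, ages = emergence_ages(report), dropped = dropped)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' extract -> profile -> classify (always), then map (when a tree is
#' given) and regress (when traits are given). Each stage's table is
#' written before the next begins; any stage error aborts naming the
#' failing stage. Reruns with identical inputs and config produce
#' byte-identical outputs (the pipeline itself draws no random numbers).
#'
#' @param fasta Protein FASTA path.
#' @param out_dir Output directory (created if needed).
#' @param cds Optional CDS FASTA path.
#' @param tree Optional Newick path (single rooted dated tree).
#' @param traits Optional trait TSV path.
#' @param trait_name Trait column to regress (required with `traits`).
#' @param config A [qa_config()].
#' @return Invisibly, a list with the stage tables (`domains`, `classes`,
#'   `clades`, and `emergence` / `regression` when computed) and `paths`
#'   of the written files (`domains.tsv`, `classes.tsv`,
#'   `clade_summary.tsv`, `emergence.tsv`, `regression.tsv`,
#'   `pipeline.log`).
#' @export
run_pipeline <- function(fasta, out_dir, cds = NULL, tree = NULL,
                         traits = NULL, trait_name = NULL,
                         config = qa_config()) {
  stopifnot(inherits(config, "qa_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_txt <- paste(deparse(unclass(config)), collapse = " ")
  tf <- tempfile()
  writeLines(cfg_txt, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  log <- c(sprintf("runxqa %s", as.character(utils::packageVersion("runxqa"))),
           sprintf("config_md5 %s", cfg_hash))

  records <- stage("read", read_protein_fasta(fasta))
  log <- c(log, sprintf("read %d records", nrow(records)))
  cds_df <- if (!is.null(cds)) stage("read_cds", read_coding_fasta(cds))

  domains <- stage("profile", profile_records(records, cds_df, config))
  dtab <- stage("profile",
                write_domain_table(domains, file.path(out_dir, "domains.tsv"),
                                   config))
  log <- c(log, sprintf("profile %d domains (%d anchored)", length(domains),
                        sum(!vapply(domains, inherits, logical(1),
                                    "anchor_not_found"))))

  ctab <- stage("classify", classify_table(domains, config))
  write_tsv(ctab, file.path(out_dir, "classes.tsv"))
  clades <- stage("classify", summarize_clades(ctab, config$var_min_span))
  write_tsv(clades, file.path(out_dir, "clade_summary.tsv"))
  log <- c(log, sprintf("classify %d sequences into %d clades",
                        nrow(ctab), nrow(clades)))

  out <- list(domains = dtab, classes = ctab, clades = clades)
  if (!is.null(tree)) {
    dt <- stage("map", read_newick(tree, config$leaf_age_tol))
    em <- stage("map", map_emergence(dt, ctab, clades, config))
    write_tsv(em$ages, file.path(out_dir, "emergence.tsv"))
    log <- c(log, sprintf("map %d origins, %s changes, %d tips dropped",
                          nrow(em$report$origins), format(em$report$changes),
                          length(em$dropped)))
    out$emergence <- em
  }
  if (!is.null(traits)) {
    if (is.null(trait_name)) stop("trait_name is required with traits")
    tt <- stage("regress", read_trait_table(traits))
    ratios <- setNames(ctab$ratio, ctab$taxon)
    rr <- stage("regress", correlate(ratios, tt, trait_name))
    rtab <- data.frame(trait = rr$trait, n = rr$n, slope = rr$slope,
                       intercept = rr$intercept, r2 = rr$r2,
                       sign = rr$sign, p = rr$p,
                       phylo_naive = rr$phylo_naive,
                       stringsAsFactors = FALSE)
    write_tsv(rtab, file.path(out_dir, "regression.tsv"))
    log <- c(log, sprintf("regress %s on %d taxa (r2 %.3f)", rr$trait,
                          rr$n, rr$r2))
    out$regression <- rr
  }
  writeLines(log, file.path(out_dir, "pipeline.log"))
  out$paths <- file.path(out_dir, c("domains.tsv", "classes.tsv",
                                    "clade_summary.tsv", "pipeline.log"))
  invisible(out)
}
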