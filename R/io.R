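# Readers and writers: FASTA (via Biostrings), Newick (via ape), TSV tables.
# All coordinates inside the package are 0-based half-open; they are
# converted to 1-based only at report boundaries.

#' Read protein sequences with clade-annotated FASTA headers
#'
#' Headers follow the dialect `>id|clade|taxon`; fields beyond the third are
#' ignored, and missing fields default to `NA` (clade) or the id (taxon).
#' Sequences must use the 20-letter amino-acid alphabet plus `X` for
#' assembly-gap ambiguity; any other character is rejected with its
#' position. Duplicate ids are a hard error.
#'
#' @param path Path to a protein FASTA file.
#' @param delim Header field delimiter (default `"|"`).
#' @return A `data.frame` with columns `id`, `taxon`, `clade`, `seq`,
#'   one row per FASTA entry, input order preserved.
#' @export
read_protein_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    warning("no FASTA records in ", path)
    return(data.frame(id = character(), taxon = character(),
                      clade = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  aa <- Biostrings::readAAStringSet(path)
  hdr <- strsplit(names(aa), delim, fixed = TRUE)
  id <- trimws(vapply(hdr, `[`, character(1), 1L))
  clade <- vapply(hdr, function(h) {
    if (length(h) >= 2 && nzchar(trimws(h[2]))) trimws(h[2]) else NA_character_
  }, character(1))
  taxon <- vapply(hdr, function(h) {
    if (length(h) >= 3 && nzchar(trimws(h[3]))) trimws(h[3]) else NA_character_
  }, character(1))
  taxon <- ifelse(is.na(taxon), id, taxon)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(seqs)], collapse = ", "))
  }
  pat <- sprintf("[^%sX]", paste(AA_ALPHABET20, collapse = ""))
  bad <- regexpr(pat, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal residue '%s' at position %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], id[i]))
  }
  data.frame(id = id, taxon = taxon, clade = clade, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Inverse of [read_protein_fasta()]: headers are rebuilt as
#' `id|clade|taxon` (bare `id` when no clade/taxon annotation exists), so a
#' write/read round trip preserves id/seq pairs exactly.
#'
#' @param records Data frame with columns `id`, `seq` and optionally
#'   `taxon`, `clade`.
#' @param path Output path.
#' @param delim Header field delimiter.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path, delim = "|") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  taxon <- if ("taxon" %in% names(records)) records$taxon else records$id
  clade <- if ("clade" %in% names(records)) records$clade else NA_character_
  hdr <- ifelse(is.na(clade) & taxon == records$id,
                records$id,
                paste(records$id, ifelse(is.na(clade), "", clade), taxon,
                      sep = delim))
  xs <- Biostrings::AAStringSet(setNames(records$seq, hdr))
  Biostrings::writeXStringSet(xs, filepath = path, width = 70L)
  invisible(path)
}

#' Read in-frame CDS nucleotide sequences
#'
#' Each entry must pair with a protein record by id (first header field),
#' have length divisible by 3, and use the alphabet ACGTN.
#'
#' @inheritParams read_protein_fasta
#' @return A `data.frame` with columns `id`, `cds`.
#' @export
read_coding_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^>", raw))) {
    warning("no FASTA records in ", path)
    return(data.frame(id = character(), cds = character(),
                      stringsAsFactors = FALSE))
  }
  dna <- Biostrings::readDNAStringSet(path)
  id <- trimws(vapply(strsplit(names(dna), delim, fixed = TRUE),
                      `[`, character(1), 1L))
  dup <- unique(id[duplicated(id)])
  if (length(dup)) stop("duplicate CDS id(s): ", paste(dup, collapse = ", "))
  cds <- toupper(as.character(dna))
  bad <- regexpr("[^ACGTN]", cds)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal nucleotide '%s' at position %d of record '%s'",
                 substr(cds[i], bad[i], bad[i]), bad[i], id[i]))
  }
  off <- nchar(cds) %% 3 != 0
  if (any(off)) {
    stop("CDS length not divisible by 3 for record(s): ",
         paste(id[off], collapse = ", "))
  }
  data.frame(id = id, cds = unname(cds), stringsAsFactors = FALSE)
}

#' Read a taxon-trait table
#'
#' Long-format TSV with columns `taxon`, `trait`, `value` (`.` decimal
#' separator). Taxon ids must be unique within each trait and values finite.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with columns `taxon`, `trait`, `value`.
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trait table missing column(s): ", paste(miss, collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) stop("non-finite trait value(s) in ", path)
  key <- paste(df$trait, df$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate taxon within a trait: ",
         paste(unique(df$taxon[duplicated(key)]), collapse = ", "))
  }
  df[need]
}

#' Annotate a rooted phylogeny with node ages
#'
#' Branch lengths are read as durations in Ma; a node's age is the maximum
#' root-to-tip path length minus its depth, so the root carries the oldest
#' age and every child is younger than its parent. Trees need not be
#' ultrametric; tip ages within `leaf_age_tol` of zero are snapped to zero
#' to absorb rounding in published branch lengths.
#'
#' @param phy An `ape::phylo` object with branch lengths; the outermost
#'   node is treated as the root, so basal polytomies are preserved.
#' @param leaf_age_tol Tip ages below this (Ma) are set to 0 (default 0.5).
#' @return A `dated_tree`: list with elements `phylo`, `ages` (node-indexed,
#'   tips first as in `ape`), `root_age`, `ntip`, `root`.
#' @export
as_dated_tree <- function(phy, leaf_age_tol = 0.5) {
  stopifnot(inherits(phy, "phylo"))
  # the outermost Newick node is taken as the root; basal polytomies are
  # legitimate (ape::is.rooted would reject them as "unrooted")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch length(s) in tree")
  depths <- ape::node.depth.edgelength(phy)
  root_age <- max(depths)
  ages <- root_age - depths
  ntip <- length(phy$tip.label)
  tip_ix <- seq_len(ntip)
  ages[tip_ix][ages[tip_ix] < leaf_age_tol] <- 0
  structure(list(phylo = phy, ages = ages, root_age = root_age,
                 ntip = ntip, root = ntip + 1L),
            class = "dated_tree")
}

#' Read a single rooted dated tree from a Newick file
#'
#' @param path Path to a Newick file containing exactly one rooted tree.
#' @inheritParams as_dated_tree
#' @return A `dated_tree` (see [as_dated_tree()]).
#' @export
read_newick <- function(path, leaf_age_tol = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse a tree from ", path)
  if (inherits(tr, "multiPhylo")) {
    stop("expected a single tree in ", path, ", found ", length(tr))
  }
  as_dated_tree(tr, leaf_age_tol = leaf_age_tol)
}

# Compact text encoding of a run's interruptions, e.g. "Q+2H;Q+6P".
encode_interruptions <- function(run) {
  if (is.null(run) || nrow(run$interruptions) == 0) return(character(0))
  sprintf("%s+%d%s", run$residue, run$interruptions$offset,
          run$interruptions$residue)
}

#' Tabulate analyzed QA domains
#'
#' Flattens a list of [assemble_domain()] / anchor-not-found results into the
#' per-species report table: one row per input record with columns `id`,
#' `taxon`, `clade`, `q_count`, `a_count`, `spacer`, `ratio` (2-decimal,
#' `NA` when undefined), `class`, `interruptions`, `motif_mismatches`.
#'
#' @param domains List of `qa_domain` and/or `anchor_not_found` objects.
#' @param config A [qa_config()] supplying the classification thresholds.
#' @return A `data.frame` in deterministic column order.
#' @export
domain_table <- function(domains, config = qa_config()) {
  rows <- lapply(domains, function(d) {
    cls <- classify_sequence(d, short_run_max = config$short_run_max)
    if (inherits(d, "anchor_not_found")) {
      data.frame(id = d$id %||% NA_character_, taxon = d$taxon %||% NA_character_,
                 clade = d$clade %||% NA_character_,
                 q_count = NA_integer_, a_count = NA_integer_,
                 spacer = NA_character_, ratio = NA_real_, class = cls,
                 interruptions = NA_character_,
                 motif_mismatches = NA_character_, stringsAsFactors = FALSE)
    } else {
      ints <- c(encode_interruptions(d$q_run), encode_interruptions(d$a_run))
      data.frame(id = d$id %||% NA_character_, taxon = d$taxon %||% NA_character_,
                 clade = d$clade %||% NA_character_,
                 q_count = d$q_count, a_count = d$a_count,
                 spacer = d$spacer, ratio = round(d$ratio, 2), class = cls,
                 interruptions = paste(ints, collapse = ";"),
                 motif_mismatches = sprintf("%d,%d", d$n_hit$mismatches,
                                            d$c_hit$mismatches),
                 stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- data.frame(id = character(), taxon = character(),
                      clade = character(), q_count = integer(),
                      a_count = integer(), spacer = character(),
                      ratio = numeric(), class = character(),
                      interruptions = character(),
                      motif_mismatches = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write the QA domain table to TSV
#'
#' @inheritParams domain_table
#' @param path Output TSV path. Missing ratios are written as `NA`.
#' @return The table, invisibly.
#' @export
write_domain_table <- function(domains, path, config = qa_config()) {
  tab <- if (is.data.frame(domains)) domains else domain_table(domains, config)
  write_tsv(tab, path)
  invisible(tab)
}

# deterministic TSV writer shared by all reports
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
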