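# Synthetic-data generator. Emulates the clade-typical QA repeat
# compositions tabulated across vertebrates (run length ranges,
# interruption residues, the single-residue spacer, conserved-but-mutable
# MSDVS/VPRLR flanks, codon composition of varying purity), so every
# pipeline stage is testable without sequence downloads. Also a toy
# replication-slippage simulator along a dated tree; the paper trail for
# slippage is direction-of-effect only, so all its rates are placeholders
# for sensitivity analysis, not estimates.

# residues safe for leader/tail padding: no Q or A (would seed spurious
# runs) and no D or V (keeps random MSDVS-like decoys out of reach of the
# 2-mismatch anchor budget)
PAD_ALPHABET <- c("G", "S", "T", "N", "E", "R", "K", "L", "I", "F",
                  "P", "H", "W", "Y", "C", "M")

# preferred (modal) codon per residue where it matters; others fall back
# to the alphabetically first synonymous codon
MODAL_CODON <- c(Q = "CAG", A = "GCC", E = "GAG")

synonym_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), unname(gc))
  syn <- lapply(syn, sort)
  for (res in names(MODAL_CODON)) {
    s <- syn[[res]]
    syn[[res]] <- c(MODAL_CODON[[res]], setdiff(s, MODAL_CODON[[res]]))
  }
  syn
}

#' Build a clade preset for the synthetic generator
#'
#' A parameter bundle matching one clade's printed repeat composition. Run
#' lengths are drawn uniformly from the closed integer ranges; interruption
#' residues are inserted between run positions with the given per-position
#' probability (never inside the first `min_seed` positions and capped at
#' half the run length, so generated runs always stay detectable under the
#' default detection thresholds); flanks receive at most 2 substitutions
#' each ("mostly conserved"); CDS codons use the modal codon with
#' probability `purity` and a synonymous alternative otherwise.
#'
#' @param name Preset/clade label.
#' @param q_len_range,a_len_range Integer pairs in \[0, 40\].
#' @param interruption_prob Per-eligible-position insertion probability.
#' @param interruption_alphabet Residues interruptions are drawn from.
#' @param spacer Residue(s) between the runs (single glutamic acid by
#'   default).
#' @param flank_mutation_prob Per-position flank substitution probability.
#' @param purity Modal-codon probability in (0, 1].
#' @param intended_class The repeat class the preset is built to produce
#'   at clade level.
#' @return A `clade_preset`.
#' @export
clade_preset <- function(name, q_len_range, a_len_range,
                         interruption_prob = 0,
                         interruption_alphabet = c("H", "A", "P", "S"),
                         spacer = "E", flank_mutation_prob = 0.05,
                         purity = 0.95, intended_class = NA_character_) {
  stopifnot(length(q_len_range) == 2, length(a_len_range) == 2)
  if (q_len_range[1] > q_len_range[2] || a_len_range[1] > a_len_range[2]) {
    stop("impossible preset '", name, "': empty length range")
  }
  if (any(c(q_len_range, a_len_range) < 0) ||
      any(c(q_len_range, a_len_range) > 40)) {
    stop("run length ranges must lie within [0, 40]")
  }
  stopifnot(interruption_prob >= 0, interruption_prob <= 1,
            flank_mutation_prob >= 0, flank_mutation_prob <= 1,
            purity > 0, purity <= 1)
  structure(list(name = name,
                 q_len_range = as.integer(q_len_range),
                 a_len_range = as.integer(a_len_range),
                 interruption_prob = interruption_prob,
                 interruption_alphabet = interruption_alphabet,
                 spacer = spacer,
                 flank_mutation_prob = flank_mutation_prob,
                 purity = purity,
                 intended_class = intended_class),
            class = "clade_preset")
}

#' Built-in clade presets
#'
#' Transcribed from the printed per-clade compositions: chondrichthyans
#' (flanks plus a short polyA, no polyQ), teleosts (short polyQ and polyA),
#' caecilians (2 Q:3-5 A), anurans (6-10 Q:2 A with proline
#' interruptions), squamate snakes (12-21 Q, A range 4-6 implied by the
#' printed Q:A ratio range 2.0-5.25), anoles (10-27 Q:4-6 A with H/A/P/S
#' interruptions), galliforms (conserved ratio 6.0, realized as 18 Q:3 A),
#' marsupials (16-24 Q:19-22 A) and eutherians (7-31 Q:4-19 A).
#'
#' @return Named list of `clade_preset` objects.
#' @export
clade_presets <- function() {
  list(
    chondrichthyan = clade_preset("chondrichthyan", c(0, 0), c(2, 4),
                                  spacer = "", purity = 0.9,
                                  intended_class = "PROTO"),
    teleost = clade_preset("teleost", c(2, 4), c(2, 4), purity = 0.8,
                           intended_class = "PRIMITIVE"),
    caecilian = clade_preset("caecilian", c(2, 2), c(3, 5), purity = 0.9,
                             intended_class = "PRIMITIVE"),
    anuran = clade_preset("anuran", c(6, 10), c(2, 2),
                          interruption_prob = 0.15,
                          interruption_alphabet = "P", purity = 0.9,
                          intended_class = "PRIMITIVE"),
    squamate = clade_preset("squamate", c(12, 21), c(4, 6), purity = 0.95,
                            intended_class = "VARIABLE"),
    anolis = clade_preset("anolis", c(10, 27), c(4, 6),
                          interruption_prob = 0.10,
                          interruption_alphabet = c("H", "A", "P", "S"),
                          purity = 0.95, intended_class = "VARIABLE"),
    galliform = clade_preset("galliform", c(18, 18), c(3, 3), purity = 1.0,
                             intended_class = "PRIMITIVE"),
    marsupial = clade_preset("marsupial", c(16, 24), c(19, 22),
                             purity = 0.95, intended_class = "VARIABLE"),
    eutherian = clade_preset("eutherian", c(7, 31), c(4, 19), purity = 0.95,
                             intended_class = "VARIABLE")
  )
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
}

# run residues with interruptions inserted between internal positions;
# returns list(chars, in_run flag per char)
build_run_chars <- function(residue, len, preset, min_seed = 2L) {
  if (len == 0) return(list(chars = character(0), in_run = logical(0)))
  chars <- rep(residue, len)
  in_run <- rep(TRUE, len)
  # eligible insertion points: after position j for j in min_seed..len-1,
  # keeping the leading seed intact and the run ends on the residue
  elig <- if (len > min_seed) seq(min_seed, len - 1L) else integer(0)
  if (length(elig) && preset$interruption_prob > 0) {
    pick <- elig[runif(length(elig)) < preset$interruption_prob]
    cap <- max(0L, floor(len / 2))
    if (length(pick) > cap) pick <- pick[seq_len(cap)]
    if (length(pick)) {
      pool <- setdiff(preset$interruption_alphabet, residue)
      if (!length(pool)) pool <- "P"
      ins <- vapply(pick, function(.) sample(pool, 1L), character(1))
      out_chars <- character(0)
      out_flag <- logical(0)
      last <- 0L
      for (k in seq_along(pick)) {
        seg <- (last + 1L):pick[k]
        out_chars <- c(out_chars, chars[seg], ins[k])
        out_flag <- c(out_flag, in_run[seg], FALSE)
        last <- pick[k]
      }
      seg <- (last + 1L):len
      chars <- c(out_chars, chars[seg])
      in_run <- c(out_flag, in_run[seg])
    }
  }
  list(chars = chars, in_run = in_run)
}

mutate_flank <- function(motif, p) {
  ch <- strsplit(motif, "")[[1]]
  k <- sum(runif(length(ch)) < p)
  k <- min(k, 2L)   # flanks stay within the anchoring mismatch budget
  if (k > 0) {
    pos <- sample(seq_along(ch), k)
    for (i in pos) ch[i] <- sample(setdiff(AA_ALPHABET20, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic clade of protein/CDS records
#'
#' Each sequence has the form leader + N-flank + polyQ(+interruptions) +
#' spacer + polyA(+interruptions) + C-flank + tail, with run lengths drawn
#' uniformly from the preset ranges. The paired CDS uses the modal codon
#' with probability `purity` at run positions (alternate synonymous codons
#' otherwise) and modal codons elsewhere. Fully reproducible per seed:
#' identical preset and seed give byte-identical FASTA via
#' [write_protein_fasta()].
#'
#' @param preset A [clade_preset()] (or a name from [clade_presets()]).
#' @param n Number of sequences (>= 1).
#' @param seed Integer seed.
#' @return List with `proteins` (data frame `id`, `taxon`, `clade`,
#'   `seq`), `cds` (data frame `id`, `cds`), `preset`, `seed`.
#' @export
generate_clade <- function(preset, n, seed = 1L) {
  if (is.character(preset)) {
    preset <- clade_presets()[[preset]] %||%
      stop("unknown preset '", preset, "'")
  }
  stopifnot(inherits(preset, "clade_preset"), n >= 1)
  syn <- synonym_table()
  with_seed(seed, {
    rows <- vector("list", n)
    cds_rows <- vector("list", n)
    for (i in seq_len(n)) {
      q_len <- sample_range(preset$q_len_range)
      a_len <- sample_range(preset$a_len_range)
      qb <- build_run_chars("Q", q_len, preset)
      ab <- build_run_chars("A", a_len, preset)
      leader <- c("M", sample(PAD_ALPHABET, 4L + sample(0:3, 1L), replace = TRUE))
      tail <- sample(PAD_ALPHABET, 25L + sample(0:5, 1L), replace = TRUE)
      nflank <- strsplit(mutate_flank("MSDVS", preset$flank_mutation_prob), "")[[1]]
      cflank <- strsplit(mutate_flank("VPRLR", preset$flank_mutation_prob), "")[[1]]
      spacer <- if (q_len > 0 && a_len > 0 && nzchar(preset$spacer)) {
        strsplit(preset$spacer, "")[[1]]
      } else {
        character(0)
      }
      chars <- c(leader, nflank, qb$chars, spacer, ab$chars, cflank, tail)
      in_run <- c(rep(FALSE, length(leader) + length(nflank)), qb$in_run,
                  rep(FALSE, length(spacer)), ab$in_run,
                  rep(FALSE, length(cflank) + length(tail)))
      codons <- vapply(seq_along(chars), function(j) {
        s <- syn[[chars[j]]]
        if (!in_run[j] || length(s) == 1L || runif(1) < preset$purity) {
          s[1]
        } else {
          sample(s[-1], 1L)
        }
      }, character(1))
      id <- sprintf("%s_%03d", preset$name, i)
      rows[[i]] <- data.frame(id = id,
                              taxon = sprintf("%s_sp%03d", preset$name, i),
                              clade = preset$name,
                              seq = paste(chars, collapse = ""),
                              stringsAsFactors = FALSE)
      cds_rows[[i]] <- data.frame(id = id,
                                  cds = paste(codons, collapse = ""),
                                  stringsAsFactors = FALSE)
    }
    list(proteins = do.call(rbind, rows), cds = do.call(rbind, cds_rows),
         preset = preset, seed = seed)
  })
}

#' Slippage simulator parameters
#'
#' A deliberately minimal model of replication slippage: along each branch
#' a Poisson number of events with mean `base_rate * (1 + purity_coupling
#' * purity) * branch_length`; each event expands the run with probability
#' `expansion_bias` (else contracts) by a geometric step of mean
#' `step_mean`, floored at 0 residues. Direction-of-effect only — the
#' literature gives no slippage rates, so these defaults are placeholders
#' for sensitivity analysis.
#'
#' @param base_rate Events per Ma (>= 0).
#' @param expansion_bias Probability an event expands, in (0, 1).
#' @param step_mean Mean step size in repeat units (>= 1).
#' @param purity_coupling Rate multiplier per unit purity (>= 0); high
#'   purity repeats stutter more.
#' @param purity Repeat purity feeding the coupling, in (0, 1].
#' @return A `slippage_params` list.
#' @export
slippage_params <- function(base_rate = 0.02, expansion_bias = 0.5,
                            step_mean = 1, purity_coupling = 0,
                            purity = 1) {
  stopifnot(base_rate >= 0, expansion_bias > 0, expansion_bias <= 1,
            step_mean >= 1, purity_coupling >= 0, purity > 0, purity <= 1)
  structure(list(base_rate = base_rate, expansion_bias = expansion_bias,
                 step_mean = step_mean, purity_coupling = purity_coupling,
                 purity = purity),
            class = "slippage_params")
}

evolve_count <- function(count, len, rate, params) {
  nev <- stats::rpois(1L, rate * len)
  if (nev == 0) return(count)
  for (i in seq_len(nev)) {
    step <- 1L + stats::rgeom(1L, prob = 1 / params$step_mean)
    delta <- if (stats::runif(1L) < params$expansion_bias) step else -step
    count <- max(count + delta, 0L)
  }
  count
}

#' Simulate repeat slippage along a dated tree
#'
#' Root Q and A counts evolve independently down every branch under the
#' model of [slippage_params()]. Reproducible per seed (fixed cladewise
#' edge traversal order).
#'
#' @param tree A `dated_tree` or `ape::phylo` with branch lengths in Ma.
#' @param root_q,root_a Non-negative root repeat counts.
#' @param params A [slippage_params()].
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return Data frame with columns `leaf`, `q_count`, `a_count`.
#' @export
simulate_slippage <- function(tree, root_q, root_a,
                              params = slippage_params(), seed = NULL) {
  if (inherits(tree, "phylo")) tree <- as_dated_tree(tree)
  stopifnot(inherits(tree, "dated_tree"), root_q >= 0, root_a >= 0)
  rate <- params$base_rate * (1 + params$purity_coupling * params$purity)
  phy <- tree$phylo
  ntip <- tree$ntip
  nn <- ntip + phy$Nnode
  with_seed(seed, {
    qc <- ac <- integer(nn)
    qc[tree$root] <- as.integer(root_q)
    ac[tree$root] <- as.integer(root_a)
    # cladewise order visits parents before children
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]
      ch <- phy$edge[e, 2]
      len <- phy$edge.length[e]
      qc[ch] <- evolve_count(qc[p], len, rate, params)
      ac[ch] <- evolve_count(ac[p], len, rate, params)
    }
    data.frame(leaf = phy$tip.label,
               q_count = qc[seq_len(ntip)],
               a_count = ac[seq_len(ntip)],
               stringsAsFactors = FALSE)
  })
}

#' Synthetic trait table with a programmed ratio-trait relationship
#'
#' Builds `value = intercept + slope * ratio + noise` with noise standard
#' deviation `noise_frac` times the signal's standard deviation — the
#' parameter-recovery fixture for [correlate()].
#'
#' @param ratios Named numeric vector, taxon -> QA ratio.
#' @param slope,intercept Linear coefficients.
#' @param noise_frac Noise SD as a fraction of signal SD (0 = exact).
#' @param trait Trait name for the table.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return Trait table data frame (`taxon`, `trait`, `value`).
#' @export
generate_trait_table <- function(ratios, slope = 1, intercept = 0,
                                 noise_frac = 0.25,
                                 trait = "facial_length", seed = NULL) {
  stopifnot(is.numeric(ratios), !is.null(names(ratios)))
  with_seed(seed, {
    signal <- intercept + slope * ratios
    noise_sd <- noise_frac * stats::sd(slope * ratios)
    value <- signal + if (noise_frac > 0) {
      stats::rnorm(length(ratios), 0, noise_sd)
    } else {
      0
    }
    data.frame(taxon = names(ratios), trait = trait, value = unname(value),
               stringsAsFactors = FALSE)
  })
}
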