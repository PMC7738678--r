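---
title: "Methods: annotating and mapping the RUNX2 QA repeat"
author: "runxqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and mapping the RUNX2 QA repeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runxqa)
```

## The biological problem

RUNX2, the master transcription factor of osteogenesis, is the only RUNX
paralog carrying a tandem poly-glutamine/poly-alanine (QA) repeat in its N
terminus. The repeat's length and Q:A ratio tune RUNX2 transactivation, and
within several mammalian orders the QA ratio correlates with facial-shape
metrics — the "tuning knob" picture of coding repeats. Across vertebrates
the repeat shows a progression of states: absent outside gnathostome
RUNX2, a proto-domain (flanks only, a short polyA without polyQ) in
cartilaginous fish, a primitive domain (short or interrupted runs) in bony
fish and amphibians, and a long, uninterrupted, length-variable domain in
amniotes, most extreme in eutherian mammals (7--31 Q : 4--19 A, with the
naked mole-rat at 31 Q : 5 A, ratio 6.2, and the Baiji at 7 Q : 16 A,
ratio 0.44).

`runxqa` operationalizes that comparative procedure as testable code:
anchoring the domain, quantifying run composition, classifying repeat
states, mapping their emergence onto a dated phylogeny, and correlating
composition with traits. A synthetic-sequence generator calibrated to the
published per-clade compositions makes every stage testable without
sequence downloads (no accession list accompanies the published survey).

## Domain anchoring

The QA domain is defined as the region between a conserved N-terminal
`MSDVS` and C-terminal `VPRLR` motif, immediately upstream of the RUNT
domain. Conservation is only approximate — the C flank occurs in the
transposed spelling `VRPLR` — so matching is Hamming-distance based with a
default budget of 2 mismatches per flank (`max_mismatch`). Two is a
declared design choice, not a published threshold: it is the smallest
budget that captures the transposed spelling, and a larger budget starts
admitting random 5-mers. `X` (assembly-gap ambiguity) always counts as a
mismatch, so gapped assemblies degrade gracefully rather than anchoring on
fabricated residues.

The search is restricted to the first `window = 120` residues because the
domain sits at the N terminus; the restriction avoids spurious downstream
hits in full-length proteins. Hit selection is deterministic: the
lowest-mismatch N hit, then the lowest-mismatch C hit downstream of it,
ties broken leftmost, with fallback to the next-best N hit when the best
one has no downstream partner. Sequences without both anchors map to the
`ABSENT` class (as for non-vertebrate runt and cyclostome RunxA/B/C).

All coordinates are 0-based and half-open internally; conversion to
1-based happens only at report boundaries.

## Run detection

PolyQ and polyA tracts are frequently interrupted (histidine, alanine,
proline, serine). A run is defined as a maximal window of the anchored
region that (i) starts and ends on the run residue, (ii) contains at least
one seed of `min_seed = 2` consecutive residues, (iii) has every
interruption stretch no longer than `max_gap = 1`, and (iv) devotes at
most `max_interrupt_frac = 0.34` of its span to interruptions. The
defaults bridge the interrupted anuran (6--10 Q with proline
interruptions) and anole tracts without merging distant runs; all four
knobs are exposed in `qa_config()`.

A subtlety: "extend across interruptions subject to a fraction cap" is
ambiguous about whether the cap applies during stepwise extension or to
the final window. Greedy left-to-right extension is order-dependent and
can miss a larger window whose intermediate prefixes violate the cap, so
`detect_run()` uses final-window semantics and computes the maximal valid
windows exactly by enumerating homopolymer-block ranges. The unit tests
check this against an independent brute force over every character
window.

Counts include only residues matching the run (interruptions are reported
separately with their offsets); whether interruptions should count toward
published Q/A tallies is not stated in the literature, and this convention
lets users reconstruct either. The Q:A ratio is `q/a` when both counts are
positive and undefined otherwise (full precision internally, 2 decimals in
tables). Codon purity of a run is the fraction of its codons equal to the
modal codon: `CAG CAG CAG CAG` scores 1.0, the alternating low-purity
`CAG CAA CAG CAA` scores 0.5.

Domain assembly always seeks the polyA downstream of the chosen polyQ —
QA order is invariant in every observed repeat structure — and only falls
back to the global best A run when no Q run exists (the chondrichthyan
proto-domain).

## Classification

Per sequence, the ordinal gates are: `ABSENT` (no anchors), `PROTO` (at
least one run missing), `PRIMITIVE` (both runs present but either count
at most `short_run_max = 5` or either run interrupted), else
candidate-`VARIABLE`. The threshold 5 is a declared decision: the longest
composition described as primitive-range (caecilians, 2 Q : 3--5 A) fits
under it, while anurans reach `PRIMITIVE` via the interruption gate. The
published boundary between "short" and long runs is never numeric.

"Variable length" cannot be judged from one sequence, so `VARIABLE` is
confirmed at clade level: the clade class is the maximum member class,
with candidate-`VARIABLE` confirmed only when the clade's Q-count or
A-count range spans at least `var_min_span = 2`; otherwise the clade is
demoted to `PRIMITIVE`. This is what demotes galliforms, whose high 6.0
ratio is conserved across the order. Single-member clades keep
candidate-`VARIABLE` but are flagged low-confidence rather than silently
losing monotreme-scale samples.

Enriching a domain (adding a missing run, lengthening past the short-run
gate, removing interruptions) never decreases its class; this
monotonicity is property-tested.

## Emergence mapping

Leaf classes are mapped onto a rooted, dated phylogeny (branch lengths in
Ma; node ages computed root-down from the maximum root-to-tip path;
non-ultrametric trees allowed, tip ages under 0.5 Ma snapped to zero to
absorb rounding in published lengths). The published emergence datings
(<450, ~350, ~312, <100 Ma) come from clade divergence times rather than
an explicit algorithm, so the parsimony machinery here is this package's
formalization and agreement with the narrative is qualitative.

The default is unordered Fitch parsimony, generalized to polytomies by
iterated pairwise set intersection in the tree's fixed child order;
top-down resolution prefers the parent's state, then the ordinally lower
state, making reconstructions deterministic. An ordered Wagner mode
(`ordered = TRUE`, change cost = ordinal distance along ABSENT < PROTO <
PRIMITIVE < VARIABLE) reflects the progressive-emergence narrative; as a
Sankoff dynamic program its cost can never undercut unordered Fitch, and
both are oracle-tested against exhaustive minimization on small trees.

Origins are read off the resolved states: a node whose state differs from
its parent's is an origin of its state, and the stem interval [node age,
parent age] is reported, `Inf` (rendered `">rootage"`) at the root.
Multiple independent origins are all listed and flagged convergent.
Newick cannot distinguish an unrooted tree from a rooted basal polytomy,
so the outermost node is always treated as the root; polytomies are
preserved.

## Trait correlation

`correlate()` performs ordinary least squares of a morphometric trait on
the QA ratio across shared taxa (at least 3; undefined ratios dropped
with a logged count; zero variance in either variable is an error). The
literature sometimes prints signed r-squared values for negative
associations; mathematically r-squared is non-negative, so the package
reports unsigned `r2` plus the slope's sign. No phylogenetic correction
is applied — the cited analyses are equally naive — and every result
carries a `phylo_naive` flag saying so. Reproducing the published r²
values for dogs, primates, carnivorans or bats is out of scope: their
morphometric datasets are external.

## The synthetic generator

`clade_presets()` transcribes the printed per-clade compositions:

```{r presets, eval = FALSE}
vapply(clade_presets(), function(p)
  sprintf("Q %d-%d, A %d-%d, purity %.2f -> %s", p$q_len_range[1],
          p$q_len_range[2], p$a_len_range[1], p$a_len_range[2],
          p$purity, p$intended_class), character(1))
```

Two preset values are derived rather than printed: the squamate polyA
range 4--6 follows from the printed snake Q range (12--21) and ratio
range (2.0--5.25), and the galliform composition is realized as 18 Q :
3 A, one concrete composition with the printed conserved ratio 6.0.

Generated sequences are leader + flank + polyQ(+interruptions) + spacer +
polyA(+interruptions) + flank + tail. The generator's contract is that
its output is always recoverable by the pipeline under default
thresholds: flank mutations are capped at 2 per flank ("mostly
conserved"), interruptions are single residues inserted between run
positions, never inside the leading seed, and capped at half the run
length so the detection fraction cap always holds. Padding residues
exclude Q and A (no spurious runs) and D and V (no random flank decoys
within the mismatch budget). Paired CDS sequences use the modal codon
(`CAG` for Q, `GCC` for A) with probability `purity` at run positions and
synonymous alternatives otherwise. Everything is reproducible per seed.

What the generator does **not** emulate: alignment error, indels outside
the repeat, paralog confusion (teleost Runx2a/Runx2b are not modelled
separately), nucleotide substitution processes, or selection. Passing the
end-to-end recovery tests therefore shows the pipeline is internally
consistent at the published compositions, not that it is robust to every
artefact of real assemblies.

The slippage simulator is explicitly a toy model: the literature states
direction of effect only (high-purity repeats stutter more; slippage
outpaces point mutation), so `slippage_params()` defaults are
placeholders for sensitivity analysis, not estimates. Per branch, events
are Poisson with mean `base_rate * (1 + purity_coupling * purity) *
branch_length`; each event expands with probability `expansion_bias` or
contracts, by a geometric step (mean `step_mean`), floored at zero. At
`expansion_bias = 0.5` the process is a martingale away from the zero
floor, which the calibration tests exploit (root counts of 10--15 keep
the floor effectively unreachable at test rates).

## Problem sizes and numerical choices

The analysis scripts and tests run at desk scale by choice: 20 sequences
per clade preset (the published survey's per-clade n ranges from 2 to
162), 1,000-replicate Monte-Carlo checks for the slippage calibration,
200 replicates for regression sign recovery (n = 30, noise SD = 0.25 x
signal SD), and exhaustive parsimony oracles on 5-leaf trees (4^5 leaf
patterns x 4^4 internal assignments). Determinism is enforced
throughout: one seed per generator invocation (recorded in outputs),
stable tie-breaks (earliest run, leftmost hit, parent-then-lower state),
and byte-identical reruns of the pipeline are tested.

Known limitations: Hamming-only motif matching (no profile/HMM), no
nucleotide-level STR calling, no likelihood ancestral reconstruction, no
PGLS, and no remote sequence retrieval. These are scope boundaries, not
oversights.
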