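---
title: "Split-inducing indels: model, rules, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-inducing indels: model, rules, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splidr)
```

## The problem and the model

Indels are not observable in single sequences; they appear as gap runs in a
multiple alignment, and their number and placement depend on the aligner.
Treating every gap column as a character therefore imports alignment noise
into tree inference. `splidr` instead restricts attention to
*split-inducing indels* (splids): gap runs whose start and stop columns are
bit-identical across two or more rows. Exact shared endpoints are the
homology signal — two runs that merely overlap are treated as independent
events. Each accepted splid partitions the taxa into presence (`1`),
absence (`0`) and missing (`?`) classes and becomes one binary character.

The three inference rules, applied per indel locus (a connected component
of gap-run overlap):

1. candidates have ≥ 2 taxa and size inside `[min_size, max_size]`
   (defaults 2 and unbounded);
2. candidates that overlap each other are *both* removed — neither boundary
   can be trusted when two plausible events compete for columns;
3. in strict mode, a candidate overlapping a single-residue indel shared by
   ≥ 2 taxa is removed; single-position gaps are too homoplastic to anchor
   a boundary, though fuzzy mode keeps such candidates for data sets where
   characters are scarce.

### Coding decisions at the boundary

Two situations are genuinely underdetermined and are resolved here the way
simple indel coding resolves inapplicable states:

* a taxon whose gap covers the splid's columns but with *different* run
  boundaries is coded `?`, not `0` or `1` — it neither carries the event
  nor demonstrates residues at those columns;
* `?` delimits gap runs: a run cannot extend through missing data, since
  the gap's true extent there is unknowable.

`N` is treated as a state-bearing residue (the sequence exists, the base is
merely uncalled), so it delimits runs and codes `0`.

### Invariants that hold — and one that does not

Strict-mode output is always a subset of fuzzy-mode output, and in strict
mode `min_size = 1` and `min_size = 2` give identical results (a
single-residue multi-taxon candidate is its own strict-filter trigger).
But the intuitive "more admissible sizes, more splids" monotonicity is
*false*: widening the size window can admit a candidate that overlaps an
accepted splid, and rule 2 then removes both. The test suite freezes a
minimal counterexample. This is a direct consequence of the rules, not an
implementation artifact — the brute-force oracle reproduces it.

## Alignment processing

Terminal gap runs are alignment artifacts (local alignments simply end) and
are masked to `?` before filtering; the masking is idempotent. Blocks are
kept when they have ≥ 2 taxa and ≥ 1 interior gap. Concatenation pads taxa
absent from a block with `?` across that block's columns and treats block
boundaries as hard breaks: extraction runs per block slice, so a gap run
can never span two source blocks even if masking leaves `?` at a boundary.
Extraction on a concatenation therefore equals extraction on the blocks
separately, and block order only permutes the output.

MAF species names are split at the first `.` (`species.chromosome`), with
the full source name available by flag since both conventions occur in the
wild; duplicate species rows within a paragraph keep the first row with a
warning. The strand field is provenance only — MAF alignment text is
already in alignment orientation.

## Tree distances

Robinson–Foulds is the symmetric difference of non-trivial bipartitions;
quartet distance enumerates all `choose(n, 4)` quadruples against split
membership matrices (brute force is the point: at n ≤ ~40 it is exact,
transparent, and independently checkable by pruning). Normalizations are
d'_RF = d_RF/(2n−6) and d'_Q = d_Q/C(n,4); printed output uses 4 decimals.
Rooted inputs are unrooted by suppressing the root. Quartets resolved in
one tree but not the other count as differences by default (irrelevant for
binary trees; a flag switches the convention).

## The simulator: what it emulates and what it does not

`simulate_alignment()` emulates an INDELible-style protocol: F81
substitutions, independent insertion and deletion Poisson processes with
per-site rates relative to substitution rate 1, and geometric or Lavalette
length distributions. Stated parameter sets: geometric with q = 0.7 or
q = 0.55 at λ_i = 0.03106, λ_d = 0.04037; Lavalette with a = 1.5, M = 120
at λ_i = 0.02899, λ_d = 0.03768; guide tree rescaled to maximum root-to-tip
height 2. Defaults use the geometric q = 0.7 condition with a root length
of 5,000 sites — a deliberate desk-scale stand-in for the 100,000-site,
100-replicate condition (available via configuration; tests scale down to
stay within CI budgets). Equilibrium frequencies default to uniform: the
original background frequencies come from a genome-alignment model file
that is not reprinted, so uniform is the one documented override point.
The 17-taxon guide tree is likewise synthetic (`synthetic_guide_tree()`,
fixed seed, height 2) because the real tree file is not redistributable.

Semantics fixed where the protocol delegates to the simulator: event counts
are Poisson(rate · L · t) with L the ungapped length at branch start; event
times are uniform on the branch and applied in order; insertions pick one
of L + 1 inter-site slots uniformly and draw new bases from π; deletions
pick a uniform start site and truncate at the sequence end. Substitutions
use a single draw from the branch-end transition matrix — exact for F81,
which is Markovian with no rate heterogeneity; inserted sites are born at
equilibrium and not further substituted on their birth branch (an
approximation, biased low by at most half a branch of substitutions on
inserted material). Substitution events are logged per branch in aggregate;
every insertion/deletion is logged individually with its final alignment
columns and descendant leaf set.

What the simulator does *not* model — and hence what a green test does not
establish: alignment error (the true alignment is emitted; there is no
re-alignment step), rate heterogeneity across sites, indel rate variation
across lineages, and selection on indels. Simulation-based tests validate
the *extraction logic against known event histories*, not robustness to
aligner behavior.

A subtlety the event-log cross-checks must respect: two deletions on nested
branches that merely *abut* in columns merge into one longer gap run in the
doubly-affected leaves, changing run boundaries. The "isolated event"
checks therefore pad each event's column range by one column before
declaring it independent. With that guard, every isolated multi-taxon
deletion is recovered as exactly one splid whose presence set is the
branch's leaf set.

Block splitting draws `1 + Geometric` lengths with mean `block_mean`
(default 140 columns, the stated re-alignment block size);
`concatenate_blocks(split_into_blocks(x))` reproduces `x` exactly, which is
why the splitter may emit blocks with pure-gap rows that readers would
reject — downstream filtering handles them.

## Numerical and degenerate-input choices

* All extraction output is deterministically ordered (block index, start
  column, taxon name); there is no RNG anywhere in extraction.
* Lavalette probabilities are normalized by direct summation over 1..M
  (exact to machine precision; no closed form is needed).
* `f81_transition` validates π (positive, sum 1) and caches per branch
  length; β = 1/(1 − Σπ²) scales branch lengths to expected substitutions.
* Blocks with < 2 taxa yield no splids (rule 1 cannot fire); zero-length
  blocks and pure-gap rows are rejected at read time.
* Tree rescaling recomputes the height after scaling to 1e-12.
* Rounding of printed 4-decimal values uses R's default (round half to
  even); all checked values are insensitive to the convention.

## Known limitations

* Quartet distance is O(n⁴ · splits): fine to n ≈ 40, not a tqDist
  replacement.
* The NEXUS writer emits a single DATA block; assumption blocks for
  specific inference tools are out of scope.
* PHYLIP output is relaxed (full names); strict 10-character truncation is
  opt-in and errors on collisions rather than silently renaming.
* The simulator is a re-implementation, not a wrapper; exact event-timing
  details of the original tool are approximated as documented above.
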