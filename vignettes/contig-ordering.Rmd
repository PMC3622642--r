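---
title: "Ordering draft-genome contigs against a reference by weighted reversals and block-interchanges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering draft-genome contigs against a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockorder)
```

## The problem

A draft genome produced by short-read sequencing is usually an unordered
set of contigs.  Each contig is an ordered list of signed gene (or
marker) IDs; the sign encodes the strand.  Rearrangement studies and
scaffolding both need those contigs ordered and oriented.  Given a
completely assembled reference genome over the same `n` genes, the
*one-sided block ordering problem* asks for an ordering and orientation
of the `m` contigs whose induced signed permutation has minimal
rearrangement distance to the reference, where distance is measured by
**reversals** (invert a segment and swap its strands, weight 1) and
**block-interchanges** (exchange two non-overlapping segments, weight 2;
transpositions are the adjacent special case).  The 1:2 weighting
reflects the observation that transpositions occur roughly half as often
as reversals in biological data.

`block_order()` solves this problem exactly.  The companion
`block_distance()` returns the distance alone without extracting the
event sequence, and `brute_force_order()` certifies optimality on small
instances by exhaustive search.

## The permutation-group machinery

A double-stranded molecule is modelled as a product of two cycles, one
per strand: contig `[b1, ..., bk]` contributes `(b1, ..., bk)` and its
reverse complement `(-bk, ..., -b1)`.  Write `Γ` for the involution
`(1,-1)(2,-2)...` pairing each element with its negation; the reverse
strand is the conjugate of the inverse of the forward strand by `Γ`.
Distances come from the **norm** `‖α‖ = |E| − n_c(α)` (the minimal
number of 2-cycles multiplying to `α`): a reversal multiplies the genome
by two 2-cycles, a block-interchange by four, so reversals change the
norm of the quotient `σπ⁻¹` by 2 and block-interchanges by 4.

Contigs are made to behave like chromosomes by **capping**: contig `i`
receives auxiliary elements (caps) `n+2i−1` (5′) and `n+2i` (3′) on its
forward strand and their negations on the reverse strand, and the
reference receives the first cap pair plus `m−1` null contigs (cap pairs
with no genes) so both capped genomes use the same extended ground set
`{±1, ..., ±(n+2m)}`.  Each element of a capped genome has a
**character**: `C5` (5′ cap), `C3` (3′ cap of a gene-bearing contig),
`N3` (3′ cap of a null contig), `T` (the first gene after a 5′ cap), or
`O` (anything else).  `genome_char()` and `five_cap()` expose this
classification.

The solver then works on the quotient permutation `σ̂π̂⁻¹` in four
phases:

1. **Cap exchanges** (weight 0): while some cycle of the quotient
   contains a pair with characters in
   {(C3,C3), (C3,N3), (T,T), (T,N3), (N3,N3)}, apply a 4-factor
   translocation that swaps caps between two strands and leaves the
   underlying molecules untouched.  Afterwards every cycle holds at most
   one `T` and one `C3` element.
2. **Fusions** (weight 0): exactly `m−1` translocations with (T, C3)
   anchor pairs concatenate the contigs into one.  When the anchor pair
   already lies on a single strand, a 3′ cap `z` of a different
   gene-bearing contig mediates the fusion (a fusion followed by an
   implicit cap exchange).  The assembled gene order is read off here,
   and the weighted distance is already determined: it is half the norm
   of the current quotient.
3. **Reversals**: adjacent quotient pairs `x, y` with `(x, Γ(y))`
   dividing the capped genome yield 2-factor reversals, each lowering
   the quotient norm by 2.
4. **Block-interchanges**: while the quotient is not the identity,
   a 4-factor block-interchange lowers it by 4.

Each event is recorded with its anchors and its 2-cycle factors;
`replay_events()` re-applies the weighted events to the assembly and
reaches the reference exactly, which the test suite asserts.

## Determinism choices

Wherever the procedure says "find" or "choose any", the package fixes a
deterministic scan so that runs are reproducible and testable:

* Cycles of the quotient are scanned **positive-first**: cycles led by a
  positive element in ascending order, then cycles led by a negative
  element by ascending absolute value (each cycle is rotated to start at
  its smallest-magnitude element, positive winning ties).  Within a
  cycle, candidate pairs are taken in cycle order from the leader.
  This particular order was chosen because it makes the solver's event
  trace coincide, factor for factor, with the published worked example
  of the algorithm; a plain smallest-magnitude-first order would pick a
  mate-equivalent cap exchange and a different (equally optimal)
  alternative fusion instead.
* The mediating cap `z` of an alternative fusion is the first eligible
  3′ cap in the same positive-first order.
* When several optimal orderings exist the scan order fixes which one is
  returned; the brute-force oracle reports all of them.

Two boundary cases deserve mention.  A cap exchange may act between the
two strands of a *single* contig: that flips the contig's reading
relative to its caps while leaving the molecule unchanged, and it is
exactly what makes a one-contig draft equal to the reverse complement of
the reference cost 0 rather than 1.  And when a block-interchange's two
anchor pairs share an element (the transposition-like event that
consumes a 3-cycle pair of the quotient), its two mate factors do not
commute; the solver composes them in whichever order keeps the capped
genome strand-symmetric.

## Diagnostics and invariants

With `check = TRUE`, `block_order()` re-verifies after every event that
the capped genome stays strand-paired (`π̂ = Γ̂π̂⁻¹Γ̂`) and admissible (no
cycle contains an element and its negation), that every quotient cycle
has its mate cycle, that the character classes obey the `T ↔ C3` duality
under `π̂Γ̂`, and that the incrementally maintained quotient equals a
from-scratch recomputation.  It also records, for every fusion, the
change of the **residual norm** `psi_norm()` — the norm of the non-cap
part of the quotient after exhausting cap exchanges — which must lie in
{−2, 0, +2}, with "good" fusions achieving +2.  The residual norm is a
diagnostic only; the solver never consults it.

## The worked example

```{r worked}
fit <- block_order(list(c(1, 4), c(-5, 6), c(3, 2)), 1:6)
summary(fit)
```

The event log shows one cap exchange, two fusions (weight 0), one
reversal and one block-interchange, so the distance is
`1 + 2 × 1 = 3`.

## The optimality oracle

`brute_force_order()` is deliberately independent of the solver: it
enumerates all `m! · 2^m` orderings and orientations, concatenates each,
and measures its distance to the reference by uniform-cost search over
raw sequence moves (all signed segment reversals, weight 1; all
non-overlapping segment exchanges, weight 2).  For `n ≤ 6` the search
from the reference is run to exhaustion once and cached, because
position moves commute with gene relabelling; for `n` of 7 or 8 a
per-query capped search is used.  The test suite checks solver
optimality on 200 random instances with `n ≤ 6`, `m ≤ 3`.

## The simulation benchmark

`run_benchmark()` emulates a resequencing study: start from the identity
reference `(1..n)`, apply `delta` random events (reversal with
probability `r/(r+t)` for ratio `r:t`, otherwise a transposition given by
three uniform distinct cut points), fragment the result at `m−1` uniform
internal adjacencies, reverse-complement each contig with probability
1/2, shuffle the contig order, and re-order with `block_order()`.
Accuracy is the **normalized mis-join error**: the number of predicted
adjacencies absent from the truth (counting an adjacency and its reverse
complement as equal, taking the better of the two whole-assembly
orientations), divided by `m − 1` for a linear chromosome.  Contig
orientations and order are randomized because a draft genome is an
unordered set; the truth strand of each fragment is not observable.

The package's standard grid uses `n = 100` genes, `m = 20` contigs,
`delta` from 0 to 20 and the four ratios 1:0, 2:1, 1:1 and 0:1 with 10
repetitions — sizes at which one grid run takes about two minutes while
still showing the regime where mis-join errors appear.  With `delta = 0`
the pipeline must reconstruct the truth exactly (distance 0, error 0),
which the acceptance tests assert over 50 repetitions.  All runs are
reproducible: per-repetition sub-seeds are drawn up front from the grid
seed.

What the generator does *not* emulate: unequal gene content, paralogs,
assembly errors inside contigs, circular or multi-chromosomal genomes.
Passing benchmarks therefore demonstrate correctness of the ordering
machinery on clean signed permutations, not robustness to annotation
noise in real drafts.

## Numerical and degenerate-input choices

* Gene IDs are validated to cover `1..n` exactly once; the reference may
  be any signed order (it is relabelled internally to `(1..n)` and the
  result mapped back).
* The assembled reading is taken from the strand whose 5′ cap is the
  smallest positive cap (falling back to smallest magnitude); the two
  strands are reverse complements with identical distance, so this is
  purely a reporting convention.
* A one-contig draft needs no fusions; an already-sorted draft returns
  distance 0 with an empty event log.
* Event weights 1 and 2 are fixed, not parameters: the optimality theory
  is specific to the 1:2 ratio.
* All phases carry iteration guards that turn a (theoretically
  impossible) failure to progress into an immediate internal error
  rather than a silent wrong answer.

## Limitations

Linear, uni-chromosomal genomes with equal gene content only; circular
and multi-chromosomal inputs are rejected rather than guessed at.  The
brute-force oracle is exponential and restricted to `m ≤ 4`, `n ≤ 8`.
Runtime of the solver grows with the number of extracted events times
the ground-set size; the benchmark sizes above run comfortably, and
instances of a few thousand genes remain practical.
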