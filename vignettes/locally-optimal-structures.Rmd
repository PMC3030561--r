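---
title: "Computing the Boltzmann ensemble of locally optimal RNA structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the Boltzmann ensemble of locally optimal RNA structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locopt)
```

## The problem

An RNA secondary structure is a set of base pairs on a sequence that are
canonical (Watson-Crick or wobble), enclose at least three unpaired bases in
every hairpin, contain no base triples and no pseudoknots. Under the
nearest-neighbor free energy model, a structure is **locally optimal** if no
single base-pair addition or removal yields a structure of strictly lower
free energy (ties do not break optimality). Locally optimal structures are
the kinetic traps of the folding landscape: leaving one requires an
energetically unfavorable elementary step. This package computes, by dynamic
programming in polynomial time,

* the partition function `Ztot = sum over locally optimal S of exp(-E(S)/RT)`,
* the exact number of locally optimal structures,
* i.i.d. Boltzmann samples from the locally optimal subensemble,

alongside the classical McCaskill quantities for the full ensemble (partition
function, exact base-pair probabilities, Ding-Lawrence-style sampling),
ensemble diversity statistics, and maximum expected accuracy (MEA) structure
prediction driven by full-ensemble, locally-optimal, or entrywise-minimum
("MIN") pairing probabilities.

## Energy model

The model is a loop-based nearest-neighbor model at 37 degrees C **without
dangling ends or coaxial stacking**: the free energy of a structure is the
sum over its unique loop decomposition of

* hairpin energies `EH(i,j)` (size-dependent, log-extrapolated beyond 30),
* internal-loop energies `EL(i,j;k,l)` covering stacks, bulges and interior
  loops up to total size 30, with a capped Ninio asymmetry term,
* affine multiloop energies `a + b u + c (h+1)` for `u` unpaired bases and
  `h` interior branches,
* a terminal AU/GU penalty applied at hairpin closing pairs, at both pairs of
  bulges and interior loops (not stacks), at multiloop branches and closing
  pairs, and at external branches. The external loop otherwise contributes
  no energy.

Two parameter sets ship with the package. `"turner"` is a Turner-style
table: Watson-Crick stacking free energies after the optical-melting
regressions, wobble stacks at published magnitudes, and size-dependent loop
initiation terms with Jacobson-Stockmayer `1.75 RT log(s/s0)` extrapolation;
`RT = 0.0019872 * 310.15` kcal/mol. `"toy"` is a deliberately flat model
(hairpin +2.0, stack -2.0, all other internal loops +1.0, multiloop
3.0/0.1/0.4, `RT = 0.6`) whose every example is computable by hand; it is
used throughout the tests to pin exact values. Custom tables are read from a
plain-text Vienna-style dialect; dangle and coaxial blocks are ignored on
load. Isolated (lonely) base pairs are permitted in the ensemble. The
internal-loop size cap of 30 is part of the ensemble definition, as is
standard practice in folding software; for sequences shorter than ~38
nucleotides the cap cannot bind, so every oracle comparison below runs over
the full unrestricted ensemble.

## Conditional optimality

Every elementary move is local to one or two loops: adding a pair splits a
loop in two, removing a pair merges the two loops it separates. A structure
is therefore locally optimal iff a finite list of *local* indicator checks
("deltas", each of the form "this move does not lower the energy, allowing
ties") holds: additions inside hairpins, inside internal loops, inside
multiloop or external unpaired stretches, and around single branches; and
removals of every pair, whose energy change depends on the loop inside and
the loop outside the pair.

The recursion carries just enough context to evaluate each check at the
moment it becomes decidable:

* `ZHP(i,j)` — locally optimal hairpins, gated by the precomputed
  hairpin-addition flag;
* `ZIL(i,j;k,l)` — structures whose outermost two pairs form the internal
  loop `(i,j;k,l)`, optimality *conditional* on `(i,j)` remaining paired.
  Tracking the outermost **two** pairs is what makes pair-removal checks
  local: removing `(k,l)` merges two loops whose energies are both known
  here. Three cases (hairpin, multiloop, inner internal loop below `(k,l)`)
  carry their own removal deltas; the addition check inside the 2-loop
  covers both splitting pairs and hairpin-creating pairs that would turn
  the 2-loop into a multiloop.
* Multiloop interiors are chains of components glued left to right. Each
  component owns its left unpaired stretch outright; its right flank enters
  only as a **tail bucket** `0..max_tail` plus one "longer" bucket, which is
  exactly the context needed to check additions that would enclose the
  branch in a new internal loop (the common case: stacking a pair directly
  onto a helix end). `ZbML(i,j)` closes a multiloop over a two-or-more
  component chain, with a final check for additions stacking inward under
  the closing pair. External chains are the same construction anchored at
  position 1 with no affine penalties and no closing.
* The total sums the external chains over final-tail buckets; the empty
  structure contributes iff it is locally optimal, which the engine decides
  by the same exact stretch flag and the tests re-verify by direct
  neighborhood enumeration.

In-stretch (hairpin-creating) additions are checked **exactly** by an
`O(n^2)` interval flag table, with no window truncation. Counting mode
replaces every Boltzmann factor by 1 while the deltas keep using energies:
local optimality is an energetic notion, only the weights are removed.

## Model assumptions, re-verified rather than trusted

Three structural assumptions keep the recursion polynomial; each is encoded
in a guard function and asserted by the test suite for the shipped models:

1. **No splitting pair helps** (`verify_multiloop_split`): a pair enclosing
   two or more branches of a multiloop (or two or more external branches)
   creates an additional multiloop closing penalty and can never lower the
   energy while `a`, `c` are positive.
2. **Only internal loops enter multiloops** (`verify_branch_assumption`):
   removing a branch pair that directly closes a hairpin or a multiloop
   always lowers the energy, so chains are built from internal-loop-topped
   components only. For the toy model with its per-unpaired-base multiloop
   credit `b = 0.1` this holds for all contexts realizable below roughly 30
   nucleotides — comfortably covering every oracle-compared length — and the
   guard takes the length bound as an argument.
3. **Tail bound** (`verify_tail_bound`): additions enclosing a branch from
   deeper than `max_tail` bases into a tail never lower the energy. Because
   internal-loop energies here depend only on pair types and strand gaps,
   the guard's exhaustive search over tail contexts is exact. For the
   shipped Turner-style set (`b = 0`) the bound holds at every length with a
   margin above 3 kcal/mol; for the toy model it holds for all multiloop
   stretches realizable at the oracle-tested lengths.

`max_tail = 10` is the default window; `max_tail = 4` trades a coarser
window for speed, and on every oracle-enumerable test sequence the two
agree (a discrepancy would require a lowering addition reaching 5-10 bases
into a tail, which neither shipped model admits there).

## Certification by an enumeration oracle

The engine's contract is semantic: `Ztot` equals the
Boltzmann sum over the locally optimal set. The `oracle` module enumerates
every structure of a short sequence by interval recursion, evaluates each
energy by full loop decomposition, filters local optima by definition-level
neighborhood comparison, and the tests assert exact agreement (counts as
integers; partition functions to relative error below 1e-6) on 100 seeded
random sequences of length 10-25 under both models, plus every
hand-computed value of the micro-example `GCAAAAGC`.

## Numerical choices

* Ties: a move "does not lower the energy" when its energy change is
  `>= -1e-9` kcal/mol; the DP deltas, the R-level neighborhood check and the
  C++ oracle share this tolerance, so exact-arithmetic ties (common in flat
  toy energies) are classified identically everywhere.
* Counts are IEEE doubles: exact integers up to 2^53 (far beyond any
  enumerable length; counts at n = 80 are ~1e18 and carry ~16 significant
  digits), which is ample for the log10 growth fits. No arbitrary-precision
  integer layer is bundled.
* No rescaling of partition values is performed: at the supported lengths
  (hundreds of nucleotides) magnitudes stay far inside double range.
* Stochastic tracebacks draw from R's RNG (reproducible via `seed`
  arguments) using inverse-CDF selection over each recursion's alternatives
  in the same fixed order as the forward fill.
* MEA tie-breaking prefers leaving the 5' position unpaired, then the
  smallest pairing partner. The MEA score is `2 gamma sum p + alpha sum q`
  with `alpha = 1`: a base pair occupies two positions, hence the factor 2.

## What the random-sequence experiments emulate

The experiment harness generates i.i.d. uniform A/C/G/U sequences (a 0th
order Markov chain), the standard null model for structure-count growth
laws; at the package's default desk scale (lengths 20-80, 20 sequences per
length) the growth fits, the decaying ratio `Ztot/Z`, and the coverage
comparison between sampled locally optimal and full ensembles reproduce the
qualitative laws (exponential growth with the all-structure exponent about
twice the locally optimal one; monotone decay; fewer distinct local optima
with higher coverage). Random sequences do not emulate evolved RNA:
naturally occurring families have conserved stems, biased composition and
modified bases, so passing these experiments says nothing about prediction
accuracy on real families; the MEA benchmarking helpers accept user-supplied
reference structures for that purpose.

## Known limitations

* No dangling ends, coaxial stacking, or temperature scanning; parameters
  are fixed at 37 degrees C.
* The move set is single-pair addition/removal only (no shift moves, no
  helix moves), matching the definition of local optimality used by the
  engine.
* Base-pair probabilities for the locally optimal subensemble come from
  sampling, not from an outside recursion.
* For energy models violating the guard assumptions (e.g. strongly negative
  multiloop terms), the engine's restriction to internal-loop-topped
  branches and windowed tail checks could misclassify rare structures; the
  guards fail loudly in that case rather than silently miscounting.
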