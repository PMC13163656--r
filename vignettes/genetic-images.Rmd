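---
title: "Genetic images: encoding, neural recognition, and the uncovering protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic images: encoding, neural recognition, and the uncovering protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method in brief

`genimage` treats the amino-acid sequences of two mitochondrial barcode
proteins — cytochrome b and cytochrome c oxidase subunit I (COI) — as a
fixed-size binary *genetic image* of an organism, and asks a simple
question: when multilayer sigmoid networks are taught to recognize the
images of a panel of organisms, whose image do they "see" inside the image
of an organism they were never taught?  Iterating that question while
removing recognized organisms from the teaching set (*uncovering*) orders a
panel along a line of decreasing similarity to a chosen apex organism, and
a codon-level transition/transversion position classifier provides an
independent, deterministic check of the same relationships.

## Encoding

Each residue letter is mapped to a five-bit code in alphabetic order:
`A` = `00001`, `B` = `00010`, `C` = `00011`, `D` = `00100`, ..., with the
padding character `-` encoded `00000`.  Only the first four assignments and
the pad are fixed by the published scheme; continuing alphabetically to `Z`
is this package's reading, chosen because the printed prefix is exactly
alphabetic order and because it gives every ambiguity code (`B`, `J`, `O`,
`U`, `X`, `Z`) a well-defined image without silently coercing it.  Unknown
characters (digits, `*`) are a hard error: coercing them to the pad would
corrupt images.

There is no multiple sequence alignment anywhere in the method.  Sequences
are *fitted* to reference lengths — end-padded with `-` or end-truncated —
defaulting to the human cytochrome b and COI lengths, 380 and 513 residues.
A concatenated image therefore always has `5 × (380 + 513) = 4465` bits
(1900 for cytochrome b alone, 2565 for COI alone).  The reference lengths
are configurable so that synthetic panels can run at a fraction of that
size.  Optional PNG rendering (one coloured cell per residue) exists purely
as a debugging aid; nothing downstream consumes the rasters.

## Recognition networks

Recognition uses full-synapse three-layer sigmoid networks:

* inputs: one per image bit (`n` = 4465 / 1900 / 2565 at the default
  reference lengths);
* outputs: one per teaching-set organism (`k`), taught to one-hot targets;
* hidden units by the geometric pyramid rule, `round(sqrt(n k))`;
* online backpropagation with momentum — one weight update per presented
  sample, `dw = -lr * grad + momentum * dw_prev` — with learning
  rate/momentum 0.07/0.07 for concatenated images and 0.3/0.1 for
  single-gene images;
* training stops when the root mean squared error over all samples and
  output units reaches 0.01.

Several details the protocol leaves open are fixed here as follows, and
each is a package design choice, not an inferred property of the original
software:

* **Bias units** on hidden and output layers.  One-hot targets at RMSE
  0.01 require outputs near 0 and 1 simultaneously; without biases the
  required operating points are much harder to reach.
* **Initialisation**: all weights uniform on `[-0.5, 0.5]` from a
  generator seeded per member, so a seed reproduces a trained network
  bit-for-bit on one platform.
* **Presentation order** is reshuffled every epoch with the same seeded
  generator; `shuffle = FALSE` gives the strictly sequential reading.
* **Epoch cap**: 50 000 epochs, after which training raises an explicit
  non-convergence error rather than looping forever.  At the scales used
  in the tests, converging members need roughly 7 000–16 000 epochs
  (smaller output layers need more epochs: the per-unit error budget at a
  fixed RMSE is tighter).
* **RMSE is evaluated at epoch end** over all samples and outputs — the
  natural reading of a stopping criterion, and the quantity logged per
  epoch.

One consequence of the one-hot construction worth stating: two identical
teaching images cannot be mapped to different outputs, so training can
never reach the target error (the error floor is `sqrt(1) / sqrt(n k)`
per duplicated pair).  `teach_ensemble()` therefore rejects duplicate
images up front with a clear message.

An *ensemble* is five such networks (seeds `base_seed + 0 … 4`).
"Recognized five times" is read as five independently initialised members
evaluated once each: forward passes are deterministic, so repeated
evaluation of one network would average five identical numbers.
Recognition averages the five activation vectors; organisms at or above
the threshold 0.01 are recognized, the highest is the *foreground* image,
the remaining ones are *background* images, and ties break
lexicographically by Latin name for determinism.  When nothing reaches the
threshold the report still carries the best sub-threshold organism,
because the protocol itself continues through sub-threshold recognitions
(bacteria are recognized at averages of 0.0084 and 0.0062 in the published
bottom-up run).

## The uncovering protocol

One step: teach ensembles on the panel minus all removed organisms,
recognize the (removed) reference organism's image, and remove what the
*main recognition system* — the concatenated-image ensemble — recognized.
Single-gene ensembles are reported alongside but never drive removal; in
the published run they lose recognition ability several steps before the
main system does, which is precisely why the concatenated system is the
main one.

The run loop adds two rules:

* **Reference switching.**  When the main system recognizes nothing, the
  reference switches to the earliest-recognized foreground organism not
  yet used as a reference (a FIFO queue over foregrounds).  This
  operationalises "the evolutionarily closest organism that was
  recognized": the first foreground is exactly that organism.
* **Sub-threshold continuation** is enabled by default only for bottom-up
  runs (mirroring the published bottom-up steps), and is flag-controlled.

Termination is structural: every productive step strictly shrinks the
teaching set, and a reference switch consumes a queue entry that only
removal can replenish.

*Threshold organisms* are detected from the homologous-position fraction
(`R` positions / length) of each foreground against the apex: top-down,
the last foreground at or above 25 % before the fraction first drops below
25 %; bottom-up, the last foreground at or below 50 % before it first
exceeds 50 %.  The first foreground after each reference switch is also
marked.  Boundary values sit on the "at or above" / "at or below" side by
definition, and the tests pin that convention.

The *virtual line of inheritance* merges a top-down and a bottom-up trace:
the top apex at position 0, top-down foregrounds in step order up to a
credibility bound, then the bottom-up foregrounds reversed from its
threshold organism back to the bottom apex, with each step's background
organisms bracketed onto their foreground's position.  The published
account applies judgment to where top-down contributions end; here the
bound is an explicit argument defaulting to the top-down threshold
organism's step.  Conflicting placements are reported, never silently
resolved, and unplaced organisms are listed.

A note on what is and is not reproducible: activation values are
stochastic (they depend on initialisation and presentation order), so no
fixed activation number is asserted anywhere; the deterministic quantities
— image sizes, position counts, the `(2n-3)!!` rooted-tree count (exact,
via a small big-integer multiply, since the 32-taxon count has 43 digits)
— are asserted exactly, and the stochastic behaviour is asserted as rates
over seeded replicates.

## Semihomologous position classification

For an aligned position with amino acids `a` and `b`:

* `R` — homologous: `a == b`, both standard;
* `#` — some codon pair `(c1, c2)` with `c1` coding `a`, `c2` coding `b`
  differs by exactly one substitution of transition type (purine–purine or
  pyrimidine–pyrimidine);
* `$` — as above but transversion type;
* `-` — at least two point mutations between every codon pair, or either
  side is a pad or uncodable symbol.

The classification is existence-based over codon sets: it asks whether a
one-point mutation *could* explain the replacement, not what historically
happened.  Two details are deliberate choices:

* **Tie policy.**  Some pairs (e.g. L/F under the universal code:
  `CUU↔UUU` is a transition, `UUA↔UUU` a transversion) admit distance-1
  codon pairs of both types.  The default gives transitions precedence,
  consistent with the transition bias of molecular evolution; a
  `tie_policy = "transversion"` flag exposes the other convention, since
  the published splits' tie rule is not printed.
* **Pads and uncodable symbols count as `-`.**  The published per-pair
  counts sum exactly to the full fitted length (862 + 24 + 3 + 4 = 893 =
  380 + 513), so padded tails must be tallied somewhere, and the
  only non-match bucket is `-`.  This also covers selenocysteine and
  pyrrolysine, whose codons are stops in both shipped tables.

Codon sets come from NCBI translation tables 1 (universal, the default)
and 2 (vertebrate mitochondrial — relevant because both markers are
mitochondrial), represented as RNA.  Switching tables can move the `#`/`$`
split of a pair but can never change whether a position is `R`; the tests
assert both facts, and an exhaustive brute-force enumeration over all
codon pairs — written independently of the package's own machinery —
pins all 400 standard pairs under both tables and both tie policies.

## The synthetic panel generator

Real panels require downloading sequences; every stage of this package is
instead exercised by a codon-level simulator that emulates descent from a
common ancestor:

* the root is a uniform random stop-free codon sequence;
* each branch applies a configured number of single-nucleotide
  substitutions at uniform sites; each is a transition with odds
  `kappa : 1` (default 3 — transitions are favoured several-fold in
  mitochondrial evolution), and proposals creating stop codons are
  rejected and redrawn, keeping every node translatable at full length;
* nodes are translated to amino acids and named so that alphabetical
  order equals generation order on a chain.

Substitutions are counted per branch rather than drawn from a clock, so
tests get exact, small, controllable divergences; the recorded
substitution list replays exactly, and the recorded transition fraction is
binomial around `kappa / (kappa + 1)` (the stop-rejection asymmetry is
measurably below one standard error at 1 000 substitutions).

Because many substitutions are synonymous, independently drawn branches
can produce identical proteins; by default the generator redraws such
branches (`distinct_proteins = TRUE`), since duplicate images make the
one-hot teaching task unrealizable and real study panels are pairwise
distinct at the protein level.

What the simulator does *not* model — realistic substitution processes
(GTR or codon models, selection, rate heterogeneity), insertions and
deletions, length variation between organisms, and compositional biases of
real mitochondrial proteins.  Passing tests on synthetic ladders therefore
show that the pipeline recovers *planted* nearest-relative structure under
clean divergence; they do not certify performance on diverged real panels,
where signal decays with saturation and the published protocol itself
needs sub-threshold continuations.

## Problem sizes used by tests and the acceptance script

All stochastic checks run at desk scale, chosen once:

* training contract: one 8-organism chain, 60 + 80 codons (700-bit
  images), five members, seeds fixed;
* nearest-relative recovery: 20 replicates of an 8-organism chain at
  30 + 40 codons with 4 substitutions per branch — 2 % of the 210
  nucleotide sites, the divergence regime the recovery claim is about;
* uncovering order fidelity: 10 full top-down runs (5 in the acceptance
  script) of the same design, compared with generation order on the
  *foreground sequence* — organisms recognized within one step are a
  foreground plus unordered background attachments, so the foreground
  sequence is the protocol's ordered output;
* simulator calibration: 1 000 substitutions on a 500-codon root.

At these sizes the full suite and the acceptance script each run in
minutes on one CPU.

## Known limitations

* Activation values are not comparable across re-trainings; only their
  order and threshold crossings are used, matching the protocol.
* The alphabetic extension of the letter codes beyond `D` and the
  semihomology tie rule are documented readings of an underspecified
  scheme; both are isolated behind flags/constructors so either can be
  swapped without touching the pipeline.
* The uncovering protocol is greedy: removal decisions are never revised,
  so an early spurious recognition propagates.  The seeded replicates in
  the tests quantify how often that matters at desk scale.
* `fit_to_reference` truncates from the end only; markers whose length
  variation is not terminal would need genuine alignment, which is out of
  scope by design.
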