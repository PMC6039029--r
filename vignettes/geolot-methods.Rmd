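---
title: "Inferring and validating the productions of a geometric language of thought"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and validating the productions of a geometric language of thought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geolot)
```

## The model

`geolot` works with a *language of geometry*: a context-free grammar whose
programs are movement recipes on the eight labelled vertices of a regular
octagon, Σ = {0, …, 7}, labels increasing clockwise. A program is a
derivation tree:

* **atomic instructions** — position-to-position maps. `+k` / `-k` move k
  vertices clockwise / anticlockwise, `+0` stays; `A`, `B`, `H`, `V` are the
  reflections `pos ↦ (c − pos) mod 8` with one odd constant `c` per axis;
  `P` is the half-turn `pos ↦ (pos + 4) mod 8`. The *extended* inventory
  adds eleven ad-hoc atomics (`DOUBLE`, `-DOUBLE`, `SQUARE`, `GAMMA`, and
  digit lookups of π, e, φ, √2, Khinchin's, Glaisher's and Chaitin's
  constants) that can express regularities but have no geometric motivation;
* **binary concatenation** — run the left part, then the right part from
  the last emitted vertex;
* **three repetition operators** over a shared block and a count
  n ∈ [2, 8]: `REP` threads the current position across cycles;
  `REP1<sym>` restarts each cycle at `sym` applied to the previous cycle's
  *start*; `REP2<sym>` emits the previous cycle's *output* transformed
  pointwise by `sym`.

Executed from an anchor vertex (which is not itself emitted), a program
yields a point sequence in Σ⁺. A trial is an (anchor, sequence) pair.

Attaching a probability vector θ to the productions — normalised within
each nonterminal block (START; INST with its atomic / concatenation /
repetition choice; REP with its three variants; ATOMIC with one entry per
symbol) — turns the grammar into a PCFG. A program's probability is
`Π_r θ_r^{f_r(p)}` times `(1/7)` per repetition node, because the
repetition count is drawn uniformly over its interval rather than
θ-weighted: the inventory assigns one probability per symbolic production,
not one per count. The likelihood is exact-match: a program either computes
the observed sequence (likelihood 1) or does not (0); there is no
perceptual-error parameter.

## Posterior inference

The posterior of θ given trials D marginalises over the programs that
explain each trial. The sampler is a two-block Gibbs scheme:

1. **Programs given θ** — an exact draw per trial. Because every explaining
   program is available through the enumeration DP (below), the conditional
   is a finite multinomial and the draw is exact, which is why short chains
   mix well.
2. **θ given programs** — conjugate: sum production counts over the drawn
   programs and draw each nonterminal block from Dirichlet(f + α).

Defaults follow the study conditions the package is designed around: unit
concentration α = (1, …, 1), 4 chains, 50 steps, burn-in 10. Chains start
at the per-block uniform θ; with exact program draws and a conjugate θ
move, the initialisation only affects the earliest steps, which burn-in
discards. One master seed drives everything; chain *c* re-seeds with
`seed + c`, so results are reproducible bit-for-bit.

The Dirichlet prior is implemented as a *product of independent Dirichlets,
one per nonterminal block*. A single flat Dirichlet over all ℓ productions
would not respect per-block normalisation; the block structure is forced by
the PCFG definition.

Summaries pool post-burn-in samples across chains and report the naive
standard error (sd/√n). MCMC samples autocorrelate, so this SE understates
uncertainty; `summarize_posterior(..., ess_correct = TRUE)` divides by an
autocorrelation-based effective sample size instead. Population contrasts
(`compare_populations()`) are Welch t-tests on the pooled θ samples of one
pre-selected production; a grammar-wide scan applies a Bonferroni
correction, since scanning all productions without multiplicity control
would overstate differences.

## Enumerating every explaining program

The core data structure is a *requirement circuit*. A requirement is a set
of parallel constraints, each "(entry vertex, target run)", all runs of
equal length; a derivation of the requirement is a single program tree
whose execution satisfies every constraint at once. Decompositions:

* run length 1 — every atomic whose map sends each entry to its target;
* binary splits — left/right sub-requirements, threading the split vertex;
  all binary association orders of a comma list arise from the recursion
  itself, and distinct association trees are counted as distinct programs
  (program statistics are statistics over derivation *trees*);
* repetitions — the shared block must explain all n cycles simultaneously,
  so the cycle constraints are *intersected* into one child requirement.
  `REP1` precomputes its param-iterated cycle starts; `REP2` first checks
  that later cycles are pointwise images of their predecessors, after which
  only cycle 1 constrains the block.

Requirements are canonicalised (sorted, deduplicated) and hash-consed, so
the circuit is a DAG whose derivations of the root correspond one-to-one to
explaining programs. One circuit then serves every quantity:

* **count** — sum-product with unit weights;
* **P_Geo** — sum-product with θ-weighted edges (the inside algorithm);
* **K_Geo** — min-plus with description-length edge costs;
* **posterior draws** — stochastic backtracking through the inside values;
* **materialisation** — recursive expansion, with a cap (default 10⁷) that
  withholds the program list while keeping the count exact.

Counts are held in doubles. At the lengths the grammar admits (≤ 8) counts
stay far below 2⁵³, where doubles are exact integers; a test pins this.

The independent check on all of this is a brute-force oracle that builds
*every* derivation tree of a given output length by exhaustive grammar
expansion — maintaining, per tree, its serialized text and its execution
table from all eight anchors — then filters by execution equality. The DP
and the oracle are compared as serialized-program *sets*, not just counts,
across random inputs up to length 4 under the original inventory (about
4.7 × 10⁵ candidate trees) and length 3 under the extended one (7.5 × 10⁴;
at length 4 the extended space exceeds 6 × 10⁶ trees, beyond the oracle's
budget — the DP itself has no such restriction).

## Description length and the coding experiment

`K_Geo` uses the model's published cost rules: each atomic instruction
costs 2 units, concatenation is additive, and a repetition adds
⌊log n⌋ to its block's cost. The package takes the logarithm in **base 2**
(description-length units; the cost rules state no base) and charges a
`REP1`/`REP2` parameter its atomic cost of 2 (the rules are silent; both
choices are arguments of `program_cost()` and `sequence_complexity()`).

`P_Geo(x)` is the unnormalised sum of program probabilities over all
explaining programs, with θ inferred from data. The coding experiment
draws, per length, up to 10,000 *unique* records — interpreted as unique
(anchor, sequence) pairs, since executing a program requires a start
point — exhaustively when fewer exist; computes K and P per record from one
shared circuit; groups records with identical K; averages P within each
group (groups of size one are retained); and fits OLS of log₁₀(mean P) on
K. A strongly negative slope with high R² is the Coding-Theorem pattern.
With fewer than two distinct K values the fit is reported as `NA` rather
than raising.

## The synthetic generator

The behavioural datasets the method was designed for (adults and
preschoolers reproducing octagon sequences; 23 adults in the reference
cohort) are not deposited, so the generator emulates their *statistical
structure*: per trial, a uniform anchor and a program drawn from the PCFG
under a ground-truth θ, conditioned on emitting exactly L = 8 points.
Conditioning uses length-indexed inside weights with top-down exact
sampling — naive generative sampling either misses the target length or
fails to terminate under heavy concatenation mass, and rejection would bias
the tree distribution.

The default θ_true is a fixed, documented choice: within the sequence
block, repetition (0.35) above plain concatenation (0.20) — the qualitative
pattern inferred from human sequences; repetition variants at 0.6/0.2/0.2;
atomic probabilities balanced between clockwise and anticlockwise with the
half-turn `P` at 0.05, the reported adult posterior mean for that
production; ad-hoc productions at zero (behaviour-like data uses only the
original inventory). Optional noise replaces each emitted point uniformly
at random with probability ε (default 0, since the likelihood is
noise-free); even heavily corrupted sequences remain explainable, because
the original atomics cover every position pair, so every (anchor, sequence)
has at least one explaining program.

What passing recovery tests on such data shows — and does not show: they
demonstrate that the inference machinery is correct and well-calibrated
*under the model's own generative assumptions* (independent trials, one
program per trial, exact reproduction). Real behavioural data add
error-correction dynamics within a trial, sequence-selection effects from
the stimulus design, and subject-level heterogeneity that the pooled θ
ignores; conclusions about human repertoires require the real data.

## Numerical choices and degenerate inputs

* Inside values are plain doubles: the smallest tree probabilities at
  length 8 are far above the double underflow threshold, and sums only
  increase them. No log-space evaluation is needed.
* Posterior backtracking guards floating-point edge cases by never landing
  on a zero-mass decomposition.
* Serialization nests right-branching concatenations in brackets
  (`"[a, [b, c]]"`), so parse(serialize(p)) is the identity on *trees*
  while plain comma lists stay left-associated on parse.
* Ties in minimal description length need no tie-break: `K_Geo` is a
  value, not a program; `enumerate_programs()` exposes the full set when a
  minimising witness is wanted.
* Empty sequences are rejected; single-point sequences are ordinary inputs
  (only atomic derivations exist). A sequence with no explaining program —
  impossible under the shipped inventories, possible under restricted
  configurations — raises a named error in inference and complexity, and
  yields probability 0.
* The Chaitin digit table derives from a published 84-bit approximation of
  one particular Ω (≈ 0.0078749969…), taken digit-by-digit mod 8. It is a
  replaceable fixture (`geo_grammar(digits = list(CHAITIN = ...))`), not a
  canonical constant.
* Reflection constants: `A` is pinned to c = 5 by the worked example in
  which `A` swaps vertices 6 and 7; `B`, `H`, `V` default to 1, 7, 3 and
  are configurable, since the original axis labelling is not
  machine-readable. Inference results are invariant to relabelling among
  reflections up to a permutation of θ entries.

## Problem sizes

The shipped tests and the acceptance script use: 300 trials of length 8
for recovery and pruning runs (with 30-trial runs for the
consistency-with-n comparison, averaged over seeds); 4 chains × 50 steps,
burn-in 10, for every Gibbs run; 10,000 unique length-5 records for the
coding experiment; brute-force cross-checks at lengths ≤ 4 as above. These
sizes were chosen to match the study conditions the package models while
keeping every run exact rather than approximate.

## Known limitations

* No hierarchical (per-subject) θ: trials are pooled per population.
* No alphabet other than the octagon's eight vertices, and no sequences
  longer than 8 without reconfiguration.
* `P_Geo` is unnormalised by design; it is a relative measure for the
  coding experiment, not a distribution over Σ⁺.
* The exact formal semantics of `REP1` (whether the starting-point
  variation composes from the previous cycle's start) follows the
  operator's name and worked usage; the semantics functions are isolated so
  an alternative reading can be swapped in.
* Counts rely on exact double-integer arithmetic below 2⁵³ — ample here,
  but a reimplementation for longer sequences would need big integers.
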