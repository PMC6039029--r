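# geolot

Bayesian validation of grammar productions for a *language of geometry*.

Cognitive models in the Language-of-Thought (LoT) tradition describe mental
representations as programs: small symbolic expressions built from atomic
operations by combinatorial rules. `geolot` implements the full analysis
pipeline for one such model — a context-free grammar whose programs describe
movement sequences on the eight labelled vertices of a regular octagon
(alphabet Σ = {0..7}, labels increasing clockwise) — and for the Bayesian
machinery that *validates* the grammar's production inventory from
behavioural data:

1. **Grammar & semantics.** Programs are derivation trees built from atomic
   moves (`+1`…`+3` clockwise, `-1`…`-3` anticlockwise, `+0` stay, four axial
   reflections `A,B,H,V`, the half-turn `P`), binary concatenation, and three
   repetition operators (`REP[...]^n` plain, `REP1<sym>[...]^n` with
   starting-point variation, `REP2<sym>[...]^n` with pointwise variation of
   the resulting sequence). An extended inventory adds 11 deliberately
   implausible *ad-hoc* atomics (doubling, squaring, factorial mod 8, digit
   lookups of π, e, φ, √2, Khinchin's, Glaisher's and Chaitin's constants)
   used to test whether inference prunes them.
2. **Exhaustive program enumeration.** For an observed trial (anchor `s`,
   sequence `x`) the package enumerates — or counts, or integrates over,
   without materialising — *every* derivation tree `p` with `p(s) = x`, via
   an exact dynamic program over derivation requirements (hash-consed in
   C++).
3. **Posterior inference.** The grammar becomes a PCFG with a probability
   vector θ over productions (normalised within each nonterminal). A Gibbs
   sampler alternates exact draws of each trial's explaining program given θ
   with conjugate Dirichlet draws of θ given the sampled production counts:

   ```
   P(Prog | θ, D) = Π_i P(p_i | d_i, θ)          (exact, via the DP)
   P(θ | Prog, D) = Dirichlet(f(Prog) + α)       (conjugate update)
   ```

   where `P(p | θ) ∝ Π_r θ_r^{f_r(p)}` with `f_r(p)` the number of uses of
   production `r`, and the likelihood is exact-match (a program either
   computes the observed sequence or has likelihood zero).
4. **Complexity and algorithmic probability.** `K_Geo(s, x)` is the minimal
   description length over all explaining programs (atomic = 2 units,
   repetition adds ⌊log₂ n⌋, concatenation is additive);
   `P_Geo(x) ∝ Σ_p P(p | θ)` sums probability over all explaining programs.
   Both are computed exactly from the same DP (min-plus and sum-product
   evaluations). `coding_theorem_experiment()` tests the empirical analogue
   of Levin's Coding Theorem — `log 1/P(x) ≈ K(x)` — for this non-universal
   language.
5. **Synthetic data.** Because the behavioural datasets are not deposited,
   `generate_dataset()` produces trials with the statistical structure the
   inference assumes: programs drawn from the PCFG under a ground-truth θ
   (exact length-conditioned sampling via inside weights), executed from
   uniform anchors, with optional point-replacement noise.

## Worked example

```r
library(geolot)
g <- geo_grammar()                      # 12 original atomics, rep n in [2,8]

p <- parse_program("[REP[+1, -1]^4]", g)
execute_program(p, 6, g)
#> [1] 7 6 7 6 7 6 7 6                   # alternates between vertices 7 and 6

enumerate_programs(6, c(7, 6, 7, 6), g)
#> <geo_enumeration> anchor 6, sequence (7,6,7,6): 441 programs
sequence_complexity(6, c(7, 6, 7, 6), g)
#> [1] 4                                 # e.g. [REP[A]^4]: 2 + floor(log2 4)

ds <- generate_dataset(generator_config(n_trials = 300, L = 8, seed = 1), g)
post <- gibbs_infer(ds, g, inference_config(seed = 2))   # 4 chains x 50 steps
head(post$summary[order(-post$summary$mean), ], 4)
#>     production mean      se
#> 1 START:[INST] 1.00 0.00000
#> 5     REP:REP0 0.59 0.00262
#> 2  INST:ATOMIC 0.48 0.00134
#> 4     INST:REP 0.37 0.00148

theta <- make_theta(setNames(post$summary$mean, post$summary$production), g)
sequence_probability(0, c(1, 2, 3, 4, 5, 6, 7, 0), g, theta)  # simple loop
#> [1] 0.001776627
sequence_probability(0, c(5, 0, 3, 6, 2, 7, 1, 4), g, theta)  # irregular
#> [1] 9.33326e-12
```

The loop around the octagon is both far more probable (10⁻³ vs 10⁻¹²) and
far simpler (K = 5 vs K = 12) than an irregular sequence of the same
length — the inverse relation the Coding-Theorem experiment quantifies:

```r
ct <- coding_theorem_experiment(theta, g, lengths = 5, max_n = 10000)
ct$fits
#>   length      slope intercept r_squared n_sequences
#> 1      5 -0.9652... 0.83...       0.97        10000
```

To test pruning, generate data from the original productions and infer
under the extended grammar: every ad-hoc production's posterior mean falls
below every originally used atomic (see `parameter_recovery_report()`).

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "geolot", package = "geolot")`): subcommands
`simulate`, `enumerate`, `infer`, `complexity`, `probability`,
`coding-theorem`, `compare`, all with `--seed`, `--grammar` and `--out`.

## Notes

- Positions are 0-based everywhere. Behavioural files with 1-based vertex
  labels must be shifted before loading (`read_trials()`).
- Program counts use double-precision arithmetic; they are exact integers
  well below 2⁵³ at the sequence lengths this grammar admits (≤ 8).
- The Chaitin digit table is a documented, editable fixture derived from a
  published 84-bit approximation of one particular Ω; see
  `geo_grammar(digits = ...)`.
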