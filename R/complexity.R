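# Minimal description length of a sequence relative to the language of
# geometry: the minimum program cost over all explaining derivation trees.

#' Minimal description length of a sequence
#'
#' The minimum of [program_cost()] over every program that computes the
#' sequence from the anchor, computed by the min-plus form of the
#' enumeration DP (no program list is materialised). Cost rules: each
#' atomic instruction 2 units, concatenation additive, a repetition adds
#' \code{floor(log2(n))} plus the atomic cost of a REP1/REP2 parameter.
#'
#' @inheritParams enumerate_programs
#' @param atomic_cost,param_cost see [program_cost()].
#' @return Numeric complexity (description-length units).
#' @examples
#' g <- geo_grammar()
#' sequence_complexity(0, c(1, 2, 3, 4, 5, 6, 7, 0), g) # 5, via [REP[+1]^8]
#' @export
sequence_complexity <- function(anchor, sequence, g, atomic_cost = 2,
                                param_cost = atomic_cost) {
  circ <- .geo_circuit(anchor, sequence, g)
  k <- .circuit_min_cost(circ, atomic_cost, param_cost)
  if (!is.finite(k))
    stop("no explaining program for anchor ", anchor, ", sequence (",
         paste(sequence, collapse = ","), ")")
  k
}

#' Complexity of every trial in a dataset
#'
#' @param dataset a \code{geo_trials}.
#' @param g a \code{geo_grammar}.
#' @return The dataset's data frame with a \code{k_geo} column appended.
#' @export
dataset_complexity <- function(dataset, g) {
  trials <- as_trial_list(dataset)
  k <- vapply(trials, function(tr)
    sequence_complexity(tr$anchor, tr$sequence, g), numeric(1))
  df <- as.data.frame(dataset)
  df$k_geo <- k
  df
}
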