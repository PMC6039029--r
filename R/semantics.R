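# Execution semantics: programs are mappings from a start vertex to a
# non-empty point sequence on the octagon (alphabet 0..7).

#' Apply one atomic instruction
#'
#' Atomic instructions are position-to-position maps: \code{+k}/\code{-k}
#' move k vertices clockwise/anticlockwise, \code{+0} stays, the four
#' reflections map \code{pos} to \code{(c - pos) mod 8} for their axis
#' constant, \code{P} is the half-turn \code{(pos + 4) mod 8}, and the
#' ad-hoc instructions apply their arithmetic or digit-table rule.
#'
#' @param symbol atomic symbol name.
#' @param pos integer position(s) in 0..7 (vectorised).
#' @param g a \code{geo_grammar}.
#' @return Integer position(s) in 0..7.
#' @examples
#' g <- geo_grammar(include_adhoc = TRUE)
#' apply_atomic("PI", 0, g) # 3: leading digit of pi, mod 8
#' @export
apply_atomic <- function(symbol, pos, g) {
  if (!symbol %in% g$symbols)
    stop("unknown atomic symbol under this grammar: ", symbol)
  pos <- .check_positions(pos)
  unname(g$atom_table[symbol, pos + 1L])
}

#' Execute a program from an anchor position
#'
#' Runs the derivation tree as a sequence of octagon moves. An atomic node
#' emits one point; concatenation emits the left part then the right part,
#' threading the current position (the last emitted point). REP0 executes
#' its block n times, threading the position across cycles. REP1 varies the
#' *starting point*: cycle 1 starts at the incoming position and each later
#' cycle starts at the parameter applied to the previous cycle's start.
#' REP2 varies the *resulting sequence*: cycle 1 is the block's output and
#' each later cycle is the previous cycle's output with the parameter
#' applied pointwise. After any repetition the threaded position is the last
#' emitted point.
#'
#' @param p a \code{geo_program} (or its text notation).
#' @param anchor starting position in 0..7 (not itself emitted).
#' @param g a \code{geo_grammar}.
#' @return Integer vector of emitted positions, length
#'   \code{output_length(p)}.
#' @examples
#' g <- geo_grammar()
#' execute_program(parse_program("[+1, +1]", g), 0, g) # 1 2
#' execute_program(parse_program("[REP[A]^8]", g), 6, g)
#' @export
execute_program <- function(p, anchor, g) {
  if (is.character(p)) p <- parse_program(p, g)
  .validate_program(p, g)
  anchor <- .check_positions(anchor, "anchor")
  stopifnot(length(anchor) == 1L)
  tab <- g$atom_table
  run <- function(q, pos) {
    switch(q$kind,
      atomic = tab[q$symbol, pos + 1L],
      concat = {
        l <- run(q$left, pos)
        c(l, run(q$right, l[length(l)]))
      },
      rep0 = {
        out <- integer(0)
        for (i in seq_len(q$n)) {
          cyc <- run(q$block, pos)
          out <- c(out, cyc)
          pos <- cyc[length(cyc)]
        }
        out
      },
      rep1 = {
        out <- integer(0)
        start <- pos
        for (i in seq_len(q$n)) {
          out <- c(out, run(q$block, start))
          start <- tab[q$param, start + 1L]
        }
        out
      },
      rep2 = {
        cyc <- run(q$block, pos)
        out <- cyc
        for (i in seq_len(q$n - 1L)) {
          cyc <- unname(tab[q$param, cyc + 1L])
          out <- c(out, cyc)
        }
        out
      })
  }
  unname(run(p, anchor))
}

#' Atomic symbols mapping one position to another
#'
#' The kernel of the enumeration: which atomic instructions explain a single
#' observed step.
#'
#' @param from_pos,to_pos positions in 0..7.
#' @param g a \code{geo_grammar}.
#' @return Character vector of atomic symbols \code{a} with
#'   \code{apply_atomic(a, from_pos, g) == to_pos}.
#' @examples
#' valid_atomics(0, 4, geo_grammar()) # "P"
#' @export
valid_atomics <- function(from_pos, to_pos, g) {
  from_pos <- .check_positions(from_pos)
  to_pos <- .check_positions(to_pos)
  stopifnot(length(from_pos) == 1L, length(to_pos) == 1L)
  g$symbols[g$atom_table[, from_pos + 1L] == to_pos]
}
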