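# Exhaustive enumeration of the derivation trees that explain an observed
# sequence, by span dynamic programming over derivation requirements.

#' Enumerate all programs explaining a sequence
#'
#' Finds the complete set of derivation trees \code{p} with
#' \code{execute_program(p, anchor, g) == sequence}. The span dynamic
#' programming shares sub-results across decompositions, handles all binary
#' association orders of concatenation, and resolves the shared block of a
#' repetition through the intersection of its per-cycle constraints, so the
#' count is exact even when the program list is withheld.
#'
#' @param anchor starting position in 0..7.
#' @param sequence integer vector of observed positions (length >= 1).
#' @param g a \code{geo_grammar}.
#' @param materialize_limit maximum number of programs to materialise; when
#'   the exact count exceeds it, \code{programs} is \code{NULL} but
#'   \code{count} is still exact.
#' @return An object of class \code{geo_enumeration}: \code{anchor},
#'   \code{sequence}, \code{count}, and \code{programs} (a list of
#'   \code{geo_program}, or \code{NULL} when withheld).
#' @examples
#' g <- geo_grammar()
#' enumerate_programs(0, c(4), g)$count # 1: only [P]
#' @export
enumerate_programs <- function(anchor, sequence, g,
                               materialize_limit = 1e7) {
  circ <- .geo_circuit(anchor, sequence, g)
  count <- .circuit_count(circ)
  programs <- NULL
  if (count <= materialize_limit && count > 0)
    programs <- .circuit_trees(circ, g, limit = materialize_limit)
  structure(list(anchor = circ$anchor, sequence = circ$sequence,
                 count = count, programs = programs,
                 grammar_hash = g$hash),
            class = "geo_enumeration")
}

#' @export
print.geo_enumeration <- function(x, ...) {
  cat(sprintf("<geo_enumeration> anchor %d, sequence (%s): %s program%s%s\n",
              x$anchor, paste(x$sequence, collapse = ","),
              format(x$count, big.mark = ","), if (x$count == 1) "" else "s",
              if (is.null(x$programs)) " (not materialised)" else ""))
  invisible(x)
}

#' Count programs explaining a sequence without materialising them
#'
#' The counting form of the enumeration DP. Counts are exact integers held
#' in doubles (far below 2^53 at the lengths this grammar admits).
#'
#' @inheritParams enumerate_programs
#' @return Numeric count (an exact integer value).
#' @export
count_programs <- function(anchor, sequence, g) {
  .circuit_count(.geo_circuit(anchor, sequence, g))
}

#' Brute-force enumeration oracle
#'
#' Generates every derivation tree of the grammar with the requested output
#' length by exhaustive grammar expansion — compositional tables of each
#' tree's execution from all eight anchors — then filters by execution
#' equality. Independent of the span DP; intended for validation at small
#' lengths.
#'
#' @inheritParams enumerate_programs
#' @param max_len refuse sequences longer than this (hard ceiling 5).
#' @return A \code{geo_enumeration} whose \code{programs} holds serialized
#'   program texts.
#' @export
brute_force_enumerate <- function(anchor, sequence, g, max_len = 5L) {
  anchor <- .check_positions(anchor, "anchor")
  sequence <- .check_positions(sequence, "sequence")
  if (max_len > 5L) stop("brute-force oracle refuses max_len > 5")
  L <- length(sequence)
  if (L > max_len) stop("sequence longer than max_len = ", max_len)
  sp <- .brute_space(L, g)
  if (L == 1L) {
    hit <- sp$out[anchor + 1L, 1L, ] == sequence
  } else {
    hit <- colSums(sp$out[anchor + 1L, , ] == sequence) == L
  }
  structure(list(anchor = anchor, sequence = sequence,
                 count = sum(hit),
                 programs = paste0("[", sp$inner[hit], "]"),
                 grammar_hash = g$hash),
            class = "geo_enumeration")
}

# Cache of brute-force spaces, keyed by grammar hash and length.
.brute_cache <- new.env(parent = emptyenv())

# A "space" of all trees with output length L: serialized texts (inner =
# comma-flattened form, elem = bracketed element form) plus, per tree, the
# 8 x L matrix of outputs from every anchor and the 8-vector of final
# positions. Built compositionally, one vectorised block per combination
# rule, so no tree is ever executed point by point.
.brute_space <- function(L, g) {
  key <- paste0(g$hash, ":", L)
  if (!is.null(.brute_cache[[key]])) return(.brute_cache[[key]])
  tab <- g$atom_table
  nsym <- length(g$symbols)

  if (L == 1L) {
    out <- array(t(tab), dim = c(8, 1, nsym))
    sp <- list(inner = g$symbols, elem = g$symbols, out = out,
               last = matrix(t(tab), nrow = 8))
    .brute_cache[[key]] <- sp
    return(sp)
  }

  parts <- list()
  # concatenation splits
  for (k in seq_len(L - 1L)) {
    left <- .brute_space(k, g); right <- .brute_space(L - k, g)
    nl <- length(left$inner); nr <- length(right$inner)
    out <- array(NA_integer_, dim = c(8, L, nl * nr))
    last <- matrix(NA_integer_, 8, nl * nr)
    inner <- character(nl * nr)
    for (i in seq_len(nl)) {
      idx <- (i - 1L) * nr + seq_len(nr)
      perm <- left$last[, i] + 1L
      out[, seq_len(k), idx] <- array(left$out[, , i], dim = c(8, k, nr))
      out[, k + seq_len(L - k), idx] <-
        right$out[perm, , , drop = FALSE]
      last[, idx] <- right$last[perm, , drop = FALSE]
      inner[idx] <- paste0(left$inner[i], ", ", right$elem)
    }
    parts[[length(parts) + 1L]] <-
      list(inner = inner, elem = paste0("[", inner, "]"), out = out,
           last = last)
  }

  # repetitions
  for (n in seq(max(2L, g$rep_range[1]), g$rep_range[2])) {
    if (L %% n != 0L) next
    bl <- L %/% n
    blk <- .brute_space(bl, g)
    nb <- length(blk$inner)

    # REP0: thread the final position across cycles
    out <- array(NA_integer_, dim = c(8, L, nb))
    pc <- matrix(seq_len(8), 8, nb)  # current start row per anchor x tree
    colidx <- rep((seq_len(nb) - 1L) * 8L, each = 8L)
    for (cy in seq_len(n)) {
      flat <- as.vector(pc) + colidx * bl  # row + 8*bl*(tree-1), col offset next
      # index into blk$out (8 x bl x nb): element (r, t, j) at r + 8*(t-1) + 8*bl*(j-1)
      for (t in seq_len(bl))
        out[, (cy - 1L) * bl + t, ] <- blk$out[flat + 8L * (t - 1L)]
      pc <- matrix(blk$last[as.vector(pc) + colidx] + 1L, 8, nb)
    }
    parts[[length(parts) + 1L]] <- list(
      inner = paste0("REP[", blk$inner, "]^", n),
      elem = paste0("REP[", blk$inner, "]^", n),
      out = out, last = matrix(out[, L, ], 8, nb))

    for (s in seq_len(nsym)) {
      sym <- g$symbols[s]
      # REP1<sym>: cycle starts are sym-iterated from the anchor
      out <- array(NA_integer_, dim = c(8, L, nb))
      starts <- seq_len(8)  # 1-based rows
      for (cy in seq_len(n)) {
        out[, (cy - 1L) * bl + seq_len(bl), ] <-
          blk$out[starts, , , drop = FALSE]
        starts <- tab[s, starts] + 1L
      }
      parts[[length(parts) + 1L]] <- list(
        inner = paste0("REP1<", sym, ">[", blk$inner, "]^", n),
        elem = paste0("REP1<", sym, ">[", blk$inner, "]^", n),
        out = out, last = matrix(out[, L, ], 8, nb))

      # REP2<sym>: pointwise images of the previous cycle
      out <- array(NA_integer_, dim = c(8, L, nb))
      cyc <- blk$out
      out[, seq_len(bl), ] <- cyc
      if (n > 1L) for (cy in 2L:n) {
        cyc <- array(tab[s, cyc + 1L], dim = dim(cyc))
        out[, (cy - 1L) * bl + seq_len(bl), ] <- cyc
      }
      parts[[length(parts) + 1L]] <- list(
        inner = paste0("REP2<", sym, ">[", blk$inner, "]^", n),
        elem = paste0("REP2<", sym, ">[", blk$inner, "]^", n),
        out = out, last = matrix(out[, L, ], 8, nb))
    }
  }

  sp <- list(
    inner = unlist(lapply(parts, `[[`, "inner")),
    elem = unlist(lapply(parts, `[[`, "elem")),
    out = array(unlist(lapply(parts, `[[`, "out")),
                dim = c(8, L, sum(vapply(parts, function(p) dim(p$out)[3], 0)))),
    last = do.call(cbind, lapply(parts, `[[`, "last")))
  .brute_cache[[key]] <- sp
  sp
}
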