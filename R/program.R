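# Programs are derivation trees: atomic leaves, binary concatenations, and
# the three repetition nodes. Stored as plain nested lists of class
# "geo_program".

.new_program <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "geo_program")
}

#' Program constructors
#'
#' Build derivation trees by hand: an atomic instruction, a binary
#' concatenation, a plain repetition (REP0), a repetition with
#' starting-point variation (REP1) or a repetition with pointwise variation
#' of the resulting sequence (REP2). REP1/REP2 carry an atomic parameter
#' expanded through the ATOMIC nonterminal, so it contributes to production
#' counts and probability.
#'
#' @param symbol,param atomic symbol name (e.g. \code{"+1"}, \code{"A"}).
#' @param left,right,block sub-programs.
#' @param n repetition count.
#' @return A \code{geo_program}.
#' @examples
#' p <- geo_concat(geo_atomic("+1"), geo_atomic("+1"))
#' serialize_program(p)
#' @export
geo_atomic <- function(symbol) .new_program("atomic", symbol = symbol)

#' @rdname geo_atomic
#' @export
geo_concat <- function(left, right) .new_program("concat", left = left, right = right)

#' @rdname geo_atomic
#' @export
geo_rep0 <- function(block, n) .new_program("rep0", block = block, n = as.integer(n))

#' @rdname geo_atomic
#' @export
geo_rep1 <- function(block, n, param)
  .new_program("rep1", block = block, n = as.integer(n), param = param)

#' @rdname geo_atomic
#' @export
geo_rep2 <- function(block, n, param)
  .new_program("rep2", block = block, n = as.integer(n), param = param)

#' @export
print.geo_program <- function(x, ...) {
  cat(serialize_program(x), "\n")
  invisible(x)
}

#' @export
format.geo_program <- function(x, ...) serialize_program(x)

.validate_program <- function(p, g) {
  stopifnot(inherits(p, "geo_program"))
  switch(p$kind,
    atomic = {
      if (!p$symbol %in% g$symbols)
        stop("unknown atomic symbol under this grammar: ", p$symbol)
    },
    concat = {
      .validate_program(p$left, g); .validate_program(p$right, g)
    },
    {
      if (p$n < g$rep_range[1] || p$n > g$rep_range[2])
        stop("repetition count ", p$n, " outside rep_range [",
             g$rep_range[1], ", ", g$rep_range[2], "]")
      if (p$kind != "rep0" && !p$param %in% g$symbols)
        stop("unknown atomic symbol under this grammar: ", p$param)
      .validate_program(p$block, g)
    }
  )
  invisible(TRUE)
}

#' Number of points a program emits
#'
#' Computed structurally: 1 for an atomic instruction, the sum for a
#' concatenation, and n times the block length for every repetition variant.
#'
#' @param p a \code{geo_program}.
#' @return Integer output length.
#' @export
output_length <- function(p) {
  switch(p$kind,
    atomic = 1L,
    concat = output_length(p$left) + output_length(p$right),
    p$n * output_length(p$block)
  )
}

# ---- serialization ---------------------------------------------------------

# Canonical notation. Comma lists are left-associated on parse, so only
# left-branching concatenation chains are flattened; a right concat operand
# is printed as a bracketed group, keeping parse(serialize(p)) == p exact.
.serialize_elem <- function(p) {
  switch(p$kind,
    atomic = p$symbol,
    concat = paste0("[", .serialize_inner(p), "]"),
    rep0 = paste0("REP[", .serialize_inner(p$block), "]^", p$n),
    rep1 = paste0("REP1<", p$param, ">[", .serialize_inner(p$block), "]^", p$n),
    rep2 = paste0("REP2<", p$param, ">[", .serialize_inner(p$block), "]^", p$n)
  )
}

.serialize_inner <- function(p) {
  if (p$kind == "concat")
    paste0(.serialize_inner(p$left), ", ", .serialize_elem(p$right))
  else .serialize_elem(p)
}

#' Serialize a program to its text notation
#'
#' @param p a \code{geo_program}.
#' @return A single string, e.g. \code{"[REP[+1]^8]"}.
#' @seealso [parse_program()]
#' @export
serialize_program <- function(p) {
  stopifnot(inherits(p, "geo_program"))
  paste0("[", .serialize_inner(p), "]")
}

# ---- parsing ---------------------------------------------------------------

.tokenize_program <- function(text, g) {
  fixed <- c("REP1", "REP2", "REP", "[", "]", "<", ">", ",", "^")
  # longest-first so "-DOUBLE" beats "-1" etc.
  syms <- g$symbols[order(nchar(g$symbols), decreasing = TRUE)]
  toks <- list(); pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    if (grepl("^\\s", rest)) { pos <- pos + 1L; next }
    m <- regmatches(rest, regexpr("^[0-9]+", rest))
    hit <- NULL
    for (cand in c(fixed, syms)) {
      if (startsWith(rest, cand)) { hit <- cand; break }
    }
    # numbers only appear after "^"; symbol names win elsewhere
    if (length(m) == 1 && (length(toks) > 0 && toks[[length(toks)]]$t == "^")) {
      toks[[length(toks) + 1L]] <- list(t = "int", v = as.integer(m), pos = pos)
      pos <- pos + nchar(m)
    } else if (!is.null(hit)) {
      type <- if (hit %in% fixed) hit else "sym"
      toks[[length(toks) + 1L]] <- list(t = type, v = hit, pos = pos)
      pos <- pos + nchar(hit)
    } else {
      stop("parse error at position ", pos, ": unknown token near '",
           substr(text, pos, min(n, pos + 7L)), "'")
    }
  }
  toks
}

#' Parse the text notation into a program
#'
#' The notation is a comma-separated instruction list in square brackets.
#' Instructions are atomic symbols, bracketed sub-lists, or repetitions
#' written \code{REP[...]^n}, \code{REP1<sym>[...]^n}, \code{REP2<sym>[...]^n}.
#' Comma lists denote the left-associated binary concatenation tree; other
#' association orders are written with nested brackets (and all associations
#' are generated by the enumerator, which works over derivation trees).
#'
#' @param text program notation, e.g. \code{"[REP[+1]^8]"}.
#' @param g a \code{geo_grammar} (defines the symbol inventory and the
#'   admissible repetition counts).
#' @return A \code{geo_program}.
#' @examples
#' g <- geo_grammar()
#' parse_program("[+1, +1]", g)
#' @export
parse_program <- function(text, g = geo_grammar(include_adhoc = TRUE)) {
  toks <- .tokenize_program(text, g)
  st <- new.env(parent = emptyenv())
  st$i <- 1L; st$toks <- toks
  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  take <- function(type = NULL) {
    tk <- peek()
    if (is.null(tk))
      stop("parse error: unexpected end of input")
    if (!is.null(type) && tk$t != type)
      stop("parse error at position ", tk$pos, ": expected '", type,
           "', found '", tk$v, "'")
    st$i <- st$i + 1L
    tk
  }
  parse_list <- function() {
    acc <- parse_item()
    while (!is.null(peek()) && peek()$t == ",") {
      take(",")
      acc <- geo_concat(acc, parse_item())
    }
    acc
  }
  parse_item <- function() {
    tk <- peek()
    if (is.null(tk)) stop("parse error: unexpected end of input")
    if (tk$t == "sym") { take(); return(geo_atomic(tk$v)) }
    if (tk$t == "[") {
      take("["); out <- parse_list(); take("]"); return(out)
    }
    if (tk$t %in% c("REP", "REP1", "REP2")) {
      kind <- take()$t
      param <- NULL
      if (kind %in% c("REP1", "REP2")) {
        take("<"); param <- take("sym")$v; take(">")
      }
      take("["); block <- parse_list(); take("]"); take("^")
      ntk <- take("int")
      if (ntk$v < g$rep_range[1] || ntk$v > g$rep_range[2])
        stop("parse error at position ", ntk$pos, ": repetition count ",
             ntk$v, " outside rep_range [", g$rep_range[1], ", ",
             g$rep_range[2], "]")
      return(switch(kind,
        REP = geo_rep0(block, ntk$v),
        REP1 = geo_rep1(block, ntk$v, param),
        REP2 = geo_rep2(block, ntk$v, param)))
    }
    stop("parse error at position ", tk$pos, ": unexpected '", tk$v, "'")
  }
  take("[")
  out <- parse_list()
  take("]")
  if (!is.null(peek()))
    stop("parse error at position ", peek()$pos, ": trailing input")
  .validate_program(out, g)
  out
}

# ---- production counts and cost -------------------------------------------

#' Count production applications in a derivation tree
#'
#' Counts every production used to derive \code{p}: the start production,
#' the structural choices at each sequence node, the repetition-variant
#' choices, the atomic-symbol choices, and the ATOMIC expansion of REP1/REP2
#' parameters. These are the sufficient statistics of the Dirichlet update.
#'
#' @param p a \code{geo_program}.
#' @param g a \code{geo_grammar}.
#' @return Named integer vector over \code{production_ids(g)}.
#' @export
production_counts <- function(p, g) {
  .validate_program(p, g)
  f <- setNames(integer(nrow(g$productions)), g$productions$id)
  bump <- function(id) f[id] <<- f[id] + 1L
  walk <- function(q) {
    switch(q$kind,
      atomic = { bump("INST:ATOMIC"); bump(paste0("ATOMIC:", q$symbol)) },
      concat = { bump("INST:CONCAT"); walk(q$left); walk(q$right) },
      rep0 = { bump("INST:REP"); bump("REP:REP0"); walk(q$block) },
      rep1 = { bump("INST:REP"); bump("REP:REP1")
               bump(paste0("ATOMIC:", q$param)); walk(q$block) },
      rep2 = { bump("INST:REP"); bump("REP:REP2")
               bump(paste0("ATOMIC:", q$param)); walk(q$block) })
  }
  bump("START:[INST]")
  walk(p)
  f
}

#' Description length of a program
#'
#' Each atomic instruction costs 2 units; a repetition costs its block plus
#' \code{floor(log2(n))} (plus the atomic cost of the REP1/REP2 parameter);
#' concatenation is additive. The log base and the parameter cost follow the
#' package's description-length convention and are configurable.
#'
#' @param p a \code{geo_program}.
#' @param atomic_cost cost of one atomic instruction (default 2).
#' @param param_cost cost of a REP1/REP2 parameter (default
#'   \code{atomic_cost}).
#' @return Numeric cost.
#' @examples
#' program_cost(geo_rep0(geo_atomic("+1"), 8)) # 2 + floor(log2(8)) = 5
#' @export
program_cost <- function(p, atomic_cost = 2, param_cost = atomic_cost) {
  switch(p$kind,
    atomic = atomic_cost,
    concat = program_cost(p$left, atomic_cost, param_cost) +
      program_cost(p$right, atomic_cost, param_cost),
    rep0 = program_cost(p$block, atomic_cost, param_cost) + floor(log2(p$n)),
    program_cost(p$block, atomic_cost, param_cost) + floor(log2(p$n)) +
      param_cost
  )
}
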