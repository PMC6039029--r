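#' @useDynLib geolot, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rgamma sd t.test p.adjust lm coef setNames runif acf
NULL

# Atomic symbol inventories. Order is the stable production order used
# everywhere (theta vectors, traces, result files).
.GEO_ORIGINAL_SYMBOLS <- c("-1", "-2", "-3", "+0", "+1", "+2", "+3",
                           "A", "B", "H", "V", "P")
.GEO_ADHOC_SYMBOLS <- c("DOUBLE", "-DOUBLE", "SQUARE", "GAMMA", "PI", "EULER",
                        "GOLD", "PYTH", "KHINCHIN", "GLAISHER", "CHAITIN")

# Leading base-10 digits of each constant, reduced mod 8 (index 0 is the
# leading printed digit, so PI(0) = 3, PI(1) = 1). CHAITIN uses a published
# 84-bit approximation of one particular Omega (0.0078749969...); it is an
# editable fixture, not a canonical value.
.GEO_DIGIT_TABLES <- list(
  PI       = c(3, 1, 4, 1, 5, 9, 2, 6) %% 8,
  EULER    = c(2, 7, 1, 8, 2, 8, 1, 8) %% 8,
  GOLD     = c(1, 6, 1, 8, 0, 3, 3, 9) %% 8,
  PYTH     = c(1, 4, 1, 4, 2, 1, 3, 5) %% 8,
  KHINCHIN = c(2, 6, 8, 5, 4, 5, 2, 0) %% 8,
  GLAISHER = c(1, 2, 8, 2, 4, 2, 7, 1) %% 8,
  CHAITIN  = c(0, 0, 7, 8, 7, 4, 9, 9) %% 8
)

.GEO_DEFAULT_AXES <- c(A = 5, B = 1, H = 7, V = 3)

#' Build the language-of-geometry grammar
#'
#' Constructs the production inventory of the geometric language: the start
#' production, the three structural productions of the sequence nonterminal
#' (atomic, concatenation, repetition), the three repetition variants, and
#' the atomic transition productions. The original inventory has 12 atomic
#' productions (clockwise/anticlockwise steps, stay, five symmetries); the
#' extended inventory adds 11 deliberately implausible "ad-hoc" productions
#' (doubling, squaring, factorial, and digit lookups of famous constants)
#' used to test whether Bayesian inference prunes them.
#'
#' Positions are the vertex labels 0..7 of a regular octagon, increasing
#' clockwise. Reflections are the permutations \code{pos -> (c - pos) mod 8}
#' with an odd constant \code{c} per axis; the default constants pin axis A
#' to \code{c = 5} (so A swaps 6 and 7) and assign B, H, V the remaining odd
#' constants. Repetition counts \code{n} range over \code{rep_range}
#' (a sub-interval of [2, 8]) and are drawn uniformly, not theta-weighted.
#'
#' @param include_adhoc logical; add the 11 ad-hoc atomic productions.
#' @param axes named integer vector mapping \code{A,B,H,V} to distinct odd
#'   reflection constants in \{1,3,5,7\}.
#' @param rep_range integer vector \code{c(lo, hi)} of allowed repetition
#'   counts, within [2, 8].
#' @param digits optional named list overriding the built-in digit tables
#'   (each entry 8 integers in 0..7); only the CHAITIN fixture is expected
#'   to need replacement.
#' @return An object of class \code{geo_grammar}: production table, atomic
#'   transition tables, and configuration.
#' @examples
#' g <- geo_grammar()
#' nrow(g$productions)
#' ge <- geo_grammar(include_adhoc = TRUE)
#' sum(ge$productions$family == "adhoc")
#' @export
geo_grammar <- function(include_adhoc = FALSE,
                        axes = .GEO_DEFAULT_AXES,
                        rep_range = c(2L, 8L),
                        digits = NULL) {
  axes <- axes[c("A", "B", "H", "V")]
  if (anyNA(axes) || length(axes) != 4L)
    stop("`axes` must name all of A, B, H, V")
  if (any(axes %% 2L == 0L) || anyDuplicated(axes) ||
      any(axes < 1L | axes > 7L))
    stop("axis constants must be distinct odd values in {1,3,5,7}")
  rep_range <- as.integer(rep_range)
  if (length(rep_range) != 2L || rep_range[1] > rep_range[2] ||
      rep_range[1] < 2L || rep_range[2] > 8L)
    stop("`rep_range` must be an interval within [2, 8]")

  digit_tables <- .GEO_DIGIT_TABLES
  if (!is.null(digits)) {
    for (nm in names(digits)) {
      v <- as.integer(digits[[nm]])
      if (length(v) != 8L || any(v < 0L | v > 7L))
        stop("digit table for ", nm, " must be 8 integers in 0..7")
      digit_tables[[nm]] <- v
    }
  }

  symbols <- .GEO_ORIGINAL_SYMBOLS
  if (include_adhoc) symbols <- c(symbols, .GEO_ADHOC_SYMBOLS)

  atom_table <- .build_atom_table(symbols, axes, digit_tables)

  atom_family <- function(sym) {
    if (sym %in% c("-1", "-2", "-3")) "acw"
    else if (sym == "+0") "stay"
    else if (sym %in% c("+1", "+2", "+3")) "cw"
    else if (sym %in% c("A", "B", "H", "V", "P")) "symmetry"
    else "adhoc"
  }
  productions <- rbind(
    data.frame(id = "START:[INST]", lhs = "START", rhs_kind = "start",
               symbol = NA_character_, family = "start"),
    data.frame(id = c("INST:ATOMIC", "INST:CONCAT", "INST:REP"),
               lhs = "INST",
               rhs_kind = c("atomic_leaf", "concat", "rep_apply"),
               symbol = NA_character_,
               family = c("basic", "concat", "rep")),
    data.frame(id = c("REP:REP0", "REP:REP1", "REP:REP2"),
               lhs = "REP", rhs_kind = c("rep0", "rep1", "rep2"),
               symbol = NA_character_, family = "rep"),
    data.frame(id = paste0("ATOMIC:", symbols), lhs = "ATOMIC",
               rhs_kind = "atomic_symbol", symbol = symbols,
               family = vapply(symbols, atom_family, character(1)))
  )
  rownames(productions) <- NULL

  g <- structure(list(
    productions = productions,
    symbols = symbols,
    atom_table = atom_table,
    include_adhoc = include_adhoc,
    rep_range = rep_range,
    axes = axes,
    digit_tables = digit_tables
  ), class = "geo_grammar")
  g$hash <- .grammar_hash(g)
  g
}

# 8-column lookup table: row = symbol, column = current position + 1,
# value = next position. All semantics of atomic productions live here.
.build_atom_table <- function(symbols, axes, digit_tables) {
  pos <- 0:7
  tab <- matrix(NA_integer_, nrow = length(symbols), ncol = 8,
                dimnames = list(symbols, NULL))
  for (sym in symbols) {
    tab[sym, ] <- as.integer(switch(sym,
      "-1" = (pos - 1) %% 8, "-2" = (pos - 2) %% 8, "-3" = (pos - 3) %% 8,
      "+0" = pos,
      "+1" = (pos + 1) %% 8, "+2" = (pos + 2) %% 8, "+3" = (pos + 3) %% 8,
      "A" = (axes[["A"]] - pos) %% 8, "B" = (axes[["B"]] - pos) %% 8,
      "H" = (axes[["H"]] - pos) %% 8, "V" = (axes[["V"]] - pos) %% 8,
      "P" = (pos + 4) %% 8,
      "DOUBLE" = (2 * pos) %% 8,
      "-DOUBLE" = (-2 * pos) %% 8,
      "SQUARE" = (pos^2) %% 8,
      "GAMMA" = factorial(pos) %% 8,
      digit_tables[[sym]]
    ))
  }
  tab
}

.grammar_hash <- function(g) {
  desc <- jsonlite::toJSON(list(
    symbols = g$symbols, atom_table = g$atom_table,
    rep_range = g$rep_range
  ), auto_unbox = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(desc), f)
  unname(tools::md5sum(f))
}

#' @export
print.geo_grammar <- function(x, ...) {
  cat(sprintf("<geo_grammar> %d productions (%d atomic%s), rep n in [%d, %d]\n",
              nrow(x$productions), length(x$symbols),
              if (x$include_adhoc) ", incl. 11 ad-hoc" else "",
              x$rep_range[1], x$rep_range[2]))
  invisible(x)
}

#' Production identifiers of a grammar
#'
#' @param g a \code{geo_grammar}.
#' @return Character vector of stable production ids ("LHS:label").
#' @export
production_ids <- function(g) g$productions$id

# Index layout used by the DP circuit and theta vectors:
# 1 START:[INST]; 2 INST:ATOMIC; 3 INST:CONCAT; 4 INST:REP;
# 5 REP:REP0; 6 REP:REP1; 7 REP:REP2; 7+s ATOMIC:<symbol s>.
.prod_index <- function(g, ids) match(ids, g$productions$id)

# Per-nonterminal blocks over production indices (theta normalises within
# each block).
.lhs_blocks <- function(g) split(seq_len(nrow(g$productions)), g$productions$lhs)

.n_rep_choices <- function(g) g$rep_range[2] - g$rep_range[1] + 1L

.check_positions <- function(x, what = "position") {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L | x > 7L))
    stop(what, " must be integers in 0..7")
  x
}

#' Family membership of each production
#'
#' @param g a \code{geo_grammar}.
#' @return Named character vector mapping production id to family tag.
#' @export
production_families <- function(g) {
  stats::setNames(g$productions$family, g$productions$id)
}
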