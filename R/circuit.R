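# R-side wrapper around the C++ requirement circuit. One compiled circuit
# per (anchor, sequence, grammar) serves counting, materialisation, inside
# probability, minimal description length, and posterior program sampling.

.geo_circuit <- function(anchor, sequence, g, max_nodes = 500000L) {
  anchor <- .check_positions(anchor, "anchor")
  sequence <- .check_positions(sequence, "sequence")
  if (length(sequence) < 1L) stop("sequence must be non-empty")
  raw <- cpp_build_circuit(anchor, sequence, g$atom_table,
                           g$rep_range[1], g$rep_range[2], max_nodes)
  n_edges <- length(raw$parent)
  n_nodes <- length(raw$node_b)

  # evaluation order: children always have strictly shorter runs
  eorder <- order(raw$node_b[raw$parent])
  # CSR grouping of edges by parent node (for sampling / materialisation)
  ord_by_parent <- order(raw$parent)
  node_ptr <- cumsum(c(1L, tabulate(raw$parent, nbins = n_nodes)))

  # per-edge production indices (1-based into c(dummy = 1, theta)):
  # slot 1 is a dummy probability of 1 for unused slots
  kind <- raw$kind
  sym1 <- raw$sym + 1L   # 1-based atomic index, 0 if none
  pad <- rep.int(1L, n_edges)
  pi1 <- pad; pi2 <- pad; pi3 <- pad
  # production index layout: see .prod_index() in grammar.R
  pi1[kind == 1L] <- 2L + 1L                     # INST:ATOMIC
  pi2[kind == 1L] <- 7L + sym1[kind == 1L] + 1L  # ATOMIC:<sym>
  pi1[kind == 2L] <- 3L + 1L                     # INST:CONCAT
  pi1[kind >= 3L] <- 4L + 1L                     # INST:REP
  pi2[kind == 3L] <- 5L + 1L                     # REP:REP0
  pi2[kind == 4L] <- 6L + 1L                     # REP:REP1
  pi2[kind == 5L] <- 7L + 1L                     # REP:REP2
  pi3[kind >= 4L] <- 7L + sym1[kind >= 4L] + 1L  # ATOMIC:<param>
  repf <- ifelse(kind >= 3L, 1 / .n_rep_choices(g), 1)

  structure(list(
    anchor = anchor, sequence = sequence, grammar_hash = g$hash,
    root = raw$root, n_nodes = n_nodes, n_edges = n_edges,
    node_b = raw$node_b,
    parent = raw$parent, c1 = raw$c1, c2 = raw$c2,
    kind = kind, sym = sym1, n = raw$n,
    eorder = eorder, node_ptr = node_ptr, eidx = ord_by_parent,
    pi1 = pi1, pi2 = pi2, pi3 = pi3, repf = repf
  ), class = "geo_circuit")
}

# theta-weighted local edge factors; theta is the full numeric vector over
# production_ids(g) in grammar order
.circuit_edge_weights <- function(circ, theta) {
  tx <- c(1, theta)
  tx[circ$pi1] * tx[circ$pi2] * tx[circ$pi3] * circ$repf
}

.circuit_edge_costs <- function(circ, atomic_cost = 2, param_cost = atomic_cost) {
  cost <- numeric(circ$n_edges)
  cost[circ$kind == 1L] <- atomic_cost
  rep_e <- circ$kind >= 3L
  cost[rep_e] <- floor(log2(circ$n[rep_e]))
  cost[circ$kind >= 4L] <- cost[circ$kind >= 4L] + param_cost
  cost
}

.circuit_count <- function(circ) {
  v <- cpp_eval_sum(circ$n_nodes, circ$eorder, circ$parent, circ$c1, circ$c2,
                    rep.int(1, circ$n_edges))
  v[circ$root]
}

.circuit_inside <- function(circ, theta) {
  w <- .circuit_edge_weights(circ, theta)
  v <- cpp_eval_sum(circ$n_nodes, circ$eorder, circ$parent, circ$c1, circ$c2, w)
  list(v = v, w = w, root_value = v[circ$root] * theta[1])  # theta[1] = START
}

.circuit_min_cost <- function(circ, atomic_cost = 2, param_cost = atomic_cost) {
  cost <- .circuit_edge_costs(circ, atomic_cost, param_cost)
  v <- cpp_eval_min(circ$n_nodes, circ$eorder, circ$parent, circ$c1, circ$c2,
                    cost)
  v[circ$root]
}

# Draw one derivation (program) from the exact posterior over explaining
# programs given theta; returns the preorder edge ids.
.circuit_sample_edges <- function(circ, inside) {
  cpp_sample_edges(circ$root, circ$node_ptr, circ$eidx, circ$c1, circ$c2,
                   inside$w, inside$v)
}

# Sufficient statistics of a sampled derivation: production counts in
# grammar order (including the start production).
.edges_to_counts <- function(circ, edges, n_prod) {
  idx <- c(circ$pi1[edges], circ$pi2[edges], circ$pi3[edges]) - 1L
  f <- tabulate(idx[idx > 0L], nbins = n_prod)
  f[1] <- f[1] + 1L  # START:[INST]
  f
}

# Rebuild the sampled geo_program from the preorder edge list.
.edges_to_program <- function(circ, edges, g) {
  i <- 0L
  build <- function() {
    i <<- i + 1L
    e <- edges[i]
    switch(circ$kind[e],
      geo_atomic(g$symbols[circ$sym[e]]),
      { l <- build(); r <- build(); geo_concat(l, r) },
      geo_rep0(build(), circ$n[e]),
      geo_rep1(build(), circ$n[e], g$symbols[circ$sym[e]]),
      geo_rep2(build(), circ$n[e], g$symbols[circ$sym[e]]))
  }
  build()
}

# Materialise every derivation of a node as a list of geo_programs.
.circuit_trees <- function(circ, g, limit = Inf) {
  memo <- vector("list", circ$n_nodes)
  done <- logical(circ$n_nodes)
  total <- 0L
  trees <- function(node) {
    if (done[node]) return(memo[[node]])
    lo <- circ$node_ptr[node]; hi <- circ$node_ptr[node + 1L] - 1L
    out <- list()
    for (k in seq_len(hi - lo + 1L)) {
      e <- circ$eidx[lo + k - 1L]
      add <- switch(circ$kind[e],
        list(geo_atomic(g$symbols[circ$sym[e]])),
        {
          L <- trees(circ$c1[e]); R <- trees(circ$c2[e])
          res <- vector("list", length(L) * length(R))
          m <- 0L
          for (l in L) for (r in R) { m <- m + 1L; res[[m]] <- geo_concat(l, r) }
          res
        },
        lapply(trees(circ$c1[e]), geo_rep0, n = circ$n[e]),
        lapply(trees(circ$c1[e]), geo_rep1, n = circ$n[e],
               param = g$symbols[circ$sym[e]]),
        lapply(trees(circ$c1[e]), geo_rep2, n = circ$n[e],
               param = g$symbols[circ$sym[e]]))
      out <- c(out, add)
      total <<- total + length(add)
      if (total > limit) stop("materialise_limit_exceeded", call. = FALSE)
    }
    memo[[node]] <<- out
    done[node] <<- TRUE
    out
  }
  trees(circ$root)
}
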