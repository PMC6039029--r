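# Shared fixtures: grammars are cheap to build but constructed once here.
G_ORIG <- geo_grammar()
G_EXT <- geo_grammar(include_adhoc = TRUE)

# Structurally random derivation tree (independent of the PCFG samplers):
# used for round-trip and counting properties.
random_program <- function(g, depth = 3) {
  kinds <- if (depth <= 0) "atomic" else c("atomic", "atomic", "concat",
                                           "rep0", "rep1", "rep2")
  kind <- sample(kinds, 1)
  sym <- function() sample(g$symbols, 1)
  n <- function() sample(seq(g$rep_range[1], g$rep_range[2]), 1)
  switch(kind,
    atomic = geo_atomic(sym()),
    concat = geo_concat(random_program(g, depth - 1),
                        random_program(g, depth - 1)),
    rep0 = geo_rep0(random_program(g, depth - 1), n()),
    rep1 = geo_rep1(random_program(g, depth - 1), n(), sym()),
    rep2 = geo_rep2(random_program(g, depth - 1), n(), sym()))
}

# Count nodes of each kind in a derivation tree.
count_nodes <- function(p) {
  kids <- switch(p$kind,
    atomic = list(),
    concat = list(p$left, p$right),
    list(p$block))
  tab <- c(atomic = 0, concat = 0, rep0 = 0, rep1 = 0, rep2 = 0)
  tab[p$kind] <- 1
  for (k in kids) tab <- tab + count_nodes(k)
  tab
}

serialized_set <- function(enum) {
  if (is.character(enum$programs)) return(sort(enum$programs))
  sort(vapply(enum$programs, serialize_program, character(1)))
}

# Minimal geo_posterior stub for summary/grouping unit tests.
posterior_stub <- function(traces, burn_in = 0L, g = G_ORIG) {
  dimnames(traces) <- list(NULL, NULL, g$productions$id)
  res <- structure(list(
    traces = traces, production_ids = g$productions$id,
    config = inference_config(n_steps = dim(traces)[2], burn_in = burn_in,
                              n_chains = dim(traces)[1]),
    grammar_hash = g$hash, schema_version = 1L),
    class = "geo_posterior")
  res$summary <- summarize_posterior(res)
  res
}
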