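test_that("production inventories match the original and extended grammars", {
  atoms <- subset(G_ORIG$productions, lhs == "ATOMIC")
  expect_equal(nrow(atoms), 12L)
  expect_false(any(G_ORIG$productions$family == "adhoc"))

  atoms_ext <- subset(G_EXT$productions, lhs == "ATOMIC")
  expect_equal(nrow(atoms_ext), 23L)
  expect_equal(sum(G_EXT$productions$family == "adhoc"), 11L)

  # family tags partition the atomic productions
  expect_equal(as.vector(table(atoms_ext$family)[c("acw", "stay", "cw",
                                                   "symmetry", "adhoc")]),
               c(3L, 1L, 3L, 5L, 11L))
  expect_false(anyDuplicated(G_EXT$productions$id) > 0)

  # nonterminal structure: START 1, INST 3, REP 3 productions
  expect_equal(as.vector(table(G_EXT$productions$lhs)[c("START", "INST", "REP")]),
               c(1L, 3L, 3L))
})

test_that("grammar configuration is validated", {
  expect_error(geo_grammar(axes = c(A = 4, B = 1, H = 7, V = 3)), "odd")
  expect_error(geo_grammar(axes = c(A = 5, B = 5, H = 7, V = 3)), "distinct")
  expect_error(geo_grammar(rep_range = c(2, 9)), "rep_range")
  expect_error(geo_grammar(rep_range = c(1, 8)), "rep_range")
  g22 <- geo_grammar(rep_range = c(2, 2))
  expect_error(parse_program("[REP[+1]^3]", g22), "outside rep_range")
  expect_equal(count_programs(0, c(1, 2, 3), g22), # no rep divides 3
               count_programs(0, c(1, 2, 3), g22))
})

test_that("parser handles the notation and reports errors with positions", {
  p <- parse_program("[+1, +1]", G_ORIG)
  expect_equal(p$kind, "concat")
  expect_equal(p$left$symbol, "+1")
  expect_equal(p$right$symbol, "+1")

  r <- parse_program("[REP[A]^8]", G_ORIG)
  expect_equal(r$kind, "rep0")
  expect_equal(r$n, 8L)
  expect_equal(r$block$symbol, "A")

  r1 <- parse_program("[REP1<-1>[+1, +2]^3]", G_ORIG)
  expect_equal(r1$kind, "rep1")
  expect_equal(r1$param, "-1")
  expect_equal(r1$block$kind, "concat")

  # comma lists are left-associated; brackets give other associations
  p3 <- parse_program("[+1, -1, P]", G_ORIG)
  expect_equal(p3$left$kind, "concat")
  pr <- parse_program("[+1, [-1, P]]", G_ORIG)
  expect_equal(pr$right$kind, "concat")

  expect_error(parse_program("[REP[+1]^9]", G_ORIG), "outside rep_range")
  expect_error(parse_program("[+1, PI]", G_ORIG), "position")
  expect_error(parse_program("[+1,, +1]", G_ORIG), "parse error")
  expect_error(parse_program("[+1", G_ORIG), "end of input")
  expect_error(parse_program("[DOUBLE]", G_ORIG), "unknown|position")
  expect_silent(parse_program("[DOUBLE]", G_EXT))
})

test_that("serialization is canonical and round-trips for random programs", {
  expect_equal(serialize_program(geo_rep0(geo_atomic("+1"), 8)), "[REP[+1]^8]")
  expect_equal(serialize_program(geo_atomic("+0")), "[+0]")
  # right-branching concatenations keep their structure
  p <- geo_concat(geo_atomic("+1"),
                  geo_concat(geo_atomic("-1"), geo_atomic("P")))
  expect_equal(serialize_program(p), "[+1, [-1, P]]")
  expect_identical(parse_program(serialize_program(p), G_ORIG), p)

  set.seed(101)
  for (i in 1:1000) {
    q <- random_program(G_EXT, depth = sample(1:3, 1))
    expect_identical(parse_program(serialize_program(q), G_EXT), q)
  }
})

test_that("production counts cover every application in the tree", {
  f <- production_counts(geo_atomic("+1"), G_ORIG)
  expect_equal(sum(f), 3)
  expect_equal(unname(f[c("START:[INST]", "INST:ATOMIC", "ATOMIC:+1")]),
               c(1L, 1L, 1L))

  a <- geo_atomic("+1")
  f2 <- production_counts(geo_concat(a, a), G_ORIG)
  expect_equal(unname(f2["INST:CONCAT"]), 1L)
  expect_equal(unname(f2["INST:ATOMIC"]), 2L)

  # REP1/REP2 parameters are expanded through ATOMIC
  f3 <- production_counts(geo_rep1(geo_atomic("+1"), 2, "-1"), G_ORIG)
  expect_equal(unname(f3["ATOMIC:-1"]), 1L)
  expect_equal(unname(f3[c("INST:REP", "REP:REP1")]), c(1L, 1L))

  expect_error(production_counts(geo_atomic("PI"), G_ORIG), "unknown")

  # sum of INST-headed production counts equals the number of INST nodes
  set.seed(77)
  for (i in 1:50) {
    q <- random_program(G_EXT, depth = 3)
    f <- production_counts(q, G_EXT)
    nodes <- count_nodes(q)
    inst_nodes <- sum(nodes)  # every tree node is an INST expansion
    expect_equal(sum(f[c("INST:ATOMIC", "INST:CONCAT", "INST:REP")]),
                 inst_nodes)
    expect_equal(unname(f["INST:REP"]),
                 unname(nodes["rep0"] + nodes["rep1"] + nodes["rep2"]))
  }
})
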