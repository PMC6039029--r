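test_that("theta construction validates per-block normalisation", {
  th <- theta_uniform(G_ORIG)
  expect_equal(unname(th["INST:ATOMIC"]), 1 / 3)
  expect_equal(sum(th[paste0("ATOMIC:", G_ORIG$symbols)]), 1)
  bad <- th
  bad["ATOMIC:+1"] <- bad["ATOMIC:+1"] + 0.1
  expect_error(make_theta(unclass(bad), G_ORIG), "sums to")
  expect_error(make_theta(unclass(th)[-1], G_ORIG), "named")
})

test_that("program log-probability follows the production-count algebra", {
  th <- default_theta_true(G_ORIG)
  lp1 <- program_log_prob(geo_atomic("+1"), th, G_ORIG)
  lp2 <- program_log_prob(geo_concat(geo_atomic("+1"), geo_atomic("+1")),
                          th, G_ORIG)
  expect_equal(lp2 - lp1,
               log(th[["INST:CONCAT"]]) + log(th[["INST:ATOMIC"]]) +
                 log(th[["ATOMIC:+1"]]))
  # repetition nodes carry the uniform 1/|rep_range| factor
  lp3 <- program_log_prob(geo_rep0(geo_atomic("+1"), 8), th, G_ORIG)
  expect_equal(lp3,
               log(th[["INST:REP"]]) + log(th[["REP:REP0"]]) - log(7) +
                 log(th[["INST:ATOMIC"]]) + log(th[["ATOMIC:+1"]]))
  # zero-probability production used => -Inf
  th0 <- unclass(th)
  th0["ATOMIC:+1"] <- 0
  th0["ATOMIC:-1"] <- th0["ATOMIC:-1"] + th[["ATOMIC:+1"]]
  expect_equal(program_log_prob(geo_atomic("+1"),
                                make_theta(th0, G_ORIG), G_ORIG), -Inf)
  # total mass of all length-1 derivations is theta_atomic-leaf
  e <- lapply(G_ORIG$symbols, geo_atomic)
  mass <- sum(vapply(e, function(p) exp(program_log_prob(p, th, G_ORIG)),
                     numeric(1)))
  expect_equal(mass, unname(th["INST:ATOMIC"]))
})

test_that("sample_theta matches Dirichlet closed-form moments", {
  set.seed(42)
  # prior only: uniform expectation per block
  draws <- replicate(4000, unclass(sample_theta(list(), G_ORIG, alpha = 1)))
  m <- rowMeans(draws)
  expect_equal(unname(m["INST:ATOMIC"]), 1 / 3, tolerance = 0.03)
  expect_equal(unname(m["ATOMIC:+1"]), 1 / 12, tolerance = 0.02)

  # fixed assignments: mean (f + 1) / sum(f + 1) within 3 sigma
  progs <- list(geo_concat(geo_atomic("+1"), geo_atomic("+1")),
                geo_rep0(geo_atomic("A"), 4))
  f <- production_counts(progs[[1]], G_ORIG) +
    production_counts(progs[[2]], G_ORIG)
  draws <- replicate(4000, unclass(sample_theta(progs, G_ORIG, alpha = 1)))
  inst <- f[c("INST:ATOMIC", "INST:CONCAT", "INST:REP")] + 1
  expected <- inst / sum(inst)
  for (id in names(expected)) {
    mu <- expected[[id]]
    sdv <- sqrt(mu * (1 - mu) / (sum(inst) + 1))
    expect_lt(abs(mean(draws[id, ]) - mu), 3 * sdv / sqrt(4000) + 3e-3)
  }

  # huge alpha concentrates at the prior mean
  draws <- replicate(400, unclass(sample_theta(progs, G_ORIG, alpha = 1000)))
  expect_lt(max(abs(rowMeans(draws)[c("INST:ATOMIC", "INST:CONCAT")] - 1 / 3)),
            0.01)
})

test_that("posterior program draws follow the exact multinomial", {
  th <- theta_uniform(G_ORIG)
  # single explaining program is always returned
  p <- sample_program_posterior(0, 4, th, G_ORIG)
  expect_equal(serialize_program(p), "[P]")

  # two equally likely programs: 50/50 within 3 sigma over 10,000 draws
  thx <- unclass(default_theta_true(G_ORIG))
  thx["INST:REP"] <- 0
  thx["INST:ATOMIC"] <- 0.6
  thx["INST:CONCAT"] <- 0.4
  thx[paste0("ATOMIC:", G_ORIG$symbols)] <- 1 / 12
  thx <- make_theta(thx, G_ORIG)
  set.seed(9)
  draws <- sample_program_posterior(6, c(7, 6), thx, G_ORIG, n = 10000)
  txt <- vapply(draws, serialize_program, character(1))
  expect_setequal(unique(txt),
                  c("[+1, -1]", "[+1, A]", "[A, -1]", "[A, A]"))
  n11 <- sum(txt == "[+1, -1]")
  expect_lt(abs(n11 - 2500), 3 * sqrt(10000 * 0.25 * 0.75))

  # draw frequencies match exact probabilities (chi-square)
  th2 <- default_theta_true(G_ORIG)
  e <- enumerate_programs(0, c(1, 2), G_ORIG)
  lp <- vapply(e$programs, program_log_prob, numeric(1), theta = th2,
               g = G_ORIG)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  set.seed(10)
  draws <- sample_program_posterior(0, c(1, 2), th2, G_ORIG, n = 50000)
  txt <- vapply(draws, serialize_program, character(1))
  lv <- vapply(e$programs, serialize_program, character(1))
  obs <- as.vector(table(factor(txt, levels = lv)))
  expect_gt(stats::chisq.test(obs, p = pr)$p.value, 0.01)

  # circuit-based and materialised-multinomial paths agree in distribution
  set.seed(11)
  d2 <- sample_program_posterior(0, c(1, 2), th2, G_ORIG, enumeration = e,
                                 n = 50000)
  obs2 <- as.vector(table(factor(vapply(d2, serialize_program, character(1)),
                                 levels = lv)))
  expect_gt(stats::chisq.test(rbind(obs, obs2))$p.value, 0.01)

  expect_error(sample_program_posterior(0, 4, th, geo_grammar(rep_range = c(2, 2))),
               NA)  # still one program under a restricted grammar
})

test_that("Gibbs posterior matches the conjugate closed form when programs are forced", {
  set.seed(7)
  n <- 40
  anchors <- sample(0:7, n, replace = TRUE)
  seqs <- lapply(seq_len(n), function(i)
    if (i %% 2) (anchors[i] + 4) %% 8 else anchors[i])  # [P] / [+0] only
  ds <- geo_trials(paste0("s", seq_len(n)), paste0("t", seq_len(n)),
                   anchors, seqs)
  post <- gibbs_infer(ds, G_ORIG,
                      inference_config(n_steps = 200, burn_in = 50,
                                       n_chains = 2, seed = 3))
  f <- setNames(numeric(19), production_ids(G_ORIG))
  f["START:[INST]"] <- n; f["INST:ATOMIC"] <- n
  f["ATOMIC:P"] <- n / 2; f["ATOMIC:+0"] <- n / 2
  closed <- f + 1
  for (b in split(seq_len(19), G_ORIG$productions$lhs))
    closed[b] <- closed[b] / sum(f[b] + 1)
  expect_lt(max(abs(post$summary$mean - unname(closed))), 0.02)
})

test_that("Gibbs chain reaches the exact joint posterior on a toy problem", {
  # two trials, few explaining programs; the stationary distribution of
  # program assignments is the Dirichlet-multinomial marginal
  trials <- list(list(anchor = 0, seq = c(1, 2)), list(anchor = 6, seq = 7))
  ds <- geo_trials(c("s1", "s1"), c("t1", "t2"),
                   vapply(trials, `[[`, numeric(1), "anchor"),
                   lapply(trials, `[[`, "seq"))
  enums <- lapply(trials, function(tr)
    enumerate_programs(tr$anchor, tr$seq, G_ORIG))
  R <- 7  # allowed repetition counts

  log_marginal <- function(p1, p2) {
    f <- production_counts(p1, G_ORIG) + production_counts(p2, G_ORIG)
    reps <- f[["INST:REP"]]
    lp <- -reps * log(R)
    for (b in split(seq_len(19), G_ORIG$productions$lhs)) {
      a <- rep(1, length(b))
      lp <- lp + lgamma(sum(a)) - lgamma(sum(a + f[b])) +
        sum(lgamma(a + f[b]) - lgamma(a))
    }
    lp
  }
  keys <- outer(seq_along(enums[[1]]$programs), seq_along(enums[[2]]$programs),
                Vectorize(function(i, j)
                  log_marginal(enums[[1]]$programs[[i]],
                               enums[[2]]$programs[[j]])))
  exact <- exp(keys - max(keys)); exact <- exact / sum(exact)
  rownames(exact) <- vapply(enums[[1]]$programs, serialize_program, character(1))
  colnames(exact) <- vapply(enums[[2]]$programs, serialize_program, character(1))

  post <- gibbs_infer(ds, G_ORIG,
                      inference_config(n_steps = 20000, burn_in = 500,
                                       n_chains = 1, seed = 12),
                      keep_programs = "all")
  dr <- post$program_draws[[1]][-(1:500), ]
  emp <- table(factor(dr[, 1], levels = rownames(exact)),
               factor(dr[, 2], levels = colnames(exact))) / nrow(dr)
  tv <- 0.5 * sum(abs(as.vector(emp) - as.vector(exact)))
  expect_lt(tv, 0.05)
})

test_that("posterior summaries pool chains and normalise per block", {
  # constant traces give zero standard error
  tr <- array(rep(unname(theta_uniform(G_ORIG)), each = 2 * 10),
              dim = c(2, 10, 19))
  stub <- posterior_stub(tr, burn_in = 2L)
  expect_true(all(stub$summary$se == 0))
  expect_equal(stub$summary$mean, unname(theta_uniform(G_ORIG)))

  # two identical chains summarise like one
  set.seed(1)
  one <- array(runif(10 * 19), dim = c(1, 10, 19))
  for (s in 1:10) for (b in split(1:19, G_ORIG$productions$lhs))
    one[1, s, b] <- one[1, s, b] / sum(one[1, s, b])
  two <- array(NA_real_, dim = c(2, 10, 19))
  two[1, , ] <- one[1, , ]; two[2, , ] <- one[1, , ]
  s1 <- posterior_stub(one, burn_in = 0L)$summary
  s2 <- posterior_stub(two, burn_in = 0L)$summary
  expect_equal(s1$mean, s2$mean)

  # summary means stay normalised within each nonterminal block
  for (b in split(1:19, G_ORIG$productions$lhs))
    expect_equal(sum(s2$mean[b]), 1, tolerance = 1e-12)

  expect_error(posterior_stub(one, burn_in = 10L), "burn")
})

test_that("family grouping partitions the posterior mass", {
  tr <- array(rep(unname(default_theta_true(G_ORIG)), each = 1 * 5),
              dim = c(1, 5, 19))
  stub <- posterior_stub(tr, burn_in = 0L)
  fams <- group_by_family(stub$summary, g = G_ORIG)
  th <- default_theta_true(G_ORIG)
  expect_equal(fams$total[fams$family == "cw"],
               sum(th[c("ATOMIC:+1", "ATOMIC:+2", "ATOMIC:+3")]))
  # INST-block families (basic/concat/rep + REP variants) stay additive
  expect_equal(sum(fams$total), sum(th))
  # singleton family equals its production's value
  expect_equal(fams$total[fams$family == "stay"], unname(th["ATOMIC:+0"]))
  expect_error(group_by_family(stub$summary,
                               family_map = c("ATOMIC:+1" = "cw")),
               "cover")
})

test_that("population comparison has the right sign convention and multiplicity control", {
  set.seed(3)
  trA <- array(rep(unname(theta_uniform(G_ORIG)), each = 2 * 20),
               dim = c(2, 20, 19)) + array(rnorm(2 * 20 * 19, 0, 1e-3),
                                           dim = c(2, 20, 19))
  a <- posterior_stub(trA, burn_in = 5L)
  trB <- trA; trB[, , 19] <- trB[, , 19] + 0.05  # shift ATOMIC:P upward
  b <- posterior_stub(trB, burn_in = 5L)

  tt <- compare_populations(a, b, "ATOMIC:P")
  expect_lt(unname(tt$statistic), 0)  # A below B => negative t
  expect_lt(tt$p.value, 1e-6)
  expect_equal(unname(compare_populations(a, a, "ATOMIC:P")$statistic), 0)

  scan <- compare_populations(a, b)
  sig <- scan$production[scan$p_adjusted < 0.01]
  expect_equal(sig, "ATOMIC:P")
})

test_that("degenerate datasets are rejected", {
  expect_error(gibbs_infer(geo_trials(character(0), character(0), integer(0),
                                      list()), G_ORIG),
               "empty|length")
  # every sequence is explainable under the full grammar (atomic coverage),
  # so the no-explaining-program error is only reachable through the
  # sampler's own guard
  expect_error(sample_program_posterior(0, 4, theta_uniform(G_ORIG), G_ORIG,
                                        enumeration = list(programs = list())),
               "no explaining program")
})
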