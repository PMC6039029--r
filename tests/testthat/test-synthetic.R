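test_that("length-conditioned program sampling is exact", {
  th <- default_theta_true(G_ORIG)
  set.seed(51)
  for (L in c(1, 3, 8)) {
    draws <- replicate(50, output_length(sample_program_from_pcfg(G_ORIG, th, L)))
    expect_true(all(draws == L))
  }

  # L = 1 reduces to the atomic block probabilities
  set.seed(52)
  d1 <- replicate(20000, sample_program_from_pcfg(G_ORIG, th, 1)$symbol)
  pr <- unclass(th)[paste0("ATOMIC:", G_ORIG$symbols)]
  obs <- as.vector(table(factor(d1, levels = G_ORIG$symbols)))
  expect_gt(stats::chisq.test(obs, p = pr / sum(pr))$p.value, 0.01)

  # L = 2: empirical distribution over whole trees matches the exact
  # conditional computed by exhaustive enumeration
  set.seed(53)
  d2 <- replicate(30000,
                  serialize_program(sample_program_from_pcfg(G_ORIG, th, 2)))
  sp2 <- brute_force_enumerate(0, c(0, 0), G_ORIG)  # warm the L=2 space
  all2 <- paste0("[", geolot:::.brute_space(2, G_ORIG)$inner, "]")
  w <- vapply(all2, function(x)
    exp(program_log_prob(parse_program(x, G_ORIG), th, G_ORIG)), numeric(1))
  obs <- as.vector(table(factor(d2, levels = all2)))
  expect_gt(stats::chisq.test(obs, p = w / sum(w))$p.value, 0.01)
})

test_that("generated datasets are deterministic and fully explainable", {
  cfg <- generator_config(n_trials = 40, L = 8, seed = 7)
  ds1 <- generate_dataset(cfg, G_ORIG)
  ds2 <- generate_dataset(cfg, G_ORIG)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials(ds1, f1); write_trials(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))

  # noise-free: every trial is explained by its own generating program
  for (tr in as_trial_list(ds1))
    expect_gte(count_programs(tr$anchor, tr$sequence, G_ORIG), 1)
  progs <- attr(ds1, "programs")
  for (i in seq_len(10))
    expect_equal(execute_program(progs[i], ds1$anchor[i], G_ORIG),
                 ds1$seq[[i]])

  # even heavy point noise leaves trials explainable (atomic coverage)
  dsn <- generate_dataset(generator_config(n_trials = 20, L = 8,
                                           noise_rate = 0.5, seed = 8),
                          G_ORIG)
  for (tr in as_trial_list(dsn))
    expect_gte(count_programs(tr$anchor, tr$sequence, G_ORIG), 1)
})

test_that("the ideal-learner generator repeats exact stimulus sequences", {
  specs <- data.frame(program = "[REP[+1]^8]", anchor = 0)
  ds <- ideal_learner_dataset(specs, repeats = 10, g = G_ORIG)
  expect_equal(nrow(ds), 10)
  for (s in ds$seq) expect_equal(s, c(1, 2, 3, 4, 5, 6, 7, 0))
  expect_error(ideal_learner_dataset(list()), "empty")

  # a repetition-heavy ideal dataset concentrates posterior mass on REP
  specs <- data.frame(
    program = c("[REP[+1]^8]", "[REP[A]^8]", "[REP[-2]^8]", "[REP[+3]^8]"),
    anchor = c(0, 6, 3, 1))
  dsr <- ideal_learner_dataset(specs, repeats = 6, g = G_ORIG)
  post <- gibbs_infer(dsr, G_ORIG, inference_config(n_chains = 2, seed = 2))
  fams <- group_by_family(post$summary, g = G_ORIG)
  expect_gt(fams$total[fams$family == "rep"],
            fams$total[fams$family == "concat"])
})

test_that("recovery metrics behave and improve with data", {
  th <- default_theta_true(G_ORIG)
  perfect <- posterior_stub(array(rep(unname(th), each = 1 * 5),
                                  dim = c(1, 5, 19)), burn_in = 0L)
  repp <- parameter_recovery_report(th, perfect, G_ORIG)
  expect_equal(repp$rmse, 0)
  expect_equal(repp$pearson_r, 1)
  expect_length(repp$adhoc_above_threshold, 0)

  # posterior RMSE shrinks from 30 to 300 trials (two seeds averaged)
  rmse_at <- function(n, seed) {
    ds <- generate_dataset(generator_config(n_trials = n, L = 8, seed = seed),
                           G_ORIG)
    post <- gibbs_infer(ds, G_ORIG,
                        inference_config(n_chains = 2, seed = seed + 100))
    parameter_recovery_report(th, post, G_ORIG)$rmse
  }
  seeds <- c(61, 62)
  r30 <- mean(vapply(seeds, function(s) rmse_at(30, s), numeric(1)))
  r300 <- mean(vapply(seeds, function(s) rmse_at(300, s), numeric(1)))
  expect_lt(r300, r30)
})
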