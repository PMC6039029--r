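# Synthetic trial generation: programs sampled from the probabilistic
# grammar under a ground-truth theta, executed from random anchors. Stands
# in for behavioural octagon-sequence data, which is not deposited.

#' Default ground-truth theta for synthetic data
#'
#' A fixed, documented choice of generating probabilities emulating an
#' adult-like population: repetition favoured over plain concatenation
#' within the sequence block; clockwise and anticlockwise steps balanced;
#' the half-turn P at 0.05 (the reported adult posterior mean for that
#' production); ad-hoc productions, when the grammar includes them, at zero
#' (behaviour-like data uses only the original inventory).
#'
#' @param g a \code{geo_grammar}.
#' @return A \code{geo_theta}.
#' @export
default_theta_true <- function(g) {
  atom <- c("-1" = 0.13, "-2" = 0.08, "-3" = 0.06, "+0" = 0.09,
            "+1" = 0.13, "+2" = 0.08, "+3" = 0.06,
            "A" = 0.08, "B" = 0.08, "H" = 0.08, "V" = 0.08, "P" = 0.05)
  v <- setNames(numeric(nrow(g$productions)), g$productions$id)
  v["START:[INST]"] <- 1
  v[c("INST:ATOMIC", "INST:CONCAT", "INST:REP")] <- c(0.45, 0.20, 0.35)
  v[c("REP:REP0", "REP:REP1", "REP:REP2")] <- c(0.6, 0.2, 0.2)
  v[paste0("ATOMIC:", names(atom))] <- atom / sum(atom)
  make_theta(v, g)
}

#' Configuration of the synthetic generator
#'
#' @param theta_true generating \code{geo_theta} (default
#'   [default_theta_true()] of the grammar at generation time when
#'   \code{NULL}).
#' @param n_trials number of trials.
#' @param L emitted sequence length per trial (1..8; default 8, the
#'   behavioural trial length).
#' @param noise_rate probability of replacing each emitted point with a
#'   uniform random point. The inference likelihood is noise-free, so this
#'   exists only to stress-test robustness; default 0.
#' @param n_subjects synthetic subject ids to spread trials over
#'   (default 23, the original adult cohort size).
#' @param seed RNG seed.
#' @return A list of class \code{geo_generator_config}.
#' @export
generator_config <- function(theta_true = NULL, n_trials = 300L, L = 8L,
                             noise_rate = 0, n_subjects = 23L, seed = 1L) {
  stopifnot(n_trials >= 1L, L >= 1L, L <= 8L,
            noise_rate >= 0, noise_rate < 1)
  structure(list(theta_true = theta_true, n_trials = as.integer(n_trials),
                 L = as.integer(L), noise_rate = noise_rate,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "geo_generator_config")
}

# Inside weights of the unconditioned PCFG by output length: W[b] is the
# total probability of all derivation trees emitting exactly b points.
.length_inside <- function(g, th, L) {
  R <- .n_rep_choices(g)
  atom_mass <- sum(th[.prod_index(g, paste0("ATOMIC:", g$symbols))])
  th_ia <- th[2]; th_c <- th[3]; th_r <- th[4]
  th_rep <- th[5:7]
  rep_var_mass <- th_rep[1] + (th_rep[2] + th_rep[3]) * atom_mass
  W <- numeric(L)
  for (b in seq_len(L)) {
    if (b == 1) { W[1] <- th_ia * atom_mass; next }
    tot <- 0
    for (k in seq_len(b - 1)) tot <- tot + th_c * W[k] * W[b - k]
    for (n in seq(max(2, g$rep_range[1]), g$rep_range[2]))
      if (b %% n == 0)
        tot <- tot + th_r * (1 / R) * rep_var_mass * W[b %/% n]
    W[b] <- tot
  }
  W
}

#' Sample a program of a given output length from the grammar
#'
#' Exact conditional sampling of a derivation tree given
#' \code{output_length == target_len}, via length-indexed inside weights
#' (top-down choice of each decomposition proportional to its conditional
#' mass; no rejection, hence no bias and guaranteed termination).
#'
#' @param g a \code{geo_grammar}.
#' @param theta a \code{geo_theta}.
#' @param target_len desired output length (1..8).
#' @return A \code{geo_program} with \code{output_length(p) == target_len}.
#' @export
sample_program_from_pcfg <- function(g, theta, target_len) {
  stopifnot(target_len >= 1L, target_len <= 8L)
  th <- .theta_vec(theta, g)
  W <- .length_inside(g, th, target_len)
  if (W[target_len] <= 0)
    stop("grammar/theta give zero mass to programs of length ", target_len)
  R <- .n_rep_choices(g)
  atom_idx <- .prod_index(g, paste0("ATOMIC:", g$symbols))
  atom_th <- th[atom_idx]
  atom_mass <- sum(atom_th)
  th_c <- th[3]; th_r <- th[4]; th_rep <- th[5:7]

  draw_atom <- function() g$symbols[sample.int(length(atom_th), 1L,
                                               prob = atom_th)]
  draw <- function(b) {
    if (b == 1L) return(geo_atomic(draw_atom()))
    opts <- list(); wts <- numeric(0)
    for (k in seq_len(b - 1L)) {
      opts[[length(opts) + 1L]] <- list(type = "concat", k = k)
      wts <- c(wts, th_c * W[k] * W[b - k])
    }
    for (n in seq(max(2L, g$rep_range[1]), g$rep_range[2])) {
      if (b %% n != 0L) next
      bl <- b %/% n
      for (variant in 1:3) {
        opts[[length(opts) + 1L]] <- list(type = "rep", variant = variant,
                                          n = n, bl = bl)
        wts <- c(wts, th_r * (1 / R) * th_rep[variant] *
                   (if (variant == 1L) 1 else atom_mass) * W[bl])
      }
    }
    ch <- opts[[sample.int(length(opts), 1L, prob = wts)]]
    if (ch$type == "concat")
      return(geo_concat(draw(ch$k), draw(b - ch$k)))
    block <- draw(ch$bl)
    switch(ch$variant,
           geo_rep0(block, ch$n),
           geo_rep1(block, ch$n, draw_atom()),
           geo_rep2(block, ch$n, draw_atom()))
  }
  draw(as.integer(target_len))
}

#' Generate a synthetic trial dataset
#'
#' For each trial: a uniform anchor, a program drawn from the probabilistic
#' grammar conditioned on the configured output length, executed from the
#' anchor; optional point-replacement noise. Deterministic given the
#' config's seed.
#'
#' @param config a [generator_config()].
#' @param g a \code{geo_grammar}.
#' @return A \code{geo_trials} dataset; attribute \code{"programs"} holds
#'   the generating program texts.
#' @export
generate_dataset <- function(config = generator_config(), g = geo_grammar()) {
  theta <- if (is.null(config$theta_true)) default_theta_true(g)
           else config$theta_true
  set.seed(config$seed)
  n <- config$n_trials
  anchors <- sample.int(8L, n, replace = TRUE) - 1L
  seqs <- vector("list", n)
  progs <- character(n)
  for (i in seq_len(n)) {
    p <- sample_program_from_pcfg(g, theta, config$L)
    s <- execute_program(p, anchors[i], g)
    if (config$noise_rate > 0) {
      flip <- runif(length(s)) < config$noise_rate
      s[flip] <- sample.int(8L, sum(flip), replace = TRUE) - 1L
    }
    seqs[[i]] <- s
    progs[i] <- serialize_program(p)
  }
  subj <- paste0("s", 1 + (seq_len(n) - 1L) %% config$n_subjects)
  ds <- geo_trials(subject_id = subj,
                   trial_id = paste0("t", seq_len(n)),
                   anchor = anchors, sequences = seqs)
  attr(ds, "programs") <- progs
  ds
}

#' Noise-free dataset from explicit program specifications
#'
#' Executes each (program text, anchor) specification exactly and repeats
#' it, producing the intended stimulus sequences of an idealised learner
#' with no response noise.
#'
#' @param program_specs data frame with columns \code{program} (text
#'   notation) and \code{anchor}, or a list of \code{list(program, anchor)}.
#' @param repeats how many trials to emit per specification.
#' @param g a \code{geo_grammar}.
#' @return A \code{geo_trials} dataset.
#' @export
ideal_learner_dataset <- function(program_specs, repeats = 1L,
                                  g = geo_grammar()) {
  if (is.data.frame(program_specs))
    program_specs <- lapply(seq_len(nrow(program_specs)), function(i)
      list(program = program_specs$program[i],
           anchor = program_specs$anchor[i]))
  if (length(program_specs) == 0L) stop("empty program specification list")
  rows <- list()
  for (sp in program_specs) {
    s <- execute_program(parse_program(sp$program, g), sp$anchor, g)
    for (r in seq_len(repeats))
      rows[[length(rows) + 1L]] <- list(anchor = sp$anchor, seq = s)
  }
  geo_trials(subject_id = rep("ideal", length(rows)),
             trial_id = paste0("t", seq_along(rows)),
             anchor = vapply(rows, `[[`, numeric(1), "anchor"),
             sequences = lapply(rows, `[[`, "seq"))
}

#' Parameter-recovery metrics
#'
#' Compares a posterior against the generating theta: per-production
#' absolute error, overall RMSE, Pearson correlation of the means, and the
#' ad-hoc productions whose posterior mean exceeds a pruning threshold.
#'
#' @param theta_true the generating \code{geo_theta}.
#' @param posterior a \code{geo_posterior}.
#' @param g a \code{geo_grammar} (for family tags).
#' @param prune_threshold ad-hoc report threshold (default 0.01).
#' @return List: \code{per_production} data frame, \code{rmse},
#'   \code{pearson_r}, \code{adhoc_above_threshold}.
#' @export
parameter_recovery_report <- function(theta_true, posterior, g,
                                      prune_threshold = 0.01) {
  if (!setequal(names(theta_true), posterior$production_ids))
    stop("theta_true and posterior cover different production ids")
  est <- setNames(posterior$summary$mean, posterior$summary$production)
  truth <- theta_true[posterior$production_ids]
  err <- abs(est - truth)
  fam <- production_families(g)[posterior$production_ids]
  adhoc <- posterior$production_ids[fam == "adhoc" &
                                      est > prune_threshold]
  list(per_production = data.frame(production = posterior$production_ids,
                                   truth = unname(truth),
                                   estimate = unname(est),
                                   abs_error = unname(err),
                                   row.names = NULL),
       rmse = sqrt(mean(err^2)),
       pearson_r = stats::cor(truth, est),
       adhoc_above_threshold = adhoc)
}
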