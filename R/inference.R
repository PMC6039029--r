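# Bayesian inference of production probabilities: Gibbs sampling that
# alternates exact draws of explaining programs given theta with conjugate
# Dirichlet draws of theta given production counts.

#' Theta vectors: per-production probabilities
#'
#' A theta vector assigns a probability to every production, normalised
#' within each nonterminal block (START, INST, REP, ATOMIC).
#' \code{theta_uniform} gives the per-block uniform vector;
#' \code{make_theta} validates an arbitrary named vector.
#'
#' @param g a \code{geo_grammar}.
#' @param values named numeric vector over \code{production_ids(g)}.
#' @return Named numeric vector of class \code{geo_theta}.
#' @export
theta_uniform <- function(g) {
  v <- numeric(nrow(g$productions))
  for (blk in .lhs_blocks(g)) v[blk] <- 1 / length(blk)
  make_theta(setNames(v, g$productions$id), g)
}

#' @rdname theta_uniform
#' @export
make_theta <- function(values, g) {
  if (is.null(names(values)) || !setequal(names(values), g$productions$id))
    stop("theta must be named by exactly the production ids of the grammar")
  v <- unname(values[g$productions$id])
  if (any(v < 0)) stop("theta entries must be non-negative")
  for (blk in .lhs_blocks(g)) {
    s <- sum(v[blk])
    if (abs(s - 1) > 1e-9)
      stop("theta block for ", g$productions$lhs[blk[1]],
           " sums to ", format(s), ", not 1")
  }
  structure(setNames(v, g$productions$id), class = "geo_theta")
}

.theta_vec <- function(theta, g) {
  if (inherits(theta, "geo_theta")) return(unname(theta[g$productions$id]))
  make_theta(theta, g)
  unname(theta[g$productions$id])
}

#' Log-probability of a program under the probabilistic grammar
#'
#' \code{sum(f_r * log(theta_r))} over the production counts of the
#' derivation tree, plus \code{log(1 / n_rep_choices)} for every repetition
#' node (the repetition count is drawn uniformly over \code{rep_range}, not
#' theta-weighted). \code{-Inf} when a used production has zero probability.
#'
#' @param p a \code{geo_program}.
#' @param theta a \code{geo_theta}.
#' @param g a \code{geo_grammar}.
#' @return Log-probability (a non-positive number or \code{-Inf}).
#' @export
program_log_prob <- function(p, theta, g) {
  th <- .theta_vec(theta, g)
  f <- production_counts(p, g)
  used <- f > 0L
  if (any(th[used] == 0)) return(-Inf)
  sum(f[used] * log(th[used])) -
    f[["INST:REP"]] * log(.n_rep_choices(g))
}

#' MCMC settings for the Gibbs sampler
#'
#' @param alpha Dirichlet concentration: a scalar (recycled over all
#'   productions) or a named vector over production ids. Default 1.
#' @param n_steps steps per chain (default 50).
#' @param burn_in initial steps discarded (default 10).
#' @param n_chains independent chains (default 4).
#' @param seed master seed; chain c uses substream seed \code{seed + c}.
#' @return A list of class \code{geo_inference_config}.
#' @export
inference_config <- function(alpha = 1, n_steps = 50L, burn_in = 10L,
                             n_chains = 4L, seed = 1L) {
  stopifnot(all(alpha > 0), burn_in < n_steps, n_chains >= 1L)
  structure(list(alpha = alpha, n_steps = as.integer(n_steps),
                 burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "geo_inference_config")
}

.alpha_vec <- function(alpha, g) {
  np <- nrow(g$productions)
  if (length(alpha) == 1L && is.null(names(alpha))) return(rep(alpha, np))
  if (is.null(names(alpha)) || !setequal(names(alpha), g$productions$id))
    stop("vector alpha must be named by the production ids")
  unname(alpha[g$productions$id])
}

# One conjugate draw: per-nonterminal Dirichlet(f + alpha) via gamma draws.
.draw_theta <- function(f, alpha_v, blocks) {
  gam <- rgamma(length(f), shape = f + alpha_v)
  for (blk in blocks) gam[blk] <- gam[blk] / sum(gam[blk])
  gam
}

#' Draw theta from its conditional given program assignments
#'
#' The conjugate move of the Gibbs sampler: sums production counts over the
#' assigned programs and draws each nonterminal block from
#' Dirichlet(counts + alpha).
#'
#' @param assignments list of \code{geo_program} (one per trial).
#' @param g a \code{geo_grammar}.
#' @param alpha concentration, as in [inference_config()].
#' @return A \code{geo_theta}.
#' @export
sample_theta <- function(assignments, g, alpha = 1) {
  f <- numeric(nrow(g$productions))
  for (p in assignments) f <- f + production_counts(p, g)
  v <- .draw_theta(f, .alpha_vec(alpha, g), .lhs_blocks(g))
  make_theta(setNames(v, g$productions$id), g)
}

#' Sample explaining programs from their exact conditional
#'
#' Draws programs with probability proportional to their probability under
#' theta, restricted to the programs that compute the observed sequence
#' (the likelihood is exact-match). With a materialised enumeration this is
#' the literal multinomial over the program list; otherwise the draw is by
#' stochastic backtracking through the inside-weighted enumeration DP —
#' the same distribution without materialisation.
#'
#' @param anchor,sequence the observed trial.
#' @param theta a \code{geo_theta}.
#' @param g a \code{geo_grammar}.
#' @param enumeration optional \code{geo_enumeration} with materialised
#'   \code{programs}.
#' @param n number of draws.
#' @return A \code{geo_program} when \code{n = 1}, else a list of them.
#' @export
sample_program_posterior <- function(anchor, sequence, theta, g,
                                     enumeration = NULL, n = 1L) {
  th <- .theta_vec(theta, g)
  if (!is.null(enumeration) && !is.null(enumeration$programs)) {
    progs <- enumeration$programs
    if (length(progs) == 0L)
      stop("no explaining program for anchor ", anchor, ", sequence (",
           paste(sequence, collapse = ","), ")")
    lp <- vapply(progs, program_log_prob, numeric(1), theta = theta, g = g)
    pr <- exp(lp - max(lp))
    idx <- sample.int(length(progs), n, replace = TRUE, prob = pr)
    out <- progs[idx]
  } else {
    circ <- .geo_circuit(anchor, sequence, g)
    ins <- .circuit_inside(circ, th)
    if (!(ins$root_value > 0))
      stop("no explaining program for anchor ", anchor, ", sequence (",
           paste(sequence, collapse = ","), ")")
    out <- lapply(seq_len(n), function(i)
      .edges_to_program(circ, .circuit_sample_edges(circ, ins), g))
  }
  if (n == 1L) out[[1]] else out
}

#' Gibbs sampler for production probabilities
#'
#' Runs independent MCMC chains over the joint posterior of (programs,
#' theta) given the observed trials, marginalising over programs by
#' alternating two exact conditional draws: each trial's explaining program
#' given theta (via the enumeration DP) and theta given the sampled
#' production counts (conjugate Dirichlet). Chains start at the per-block
#' uniform theta.
#'
#' @param dataset a \code{geo_trials} dataset (see [geo_trials()]).
#' @param g a \code{geo_grammar}.
#' @param config a [inference_config()].
#' @param keep_programs \code{"none"} (default), \code{"last"} (final
#'   sampled program per trial) or \code{"all"} (serialized draws per step;
#'   intended for small diagnostics).
#' @param progress print per-chain progress.
#' @return An object of class \code{geo_posterior}: \code{traces} (array
#'   chain x step x production), \code{summary} (per-production posterior
#'   mean and naive standard error over pooled post-burn-in samples),
#'   \code{config}, \code{production_ids}, \code{grammar_hash}.
#' @export
gibbs_infer <- function(dataset, g, config = inference_config(),
                        keep_programs = c("none", "last", "all"),
                        progress = FALSE) {
  keep_programs <- match.arg(keep_programs)
  trials <- as_trial_list(dataset)
  if (length(trials) == 0L) stop("empty dataset")
  np <- nrow(g$productions)
  blocks <- .lhs_blocks(g)
  alpha_v <- .alpha_vec(config$alpha, g)

  # circuits are theta-independent: build once per unique (anchor, sequence)
  keys <- vapply(trials, function(tr)
    paste0(tr$anchor, ":", paste(tr$sequence, collapse = "")), character(1))
  ukeys <- unique(keys)
  circs <- vector("list", length(ukeys))
  names(circs) <- ukeys
  for (i in seq_along(ukeys)) {
    tr <- trials[[match(ukeys[i], keys)]]
    circ <- .geo_circuit(tr$anchor, tr$sequence, g)
    if (.circuit_count(circ) == 0)
      stop("trial ", tr$subject_id, "/", tr$trial_id,
           " has no explaining program under this grammar")
    circs[[i]] <- circ
  }
  trial_circ <- match(keys, ukeys)

  n_trials <- length(trials)
  traces <- array(NA_real_,
                  dim = c(config$n_chains, config$n_steps, np),
                  dimnames = list(NULL, NULL, g$productions$id))
  prog_draws <- if (keep_programs == "all")
    vector("list", config$n_chains) else NULL
  last_programs <- NULL

  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain)
    th <- unname(theta_uniform(g))
    chain_draws <- if (keep_programs == "all")
      matrix(NA_character_, config$n_steps, n_trials) else NULL
    for (step in seq_len(config$n_steps)) {
      f <- numeric(np)
      for (i in seq_len(n_trials)) {
        circ <- circs[[trial_circ[i]]]
        ins <- .circuit_inside(circ, th)
        edges <- .circuit_sample_edges(circ, ins)
        f <- f + .edges_to_counts(circ, edges, np)
        if (keep_programs == "all")
          chain_draws[step, i] <-
            serialize_program(.edges_to_program(circ, edges, g))
        if (keep_programs == "last" && step == config$n_steps &&
            chain == config$n_chains) {
          if (is.null(last_programs))
            last_programs <- vector("list", n_trials)
          last_programs[[i]] <- .edges_to_program(circ, edges, g)
        }
      }
      th <- .draw_theta(f, alpha_v, blocks)
      traces[chain, step, ] <- th
    }
    if (keep_programs == "all") prog_draws[[chain]] <- chain_draws
    if (progress) message("chain ", chain, " done")
  }

  res <- structure(list(
    traces = traces,
    production_ids = g$productions$id,
    config = config,
    grammar_hash = g$hash,
    program_draws = prog_draws,
    last_programs = last_programs,
    schema_version = 1L
  ), class = "geo_posterior")
  res$summary <- summarize_posterior(res)
  res
}

#' @export
print.geo_posterior <- function(x, ...) {
  cat(sprintf("<geo_posterior> %d chains x %d steps, %d productions (burn-in %d)\n",
              dim(x$traces)[1], dim(x$traces)[2], dim(x$traces)[3],
              x$config$burn_in))
  print(utils::head(x$summary, 12))
  if (nrow(x$summary) > 12) cat("...\n")
  invisible(x)
}

.post_samples <- function(result, production = NULL) {
  keep <- seq(result$config$burn_in + 1L, dim(result$traces)[2])
  if (is.null(production)) {
    m <- result$traces[, keep, , drop = FALSE]
    matrix(m, ncol = dim(m)[3],
           dimnames = list(NULL, result$production_ids))
  } else {
    if (!production %in% result$production_ids)
      stop("production ", production, " not present in this result")
    as.vector(result$traces[, keep, production])
  }
}

#' Posterior means and standard errors
#'
#' Pools the post-burn-in theta samples of all chains and reports each
#' production's mean and standard error. The default SE is the naive pooled
#' one; \code{ess_correct = TRUE} inflates it by the autocorrelation-based
#' effective sample size.
#'
#' @param result a \code{geo_posterior}.
#' @param ess_correct correct the SE for autocorrelation.
#' @return Data frame with columns \code{production}, \code{family} is
#'   omitted here (see [group_by_family()]), \code{mean}, \code{se}.
#' @export
summarize_posterior <- function(result, ess_correct = FALSE) {
  if (result$config$burn_in >= dim(result$traces)[2])
    stop("burn_in >= n_steps: no post-burn-in samples")
  s <- .post_samples(result)
  n <- nrow(s)
  se <- apply(s, 2, sd) / sqrt(n)
  if (ess_correct) {
    ess <- apply(s, 2, .ess)
    se <- apply(s, 2, sd) / sqrt(pmax(ess, 1))
  }
  data.frame(production = result$production_ids,
             mean = colMeans(s), se = se, row.names = NULL)
}

# initial-positive-sequence effective sample size
.ess <- function(x) {
  n <- length(x)
  if (sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 50L), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Aggregate posterior mass by production family
#'
#' Sums posterior mean probabilities within family tags (clockwise,
#' anticlockwise, stay, symmetry, ad-hoc, concatenation, repetition, ...),
#' the grouping used to contrast repetition against plain concatenation and
#' to expose the low total mass of the ad-hoc productions.
#'
#' @param summary the \code{summary} data frame of a \code{geo_posterior}
#'   (or a \code{geo_posterior} itself).
#' @param family_map named character vector production id -> family tag;
#'   defaults to the grammar families via \code{g}.
#' @param g grammar used for the default family map.
#' @return Data frame with columns \code{family}, \code{total},
#'   \code{members}.
#' @export
group_by_family <- function(summary, family_map = NULL, g = NULL) {
  if (inherits(summary, "geo_posterior")) summary <- summary$summary
  if (is.null(family_map)) {
    if (is.null(g)) stop("provide family_map or g")
    family_map <- production_families(g)
  }
  if (!all(summary$production %in% names(family_map)))
    stop("family_map does not cover all productions")
  fam <- family_map[summary$production]
  agg <- tapply(summary$mean, fam, sum)
  data.frame(
    family = names(agg),
    total = as.numeric(agg),
    members = vapply(names(agg), function(f)
      paste(summary$production[fam == f], collapse = ","), character(1)),
    row.names = NULL)
}

#' Compare a production's posterior between two populations
#'
#' Welch two-sample t-test on the pooled post-burn-in theta samples of the
#' production in each result (negative t means the first population's mean
#' is lower). With \code{production = NULL} every production is tested and
#' p-values are Bonferroni-adjusted.
#'
#' @param result_a,result_b \code{geo_posterior} objects over the same
#'   grammar.
#' @param production a production id, or \code{NULL} for a grammar-wide
#'   scan.
#' @return An \code{htest} for a single production; a data frame
#'   (\code{production}, \code{t}, \code{p_value}, \code{p_adjusted}) for a
#'   scan.
#' @export
compare_populations <- function(result_a, result_b, production = NULL) {
  if (!identical(result_a$production_ids, result_b$production_ids))
    stop("results cover different production inventories")
  if (!is.null(production)) {
    x <- .post_samples(result_a, production)
    y <- .post_samples(result_b, production)
    return(t.test(x, y))
  }
  tests <- lapply(result_a$production_ids, function(pid)
    t.test(.post_samples(result_a, pid), .post_samples(result_b, pid)))
  p <- vapply(tests, function(tt) tt$p.value, numeric(1))
  data.frame(production = result_a$production_ids,
             t = vapply(tests, function(tt) unname(tt$statistic), numeric(1)),
             p_value = p,
             p_adjusted = p.adjust(p, method = "bonferroni"),
             row.names = NULL)
}
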