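# Algorithmic probability relative to the language of geometry, and the
# empirical Coding-Theorem experiment relating it to description length.

#' Algorithmic probability of a sequence
#'
#' The unnormalised probability of a sequence relative to the grammar and
#' theta: the sum, over every program that computes the sequence from the
#' anchor, of the program's probability under theta. Computed by the
#' probability-weighted (inside) form of the enumeration DP, so no program
#' list is materialised; on small inputs it equals the explicit sum of
#' \code{exp(program_log_prob(...))} over [enumerate_programs()].
#'
#' @inheritParams enumerate_programs
#' @param theta a \code{geo_theta}.
#' @return Non-negative probability mass (unnormalised).
#' @export
sequence_probability <- function(anchor, sequence, g, theta) {
  th <- .theta_vec(theta, g)
  circ <- .geo_circuit(anchor, sequence, g)
  .circuit_inside(circ, th)$root_value
}

#' Sample unique (anchor, sequence) records of a given length
#'
#' Uniform sample without replacement over all \code{8^(L+1)} pairs of an
#' anchor and a length-L sequence; exhaustive when there are at most
#' \code{max_n} pairs.
#'
#' @param L sequence length (>= 1).
#' @param max_n maximum number of records (default 10000).
#' @return Data frame with columns \code{anchor} and \code{s1..sL}.
#' @export
sample_unique_records <- function(L, max_n = 10000L) {
  stopifnot(L >= 1L)
  total <- 8^(L + 1)
  codes <- if (total <= max_n) seq_len(total) - 1
           else sample.int(total, max_n) - 1
  out <- matrix(0L, length(codes), L + 1L)
  rest <- codes
  for (j in (L + 1L):1L) {  # least-significant digit = last sequence point
    out[, j] <- as.integer(rest %% 8)
    rest <- rest %/% 8
  }
  df <- as.data.frame(out)
  names(df) <- c("anchor", paste0("s", seq_len(L)))
  df
}

#' Empirical Coding-Theorem experiment
#'
#' For each requested length: sample unique (anchor, sequence) records,
#' compute each record's description length K and algorithmic probability P
#' from one shared DP circuit, group records with identical K, average P
#' within each group, and fit ordinary least squares of log10(mean P) on K.
#' An inverse log-linear relation (negative slope, high R^2) is the
#' Coding-Theorem pattern.
#'
#' @param theta a \code{geo_theta}.
#' @param g a \code{geo_grammar}.
#' @param lengths sequence lengths to test (subset of 1..8).
#' @param max_n records per length (default 10000).
#' @return Object of class \code{geo_codingfit}: \code{fits} (per-length
#'   slope, intercept, r_squared, n_sequences), \code{groups} (per-length
#'   K, mean P, count) and \code{records} (per-record anchor, sequence,
#'   k_geo, p_geo).
#' @export
coding_theorem_experiment <- function(theta, g, lengths = 4:8,
                                      max_n = 10000L) {
  stopifnot(all(lengths >= 1L), all(lengths <= 8L))
  th <- .theta_vec(theta, g)
  fits <- list(); groups <- list(); records <- list()
  for (L in lengths) {
    recs <- sample_unique_records(L, max_n)
    seqs <- as.matrix(recs[, -1, drop = FALSE])
    n <- nrow(recs)
    K <- numeric(n); P <- numeric(n)
    for (i in seq_len(n)) {
      circ <- .geo_circuit(recs$anchor[i], seqs[i, ], g)
      K[i] <- .circuit_min_cost(circ)
      P[i] <- .circuit_inside(circ, th)$root_value
    }
    recs$k_geo <- K
    recs$p_geo <- P
    fit <- fit_coding_relation(K, P)
    fits[[as.character(L)]] <- data.frame(length = L, slope = fit$slope,
                                          intercept = fit$intercept,
                                          r_squared = fit$r_squared,
                                          n_sequences = n)
    fit$groups$length <- L
    groups[[as.character(L)]] <- fit$groups
    records[[as.character(L)]] <- recs
  }
  structure(list(fits = do.call(rbind, c(fits, make.row.names = FALSE)),
                 groups = do.call(rbind, c(groups, make.row.names = FALSE)),
                 records = records),
            class = "geo_codingfit")
}

#' Fit the log-linear complexity/probability relation
#'
#' @param k,p vectors of per-record complexity and probability.
#' @return List: \code{slope}, \code{intercept}, \code{r_squared} (all
#'   \code{NA} when fewer than two distinct complexity values or no positive
#'   mean probabilities), and \code{groups} (K, mean_p, count).
#' @export
fit_coding_relation <- function(k, p) {
  mean_p <- tapply(p, k, mean)
  groups <- data.frame(k = as.numeric(names(mean_p)),
                       mean_p = as.numeric(mean_p),
                       count = as.integer(table(k)), row.names = NULL)
  ok <- groups$mean_p > 0
  if (sum(ok) < 2L)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, groups = groups))
  fit <- lm(log10(mean_p) ~ k, data = groups[ok, ])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, groups = groups)
}

#' @export
print.geo_codingfit <- function(x, ...) {
  cat("<geo_codingfit>\n")
  print(x$fits)
  invisible(x)
}

#' Histograms of complexity and probability
#'
#' Base-graphics convenience mirroring the usual complexity / probability
#' histograms for one length.
#'
#' @param x a \code{geo_codingfit}.
#' @param length which sequence length to plot.
#' @param ... passed to \code{hist}.
#' @export
plot.geo_codingfit <- function(x, length = NULL, ...) {
  ln <- if (is.null(length)) names(x$records)[1] else as.character(length)
  recs <- x$records[[ln]]
  if (is.null(recs)) stop("length ", ln, " not present in this experiment")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(recs$k_geo, main = paste0("K, |x| = ", ln),
                 xlab = "complexity", ...)
  graphics::hist(log10(recs$p_geo), main = paste0("log10 P, |x| = ", ln),
                 xlab = "log10 probability", ...)
  invisible(x)
}
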