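# Trial datasets, CSV readers/writers, grammar config and results JSON.
# Positions are 0-based everywhere (the alphabet is {0..7}); behavioural
# files with 1-based labels must be shifted before loading.

#' Construct a trial dataset
#'
#' A trial is an anchor (the starting vertex, not itself part of the
#' response) plus the observed point sequence. Stored as a data frame with
#' a list column of sequences.
#'
#' @param subject_id,trial_id character vectors.
#' @param anchor integer vector of positions in 0..7.
#' @param sequences list of integer vectors (each length 1..8, values
#'   0..7).
#' @return An object of class \code{geo_trials}.
#' @export
geo_trials <- function(subject_id, trial_id, anchor, sequences) {
  anchor <- .check_positions(anchor, "anchor")
  sequences <- lapply(sequences, .check_positions, what = "sequence point")
  if (any(lengths(sequences) < 1L)) stop("sequences must be non-empty")
  n <- length(anchor)
  stopifnot(length(subject_id) == n, length(trial_id) == n,
            length(sequences) == n)
  if (anyDuplicated(paste(subject_id, trial_id)))
    stop("trial ids must be unique within subject")
  df <- data.frame(subject_id = as.character(subject_id),
                   trial_id = as.character(trial_id),
                   anchor = anchor, stringsAsFactors = FALSE)
  df$seq <- sequences
  structure(df, class = c("geo_trials", "data.frame"))
}

#' @export
print.geo_trials <- function(x, ...) {
  cat(sprintf("<geo_trials> %d trials, %d subjects\n", nrow(x),
              length(unique(x$subject_id))))
  invisible(x)
}

#' Dataset as a list of trials
#'
#' @param dataset a \code{geo_trials}.
#' @return List of \code{list(subject_id, trial_id, anchor, sequence)}.
#' @export
as_trial_list <- function(dataset) {
  stopifnot(inherits(dataset, "geo_trials"))
  lapply(seq_len(nrow(dataset)), function(i)
    list(subject_id = dataset$subject_id[i], trial_id = dataset$trial_id[i],
         anchor = dataset$anchor[i], sequence = dataset$seq[[i]]))
}

#' @export
as.data.frame.geo_trials <- function(x, ...) {
  L <- max(lengths(x$seq))
  pts <- t(vapply(x$seq, function(s) c(s, rep(NA_integer_, L - length(s))),
                  integer(L)))
  df <- data.frame(subject_id = x$subject_id, trial_id = x$trial_id,
                   anchor = x$anchor)
  df[paste0("p", seq_len(L))] <- as.data.frame(pts)
  df
}

#' Read a trials CSV
#'
#' The file has a header \code{subject_id,trial_id,anchor,p1,...,pL}
#' (ragged rows padded with blanks). In \code{"explicit"} mode the anchor
#' column holds the starting vertex; in \code{"first_point"} mode there is
#' no anchor column, the first recorded point is taken as the anchor and
#' the remaining points as the sequence.
#'
#' @param path CSV path.
#' @param anchor_mode \code{"explicit"} or \code{"first_point"}.
#' @return A \code{geo_trials}.
#' @export
read_trials <- function(path, anchor_mode = c("explicit", "first_point")) {
  anchor_mode <- match.arg(anchor_mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty trials file: ", path)
  need <- c("subject_id", "trial_id",
            if (anchor_mode == "explicit") "anchor")
  if (!all(need %in% names(df)))
    stop("missing columns in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anchor_mode == "first_point" && "anchor" %in% names(df))
    stop("first_point mode expects no anchor column (header shape mismatch)")
  pcols <- grep("^p[0-9]+$", names(df), value = TRUE)
  pcols <- pcols[order(as.integer(sub("p", "", pcols)))]
  if (length(pcols) == 0L) stop("no point columns p1..pL in ", path)
  pts <- as.matrix(df[pcols])
  bad <- which(!is.na(pts) & (pts < 0 | pts > 7 | pts != floor(pts)),
               arr.ind = TRUE)
  if (length(bad))
    stop("out-of-range position in row ", bad[1, 1], ", column ",
         pcols[bad[1, 2]], " of ", path)
  seqs <- lapply(seq_len(nrow(pts)), function(i) {
    v <- pts[i, ]
    v <- v[seq_len(max(which(!is.na(v))))]
    if (anyNA(v)) stop("gap in point columns at row ", i, " of ", path)
    as.integer(v)
  })
  if (anchor_mode == "explicit") {
    anchor <- df$anchor
    if (anyNA(anchor) || any(anchor < 0 | anchor > 7))
      stop("out-of-range anchor in ", path, " (row ",
           which(is.na(anchor) | anchor < 0 | anchor > 7)[1], ")")
  } else {
    anchor <- vapply(seqs, `[`, integer(1), 1L)
    seqs <- lapply(seqs, `[`, -1L)
    if (any(lengths(seqs) == 0L))
      stop("first_point mode needs at least two points per row")
  }
  geo_trials(df$subject_id, df$trial_id, anchor, seqs)
}

#' Write a trials CSV
#'
#' @param dataset a \code{geo_trials}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

# ---- grammar configuration ------------------------------------------------

#' Read / write a grammar configuration JSON
#'
#' The configuration records the production inventory switches: whether the
#' ad-hoc productions are included, the repetition-count interval, the
#' reflection axis constants, and the digit tables of the ad-hoc constants.
#'
#' @param g a \code{geo_grammar}.
#' @param path JSON path.
#' @return \code{read_grammar_config} returns a \code{geo_grammar}.
#' @export
write_grammar_config <- function(g, path) {
  jsonlite::write_json(list(
    include_adhoc = g$include_adhoc,
    rep_range = g$rep_range,
    axes = as.list(g$axes),
    digits = g$digit_tables
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grammar_config
#' @export
read_grammar_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  geo_grammar(include_adhoc = isTRUE(cfg$include_adhoc),
              axes = unlist(cfg$axes),
              rep_range = cfg$rep_range,
              digits = cfg$digits)
}

# ---- results JSON ---------------------------------------------------------

#' Write / read inference results
#'
#' Schema-versioned JSON holding the posterior traces, summary, config and
#' the grammar hash, so results from different grammars cannot be silently
#' combined. A \code{.gz} suffix (or \code{gzip = TRUE}) compresses.
#'
#' @param result a \code{geo_posterior}.
#' @param path output path.
#' @param gzip compress the JSON.
#' @return \code{read_results} returns the \code{geo_posterior}.
#' @export
write_results <- function(result, path, gzip = grepl("\\.gz$", path)) {
  stopifnot(inherits(result, "geo_posterior"))
  payload <- list(
    schema_version = 1L,
    grammar_hash = result$grammar_hash,
    config = unclass(result$config),
    production_ids = result$production_ids,
    traces = result$traces,
    summary = result$summary
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.character(js), con)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  payload <- jsonlite::fromJSON(paste(readLines(con), collapse = "\n"))
  if (is.null(payload$schema_version) || payload$schema_version != 1L)
    stop("unsupported results schema in ", path)
  traces <- payload$traces
  dimnames(traces) <- list(NULL, NULL, payload$production_ids)
  cfg <- payload$config
  structure(list(
    traces = traces,
    production_ids = payload$production_ids,
    config = inference_config(alpha = cfg$alpha, n_steps = cfg$n_steps,
                              burn_in = cfg$burn_in, n_chains = cfg$n_chains,
                              seed = cfg$seed),
    grammar_hash = payload$grammar_hash,
    summary = payload$summary,
    schema_version = 1L
  ), class = "geo_posterior")
}

#' Pool the chains of two posteriors over the same grammar
#'
#' Refuses to merge results whose grammar hashes differ.
#'
#' @param a,b \code{geo_posterior} objects.
#' @return A \code{geo_posterior} with the chains of both.
#' @export
merge_posteriors <- function(a, b) {
  if (!identical(a$grammar_hash, b$grammar_hash))
    stop("cannot merge results from different grammars (hash mismatch)")
  if (!identical(dim(a$traces)[2:3], dim(b$traces)[2:3]) ||
      a$config$burn_in != b$config$burn_in)
    stop("cannot merge results with different step/burn-in structure")
  traces <- array(NA_real_, dim = c(dim(a$traces)[1] + dim(b$traces)[1],
                                    dim(a$traces)[2], dim(a$traces)[3]),
                  dimnames = dimnames(a$traces))
  traces[seq_len(dim(a$traces)[1]), , ] <- a$traces
  traces[dim(a$traces)[1] + seq_len(dim(b$traces)[1]), , ] <- b$traces
  out <- a
  out$traces <- traces
  out$config$n_chains <- dim(traces)[1]
  out$summary <- summarize_posterior(out)
  out
}
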