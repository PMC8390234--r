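# Two-round Baum-Welch training with BIC model selection, low-occupancy
# state pruning, Viterbi decoding and per-mark marginalization.

as_seq_list <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequence_list(sequences)
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- lapply(sequences, as.integer)
  if (!length(sequences) || !sum(lengths(sequences))) {
    stop("no observation sequences supplied")
  }
  sequences
}

#' Baum-Welch training
#'
#' Runs expectation-maximization from `model0` until the log-likelihood
#' improvement drops below `tol` or `max_iter` iterations are reached.
#' Sequences are treated as independent; the initial distribution is
#' re-estimated from per-sequence first positions.  An emission floor of
#' `em_floor` is applied after each M-step so the large bitmask alphabet
#' (where many symbols are unseen) cannot zero-lock a state.
#'
#' @param sequences List of integer symbol vectors (0-based symbols), or the
#'   table returned by [build_sequences()].
#' @param model0 Starting `hmm_model`.
#' @param max_iter Iteration cap (first round default 300).
#' @param tol Log-likelihood convergence tolerance.
#' @param em_floor Emission probability floor.
#' @return A `nuc_training_result`: list with `model`,
#'   `log_likelihood_trace`, `loglik`, `bic`, `state_occupancy` (fraction of
#'   nucleosomes Viterbi-assigned to each state) and `n_obs`.
#' @export
baum_welch <- function(sequences, model0, max_iter = 300L, tol = 1e-4,
                       em_floor = 1e-10) {
  stopifnot(max_iter >= 1L)
  seqs <- as_seq_list(sequences)
  V <- n_symbols(model0)
  rng <- range(unlist(seqs))
  if (rng[1] < 0L || rng[2] >= V) stop("symbol out of range [0, V)")
  fit <- bw_fit_cpp(model0$pi, model0$A, model0$B, seqs,
                    as.integer(max_iter), tol, em_floor)
  model <- hmm_model(fit$pi, fit$A, fit$B, mark_order = model0$mark_order)
  n_obs <- sum(lengths(seqs))
  occ <- state_occupancy(model, seqs)
  res <- list(model = model, log_likelihood_trace = fit$trace,
              loglik = fit$loglik, bic = bic(model, fit$loglik, n_obs),
              state_occupancy = occ, n_obs = n_obs)
  class(res) <- "nuc_training_result"
  res
}

#' @export
print.nuc_training_result <- function(x, ...) {
  cat(sprintf(
    "<nuc_training_result> %d states, logL = %.2f, BIC = %.2f, %d iter\n",
    n_states(x$model), x$loglik, x$bic, length(x$log_likelihood_trace)))
  invisible(x)
}

#' Bayesian information criterion of a fitted HMM
#'
#' `BIC = k ln(n_obs) - 2 logL` with free-parameter count
#' `k = (S-1) + S(S-1) + S(V-1)` (initial distribution, transition rows and
#' emission rows each lose one degree of freedom to normalization).
#'
#' @param model An `hmm_model`.
#' @param logL Model log-likelihood on the training data.
#' @param n_obs Total number of observations (nucleosomes).
#' @return BIC value (smaller is better).
#' @export
bic <- function(model, logL, n_obs) {
  stopifnot(n_obs >= 1)
  S <- n_states(model); V <- n_symbols(model)
  k <- (S - 1) + S * (S - 1) + S * (V - 1)
  k * log(n_obs) - 2 * logL
}

#' Log-likelihood of sequences under a model
#'
#' @param model An `hmm_model`.
#' @param sequences Observation sequences (see [baum_welch()]).
#' @return Total log-likelihood (scaled forward algorithm).
#' @export
hmm_loglik <- function(model, sequences) {
  seqs <- as_seq_list(sequences)
  hmm_loglik_cpp(model$pi, model$A, model$B, seqs)
}

#' Viterbi-path state occupancy
#'
#' @param model An `hmm_model`.
#' @param sequences Observation sequences (see [baum_welch()]).
#' @return Numeric vector: fraction of observations decoded into each state.
#' @export
state_occupancy <- function(model, sequences) {
  seqs <- as_seq_list(sequences)
  counts <- numeric(n_states(model))
  for (s in seqs) {
    p <- viterbi_cpp(model$pi, model$A, model$B, s) + 1L
    tab <- tabulate(p, nbins = n_states(model))
    counts <- counts + tab
  }
  counts / sum(counts)
}

#' First-round model selection over a state range
#'
#' Trains `replicates` seeded random initializations for every state count
#' in `state_range` and returns the fit with minimum BIC; ties are broken
#' toward fewer states, then toward the lower replicate seed.
#'
#' @param sequences Observation sequences.
#' @param n_symbols Alphabet size V.
#' @param state_range Integer vector of candidate state counts
#'   (default 15:25).
#' @param replicates Random restarts per state count (default 5).
#' @param max_iter,tol Passed to [baum_welch()].
#' @param seed Base seed; the seed of replicate r at S states is
#'   `seed + 1000*S + r`.
#' @return The best `nuc_training_result`, with `all_bic` (data.frame of
#'   every candidate's BIC) attached.
#' @export
select_best <- function(sequences, n_symbols, state_range = 15:25,
                        replicates = 5L, max_iter = 300L, tol = 1e-4,
                        seed = 1L) {
  stopifnot(length(state_range) >= 1L, replicates >= 1L)
  seqs <- as_seq_list(sequences)
  best <- NULL
  grid <- expand.grid(rep = seq_len(replicates), S = sort(state_range))
  all_bic <- data.frame(S = grid$S, rep = grid$rep, bic = NA_real_,
                        loglik = NA_real_)
  for (i in seq_len(nrow(grid))) {
    S <- grid$S[i]; r <- grid$rep[i]
    m0 <- init_hmm_model(S, n_symbols, seed = seed + 1000L * S + r)
    fit <- baum_welch(seqs, m0, max_iter = max_iter, tol = tol)
    all_bic$bic[i] <- fit$bic
    all_bic$loglik[i] <- fit$loglik
    # strict < : earlier candidates (fewer states, lower replicate) win ties
    if (is.null(best) || fit$bic < best$bic) best <- fit
  }
  best$all_bic <- all_bic
  best
}

#' Prune low-occupancy states
#'
#' States holding less than `cutoff` (default 0.5%) of the nucleosomes are
#' removed from pi, A and B; for each surviving row the probability mass
#' that pointed at removed destinations is redistributed evenly over the
#' surviving destinations, so every row still sums to 1.
#'
#' @param model An `hmm_model`.
#' @param occupancy Per-state occupancy fractions (e.g. from a
#'   `nuc_training_result`).
#' @param cutoff Occupancy threshold.
#' @return The pruned `hmm_model`, with attribute `kept` giving the
#'   surviving original state indices.
#' @export
prune_states <- function(model, occupancy, cutoff = 0.005) {
  stopifnot(length(occupancy) == n_states(model))
  keep <- which(occupancy >= cutoff)
  if (!length(keep)) stop("all states fall below the occupancy cutoff")
  if (length(keep) == n_states(model)) {
    out <- model
    attr(out, "kept") <- keep
    return(out)
  }
  nk <- length(keep)
  pi <- model$pi[keep]
  pi <- pi + (1 - sum(pi)) / nk
  A <- model$A[keep, keep, drop = FALSE]
  A <- A + (1 - rowSums(A)) / nk
  B <- model$B[keep, , drop = FALSE]
  out <- hmm_model(pi, A, B, mark_order = model$mark_order)
  attr(out, "kept") <- keep
  out
}

#' Second-round retraining of a pruned model
#'
#' @inheritParams baum_welch
#' @param pruned The pruned `hmm_model` used as the starting point.
#' @param max_iter Second-round iteration cap (default 200).
#' @return A `nuc_training_result`.
#' @export
retrain <- function(sequences, pruned, max_iter = 200L, tol = 1e-4) {
  baum_welch(sequences, pruned, max_iter = max_iter, tol = tol)
}

#' Viterbi decoding
#'
#' Maximum-probability state path in log space; ties are broken toward the
#' lower state index.
#'
#' @param sequence Integer symbol vector (0-based).
#' @param model An `hmm_model`.
#' @return Integer state path (1-based states).
#' @export
viterbi <- function(sequence, model) {
  sequence <- as.integer(sequence)
  if (length(sequence) &&
      (min(sequence) < 0L || max(sequence) >= n_symbols(model))) {
    stop("symbol out of range [0, V)")
  }
  viterbi_cpp(model$pi, model$A, model$B, sequence) + 1L
}

#' Per-mark marginal emission probabilities (mark-state matrix)
#'
#' For each state and mark, sums the emission probabilities of every symbol
#' whose bitmask carries that mark's bit, giving the marginal probability
#' that the state emits the mark.
#'
#' @param model An `hmm_model` whose alphabet size is `2^n`.
#' @param n Number of marks.
#' @param mark_order Optional mark names for the columns.
#' @return S x n matrix of probabilities in `[0, 1]`.
#' @export
mark_state_matrix <- function(model, n, mark_order = model$mark_order) {
  V <- n_symbols(model)
  if (V != bitwShiftL(1L, n)) stop("alphabet size is not 2^n")
  syms <- 0:(V - 1L)
  out <- vapply(0:(n - 1L), function(id) {
    carry <- bitwAnd(syms, bitwShiftL(1L, id)) > 0L
    rowSums(model$B[, carry, drop = FALSE])
  }, numeric(n_states(model)))
  out <- matrix(out, nrow = n_states(model))
  colnames(out) <- mark_order[seq_len(n)] %||% paste0("mark", 0:(n - 1L))
  out
}

#' Decode a full observation table
#'
#' Runs [viterbi()] per gene sequence and returns the table with a `state`
#' column appended.
#'
#' @param seq_table Table from [build_sequences()].
#' @param model An `hmm_model`.
#' @return The input table with `state` (1-based) added.
#' @export
decode_states <- function(seq_table, model) {
  dt <- data.table::as.data.table(seq_table)
  dt[, state := {
    as.integer(viterbi(symbol, model))
  }, by = gene_id]
  dt[]
}
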