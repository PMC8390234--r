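# The HMM container: initial probabilities pi (length S), transition matrix
# A (S x S), emission matrix B (S x V) over the 2^n bitmask alphabet.

#' Construct a discrete HMM
#'
#' @param pi Initial-state probability vector (length S, sums to 1).
#' @param A S x S row-stochastic transition matrix.
#' @param B S x V row-stochastic emission matrix; V is typically `2^n` for
#'   `n` histone marks.
#' @param mark_order Optional character vector recording the mark bit
#'   ordering the alphabet was built with.
#' @return An object of class `hmm_model`.
#' @export
hmm_model <- function(pi, A, B, mark_order = NULL) {
  pi <- as.numeric(pi)
  A <- as.matrix(A); B <- as.matrix(B)
  m <- structure(list(pi = pi, A = A, B = B, mark_order = mark_order),
                 class = "hmm_model")
  validate_hmm_model(m)
  m
}

validate_hmm_model <- function(m, tol = 1e-9) {
  S <- length(m$pi)
  stopifnot(nrow(m$A) == S, ncol(m$A) == S, nrow(m$B) == S)
  if (any(m$pi < 0) || any(m$A < 0) || any(m$B < 0)) {
    stop("hmm_model: negative probabilities")
  }
  if (abs(sum(m$pi) - 1) > tol) stop("hmm_model: pi does not sum to 1")
  if (any(abs(rowSums(m$A) - 1) > tol)) {
    stop("hmm_model: transition rows do not sum to 1")
  }
  if (any(abs(rowSums(m$B) - 1) > tol)) {
    stop("hmm_model: emission rows do not sum to 1")
  }
  invisible(m)
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states, %d symbols\n",
              n_states(x), n_symbols(x)))
  invisible(x)
}

#' Number of hidden states / observation symbols of a model
#' @param model An `hmm_model`.
#' @return Integer count.
#' @export
n_states <- function(model) length(model$pi)

#' @rdname n_states
#' @export
n_symbols <- function(model) ncol(model$B)

# Dirichlet(1) row
rdirichlet_row <- function(k, alpha = 1) {
  g <- rgamma(k, shape = alpha)
  g / sum(g)
}

#' Random HMM initialization
#'
#' Draws pi and each row of A and B from a symmetric Dirichlet under a fixed
#' seed; used to seed Baum-Welch replicates.
#'
#' @param n_states,n_symbols Model dimensions.
#' @param seed Integer RNG seed.
#' @param alpha Dirichlet concentration (1 = uniform over the simplex).
#' @return An `hmm_model`.
#' @export
init_hmm_model <- function(n_states, n_symbols, seed, alpha = 1) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  pi <- rdirichlet_row(n_states, alpha)
  A <- t(vapply(seq_len(n_states), function(i) rdirichlet_row(n_states, alpha),
                numeric(n_states)))
  B <- t(vapply(seq_len(n_states),
                function(i) rdirichlet_row(n_symbols, alpha),
                numeric(n_symbols)))
  if (n_states == 1L) { A <- matrix(1, 1, 1); B <- matrix(B, nrow = 1) }
  hmm_model(pi, A, B)
}
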