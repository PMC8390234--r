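# Independent oracles and small fixture builders shared across tests.
# These deliberately use naive algorithms (enumeration, quadratic scans)
# so they stay independent of the package's implementations.

# log-probability of one (path, observations) pair
path_logprob <- function(pi, A, B, path, obs) {
  lp <- log(pi[path[1]]) + log(B[path[1], obs[1] + 1])
  for (t in seq_along(obs)[-1]) {
    lp <- lp + log(A[path[t - 1], path[t]]) + log(B[path[t], obs[t] + 1])
  }
  lp
}

# exhaustive Viterbi: enumerate all S^T paths, return max log-probability
# and the set of maximizing paths
brute_viterbi <- function(pi, A, B, obs) {
  S <- length(pi); T <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  lp <- log(pi[grid[, 1]]) + log(B[cbind(grid[, 1], obs[1] + 1)])
  if (T > 1) {
    for (t in 2:T) {
      lp <- lp + log(A[cbind(grid[, t - 1], grid[, t])]) +
        log(B[cbind(grid[, t], obs[t] + 1)])
    }
  }
  best <- max(lp)
  list(logp = best, paths = grid[lp >= best - 1e-12, , drop = FALSE])
}

# exhaustive discrete Frechet: recursively enumerate monotone couplings
brute_frechet <- function(a, b) {
  da <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    d <- da(i, j)
    if (i == 1 && j == 1) return(d)
    opts <- c(
      if (i > 1) rec(i - 1, j),
      if (j > 1) rec(i, j - 1),
      if (i > 1 && j > 1) rec(i - 1, j - 1))
    max(min(opts), d)
  }
  rec(nrow(a), nrow(b))
}

# quadratic brute-force array grouping: same chrom, same state, all
# consecutive dyad gaps < max_gap
brute_arrays <- function(df, max_gap) {
  id <- integer(nrow(df))
  cur <- 1L
  id[1] <- 1L
  for (i in seq_len(nrow(df))[-1]) {
    same <- df$chrom[i] == df$chrom[i - 1] &&
      df$state[i] == df$state[i - 1] &&
      (df$dyad[i] - df$dyad[i - 1]) < max_gap
    if (!same) cur <- cur + 1L
    id[i] <- cur
  }
  id
}

# best permutation match of estimated vs true model; returns max absolute
# errors of A and B after relabeling
perm_match_error <- function(true, est) {
  S <- length(true$pi)
  perms <- as.matrix(expand.grid(rep(list(seq_len(S)), S)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == S), ,
                 drop = FALSE]
  best <- Inf; out <- NULL
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    eA <- max(abs(true$A - est$A[p, p, drop = FALSE]))
    eB <- max(abs(true$B - est$B[p, , drop = FALSE]))
    if (max(eA, eB) < best) { best <- max(eA, eB); out <- c(A = eA, B = eB) }
  }
  out
}

# simulate symbols at roughly 10k (or n-target) nucleosomes from a truth
# model through the synthetic module, returning per-gene symbol sequences
sim_sequences <- function(truth, n_genes, seed) {
  gen <- simulate_genome(n_genes, gene_len_range = c(8000L, 20000L),
                         seed = seed)
  sim <- simulate_states_and_marks(gen$genes, truth, seed = seed + 1L,
                                   n_marks = round(log2(n_symbols(truth))))
  list(seqs = split(sim$nucleosomes$symbol, sim$nucleosomes$gene_id),
       sim = sim, genes = gen$genes)
}

random_model <- function(S, V, seed) init_hmm_model(S, V, seed = seed)

# nucleosome table laid out on one chromosome with given states and gaps
toy_nuc_table <- function(states, gaps, chrom = "chr1", start0 = 1000L) {
  dyad <- start0 + cumsum(c(0L, gaps))
  data.frame(chrom = chrom, dyad = dyad, start = dyad - 73L,
             end = dyad + 74L, state = states)
}
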