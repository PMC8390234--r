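# HMM core: Baum-Welch, BIC, pruning, retraining, Viterbi, marginalization.

test_that("single-state Baum-Welch reduces to empirical symbol frequencies", {
  seqs <- list(c(0L, 1L, 1L, 2L), c(2L, 2L, 1L))
  m0 <- hmm_model(1, matrix(1), matrix(rep(0.25, 4), 1))
  fit <- baum_welch(seqs, m0, max_iter = 5)
  emp <- tabulate(unlist(seqs) + 1L, 4) / 7
  expect_equal(as.numeric(fit$model$B), emp, tolerance = 1e-8)
  expect_equal(fit$state_occupancy, 1)
})

test_that("Baum-Welch log-likelihood is monotone and improves the model", {
  set.seed(3)
  for (rep in 1:5) {
    seqs <- lapply(1:4, function(i) sample(0:7, 60, replace = TRUE))
    m0 <- init_hmm_model(3, 8, seed = rep)
    fit <- baum_welch(seqs, m0, max_iter = 50)
    expect_true(all(diff(fit$log_likelihood_trace) >= -1e-6))
    expect_gte(fit$loglik, fit$log_likelihood_trace[1])
    # stochasticity preserved
    expect_equal(sum(fit$model$pi), 1, tolerance = 1e-9)
    expect_equal(rowSums(fit$model$A), rep(1, 3), tolerance = 1e-9)
    expect_equal(rowSums(fit$model$B), rep(1, 3), tolerance = 1e-9)
  }
  expect_error(baum_welch(list(), init_hmm_model(2, 4, 1)), "no observation")
  expect_error(baum_welch(list(c(0L, 5L)), init_hmm_model(2, 4, 1)),
               "out of range")
})

test_that("bic applies the free-parameter count k ln(n) - 2 logL", {
  m <- init_hmm_model(2, 2, seed = 1)
  k <- (2 - 1) + 2 * (2 - 1) + 2 * (2 - 1)  # = 5
  expect_equal(bic(m, logL = -100, n_obs = 1000), 5 * log(1000) + 200)
  # lower BIC at equal logL for smaller S
  m3 <- init_hmm_model(3, 2, seed = 1)
  expect_lt(bic(m, -50, 500), bic(m3, -50, 500))
})

test_that("viterbi equals exhaustive path enumeration on small instances", {
  set.seed(11)
  for (rep in 1:25) {
    S <- sample(2:4, 1); V <- sample(2:5, 1); T <- sample(2:6, 1)
    m <- init_hmm_model(S, V, seed = 1000 + rep)
    obs <- sample(0:(V - 1), T, replace = TRUE)
    path <- viterbi(obs, m)
    oracle <- brute_viterbi(m$pi, m$A, m$B, obs)
    expect_equal(path_logprob(m$pi, m$A, m$B, path, obs), oracle$logp,
                 tolerance = 1e-9)
    if (nrow(oracle$paths) == 1L) {
      expect_equal(path, as.integer(oracle$paths[1, ]))
    }
  }
})

test_that("viterbi handles deterministic and uniform models", {
  # one-to-one emissions: path equals the symbol-to-state map
  B <- diag(3)
  A <- matrix(1 / 3, 3, 3)
  m <- hmm_model(rep(1 / 3, 3), A, B)
  obs <- c(2L, 0L, 1L, 1L)
  expect_equal(viterbi(obs, m), obs + 1L)
  # fully uniform model: tie-break toward the lowest state index
  mu <- hmm_model(rep(1 / 3, 3), A, matrix(1 / 4, 3, 4))
  expect_equal(viterbi(c(0L, 3L, 2L), mu), rep(1L, 3))
})

test_that("prune_states redistributes removed mass evenly", {
  A <- rbind(c(0.5, 0.3, 0.2), c(0.1, 0.6, 0.3), c(0.3, 0.3, 0.4))
  B <- matrix(1 / 4, 3, 4)
  m <- hmm_model(c(0.4, 0.4, 0.2), A, B)
  pruned <- prune_states(m, occupancy = c(0.6, 0.39, 0.004))
  expect_equal(n_states(pruned), 2L)
  expect_equal(pruned$A[1, ], c(0.6, 0.4))  # 0.2 split over 2 survivors
  expect_equal(pruned$A[2, ], c(0.25, 0.75))
  expect_equal(rowSums(pruned$A), c(1, 1))
  expect_equal(sum(pruned$pi), 1)
  expect_equal(attr(pruned, "kept"), 1:2)
  # no state below cutoff: unchanged
  same <- prune_states(m, occupancy = c(0.4, 0.3, 0.3))
  expect_equal(same$A, m$A)
  expect_error(prune_states(m, occupancy = c(1e-4, 1e-4, 1e-4)),
               "below the occupancy cutoff")
})

test_that("two-round training drops injected junk states", {
  set.seed(21)
  truth <- sim_truth_model(3, 3, seed = 8)
  sims <- sim_sequences(truth, n_genes = 20, seed = 30)
  # embed the 3 real states plus 2 junk states that are almost never
  # entered
  eps <- 1e-4
  A5 <- matrix(eps / 5, 5, 5)
  A5[1:3, 1:3] <- truth$A * (1 - 2 * eps)
  A5 <- A5 / rowSums(A5)
  B5 <- rbind(truth$B, matrix(1 / 8, 2, 8))
  pi5 <- c(truth$pi * (1 - 2 * eps), rep(eps, 2))
  m5 <- hmm_model(pi5 / sum(pi5), A5, B5)
  occ <- state_occupancy(m5, sims$seqs)
  expect_lt(sum(occ[4:5]), 0.005)
  pruned <- prune_states(m5, occ, cutoff = 0.005)
  expect_equal(n_states(pruned), 3L)
  ll_pruned <- hmm_loglik(pruned, sims$seqs)
  fit <- retrain(sims$seqs, pruned, max_iter = 100)
  expect_gte(fit$loglik, ll_pruned - 1e-6)
  # a fixed point stays put within tolerance
  fit2 <- retrain(sims$seqs, fit$model, max_iter = 50, tol = 1e-4)
  expect_equal(fit2$model$A, fit$model$A, tolerance = 0.01)
})

test_that("mark_state_matrix marginalizes emission rows over mark bits", {
  # uniform over 4 symbols (n = 2): each mark carried by half the symbols
  m <- hmm_model(1, matrix(1), matrix(1 / 4, 1, 4))
  expect_equal(as.numeric(mark_state_matrix(m, 2)), c(0.5, 0.5))
  # all mass on symbol 0: no marks
  B0 <- matrix(c(1, 0, 0, 0), 1)
  expect_equal(as.numeric(mark_state_matrix(hmm_model(1, matrix(1), B0), 2)),
               c(0, 0))
  # random rows match a brute-force bit scan
  set.seed(5)
  mr <- init_hmm_model(3, 16, seed = 99)
  msm <- mark_state_matrix(mr, 4)
  for (s in 1:3) for (id in 0:3) {
    expected <- sum(mr$B[s, which(bitwAnd(0:15, 2^id) > 0) ])
    expect_equal(unname(msm[s, id + 1]), expected)
  }
  expect_error(mark_state_matrix(init_hmm_model(2, 6, 1), 3), "not 2\\^n")
})

test_that("select_best is deterministic and honors a singleton range", {
  set.seed(6)
  seqs <- lapply(1:5, function(i) sample(0:3, 40, replace = TRUE))
  one <- select_best(seqs, n_symbols = 4, state_range = 3, replicates = 2,
                     max_iter = 20, seed = 7)
  expect_equal(n_states(one$model), 3L)
  again <- select_best(seqs, n_symbols = 4, state_range = 3,
                       replicates = 2, max_iter = 20, seed = 7)
  expect_identical(one$model$B, again$model$B)
  expect_identical(one$bic, again$bic)
})
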