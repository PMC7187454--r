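toy_obs <- function(T_, M, seed) {
  set.seed(seed)
  matrix(rbinom(T_ * M, 1L, 0.5), T_, M)
}

test_that("K = 1 reduces to the closed form", {
  obs <- toy_obs(200L, 3L, 1)
  fit <- fit_chromatin_hmm(obs, K = 1, seed = 1)
  expect_equal(as.numeric(fit$emission), colMeans(obs), tolerance = 1e-6)
  expect_equal(fit$transition, matrix(1, 1, 1))
  expect_equal(fit$initial, 1)
  expect_true(all(viterbi_decode(fit, obs) == 1L))
  post <- posterior_marginals(fit, obs)
  expect_true(all(post == 1))
})

test_that("total log-likelihood matches exhaustive path enumeration", {
  set.seed(2)
  for (rep in 1:5) {
    K <- sample(2:3, 1L)
    p <- random_hmm_params(K, 2L)
    X <- matrix(rbinom(6L * 2L, 1L, 0.5), 6L, 2L)
    ref <- enumerate_hmm(p$pi0, p$A, p$E, X)
    m <- chromatin_hmm(p$pi0, p$A, p$E)
    ll <- chromstates:::chain_loglik(list(X * 1.0), p$pi0, p$A, p$E)
    expect_equal(ll, ref$loglik, tolerance = 1e-9)
    post <- posterior_marginals(m, X)
    expect_lt(max(abs(post - ref$posterior)), 1e-9)
    expect_equal(unname(rowSums(post)), rep(1, 6L), tolerance = 1e-9)
  }
})

test_that("Viterbi attains the maximum path score on small instances", {
  set.seed(3)
  for (rep in 1:6) {
    K <- sample(2:3, 1L)
    T_ <- sample(4:8, 1L)
    p <- random_hmm_params(K, 2L)
    X <- matrix(rbinom(T_ * 2L, 1L, 0.5), T_, 2L)
    m <- chromatin_hmm(p$pi0, p$A, p$E)
    path <- viterbi_decode(m, X)
    score <- path_logprob(path, p$pi0, p$A, p$E, X)
    ref <- enumerate_hmm(p$pi0, p$A, p$E, X)
    expect_equal(score, ref$best_path_score, tolerance = 1e-9)
  }
})

test_that("noiseless emissions are decoded exactly", {
  E <- rbind(c(1, 0), c(0, 1))
  m <- chromatin_hmm(c(0.5, 0.5), diag(2) * 0.98 + 0.01, E)
  X <- matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 0, 0), 5L, 2L, byrow = TRUE)
  # rows (1,0) emit only from state 1, (0,1) only from state 2
  expect_equal(viterbi_decode(m, rbind(c(1, 0), c(0, 1), c(1, 0))), c(1L, 2L, 1L))
})

test_that("EM log-likelihood increases monotonically", {
  cfg <- simulation_config(layout = genome_layout("chr1", 2e5, 200), seed = 10)
  seg <- simulate_state_chain(cfg)
  obs <- stack_tracks(simulate_marks(seg, cfg))
  fit <- fit_chromatin_hmm(obs, K = 4, layout = cfg$layout, seed = 2,
                           max_iter = 40)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_gte(fit$log_likelihood, max(fit$loglik_trace) - 1e-8)
})

test_that("decoding is equivariant under state relabelling", {
  set.seed(4)
  p <- random_hmm_params(3L, 2L)
  X <- matrix(rbinom(60L, 1L, 0.5), 30L, 2L)
  m <- chromatin_hmm(p$pi0, p$A, p$E)
  perm <- c(3L, 1L, 2L)
  mp <- chromatin_hmm(p$pi0[perm], p$A[perm, perm], p$E[perm, , drop = FALSE])
  path <- viterbi_decode(m, X)
  path_p <- viterbi_decode(mp, X)
  expect_equal(match(path, perm), path_p)
  post <- posterior_marginals(m, X)
  post_p <- posterior_marginals(mp, X)
  expect_lt(max(abs(post[, perm] - post_p)), 1e-9)
})

test_that("parameters are recovered on simulated data (K = 2)", {
  E <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2L, byrow = TRUE)
  truth <- chromatin_hmm(c(0.5, 0.5), A, E)
  sim <- simulate(truth, nsim = 5e4, seed = 99)
  fit <- fit_chromatin_hmm(sim$obs, K = 2, seed = 1)
  best <- best_permutation_mae(fit$emission, E)
  expect_lt(best$mae, 0.03)
  perm <- best$perm
  expect_lt(mean(abs(fit$transition[perm, perm] - A)), 0.05)
})

test_that("state-count selection finds a well-separated truth", {
  E <- rbind(c(0.95, 0.05, 0.05), c(0.05, 0.95, 0.05), c(0.05, 0.05, 0.95))
  truth <- chromatin_hmm(rep(1 / 3, 3), default_transition_truth(3, 0.9), E)
  sim <- simulate(truth, nsim = 3e4, seed = 7)
  sel <- select_state_count(sim$obs, K_range = 2:5, seed = 11, max_iter = 60)
  expect_equal(sel$recommended_K, 3L)
  expect_true(all(diff(sel$report$logLik[1:2]) > 0))

  sel1 <- select_state_count(toy_obs(50L, 2L, 5), K_range = 1L)
  expect_equal(sel1$recommended_K, 1L)
  expect_equal(sel1$report$redundancy, 0)
  expect_error(select_state_count(toy_obs(50L, 2L, 5), integer(0)), "non-empty")
})

test_that("semantic labels fire in priority order", {
  marks <- default_marks()
  E <- rbind(
    c(1, 0, 0, 0, 0),          # promoter
    c(0, 0.9, 0.9, 0, 0),      # strong enhancer: H3K4me1 + H3K27ac
    c(0, 0.9, 0.1, 0, 0),      # weak enhancer
    c(0, 0, 0, 0, 0.9),        # transcription
    c(0, 0, 0, 0.9, 0),        # Polycomb
    c(0.05, 0.05, 0.05, 0.05, 0.05), # quiescent
    c(0.3, 0.3, 0.3, 0.3, 0.3)       # none of the rules
  )
  m <- chromatin_hmm(rep(1 / 7, 7), default_transition_truth(7, 0.9), E,
                     mark_names = marks)
  m <- label_states(m)
  expect_equal(m$state_labels,
               c("1_TssS", "2_EnhS", "3_EnhW", "4_Tx", "5_ReprPC",
                 "6_Quies", "7_Mixed"))
  bad <- label_rules(marks = c(tss = "H3K4me3", enh1 = "H3K4me1",
                               ac = "H3K27ac", tx = "H3K36me3",
                               repr = "H3K9me3"))
  expect_error(label_states(m, bad), "H3K9me3")
})

test_that("model TSV round trip is bit exact", {
  set.seed(6)
  p <- random_hmm_params(4L, 5L)
  m <- chromatin_hmm(p$pi0, p$A, p$E, mark_names = default_marks(),
                     state_labels = c("1_TssS", "2_EnhS", "3_Tx", "4_Quies"))
  m$log_likelihood <- -12345.6789
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hmm_model(m, f)
  m2 <- read_hmm_model(f)
  expect_identical(m2$initial, m$initial)
  expect_identical(unname(m2$transition), unname(m$transition))
  expect_identical(unname(m2$emission), unname(m$emission))
  expect_identical(m2$state_labels, m$state_labels)
  expect_identical(m2$log_likelihood, m$log_likelihood)
})

test_that("invalid inputs are rejected", {
  obs <- toy_obs(20L, 2L, 8)
  expect_error(fit_chromatin_hmm(obs, K = 30), "exceeds")
  expect_error(fit_chromatin_hmm(obs + 1L, K = 2), "binary")
  m <- fit_chromatin_hmm(obs, K = 2, seed = 1)
  expect_error(viterbi_decode(m, toy_obs(10L, 3L, 9)), "marks")
})
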