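# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# --- per-bp membership oracle for interval algebra ------------------------

# every covered base pair as a "chrom:pos" key (small sets only)
bp_keys <- function(set) {
  df <- as.data.frame(set)
  if (nrow(df) == 0L) return(character(0))
  unique(unlist(lapply(seq_len(nrow(df)), function(i) {
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1L))
  })))
}

# a random small interval set (uses the caller's RNG stream)
random_small_set <- function(max_intervals = 8L, chroms = c("chr1", "chr2"),
                             span = 5000L, max_len = 400L) {
  n <- sample.int(max_intervals, 1L)
  start <- sample.int(span, n) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  interval_set(sample(chroms, n, replace = TRUE), start, start + len)
}

# --- exhaustive-path oracle for the HMM -----------------------------------

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# joint log-probability of one state path for product-Bernoulli emissions
path_logprob <- function(path, pi0, A, E, X) {
  T_ <- nrow(X)
  lp <- log(pi0[path[1L]])
  if (T_ > 1L) lp <- lp + sum(log(A[cbind(path[-T_], path[-1L])]))
  P <- E[path, , drop = FALSE]
  lp + sum(log(ifelse(X == 1, P, 1 - P)))
}

# enumerate all K^T paths: total log-likelihood, posterior marginals and
# the maximum-probability path score
enumerate_hmm <- function(pi0, A, E, X) {
  K <- length(pi0)
  T_ <- nrow(X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  logp <- vapply(seq_len(nrow(paths)), function(i) {
    path_logprob(paths[i, ], pi0, A, E, X)
  }, 0)
  total <- log_sum_exp(logp)
  post <- matrix(0, T_, K)
  for (t in seq_len(T_)) {
    for (k in seq_len(K)) {
      sel <- paths[, t] == k
      post[t, k] <- if (any(sel)) exp(log_sum_exp(logp[sel]) - total) else 0
    }
  }
  list(loglik = total, posterior = post, best_path_score = max(logp))
}

# random valid HMM parameters (uses the caller's RNG stream)
random_hmm_params <- function(K, M) {
  pi0 <- stats::runif(K) + 0.1
  pi0 <- pi0 / sum(pi0)
  A <- matrix(stats::runif(K * K) + 0.1, K, K)
  A <- A / rowSums(A)
  E <- matrix(stats::runif(K * M, 0.05, 0.95), K, M)
  list(pi0 = pi0, A = A, E = E)
}

# --- quadratic overlap-count oracle ---------------------------------------

count_overlap_oracle <- function(query, reference, min_bp = 1L) {
  q <- as.data.frame(query)
  r <- as.data.frame(merge_intervals(reference))
  if (nrow(q) == 0L || nrow(r) == 0L) return(0L)
  hits <- 0L
  for (i in seq_len(nrow(q))) {
    ov <- 0L
    for (j in seq_len(nrow(r))) {
      if (q$chrom[i] != r$chrom[j]) next
      ov <- ov + max(0, min(q$end[i], r$end[j]) - max(q$start[i], r$start[j]))
    }
    if (ov >= min_bp) hits <- hits + 1L
  }
  hits
}

# optimal state matching: minimal emission MAE over all permutations
best_permutation_mae <- function(est, truth) {
  K <- nrow(truth)
  perms <- permutations_of(K)
  best <- Inf
  best_perm <- seq_len(K)
  for (p in perms) {
    mae <- mean(abs(est[p, , drop = FALSE] - truth))
    if (mae < best) { best <- mae; best_perm <- p }
  }
  list(mae = best, perm = best_perm)
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    for (rest in permutations_of(K - 1L)) {
      tail <- seq_len(K)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

# independent bin-index computation (integer division on layout fields)
genome_bin_index_for_test <- function(layout, chrom, pos0) {
  as.integer(layout$bin_offsets[chrom] + pos0 %/% layout$bin_size + 1L)
}
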