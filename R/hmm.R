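#' Fit a multivariate Bernoulli hidden Markov chromatin-state model
#'
#' The core estimator of the package. Bins of the genome carry a binary
#' vector of histone-mark calls; a hidden chromatin state per bin emits
#' each mark independently with a state-specific Bernoulli probability,
#' and states follow a first-order Markov chain that restarts from the
#' initial distribution at every chromosome. Parameters are estimated by
#' Baum-Welch expectation-maximisation with scaled forward-backward
#' recursions (per-position normalisation; the log-likelihood is
#' accumulated from the scaling factors).
#'
#' @param obs Binary observation matrix (bins x marks, entries 0/1), or a
#'   list of such matrices (one chain per element). When `layout` is
#'   supplied a single matrix is split into per-chromosome chains.
#' @param K Number of hidden states (>= 1).
#' @param layout Optional [genome_layout()] used to split `obs` by
#'   chromosome and carried into decoded segmentations.
#' @param seed Integer seed controlling initialisation.
#' @param max_iter Maximum EM iterations (default 200).
#' @param tol Convergence tolerance on the total log-likelihood
#'   improvement (default 1e-4).
#' @param n_init Number of short-run restarts: each candidate
#'   initialisation is advanced `init_iter` EM iterations and the best
#'   by log-likelihood is run to convergence (default 3; standard
#'   guard against local optima of Baum-Welch).
#' @param init_iter Burn-in iterations per restart (default 15).
#' @param mark_names Optional mark names; defaults to `colnames(obs)`.
#' @param verbose Print per-iteration log-likelihood.
#' @return An object of class `chromatin_hmm` with components `initial`,
#'   `transition` (K x K row-stochastic), `emission` (K x M Bernoulli
#'   parameters), `state_labels`, `mark_names`, `log_likelihood`,
#'   `n_iter`, `converged`.
#' @details Initialisation uses k-means seeding of the emission matrix on
#'   a random subsample of bins plus jitter, sticky uniform transitions
#'   (0.9 self weight) and a uniform initial distribution; all draws are
#'   governed by `seed`. With `K = 1` the fit reduces to the closed form:
#'   emissions are the per-mark empirical frequencies and the transition
#'   matrix is `[[1]]`.
#' @seealso [viterbi_decode()], [posterior_marginals()],
#'   [select_state_count()], [label_states()]
#' @examples
#' set.seed(1)
#' obs <- matrix(rbinom(400, 1, 0.3), ncol = 2)
#' fit <- fit_chromatin_hmm(obs, K = 2, seed = 1)
#' coef(fit)$emission
#' @export
fit_chromatin_hmm <- function(obs, K, layout = NULL, seed = 1L,
                              max_iter = 200L, tol = 1e-4,
                              n_init = 3L, init_iter = 15L,
                              mark_names = NULL, verbose = FALSE) {
  chains <- as_chain_list(obs, layout)
  M <- ncol(chains[[1L]])
  K <- as.integer(K)
  if (K < 1L) stopf("K must be >= 1")
  total_bins <- sum(vapply(chains, nrow, 1L))
  if (K > total_bins) stopf("K (%d) exceeds the number of bins (%d)", K, total_bins)
  mark_names <- mark_names %||% colnames(chains[[1L]]) %||% paste0("mark", seq_len(M))

  # short-run restarts: advance each candidate initialisation a few EM
  # iterations and keep the best by log-likelihood
  best <- NULL
  n_init <- max(1L, as.integer(n_init))
  for (r in seq_len(n_init)) {
    init <- with_seed(substream_seed(seed, paste0("init", r)),
                      init_params(chains, K, M))
    pi0 <- init$initial; A <- init$transition; E <- init$emission
    ll_r <- -Inf
    if (K > 1L) {
      for (it in seq_len(init_iter)) {
        st <- em_step(chains, pi0, A, E)
        ll_r <- st$loglik
        pi0 <- st$initial; A <- st$transition; E <- st$emission
      }
    }
    if (is.null(best) || ll_r > best$ll) {
      best <- list(ll = ll_r, pi0 = pi0, A = A, E = E)
    }
    if (K == 1L) break
  }
  pi0 <- best$pi0; A <- best$A; E <- best$E

  ll_old <- -Inf
  ll <- NA_real_
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    st <- em_step(chains, pi0, A, E)
    ll <- st$loglik
    trace <- c(trace, ll)
    if (verbose) message(sprintf("iter %3d  logLik %.6f", iter, ll))
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      pi0 <- st$initial; A <- st$transition; E <- st$emission
      break
    }
    ll_old <- ll
    pi0 <- st$initial; A <- st$transition; E <- st$emission
  }
  # log-likelihood reported for the returned (last updated) parameters
  ll_final <- chain_loglik(chains, pi0, A, E)

  structure(
    list(
      n_states = K, n_marks = M,
      initial = pi0, transition = A, emission = E,
      mark_names = mark_names,
      state_labels = paste0("S", seq_len(K)),
      log_likelihood = ll_final,
      loglik_trace = trace,
      n_iter = iter, converged = converged,
      seed = seed, tol = tol,
      call = match.call()
    ),
    class = "chromatin_hmm"
  )
}

# normalise obs input to a list of validated binary matrices
as_chain_list <- function(obs, layout = NULL) {
  if (is.matrix(obs)) {
    chains <- if (is.null(layout)) list(obs) else split_by_chrom(layout, obs)
  } else if (is.list(obs)) {
    chains <- obs
  } else {
    stopf("obs must be a binary matrix or a list of binary matrices")
  }
  M <- ncol(chains[[1L]])
  for (x in chains) {
    if (!is.matrix(x) || ncol(x) != M) stopf("all chains must share mark columns")
    if (!all(x %in% c(0, 1))) stopf("observations must be binary (0/1)")
  }
  if (!any(vapply(chains, nrow, 1L) >= 2L)) {
    stopf("need at least one chain with >= 2 bins")
  }
  lapply(chains, function(x) { storage.mode(x) <- "double"; x })
}

init_params <- function(chains, K, M) {
  X <- do.call(rbind, chains)
  n <- nrow(X)
  sub <- X[sample.int(n, min(n, 20000L)), , drop = FALSE]
  E <- matrix(stats::runif(K * M, 0.2, 0.8), K, M)
  uniq <- unique(sub)
  if (K > 1L && nrow(uniq) >= K) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(sub, centers = K, iter.max = 30L,
                                     nstart = 1L)),
      error = function(e) NULL
    )
    if (!is.null(km)) E <- km$centers
  } else if (K == 1L) {
    E <- matrix(colMeans(sub), 1L, M)
  }
  E <- E + matrix(stats::runif(K * M, -0.05, 0.05), K, M)
  E <- pmin(pmax(E, 0.02), 0.98)
  A <- matrix(if (K > 1L) 0.1 / (K - 1L) else 0, K, K)
  diag(A) <- if (K > 1L) 0.9 else 1
  list(initial = rep(1 / K, K), transition = A, emission = E)
}

# per-bin log emission likelihoods under product-Bernoulli emissions
log_emission <- function(X, E) {
  Ec <- pmin(pmax(E, 1e-10), 1 - 1e-10)
  X %*% t(log(Ec)) + (1 - X) %*% t(log1p(-Ec))
}

fb_chain <- function(X, pi0, A, E) {
  logB <- log_emission(X, E)
  shift <- apply(logB, 1L, max)
  B <- exp(logB - shift)
  res <- fb_cpp(pi0, A, B)
  res$loglik <- res$loglik + sum(shift)
  res
}

em_step <- function(chains, pi0, A, E) {
  K <- length(pi0); M <- ncol(chains[[1L]])
  ll <- 0
  init_acc <- numeric(K)
  xi_acc <- matrix(0, K, K)
  gw <- numeric(K)           # total posterior weight per state
  gx <- matrix(0, K, M)      # posterior-weighted mark sums
  for (X in chains) {
    r <- fb_chain(X, pi0, A, E)
    ll <- ll + r$loglik
    init_acc <- init_acc + r$gamma[1L, ]
    xi_acc <- xi_acc + r$xi
    gw <- gw + colSums(r$gamma)
    gx <- gx + t(r$gamma) %*% X
  }
  new_pi <- init_acc / sum(init_acc)
  if (K == 1L) {
    new_A <- matrix(1, 1L, 1L)
  } else {
    rs <- rowSums(xi_acc)
    new_A <- xi_acc / ifelse(rs > 0, rs, 1)
    new_A[rs == 0, ] <- 1 / K
  }
  new_E <- gx / ifelse(gw > 0, gw, 1)
  new_E <- pmin(pmax(new_E, 1e-8), 1 - 1e-8)
  list(loglik = ll, initial = new_pi, transition = new_A, emission = new_E)
}

chain_loglik <- function(chains, pi0, A, E) {
  sum(vapply(chains, function(X) fb_chain(X, pi0, A, E)$loglik, 0))
}

#' @export
print.chromatin_hmm <- function(x, ...) {
  cat(sprintf("chromatin_hmm: %d states, %d marks, logLik %.3f (%d EM iterations%s)\n",
              x$n_states, x$n_marks, x$log_likelihood, x$n_iter,
              if (x$converged) ", converged" else ""))
  cat("states:", paste(x$state_labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.chromatin_hmm <- function(object, ...) {
  em <- round(object$emission, 3)
  dimnames(em) <- list(object$state_labels, object$mark_names)
  tr <- round(object$transition, 4)
  dimnames(tr) <- list(object$state_labels, object$state_labels)
  out <- list(emission = em, transition = tr,
              initial = stats::setNames(round(object$initial, 4),
                                        object$state_labels),
              log_likelihood = object$log_likelihood,
              n_iter = object$n_iter, converged = object$converged)
  class(out) <- "summary.chromatin_hmm"
  out
}

#' @export
print.summary.chromatin_hmm <- function(x, ...) {
  cat("Emission probabilities (state x mark):\n"); print(x$emission)
  cat("\nTransition matrix:\n"); print(x$transition)
  cat("\nInitial distribution:\n"); print(x$initial)
  cat(sprintf("\nlogLik %.3f after %d iterations%s\n", x$log_likelihood,
              x$n_iter, if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
coef.chromatin_hmm <- function(object, ...) {
  list(initial = object$initial, transition = object$transition,
       emission = object$emission)
}

#' @export
logLik.chromatin_hmm <- function(object, ...) {
  K <- object$n_states; M <- object$n_marks
  structure(object$log_likelihood,
            df = (K - 1) + K * (K - 1) + K * M,
            class = "logLik")
}

#' @export
plot.chromatin_hmm <- function(x, ...) {
  E <- x$emission
  graphics::image(seq_len(ncol(E)), seq_len(nrow(E)), t(E[nrow(E):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(ncol(E)), labels = x$mark_names, las = 2)
  graphics::axis(2, at = seq_len(nrow(E)), labels = rev(x$state_labels), las = 1)
  graphics::box()
  invisible(x)
}

#' Decode the most probable state path (Viterbi)
#'
#' @param model A [fit_chromatin_hmm()] model.
#' @param obs Binary observation matrix or list of matrices (see
#'   [fit_chromatin_hmm()]).
#' @param layout Optional [genome_layout()]; when given, the result is a
#'   [segmentation()] bound to it.
#' @return A `segmentation` when `layout` is supplied, else an integer
#'   vector of 1-based state indices. Ties are broken toward the smaller
#'   state index.
#' @export
viterbi_decode <- function(model, obs, layout = NULL) {
  stopifnot(inherits(model, "chromatin_hmm"))
  chains <- as_chain_list(obs, layout)
  if (ncol(chains[[1L]]) != model$n_marks) {
    stopf("observation has %d marks but model has %d",
          ncol(chains[[1L]]), model$n_marks)
  }
  lp <- log(pmax(model$initial, 1e-300))
  lA <- log(pmax(model$transition, 1e-300))
  states <- unlist(lapply(chains, function(X) {
    viterbi_cpp(lp, lA, log_emission(X, model$emission))
  }), use.names = FALSE)
  if (is.null(layout)) return(states)
  segmentation(layout, states, state_labels = model$state_labels)
}

#' Posterior state probabilities per bin
#'
#' @inheritParams viterbi_decode
#' @return Matrix (bins x K); every row sums to 1.
#' @export
posterior_marginals <- function(model, obs, layout = NULL) {
  stopifnot(inherits(model, "chromatin_hmm"))
  chains <- as_chain_list(obs, layout)
  if (ncol(chains[[1L]]) != model$n_marks) {
    stopf("observation has %d marks but model has %d",
          ncol(chains[[1L]]), model$n_marks)
  }
  out <- do.call(rbind, lapply(chains, function(X) {
    fb_chain(X, model$initial, model$transition, model$emission)$gamma
  }))
  colnames(out) <- model$state_labels
  out
}

#' @rdname viterbi_decode
#' @param object A `chromatin_hmm`.
#' @param newdata Observations to decode.
#' @param type `"states"` for the Viterbi path, `"posterior"` for
#'   per-bin marginals.
#' @param ... Unused.
#' @export
predict.chromatin_hmm <- function(object, newdata, layout = NULL,
                                  type = c("states", "posterior"), ...) {
  type <- match.arg(type)
  if (type == "states") viterbi_decode(object, newdata, layout)
  else posterior_marginals(object, newdata, layout)
}

#' Simulate observations from a fitted or constructed model
#'
#' @param object A `chromatin_hmm`.
#' @param nsim Number of bins to simulate when no `layout` is given.
#' @param seed Integer seed.
#' @param layout Optional [genome_layout()]; when supplied one chain is
#'   generated per chromosome and a bound [segmentation()] is returned.
#' @param ... Unused.
#' @return List with `states` (integer vector or `segmentation`) and
#'   `obs` (binary matrix).
#' @export
simulate.chromatin_hmm <- function(object, nsim = 1000L, seed = NULL,
                                   layout = NULL, ...) {
  seed <- seed %||% sample.int(.Machine$integer.max, 1L)
  with_seed(seed, {
    lens <- if (is.null(layout)) nsim else unname(layout$n_bins_per_chrom)
    states <- unlist(lapply(lens, function(n) {
      sim_markov_cpp(object$initial, object$transition, stats::runif(n))
    }), use.names = FALSE)
    obs <- matrix(0L, length(states), object$n_marks,
                  dimnames = list(NULL, object$mark_names))
    for (m in seq_len(object$n_marks)) {
      obs[, m] <- stats::rbinom(length(states), 1L, object$emission[states, m])
    }
    st <- if (is.null(layout)) states else
      segmentation(layout, states, state_labels = object$state_labels)
    list(states = st, obs = obs)
  })
}

#' Construct a chromatin-state model from explicit parameters
#'
#' Useful for simulation and for tests with known ground truth.
#'
#' @param initial K initial probabilities.
#' @param transition K x K row-stochastic matrix.
#' @param emission K x M Bernoulli matrix.
#' @param mark_names,state_labels Optional names.
#' @return A `chromatin_hmm`.
#' @export
chromatin_hmm <- function(initial, transition, emission,
                          mark_names = NULL, state_labels = NULL) {
  K <- length(initial)
  emission <- as.matrix(emission)
  transition <- as.matrix(transition)
  check_prob_vector(initial, "initial distribution")
  check_stochastic_matrix(transition, "transition matrix")
  if (any(emission < 0 | emission > 1)) stopf("emission entries must be in [0, 1]")
  if (nrow(transition) != K || ncol(transition) != K || nrow(emission) != K) {
    stopf("parameter dimensions disagree")
  }
  labels <- state_labels %||% paste0("S", seq_len(K))
  if (anyDuplicated(labels)) stopf("state labels must be unique")
  structure(
    list(n_states = K, n_marks = ncol(emission),
         initial = as.numeric(initial), transition = transition,
         emission = emission,
         mark_names = mark_names %||% colnames(emission) %||%
           paste0("mark", seq_len(ncol(emission))),
         state_labels = labels,
         log_likelihood = NA_real_, loglik_trace = numeric(0),
         n_iter = 0L, converged = NA, seed = NA_integer_, tol = NA_real_,
         call = match.call()),
    class = "chromatin_hmm"
  )
}

#' Choose the number of chromatin states
#'
#' Fits one model per candidate `K` and checks whether every state is
#' still separated: the redundancy score of a model is the maximum
#' Pearson correlation over pairs of emission rows (near-duplicate
#' emission profiles mean the vocabulary stopped growing), and a state
#' whose stationary occupancy falls below `min_occupancy` is likewise
#' counted as unseparated — it describes no appreciable fraction of the
#' genome. The recommended `K` is the largest candidate passing both
#' checks, the operational form of growing the model until states stop
#' separating.
#'
#' @inheritParams fit_chromatin_hmm
#' @param K_range Ascending vector of candidate state counts.
#' @param redundancy_threshold Maximum tolerated emission-row correlation
#'   (default 0.95).
#' @param min_occupancy Minimum stationary occupancy per state
#'   (default 0.01).
#' @return List with `report` (data.frame: K, logLik, redundancy,
#'   min_occupancy), `recommended_K`, and `models` (one per K).
#' @export
select_state_count <- function(obs, K_range, layout = NULL, seed = 1L,
                               redundancy_threshold = 0.95,
                               min_occupancy = 0.01,
                               max_iter = 200L, tol = 1e-4) {
  if (length(K_range) == 0L) stopf("K_range must be non-empty")
  if (is.unsorted(K_range, strictly = TRUE)) stopf("K_range must be ascending")
  models <- lapply(K_range, function(K) {
    fit_chromatin_hmm(obs, K, layout = layout,
                      seed = substream_seed(seed, paste0("K", K)),
                      max_iter = max_iter, tol = tol)
  })
  red <- vapply(models, function(m) emission_redundancy(m$emission), 0)
  occ <- vapply(models, function(m)
    min(stationary_distribution(m$transition)), 0)
  ll <- vapply(models, function(m) m$log_likelihood, 0)
  ok <- which(red <= redundancy_threshold & occ >= min_occupancy)
  recommended <- if (length(ok)) K_range[max(ok)] else K_range[which.min(red)]
  list(
    report = data.frame(K = K_range, logLik = ll, redundancy = red,
                        min_occupancy = occ),
    recommended_K = recommended,
    models = stats::setNames(models, paste0("K", K_range))
  )
}

emission_redundancy <- function(E) {
  K <- nrow(E)
  if (K < 2L) return(0)
  best <- -1
  for (i in seq_len(K - 1L)) {
    for (j in seq((i + 1L), K)) {
      r1 <- E[i, ]; r2 <- E[j, ]
      if (stats::sd(r1) == 0 || stats::sd(r2) == 0) {
        r <- as.numeric(max(abs(r1 - r2)) < 1e-12)
      } else {
        r <- stats::cor(r1, r2)
      }
      if (r > best) best <- r
    }
  }
  best
}

#' Default semantic labelling rules for histone-mark states
#'
#' Thresholded rules applied in priority order to the emission matrix:
#' strong promoter (TssS) when H3K4me3 is high; strong enhancer (EnhS)
#' when H3K4me1 and H3K27ac are both high without promoter-level H3K4me3;
#' weak enhancer (EnhW) when only H3K4me1 is high; transcription (Tx) on
#' H3K36me3; Polycomb repression (ReprPC) on H3K27me3; quiescent (Quies)
#' when every mark is near zero; otherwise Mixed.
#'
#' @param high Emission threshold treated as "mark present" (default 0.5).
#' @param quiescent Ceiling below which all marks count as absent
#'   (default 0.2).
#' @param marks Named character vector mapping the roles `tss`, `enh1`,
#'   `ac`, `tx`, `repr` to mark names in the model.
#' @return A labelling ruleset for [label_states()].
#' @export
label_rules <- function(high = 0.5, quiescent = 0.2,
                        marks = c(tss = "H3K4me3", enh1 = "H3K4me1",
                                  ac = "H3K27ac", tx = "H3K36me3",
                                  repr = "H3K27me3")) {
  structure(list(high = high, quiescent = quiescent, marks = marks),
            class = "label_rules")
}

#' Assign semantic state labels from emission probabilities
#'
#' Labels follow the field convention `<index>_<name>` (e.g. `13_EnhS`),
#' which also keeps them unique.
#'
#' @param model A `chromatin_hmm` whose `mark_names` include the marks the
#'   rules reference.
#' @param rules A [label_rules()] ruleset.
#' @return The model with `state_labels` replaced.
#' @export
label_states <- function(model, rules = label_rules()) {
  stopifnot(inherits(model, "chromatin_hmm"), inherits(rules, "label_rules"))
  missing <- setdiff(rules$marks, model$mark_names)
  if (length(missing)) {
    stopf("rules reference marks absent from the model: %s",
          paste(missing, collapse = ", "))
  }
  e <- function(k, role) model$emission[k, match(rules$marks[[role]], model$mark_names)]
  hi <- rules$high
  names <- vapply(seq_len(model$n_states), function(k) {
    if (e(k, "tss") >= hi) "TssS"
    else if (e(k, "enh1") >= hi && e(k, "ac") >= hi) "EnhS"
    else if (e(k, "enh1") >= hi) "EnhW"
    else if (e(k, "tx") >= hi) "Tx"
    else if (e(k, "repr") >= hi) "ReprPC"
    else if (all(model$emission[k, ] < rules$quiescent)) "Quies"
    else "Mixed"
  }, "")
  model$state_labels <- paste0(seq_len(model$n_states), "_", names)
  model
}

#' Write / read a chromatin-state model as plain TSV blocks
#'
#' The text format stores every number at full precision
#' (`%.17g`), so `read_hmm_model(write_hmm_model(m, f))` reproduces the
#' model bit-exactly.
#'
#' @param model A `chromatin_hmm`.
#' @param path File path.
#' @return `path` (write) or a `chromatin_hmm` (read).
#' @export
write_hmm_model <- function(model, path) {
  stopifnot(inherits(model, "chromatin_hmm"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(..., sep = "\t"), con)
  wl("#chromatin_hmm", model$n_states, model$n_marks)
  wl("#marks", paste(model$mark_names, collapse = "\t"))
  wl("#labels", paste(model$state_labels, collapse = "\t"))
  wl("#loglik", format_full(model$log_likelihood))
  wl("#initial", paste(format_full(model$initial), collapse = "\t"))
  for (i in seq_len(model$n_states)) {
    wl("transition", i, paste(format_full(model$transition[i, ]), collapse = "\t"))
  }
  for (i in seq_len(model$n_states)) {
    wl("emission", i, paste(format_full(model$emission[i, ]), collapse = "\t"))
  }
  invisible(path)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(path) {
  lines <- readLines(path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (f[[1L]][1L] != "#chromatin_hmm") stopf("%s: not a chromatin_hmm file", path)
  K <- as.integer(f[[1L]][2L]); M <- as.integer(f[[1L]][3L])
  marks <- f[[2L]][-1L]
  labels <- f[[3L]][-1L]
  ll <- as.numeric(f[[4L]][2L])
  init <- as.numeric(f[[5L]][-1L])
  A <- matrix(0, K, K); E <- matrix(0, K, M)
  for (ln in f[-(1:5)]) {
    i <- as.integer(ln[2L])
    vals <- as.numeric(ln[-(1:2)])
    if (ln[1L] == "transition") A[i, ] <- vals else E[i, ] <- vals
  }
  m <- chromatin_hmm(init, A, E, mark_names = marks, state_labels = labels)
  m$log_likelihood <- ll
  m
}
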