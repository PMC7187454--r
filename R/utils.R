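# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every generator reproducible without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic per-stage substream: fold a short tag into a base seed.
# Result always fits in a 32-bit integer.
substream_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 100003L
  as.integer((abs(as.numeric(seed)) %% 1000000) * 1009 + h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob_vector <- function(p, what, tol = 1e-9) {
  if (any(p < -tol) || any(p > 1 + tol)) {
    stopf("%s has entries outside [0, 1]", what)
  }
  if (abs(sum(p) - 1) > tol) {
    stopf("%s does not sum to 1 (sum = %.12g)", what, sum(p))
  }
  invisible(TRUE)
}

check_stochastic_matrix <- function(A, what, tol = 1e-9) {
  for (i in seq_len(nrow(A))) {
    check_prob_vector(A[i, ], sprintf("%s row %d", what, i), tol = tol)
  }
  invisible(TRUE)
}

# Full-precision number formatting for bit-exact text round trips.
format_full <- function(x) sprintf("%.17g", x)
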