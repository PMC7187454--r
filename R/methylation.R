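#' Assign CpG sites to chromatin states
#'
#' Array coordinates are 1-based site positions; each is converted once
#' to a 0-based point and assigned the state of its containing bin.
#' Sites on chromosomes absent from the layout (or beyond the
#' chromosome end) are flagged unassigned, not dropped.
#'
#' @param cpgs A `cpg_table` (see [read_cpg_table()]).
#' @param seg A [segmentation()].
#' @return Character vector of state labels per site; `NA` for
#'   unassigned sites. The 1-based state indices are attached as
#'   attribute `"state_index"`.
#' @export
assign_cpgs <- function(cpgs, seg) {
  stopifnot(inherits(seg, "segmentation"))
  bins <- genome_bin_index(seg$layout, cpgs$chrom, cpgs$pos - 1)
  idx <- ifelse(is.na(bins), NA_integer_, seg$states[bins])
  out <- ifelse(is.na(idx), NA_character_, seg$state_labels[idx])
  attr(out, "state_index") <- idx
  out
}

#' Per-state methylation summary
#'
#' For every chromatin state: CpG count, mean/median beta before and
#' after, the mean beta change, the count and fraction of significant
#' hypomethylated (demethylated) CpGs, and the two headline
#' percentages — the state's share of all assigned CpGs (`pct_all`) and
#' its share of all demethylated CpGs (`pct_demeth`).
#'
#' @param cpgs A `cpg_table`.
#' @param assignments Output of [assign_cpgs()] for `cpgs`.
#' @param hypo_only Count only `direction == "hypo"` significant sites
#'   as demethylated (default TRUE, the direction the analysis is
#'   about).
#' @return A data.frame of class `state_methylation_summary`, one row
#'   per state present.
#' @export
summarize_states <- function(cpgs, assignments, hypo_only = TRUE) {
  keep <- !is.na(assignments)
  if (!any(keep)) stopf("no CpG site falls on the segmentation's layout")
  lab <- assignments[keep]
  cp <- as.data.frame(cpgs)[keep, , drop = FALSE]
  demeth <- cp$significant == 1
  if (hypo_only && !is.null(cp$direction)) {
    demeth <- demeth & cp$direction == "hypo"
  }
  total_demeth <- sum(demeth)
  if (total_demeth == 0L) warnf("no significant demethylated CpGs; pct_demeth is all 0")
  states <- unique(lab)
  rows <- lapply(states, function(s) {
    i <- lab == s
    data.frame(
      state = s,
      n_cpg = sum(i),
      mean_beta_before = mean(cp$beta_before[i]),
      median_beta_before = stats::median(cp$beta_before[i]),
      mean_beta_after = mean(cp$beta_after[i]),
      median_beta_after = stats::median(cp$beta_after[i]),
      mean_delta_beta = mean(cp$beta_after[i] - cp$beta_before[i]),
      n_demeth = sum(demeth & i),
      frac_demeth = sum(demeth & i) / sum(i),
      pct_all = 100 * sum(i) / sum(keep),
      pct_demeth = if (total_demeth > 0) 100 * sum(demeth & i) / total_demeth else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$state), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("state_methylation_summary", "data.frame")
  out
}

#' Permutation chi-square test for state-dependent demethylation
#'
#' Tests independence between chromatin state and the
#' significant-demethylation flag. The statistic is the Pearson
#' chi-square on the states-by-(significant, not) contingency table; the
#' null distribution is generated by permuting the significance flags
#' across sites (margins preserved), and the p-value uses the add-one
#' estimator \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) /
#' (1 + n_{perm})}, so the attainable minimum is `1/(n_perm+1)`.
#'
#' @param assignments State labels per site ([assign_cpgs()] output);
#'   `NA` (unassigned) sites are excluded.
#' @param significant Logical or 0/1 vector per site.
#' @param n_perm Number of Monte Carlo permutations (default 1000).
#' @param seed Integer seed; fixed seeds give bit-identical p-values.
#' @return Object of class `perm_chisq`: `statistic`, `df` (of the
#'   asymptotic analogue), `p_value`, `n_perm`, `seed`, `table`.
#' @export
permutation_chisq <- function(assignments, significant, n_perm = 1000L,
                              seed = 1L) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  keep <- !is.na(assignments)
  lab <- as.character(assignments[keep])
  sig <- as.integer(significant[keep]) == 1L
  present <- unique(lab)
  if (is.factor(assignments) &&
      length(setdiff(levels(assignments), present)) > 0L) {
    warnf("state(s) with zero sites dropped from the table: %s",
          paste(setdiff(levels(assignments), present), collapse = ", "))
  }
  if (length(present) < 2L) stopf("need at least 2 states with sites")
  state_int <- match(lab, present)
  K <- length(present)
  n <- length(state_int)
  s <- sum(sig)
  n_k <- tabulate(state_int, K)

  chisq_stat <- function(sig_k) {
    e_k <- n_k * s / n
    f_k <- n_k - e_k
    sum((sig_k - e_k)^2 / e_k) + sum(((n_k - sig_k) - f_k)^2 / f_k)
  }
  obs_sig_k <- tabulate(state_int[sig], K)
  stat <- chisq_stat(obs_sig_k)

  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      perm_sig_k <- tabulate(state_int[sample.int(n, s)], K)
      if (chisq_stat(perm_sig_k) >= stat) count <- count + 1L
    }
    count
  })
  tab <- cbind(significant = obs_sig_k, not_significant = n_k - obs_sig_k)
  rownames(tab) <- present
  structure(
    list(statistic = stat, df = K - 1L,
         p_value = (1 + exceed) / (1 + n_perm),
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         table = tab),
    class = "perm_chisq"
  )
}

#' @export
print.perm_chisq <- function(x, ...) {
  cat(sprintf(
    "Permutation chi-square: X2 = %.4f (asymptotic df %d), p = %.6g (%d permutations, seed %d)\n",
    x$statistic, x$df, x$p_value, x$n_perm, x$seed))
  print(x$table)
  invisible(x)
}
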