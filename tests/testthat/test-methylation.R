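make_cpgs <- function(chrom, pos, sig = 0, before = 0.8, after = NULL) {
  n <- length(pos)
  df <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                   beta_before = rep_len(before, n),
                   beta_after = after %||% rep_len(before, n) -
                     0.3 * rep_len(sig, n),
                   significant = rep_len(sig, n),
                   direction = ifelse(rep_len(sig, n) == 1, "hypo", "."),
                   stringsAsFactors = FALSE)
  class(df) <- c("cpg_table", "data.frame")
  df
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("CpG sites land in the right bins, including boundaries", {
  layout <- genome_layout("chr1", 1000, 200)
  seg <- segmentation(layout, c(1L, 2L, 1L, 2L, 1L),
                      state_labels = c("1_Quies", "2_EnhS"))
  cp <- make_cpgs("chr1", c(250, 200, 201, 1000, 1))
  asg <- assign_cpgs(cp, seg)
  # pos 250 (1-based) -> 0-based 249 -> bin 2
  expect_equal(asg[1L], "2_EnhS")
  # pos 200 -> 0-based 199 -> still bin 1
  expect_equal(asg[2L], "1_Quies")
  # pos 201 -> 0-based 200 -> bin 2
  expect_equal(asg[3L], "2_EnhS")
  # last bp of the chromosome -> bin 5
  expect_equal(asg[4L], "1_Quies")
  expect_equal(asg[5L], "1_Quies")
  # unknown chromosome is unassigned, not an error
  cp2 <- make_cpgs(c("chrX", "chr1"), c(100, 100))
  asg2 <- assign_cpgs(cp2, seg)
  expect_true(is.na(asg2[1L]))
  expect_equal(asg2[2L], "1_Quies")
})

test_that("state summaries reproduce hand-counted shares", {
  layout <- genome_layout("chr1", 2000, 200)
  seg <- segmentation(layout, c(rep(2L, 4L), rep(1L, 6L)),
                      state_labels = c("1_Quies", "2_EnhS"))
  # 10 sites, one per bin; 4 in the enhancer state; significant: 3 of the
  # 4 enhancer sites plus 1 quiescent site
  pos <- seq(100, 1900, by = 200)
  sig <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cp <- make_cpgs("chr1", pos, sig)
  s <- summarize_states(cp, assign_cpgs(cp, seg))
  enh <- s[s$state == "2_EnhS", ]
  expect_equal(enh$n_cpg, 4L)
  expect_equal(enh$pct_all, 40)
  expect_equal(enh$pct_demeth, 75)
  expect_equal(enh$n_demeth, 3L)
  expect_equal(sum(s$n_cpg), 10L)
  expect_equal(sum(s$pct_all), 100)
  expect_equal(sum(s$pct_demeth), 100)
  expect_equal(enh$mean_delta_beta, -0.3 * 3 / 4)
  # single-state degenerate case
  seg1 <- segmentation(layout, rep(1L, 10L), state_labels = "1_Quies")
  s1 <- summarize_states(cp, assign_cpgs(cp, seg1))
  expect_equal(s1$pct_all, 100)
  expect_equal(s1$pct_demeth, 100)
  # zero significant sites warn and zero the demethylated column
  cp0 <- make_cpgs("chr1", pos, 0)
  expect_warning(s0 <- summarize_states(cp0, assign_cpgs(cp0, seg)),
                 "no significant")
  expect_true(all(s0$pct_demeth == 0))
})

test_that("observed chi-square equals the closed-form Pearson statistic", {
  asg <- rep(c("A", "B"), each = 100)
  sig <- c(rep(1, 90), rep(0, 10), rep(1, 10), rep(0, 90))
  pc <- permutation_chisq(asg, sig, n_perm = 50, seed = 1)
  expect_equal(pc$statistic, 128)        # hand-computed Pearson value
  expect_equal(pc$statistic,
               unname(stats::chisq.test(table(asg, sig),
                                        correct = FALSE)$statistic))
  expect_equal(pc$df, 1L)
  expect_equal(unname(pc$table[, "significant"]), c(90L, 10L))
})

test_that("extreme association reaches the permutation floor", {
  asg <- rep(c("EnhS", "Quies"), c(100, 400))
  sig <- c(rep(1, 100), rep(0, 400))
  pc <- permutation_chisq(asg, sig, n_perm = 1000, seed = 3)
  expect_equal(pc$p_value, 1 / 1001)
})

test_that("permutation p-values are reproducible and seed-sensitive", {
  set.seed(71)
  asg <- sample(c("A", "B", "C"), 300, replace = TRUE)
  sig <- rbinom(300, 1, 0.2)
  p1 <- permutation_chisq(asg, sig, n_perm = 200, seed = 9)
  p2 <- permutation_chisq(asg, sig, n_perm = 200, seed = 9)
  expect_identical(p1$p_value, p2$p_value)
})

test_that("permutation p approaches the asymptotic chi-square p", {
  set.seed(72)
  asg <- sample(c("A", "B"), 2000, replace = TRUE)
  sig <- rbinom(2000, 1, 0.25 + 0.05 * (asg == "A"))
  pc <- permutation_chisq(asg, sig, n_perm = 2000, seed = 5)
  asym <- stats::pchisq(pc$statistic, df = 1, lower.tail = FALSE)
  expect_lt(abs(pc$p_value - asym), 0.05)
})

test_that("unassigned sites are excluded and degenerate tables rejected", {
  asg <- c("A", "A", NA, "B", "B")
  sig <- c(1, 0, 1, 0, 1)
  pc <- permutation_chisq(asg, sig, n_perm = 10, seed = 1)
  expect_equal(sum(pc$table), 4L)
  expect_error(permutation_chisq(c("A", "A"), c(1, 0), n_perm = 10),
               "at least 2 states")
  f <- factor(c("A", "A", "B", "B"), levels = c("A", "B", "C"))
  expect_warning(permutation_chisq(f, c(1, 0, 1, 0), n_perm = 10, seed = 1),
                 "zero sites")
})
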