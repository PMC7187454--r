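tiny_layout <- function(bp = 4e5, chroms = 1L) {
  genome_layout(paste0("chr", seq_len(chroms)), rep(bp, chroms), 200L)
}

test_that("state chain respects degenerate configurations", {
  cfg1 <- simulation_config(
    layout = tiny_layout(2e4),
    emission_truth = matrix(0.5, 1L, 2L),
    transition_truth = matrix(1, 1L, 1L),
    initial_truth = 1, flow_truth = matrix(1, 1L, 1L),
    state_names = "only", mark_names = c("m1", "m2"), seed = 1
  )
  seg <- simulate_state_chain(cfg1)
  expect_true(all(seg$states == 1L))

  # absorbing states: identity transitions freeze the initial draw
  cfg <- simulation_config(
    layout = tiny_layout(2e4),
    emission_truth = matrix(c(0.9, 0.1, 0.1, 0.9), 2L, 2L),
    transition_truth = diag(2L), initial_truth = c(0.5, 0.5),
    flow_truth = diag(2L), state_names = c("a", "b"),
    mark_names = c("m1", "m2"), seed = 5
  )
  seg <- simulate_state_chain(cfg)
  expect_equal(length(unique(seg$states)), 1L)
})

test_that("simulated chains reproduce the transition matrix empirically", {
  cfg <- simulation_config(layout = genome_layout("chr1", 2e8, 200), seed = 2)
  seg <- simulate_state_chain(cfg)          # 1e6 bins
  K <- cfg$n_states
  emp <- table(factor(seg$states[-length(seg$states)], levels = 1:K),
               factor(seg$states[-1L], levels = 1:K))
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - cfg$transition_truth)), 0.01)
})

test_that("mark emission frequencies match the truth per state", {
  E <- rbind(c(0.9, 0.2, 0.5), c(0.1, 0.7, 0.05))
  cfg <- simulation_config(
    layout = genome_layout("chr1", 6e7, 200),  # 3e5 bins
    emission_truth = E, transition_truth = matrix(0.5, 2, 2),
    initial_truth = c(0.5, 0.5), flow_truth = diag(2),
    state_names = c("a", "b"), mark_names = paste0("m", 1:3), seed = 3
  )
  seg <- simulate_state_chain(cfg)
  tracks <- simulate_marks(seg, cfg)
  expect_length(tracks, 3L)
  for (m in 1:3) {
    for (k in 1:2) {
      emp <- mean(tracks[[m]]$calls[seg$states == k])
      expect_lt(abs(emp - E[k, m]), 0.01)
    }
  }
  # degenerate emissions
  cfg0 <- cfg; cfg0$emission_truth <- matrix(0, 2, 3)
  expect_true(all(simulate_marks(seg, cfg0)[[1L]]$calls == 0L))
  cfg1 <- cfg; cfg1$emission_truth <- matrix(1, 2, 3)
  expect_true(all(simulate_marks(seg, cfg1)[[2L]]$calls == 1L))
})

test_that("condition pair follows the flow truth", {
  cfg <- simulation_config(layout = tiny_layout(2e5), seed = 4)
  segA <- simulate_state_chain(cfg)
  cfg_id <- cfg; cfg_id$flow_truth <- diag(cfg$n_states)
  expect_identical(simulate_condition_pair(segA, cfg_id)$states, segA$states)

  # a quiescent row concentrated on the enhancer state converts ~all bins
  K <- cfg$n_states
  conc <- diag(K); conc[6L, ] <- 0; conc[6L, 2L] <- 1
  cfg_c <- cfg; cfg_c$flow_truth <- conc
  segB <- simulate_condition_pair(segA, cfg_c)
  expect_true(all(segB$states[segA$states == 6L] == 2L))

  # empirical flow at 1e6 bins
  cfg_big <- simulation_config(layout = genome_layout("chr1", 2e8, 200), seed = 6)
  segA <- simulate_state_chain(cfg_big)
  segB <- simulate_condition_pair(segA, cfg_big)
  emp <- table(factor(segA$states, levels = 1:K), factor(segB$states, levels = 1:K))
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - cfg_big$flow_truth)), 0.01)
})

test_that("methylation flags follow the per-state probabilities", {
  probs <- c(0.3, 0.05)
  cfg <- simulation_config(
    layout = genome_layout("chr1", 4e6, 200),
    emission_truth = matrix(c(0.9, 0.1), 2L, 1L),
    transition_truth = matrix(0.5, 2, 2), initial_truth = c(0.5, 0.5),
    flow_truth = diag(2), state_names = c("a", "b"), mark_names = "m1",
    cpg_density = 10, demeth_prob_by_state = probs, seed = 8
  )
  seg <- simulate_state_chain(cfg)
  cp <- simulate_methylation(seg, cfg)
  expect_true(all(cp$beta_before >= 0 & cp$beta_before <= 1))
  expect_true(all(cp$beta_after >= 0 & cp$beta_after <= 1))
  st <- seg$states[genome_bin_index_for_test(seg$layout, cp$chrom, cp$pos - 1)]
  for (k in 1:2) {
    n_k <- sum(st == k)
    expect_gt(n_k, 1e4)
    expect_lt(abs(mean(cp$significant[st == k]) - probs[k]), 0.02)
  }
  # zero probabilities give zero flags; unit probability confines flags
  cfg0 <- cfg; cfg0$demeth_prob_by_state <- c(0, 0)
  expect_equal(sum(simulate_methylation(seg, cfg0)$significant), 0L)
  cfg1 <- cfg; cfg1$demeth_prob_by_state <- c(1, 0)
  cp1 <- simulate_methylation(seg, cfg1)
  expect_true(all(st[cp1$significant == 1L] == 1L))
})

test_that("planted sequences carry the motif exactly as configured", {
  cfg <- simulation_config(layout = tiny_layout(2e4),
                           motif_plant_rate_new = 1,
                           motif_plant_rate_constant = 0, seed = 9)
  sq <- simulate_enhancer_sequences(30L, 30L, 300L, cfg)
  permissive <- pwm_threshold(cfg$motif_pwm, 0.25)
  hits_new <- vapply(sq$new, function(s)
    nrow(scan_sequence(s, cfg$motif_pwm, permissive)) >= 1L, TRUE)
  expect_true(all(hits_new))
  expect_true(all(!sq$planted_constant))
  expect_error(simulate_enhancer_sequences(2L, 2L, 5L, cfg), "length")
})

test_that("identical seeds reproduce every generator bit-identically", {
  cfg <- simulation_config(layout = tiny_layout(1e5), cpg_density = 5, seed = 123)
  a1 <- simulate_state_chain(cfg); a2 <- simulate_state_chain(cfg)
  expect_identical(a1$states, a2$states)
  expect_identical(lapply(simulate_marks(a1, cfg), `[[`, "calls"),
                   lapply(simulate_marks(a1, cfg), `[[`, "calls"))
  expect_identical(simulate_condition_pair(a1, cfg)$states,
                   simulate_condition_pair(a1, cfg)$states)
  expect_identical(simulate_methylation(a1, cfg),
                   simulate_methylation(a1, cfg))
  expect_identical(simulate_enhancer_sequences(5L, 5L, 100L, cfg),
                   simulate_enhancer_sequences(5L, 5L, 100L, cfg))
  # different seed, different draw
  cfg2 <- simulation_config(layout = tiny_layout(1e5), seed = 124)
  expect_false(identical(simulate_state_chain(cfg2)$states, a1$states))
})

test_that("cpg table TSV round trips", {
  cfg <- simulation_config(layout = tiny_layout(1e5), cpg_density = 2, seed = 3)
  seg <- simulate_state_chain(cfg)
  cp <- simulate_methylation(seg, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cpg_table(cp, f)
  cp2 <- read_cpg_table(f)
  expect_equal(cp2$pos, cp$pos)
  expect_equal(cp2$beta_after, cp$beta_after, tolerance = 1e-12)
  expect_equal(cp2$significant, cp$significant)
})
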