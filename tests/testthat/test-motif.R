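uniform_pwm <- function(L = 4L) {
  motif_pwm(matrix(0.25, L, 4L), name = "flat")
}

rc <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

test_that("a background-equal PWM scores zero everywhere", {
  pwm <- uniform_pwm()
  # log2((0.25 + pc*0.25)/0.25) = log2(1 + pc) per position
  hits <- scan_sequence("ACGTACGTACGT", pwm, score_threshold = 1)
  expect_equal(nrow(hits), 0L)
  all_hits <- scan_sequence("ACGTACGT", pwm, score_threshold = -1)
  # per position: log2((0.25 + 0.01 * 0.25) / 0.25) = log2(1.01)
  expect_equal(unique(round(all_hits$score, 6)),
               round(4 * log2(1.01), 6))
})

test_that("the consensus sequence attains the maximal score", {
  pwm <- sox9_like_pwm()
  cons <- paste(colnames(pwm$matrix)[apply(pwm$matrix, 1L, which.max)],
                collapse = "")
  seq <- paste0("GGGGG", cons, "GGGGG")
  hits <- scan_sequence(seq, pwm, score_threshold = pwm_max_score(pwm) - 1e-9)
  expect_equal(hits$position, 6L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, pwm_max_score(pwm), tolerance = 1e-12)
})

test_that("scanning matches a naive per-window rescoring oracle", {
  set.seed(91)
  pwm <- sox9_like_pwm()
  L <- nrow(pwm$matrix)
  sc <- log2((pwm$matrix + pwm$pseudocount * 0.25) / 0.25)
  naive_scan <- function(seq, thr) {
    ch <- strsplit(seq, "")[[1L]]
    out <- NULL
    for (i in seq_len(nchar(seq) - L + 1L)) {
      win <- ch[i:(i + L - 1L)]
      for (strand in c("+", "-")) {
        w <- if (strand == "+") win else
          rev(chartr("ACGT", "TGCA", win))
        if (any(w == "N")) next
        s <- sum(sc[cbind(seq_len(L), match(w, c("A", "C", "G", "T")))])
        if (s >= thr) out <- rbind(out, data.frame(position = i,
                                                   strand = strand,
                                                   score = s))
      }
    }
    out
  }
  for (rep in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
    thr <- pwm_threshold(pwm, 0.35)
    mine <- scan_sequence(seq, pwm, thr)
    ref <- naive_scan(seq, thr)
    if (is.null(ref)) {
      expect_equal(nrow(mine), 0L)
    } else {
      ref <- ref[order(ref$position, ref$strand), ]
      expect_equal(mine$position, ref$position)
      expect_equal(mine$strand, ref$strand)
      expect_equal(mine$score, ref$score, tolerance = 1e-12)
    }
  }
})

test_that("scanning is strand-symmetric", {
  set.seed(92)
  pwm <- sox9_like_pwm()
  cons <- paste(colnames(pwm$matrix)[apply(pwm$matrix, 1L, which.max)],
                collapse = "")
  # embed one forward and one reverse-complement instance among noise
  seq <- paste0(
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    cons,
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    rc(cons),
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""))
  thr <- pwm_threshold(pwm, 0.3)
  h1 <- scan_sequence(seq, pwm, thr)
  h2 <- scan_sequence(rc(seq), pwm, thr)
  L <- nrow(pwm$matrix)
  mirrored <- data.frame(
    position = nchar(seq) - L + 2L - h1$position,
    strand = ifelse(h1$strand == "+", "-", "+"),
    score = h1$score
  )
  mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
  expect_equal(h2$position, mirrored$position)
  expect_equal(h2$strand, mirrored$strand)
  expect_equal(h2$score, mirrored$score, tolerance = 1e-12)
})

test_that("windows with N are skipped and short sequences yield no hits", {
  pwm <- sox9_like_pwm()
  expect_equal(nrow(scan_sequence("ACG", pwm, -100)), 0L)
  hits <- scan_sequence("AACANTATTGTT", pwm, score_threshold = -100)
  expect_equal(nrow(hits), 0L)  # the only window contains N
})

test_that("MEME minimal format round trips", {
  pwm <- sox9_like_pwm()
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme_pwm(pwm, f)
  back <- read_meme_pwm(f)
  expect_equal(back$name, pwm$name)
  expect_equal(unname(back$matrix), unname(pwm$matrix), tolerance = 1e-5)
  expect_equal(back$background, pwm$background, tolerance = 1e-6)
})

test_that("Fisher enrichment equals hypergeometric enumeration on 2x2 tables", {
  # new: 9/10 with motif; constant: 1/10
  p_manual <- sum(stats::dhyper(9:10, 10, 10, 10))
  cfg <- simulation_config(seed = 1)
  # build sequence sets whose hit pattern is forced: consensus vs all-G
  pwm <- cfg$motif_pwm
  cons <- paste(colnames(pwm$matrix)[apply(pwm$matrix, 1L, which.max)],
                collapse = "")
  with_motif <- paste0(strrep("G", 20), cons, strrep("G", 20))
  without <- strrep("G", 52)
  res <- relative_enrichment(
    c(rep(with_motif, 9), without),
    c(with_motif, rep(without, 9)),
    pwm
  )
  expect_equal(res$hits_new, 9)
  expect_equal(res$hits_constant, 1)
  expect_equal(res$p_one_sided, p_manual, tolerance = 1e-12)
  # internal consistency with the region-overlap hypergeometric:
  # drawing the 10 "new" slots from 20 sequences of which 10 have the motif
  ht <- hypergeom_upper_tail(20, 10, 10, 9)
  expect_equal(res$p_one_sided, ht$p_upper, tolerance = 1e-12)
  # Haldane-corrected odds ratio when a cell is zero
  res0 <- relative_enrichment(rep(with_motif, 5), rep(without, 5), pwm)
  expect_equal(res0$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))
  expect_error(relative_enrichment(character(0), without, pwm), "non-empty")
})

test_that("balanced hit rates give no one-sided signal", {
  # identical sequence sets give identical hit counts: one-sided p > 0.5
  cfg <- simulation_config(motif_plant_rate_new = 0.3,
                           motif_plant_rate_constant = 0.3, seed = 94)
  sq <- simulate_enhancer_sequences(150L, 150L, 400L, cfg)
  res_same <- relative_enrichment(sq$new, sq$new, cfg$motif_pwm)
  expect_gte(res_same$p_one_sided, 0.5)
  # equal planting rates: p has no systematic excess of small values
  ps <- vapply(1:8, function(i) {
    cfg_i <- simulation_config(motif_plant_rate_new = 0.3,
                               motif_plant_rate_constant = 0.3,
                               seed = 940 + i)
    s <- simulate_enhancer_sequences(100L, 100L, 400L, cfg_i)
    relative_enrichment(s$new, s$constant, cfg_i$motif_pwm)$p_one_sided
  }, 0)
  expect_gt(stats::median(ps), 0.1)
})
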