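#' Default mark panel, state set and ground-truth parameters
#'
#' The generator emulates a mesenchymal-stem-cell to chondrocyte
#' differentiation design: five histone marks (H3K4me3, H3K4me1,
#' H3K27ac, H3K27me3, H3K36me3) binarized on 200-bp bins, a six-state
#' chromatin vocabulary (strong promoter, strong enhancer, weak
#' enhancer, transcription, Polycomb repression, quiescent), a paired
#' condition whose state map is the first condition's map pushed through
#' a flow matrix dominated by state persistence plus gains of strong
#' enhancers from quiescent/repressed chromatin, CpG sites whose
#' demethylation probability is concentrated in the strong-enhancer
#' state, and enhancer sequence sets with a SOX9-like motif planted at
#' class-specific rates.
#'
#' @name synthetic-defaults
#' @return `default_marks()`: the mark names. `default_state_names()`:
#'   the state names. `default_emission_truth()`: 6 x 5 Bernoulli
#'   emission matrix. `default_transition_truth()`: sticky 6 x 6
#'   transition matrix. `default_flow_truth()`: condition-B-given-A
#'   resampling matrix. `default_layout()`: 4 chromosomes x 10 Mb at
#'   200-bp bins. `sox9_like_pwm()`: a near-degenerate PWM on the
#'   SOX9 consensus core AACAAT.
NULL

#' @rdname synthetic-defaults
#' @export
default_marks <- function() {
  c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3", "H3K36me3")
}

#' @rdname synthetic-defaults
#' @export
default_state_names <- function() {
  c("TssS", "EnhS", "EnhW", "Tx", "ReprPC", "Quies")
}

#' @rdname synthetic-defaults
#' @export
default_emission_truth <- function() {
  E <- rbind(
    TssS   = c(0.95, 0.30, 0.60, 0.02, 0.05),
    EnhS   = c(0.05, 0.90, 0.85, 0.02, 0.05),
    EnhW   = c(0.05, 0.80, 0.10, 0.05, 0.05),
    Tx     = c(0.02, 0.10, 0.05, 0.02, 0.90),
    ReprPC = c(0.02, 0.05, 0.02, 0.90, 0.02),
    Quies  = c(0.02, 0.03, 0.02, 0.05, 0.03)
  )
  colnames(E) <- default_marks()
  E
}

#' @rdname synthetic-defaults
#' @export
default_state_occupancy <- function() {
  # genome-scale shares: quiescent chromatin dominates, promoters and
  # strong enhancers are rare (about 2% each)
  c(TssS = 0.02, EnhS = 0.02, EnhW = 0.08, Tx = 0.15,
    ReprPC = 0.10, Quies = 0.63)
}

#' @rdname synthetic-defaults
#' @param K Number of states.
#' @param self Self-transition stickiness (default 0.97, mean segment
#'   length about 33 bins).
#' @param stationary Target stationary distribution; default
#'   [default_state_occupancy()] when `K = 6`, else uniform.
#' @export
default_transition_truth <- function(K = 6L, self = 0.97, stationary = NULL) {
  stationary <- stationary %||%
    if (K == 6L) unname(default_state_occupancy()) else rep(1 / K, K)
  # restart chain A = s I + (1 - s) 1 pi' has stationary pi exactly
  A <- self * diag(K) +
    (1 - self) * matrix(stationary, K, K, byrow = TRUE)
  A
}

#' @rdname synthetic-defaults
#' @export
default_flow_truth <- function() {
  # rows: condition-A state; columns: condition-B state.
  # Persistence-dominated, with quiescent/repressed chromatin feeding the
  # strong-enhancer state (new enhancers) during differentiation. Gains
  # are scaled so the destination strong-enhancer occupancy stays near
  # 2% of bins — the rare-enhancer regime of genome-wide state maps.
  A <- rbind(
    TssS   = c(0.920, 0.002, 0.020, 0.020, 0.008, 0.030),
    EnhS   = c(0.020, 0.800, 0.080, 0.020, 0.020, 0.060),
    EnhW   = c(0.020, 0.006, 0.800, 0.040, 0.020, 0.114),
    Tx     = c(0.010, 0.001, 0.020, 0.900, 0.009, 0.060),
    ReprPC = c(0.010, 0.012, 0.030, 0.010, 0.850, 0.088),
    Quies  = c(0.008, 0.004, 0.030, 0.020, 0.018, 0.920)
  )
  colnames(A) <- default_state_names()
  A
}

#' @rdname synthetic-defaults
#' @export
default_layout <- function() {
  genome_layout(paste0("chr", 1:4), rep(1e7, 4L), bin_size = 200L)
}

#' @rdname synthetic-defaults
#' @export
sox9_like_pwm <- function() {
  # tandem repeat of the AACAAT HMG-box half-site, as SOX9 binds paired
  # sites in cartilage enhancers; near-degenerate columns
  consensus <- strsplit("AACAATAACAAT", "")[[1L]]
  bases <- c("A", "C", "G", "T")
  mat <- t(vapply(consensus, function(b) {
    p <- rep(0.02, 4L); p[match(b, bases)] <- 0.94; p
  }, numeric(4L)))
  motif_pwm(mat, name = "SOX9dimer")
}

#' Configuration for the synthetic-data generator
#'
#' Bundles the ground truth every simulator draws from. Defaults are the
#' package's reference study conditions (see `vignette` and
#' [synthetic-defaults]); any component can be overridden.
#'
#' @param layout Coordinate frame ([genome_layout()]).
#' @param emission_truth K x M Bernoulli emission matrix.
#' @param transition_truth K x K row-stochastic transition matrix.
#' @param initial_truth K initial probabilities (default uniform).
#' @param flow_truth K x K row-stochastic condition-B-given-A matrix.
#' @param state_names K state names.
#' @param mark_names M mark names.
#' @param cpg_density CpG sites per kb (default 1).
#' @param demeth_prob_by_state Per-state probability that a CpG site in
#'   that state is flagged significantly demethylated. Default: 0.35 in
#'   the strong-enhancer state, 0.01 elsewhere — the enhancer-focused
#'   demethylation pattern of chondrogenic differentiation.
#' @param demeth_effect Beta-value drop applied to flagged sites
#'   (default 0.3).
#' @param motif_pwm A [motif_pwm()] to plant (default [sox9_like_pwm()]).
#' @param motif_plant_rate_new,motif_plant_rate_constant Per-sequence
#'   probabilities of planting one motif instance in new / constant
#'   enhancer sequences (defaults 0.6 and 0.1).
#' @param seed Base seed; each generator derives a fixed substream from
#'   it, so regenerating one output never perturbs the others.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(layout = default_layout(),
                              emission_truth = default_emission_truth(),
                              transition_truth = NULL,
                              initial_truth = NULL,
                              flow_truth = NULL,
                              state_names = NULL,
                              mark_names = NULL,
                              cpg_density = 1,
                              demeth_prob_by_state = NULL,
                              demeth_effect = 0.3,
                              motif_pwm = sox9_like_pwm(),
                              motif_plant_rate_new = 0.6,
                              motif_plant_rate_constant = 0.1,
                              seed = 1L) {
  emission_truth <- as.matrix(emission_truth)
  K <- nrow(emission_truth)
  M <- ncol(emission_truth)
  transition_truth <- transition_truth %||% default_transition_truth(K)
  # default initial distribution: the transition chain's stationary
  # distribution, so occupancies hold from the first bin
  initial_truth <- initial_truth %||% stationary_distribution(transition_truth)
  if (is.null(flow_truth)) {
    flow_truth <- if (K == 6L) default_flow_truth() else diag(K)
  }
  state_names <- state_names %||% rownames(emission_truth) %||%
    paste0("S", seq_len(K))
  mark_names <- mark_names %||% colnames(emission_truth) %||%
    paste0("mark", seq_len(M))
  if (is.null(demeth_prob_by_state)) {
    demeth_prob_by_state <- rep(0.01, K)
    enh <- which(state_names == "EnhS")
    if (length(enh)) demeth_prob_by_state[enh] <- 0.35
  }
  check_prob_vector(initial_truth, "initial_truth")
  check_stochastic_matrix(transition_truth, "transition_truth")
  check_stochastic_matrix(flow_truth, "flow_truth")
  if (any(emission_truth < 0 | emission_truth > 1)) {
    stopf("emission_truth entries must be in [0, 1]")
  }
  if (length(demeth_prob_by_state) != K ||
      any(demeth_prob_by_state < 0 | demeth_prob_by_state > 1)) {
    stopf("demeth_prob_by_state must be K probabilities")
  }
  if (cpg_density <= 0) stopf("cpg_density must be positive")
  structure(
    list(layout = layout, n_states = K, n_marks = M,
         emission_truth = emission_truth,
         transition_truth = transition_truth,
         initial_truth = initial_truth,
         flow_truth = flow_truth,
         state_names = state_names, mark_names = mark_names,
         cpg_density = cpg_density,
         demeth_prob_by_state = demeth_prob_by_state,
         demeth_effect = demeth_effect,
         motif_pwm = motif_pwm,
         motif_plant_rate_new = motif_plant_rate_new,
         motif_plant_rate_constant = motif_plant_rate_constant,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate the condition-A chromatin-state chain
#'
#' States are a first-order Markov chain per chromosome; the chain
#' restarts from the initial distribution at every chromosome.
#'
#' @param config A [simulation_config()].
#' @return A [segmentation()] whose labels are `"<index>_<name>"`.
#' @export
simulate_state_chain <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(substream_seed(config$seed, "state_chain"), {
    states <- unlist(lapply(unname(config$layout$n_bins_per_chrom), function(n) {
      sim_markov_cpp(config$initial_truth, config$transition_truth,
                     stats::runif(n))
    }), use.names = FALSE)
    segmentation(config$layout, states,
                 state_labels = truth_labels(config))
  })
}

truth_labels <- function(config) {
  paste0(seq_len(config$n_states), "_", config$state_names)
}

#' Simulate binarized mark tracks from a segmentation
#'
#' Mark `m` in a bin of state `k` is 1 with probability
#' `emission_truth[k, m]`, independently across bins and marks.
#'
#' @param seg A [segmentation()] with states in `1..K`.
#' @param config A [simulation_config()].
#' @return List of [binary_mark_track()] objects, one per mark.
#' @export
simulate_marks <- function(seg, config) {
  stopifnot(inherits(seg, "segmentation"), inherits(config, "simulation_config"))
  if (max(seg$states) > config$n_states) {
    stopf("segmentation has states beyond the config's K")
  }
  with_seed(substream_seed(config$seed, "marks"), {
    lapply(seq_len(config$n_marks), function(m) {
      p <- config$emission_truth[seg$states, m]
      binary_mark_track(seg$layout, config$mark_names[m],
                        stats::rbinom(length(p), 1L, p))
    })
  })
}

#' Simulate the paired condition-B segmentation
#'
#' Each bin's condition-B state is drawn from the flow-truth row of its
#' condition-A state, independently per bin.
#'
#' @param segA Condition-A [segmentation()].
#' @param config A [simulation_config()].
#' @return Condition-B [segmentation()] on the same layout.
#' @export
simulate_condition_pair <- function(segA, config) {
  stopifnot(inherits(segA, "segmentation"), inherits(config, "simulation_config"))
  with_seed(substream_seed(config$seed, "condition_pair"), {
    K <- config$n_states
    b <- integer(length(segA$states))
    for (k in seq_len(K)) {
      idx <- which(segA$states == k)
      if (length(idx)) {
        b[idx] <- sample.int(K, length(idx), replace = TRUE,
                             prob = config$flow_truth[k, ])
      }
    }
    segmentation(segA$layout, b, state_labels = truth_labels(config))
  })
}

#' Simulate a CpG methylation table over a segmentation
#'
#' CpG positions are placed uniformly along each chromosome at
#' `cpg_density` sites per kb. Baseline beta values follow the bimodal
#' mixture 0.5 Beta(0.5, 5) + 0.5 Beta(5, 0.5) (a stand-in for the
#' marginal beta distribution of methylation arrays; no real-array noise
#' model is fitted). A site is flagged significantly demethylated with
#' the probability configured for the chromatin state of its containing
#' bin; flagged sites lose `demeth_effect` beta (clamped to \[0, 1\]),
#' unflagged sites receive small Gaussian jitter.
#'
#' @param segB The destination-condition [segmentation()].
#' @param config A [simulation_config()].
#' @return A `cpg_table` data.frame: chrom, pos (1-based), beta_before,
#'   beta_after, significant (0/1), direction ("hypo" or ".").
#' @export
simulate_methylation <- function(segB, config) {
  stopifnot(inherits(segB, "segmentation"), inherits(config, "simulation_config"))
  layout <- segB$layout
  with_seed(substream_seed(config$seed, "methylation"), {
    tabs <- lapply(seq_along(layout$chrom_names), function(i) {
      len <- layout$chrom_lengths[i]
      n <- max(1L, round(len / 1000 * config$cpg_density))
      pos <- sort(sample.int(len, min(n, len)))
      data.frame(chrom = layout$chrom_names[i], pos = pos,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, tabs)
    n <- nrow(df)
    lowhigh <- stats::rbinom(n, 1L, 0.5)
    beta_before <- ifelse(lowhigh == 1L,
                          stats::rbeta(n, 5, 0.5),
                          stats::rbeta(n, 0.5, 5))
    bins <- genome_bin_index(layout, df$chrom, df$pos - 1)
    state <- segB$states[bins]
    sig <- stats::rbinom(n, 1L, config$demeth_prob_by_state[state])
    noise <- stats::rnorm(n, 0, 0.02)
    beta_after <- ifelse(sig == 1L,
                         beta_before - config$demeth_effect,
                         beta_before + noise)
    beta_after <- pmin(pmax(beta_after, 0), 1)
    out <- data.frame(
      chrom = df$chrom, pos = df$pos,
      beta_before = beta_before, beta_after = beta_after,
      significant = sig,
      direction = ifelse(sig == 1L, "hypo", "."),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    class(out) <- c("cpg_table", "data.frame")
    out
  })
}

#' Simulate new/constant enhancer sequence sets with a planted motif
#'
#' Sequences are i.i.d. uniform over A/C/G/T; with the class-specific
#' planting probability one motif instance (sampled column-wise from the
#' PWM) is inserted at a uniform position.
#'
#' @param n_new,n_constant Sequence counts per class.
#' @param length Sequence length in bp (must be >= the motif length).
#' @param config A [simulation_config()].
#' @return List with character vectors `new` and `constant` (named
#'   sequences) and logical vectors `planted_new`, `planted_constant`.
#' @export
simulate_enhancer_sequences <- function(n_new, n_constant, length, config) {
  stopifnot(inherits(config, "simulation_config"))
  pwm <- config$motif_pwm
  L <- nrow(pwm$matrix)
  if (length < L) stopf("sequence length (%d) < motif length (%d)", length, L)
  bases <- c("A", "C", "G", "T")
  with_seed(substream_seed(config$seed, "enhancer_sequences"), {
    gen_class <- function(n, rate, prefix) {
      planted <- stats::runif(n) < rate
      seqs <- vapply(seq_len(n), function(i) {
        s <- sample(bases, length, replace = TRUE)
        if (planted[i]) {
          inst <- vapply(seq_len(L), function(j) {
            sample(bases, 1L, prob = pwm$matrix[j, ])
          }, "")
          at <- sample.int(length - L + 1L, 1L)
          s[at:(at + L - 1L)] <- inst
        }
        paste(s, collapse = "")
      }, "")
      names(seqs) <- paste0(prefix, "_", seq_len(n))
      list(seqs = seqs, planted = planted)
    }
    new <- gen_class(n_new, config$motif_plant_rate_new, "new")
    con <- gen_class(n_constant, config$motif_plant_rate_constant, "constant")
    list(new = new$seqs, constant = con$seqs,
         planted_new = new$planted, planted_constant = con$planted)
  })
}

#' Simulate a two-group family of enhancer interval sets
#'
#' Builds per-sample strong-enhancer interval sets for a planted
#' two-group design: samples inside a group share a fixed block core, so
#' pairwise base-pair Jaccard similarity is high within groups and low
#' between them. Used to exercise cross-epigenome similarity clustering
#' with a known partition.
#'
#' @param n_per_group Samples per group (2 groups).
#' @param n_core_blocks Blocks in each group core.
#' @param block_bp Block width in bp.
#' @param jaccard_within,jaccard_between Target approximate pairwise
#'   Jaccard similarity within and between groups (defaults 0.8, 0.05).
#' @param layout A [genome_layout()].
#' @param seed Integer seed.
#' @return List with `sets` (named list of [interval_set()]) and
#'   `groups` (named group assignment).
#' @export
simulate_epigenome_groups <- function(n_per_group = 4L, n_core_blocks = 100L,
                                      block_bp = 2000L,
                                      jaccard_within = 0.8,
                                      jaccard_between = 0.05,
                                      layout = default_layout(), seed = 1L) {
  # core of size m per group; p private blocks per sample gives
  # J_within ~= m / (m + 2p); shared cross-group blocks c give
  # J_between ~= c / (2(m + p) - c)
  m <- n_core_blocks
  p <- max(1L, round(m * (1 - jaccard_within) / (2 * jaccard_within)))
  c_shared <- max(0L, round(2 * (m + p) * jaccard_between / (1 + jaccard_between)))
  with_seed(seed, {
    total_blocks <- 2L * m + 2L * n_per_group * p + 8L
    # non-overlapping candidate block slots across the genome
    coords <- block_slots(layout, total_blocks, block_bp)
    take <- function(k) {
      idx <- seq_len(k)
      out <- coords[idx, , drop = FALSE]
      coords <<- coords[-idx, , drop = FALSE]
      out
    }
    shared <- take(c_shared)
    core1 <- rbind(shared, take(m - c_shared))
    core2 <- rbind(shared, take(m - c_shared))
    sets <- list(); groups <- character(0)
    for (g in 1:2) {
      core <- if (g == 1L) core1 else core2
      for (s in seq_len(n_per_group)) {
        priv <- take(p)
        df <- rbind(core, priv)
        nm <- sprintf("g%d_s%d", g, s)
        sets[[nm]] <- merge_intervals(
          interval_set(df$chrom, df$start, df$end))
        groups[nm] <- paste0("group", g)
      }
    }
    list(sets = sets, groups = groups)
  })
}

#' Stationary distribution of a row-stochastic matrix
#' @param A K x K row-stochastic transition matrix.
#' @return K probabilities (left eigenvector of eigenvalue 1).
#' @export
stationary_distribution <- function(A) {
  ev <- eigen(t(A))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v / sum(v)
  pmax(v, 0) / sum(pmax(v, 0))
}

# evenly spaced non-overlapping block slots, shuffled
block_slots <- function(layout, n_blocks, block_bp) {
  per_chrom <- ceiling(n_blocks / length(layout$chrom_names))
  out <- do.call(rbind, lapply(seq_along(layout$chrom_names), function(i) {
    len <- layout$chrom_lengths[i]
    gap <- floor(len / per_chrom)
    if (gap <= block_bp) stopf("layout too small for %d blocks of %d bp",
                               n_blocks, block_bp)
    start <- (seq_len(per_chrom) - 1L) * gap
    data.frame(chrom = layout$chrom_names[i], start = start,
               end = start + block_bp, stringsAsFactors = FALSE)
  }))
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Read / write a CpG methylation table as TSV
#'
#' Columns: chrom, pos (1-based), beta_before, beta_after, significant
#' (0/1), direction. A header line is written.
#'
#' @param cpgs A `cpg_table` data.frame.
#' @param path File path.
#' @return `path` (write); a `cpg_table` (read).
#' @export
write_cpg_table <- function(cpgs, path) {
  utils::write.table(as.data.frame(cpgs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_cpg_table
#' @export
read_cpg_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "beta_before", "beta_after", "significant")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("%s: missing columns %s", path,
                             paste(missing, collapse = ", "))
  if (is.null(df$direction)) df$direction <- ifelse(df$significant == 1, "hypo", ".")
  if (any(df$beta_before < 0 | df$beta_before > 1 |
            df$beta_after < 0 | df$beta_after > 1)) {
    stopf("%s: beta values outside [0, 1]", path)
  }
  if (any(df$pos <= 0)) stopf("%s: positions must be 1-based positive", path)
  if (anyDuplicated(df[c("chrom", "pos")])) stopf("%s: duplicate (chrom, pos)", path)
  class(df) <- c("cpg_table", "data.frame")
  df
}
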