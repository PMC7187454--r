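#' End-to-end synthetic demonstration run
#'
#' Exercises every stage of the pipeline on generated data with known
#' ground truth: simulate a condition-A state chain and binarized mark
#' tracks, learn a chromatin-state model, decode both conditions, tally
#' state flows, classify new/constant enhancers, integrate simulated
#' CpG methylation with the permutation chi-square test, cluster
#' simulated epigenome replicates by enhancer Jaccard similarity, test
#' region overlap hypergeometrically and score relative motif
#' enrichment. Every artifact is written as plain text under `out_dir`
#' and listed with its MD5 checksum in `manifest.tsv`, so identical
#' seeds give identical trees.
#'
#' @param seed Integer seed; fanned out deterministically to stages.
#' @param out_dir Output directory (created if absent).
#' @param config A [simulation_config()]; default a desk-scale layout
#'   (2 chromosomes x 2 Mb, 200-bp bins) with the package's reference
#'   ground truth.
#' @param n_states Number of states to learn (default: the truth's K).
#' @param max_iter EM iteration cap for the demo fit (default 100).
#' @param n_perm Permutations for the methylation test (default 1000).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest data.frame.
#' @export
run_demo <- function(seed = 1L, out_dir, config = NULL, n_states = NULL,
                     max_iter = 100L, n_perm = 1000L, quiet = FALSE) {
  if (missing(out_dir)) stopf("out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  config <- config %||% simulation_config(
    layout = genome_layout(c("chr1", "chr2"), c(2e6, 2e6), 200L),
    seed = substream_seed(seed, "sim")
  )
  n_states <- n_states %||% config$n_states
  paths <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    paths[[length(paths) + 1L]] <<- p
    p
  }

  say("simulating ground truth (seed %d)", seed)
  segA <- simulate_state_chain(config)
  segB <- simulate_condition_pair(segA, config)
  tracksA <- simulate_marks(segA, config)
  cfgB <- config
  cfgB$seed <- substream_seed(seed, "marksB")
  tracksB <- simulate_marks(segB, cfgB)
  write_segmentation_bed(segA, emit("truth_conditionA.bed"))
  write_segmentation_bed(segB, emit("truth_conditionB.bed"))
  for (t in tracksA) write_track_tsv(t, emit(sprintf("trackA_%s.tsv", t$mark)))

  say("learning a %d-state model", n_states)
  obsA <- stack_tracks(tracksA)
  obsB <- stack_tracks(tracksB)
  # joint training on both conditions (each chromosome of each condition
  # is its own chain)
  chains <- c(split_by_chrom(config$layout, obsA),
              split_by_chrom(config$layout, obsB))
  model <- fit_chromatin_hmm(chains, K = n_states,
                             seed = substream_seed(seed, "fit"),
                             max_iter = max_iter,
                             mark_names = config$mark_names)
  model <- label_states(model)
  write_hmm_model(model, emit("model.tsv"))

  say("decoding segmentations")
  decA <- viterbi_decode(model, obsA, config$layout)
  decB <- viterbi_decode(model, obsB, config$layout)
  write_segmentation_bed(decA, emit("segmentation_A.bed"))
  write_segmentation_bed(decB, emit("segmentation_B.bed"))

  say("state flows and enhancer classes")
  flow <- flow_matrix(decA, decB)
  write_flow_tsv(flow, emit("flow_matrix.tsv"))
  enh_label <- grep("_EnhS$", decB$state_labels, value = TRUE)
  cls <- NULL
  if (length(enh_label)) {
    cls <- tryCatch(classify_enhancers(decA, decB), error = function(e) NULL)
  }
  if (!is.null(cls)) {
    write_bed(cls$new_enhancers, emit("enhancers_new.bed"))
    write_bed(cls$constant_enhancers, emit("enhancers_constant.bed"))
    write_bed(cls$other_gain, emit("enhancers_other_gain.bed"))
  }

  say("methylation integration (%d permutations)", n_perm)
  cpgs <- simulate_methylation(segB, config)
  write_cpg_table(cpgs, emit("cpgs.tsv"))
  assign <- assign_cpgs(cpgs, decB)
  meth_summary <- summarize_states(cpgs, assign)
  utils::write.table(meth_summary, emit("methylation_by_state.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chisq <- permutation_chisq(assign, cpgs$significant, n_perm = n_perm,
                             seed = substream_seed(seed, "perm"))
  writeLines(c(
    sprintf("statistic\t%s", format_full(chisq$statistic)),
    sprintf("df\t%d", chisq$df),
    sprintf("p_value\t%s", format_full(chisq$p_value)),
    sprintf("n_perm\t%d", chisq$n_perm),
    sprintf("seed\t%d", chisq$seed)
  ), emit("methylation_chisq.tsv"))

  say("epigenome similarity clustering")
  groups <- simulate_epigenome_groups(layout = config$layout,
                                      seed = substream_seed(seed, "groups"))
  sim <- pairwise_similarity(groups$sets)
  write_similarity_tsv(sim, emit("similarity.tsv"))
  clust <- cluster_samples(sim)
  writeLines(clust$newick, emit("dendrogram.nwk"))
  writeLines(clust$leaf_order, emit("leaf_order.txt"))

  say("overlap test and motif enrichment")
  truth_enh <- state_intervals(segB, "EnhS")
  overlap <- NULL
  if (!is.null(cls) && nrow(cls$new_enhancers) > 0L && nrow(truth_enh) > 0L) {
    dec_enh <- state_intervals(decB, enh_label[1L])
    N <- nrow(dec_enh)
    Km <- count_region_overlap(dec_enh, truth_enh)
    nn <- nrow(cls$new_enhancers)
    kk <- count_region_overlap(cls$new_enhancers, truth_enh)
    overlap <- hypergeom_upper_tail(N, Km, nn, kk)
    writeLines(c(
      sprintf("universe_n\t%g", N), sprintf("marked_k\t%g", Km),
      sprintf("drawn_n\t%g", nn), sprintf("observed_k\t%g", kk),
      sprintf("p_upper\t%s", format_full(overlap$p_upper)),
      sprintf("log10_p\t%s", format_full(overlap$log10_p))
    ), emit("overlap_test.tsv"))
  }
  seqs <- simulate_enhancer_sequences(200L, 200L, 500L, config)
  write_fasta(seqs$new, emit("enhancers_new.fa"))
  write_fasta(seqs$constant, emit("enhancers_constant.fa"))
  write_meme_pwm(config$motif_pwm, emit("motif.meme"))
  enr <- relative_enrichment(seqs$new, seqs$constant, config$motif_pwm)
  writeLines(c(
    sprintf("hits_new\t%d", enr$hits_new), sprintf("n_new\t%d", enr$n_new),
    sprintf("hits_constant\t%d", enr$hits_constant),
    sprintf("n_constant\t%d", enr$n_constant),
    sprintf("odds_ratio\t%s", format_full(enr$odds_ratio)),
    sprintf("p_one_sided\t%s", format_full(enr$p_one_sided))
  ), emit("motif_enrichment.tsv"))

  manifest <- data.frame(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("done: %d artifacts in %s", nrow(manifest), out_dir)
  invisible(list(model = model, flow = flow, classification = cls,
                 methylation = list(summary = meth_summary, test = chisq),
                 clustering = clust, overlap = overlap, motif = enr,
                 manifest = manifest))
}
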