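#' Position weight matrix for motif scanning
#'
#' @param matrix L x 4 matrix of base probabilities, columns A, C, G, T;
#'   each row must sum to 1.
#' @param name Motif name.
#' @param background Background base frequencies (default uniform).
#' @param pseudocount Pseudocount fraction mixed into the matrix when
#'   scoring (default 0.01), so zero entries stay finite in log-odds.
#' @return An object of class `motif_pwm`.
#' @export
motif_pwm <- function(matrix, name = "motif",
                      background = rep(0.25, 4L), pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stopf("PWM must have 4 columns (A, C, G, T)")
  if (nrow(matrix) < 1L) stopf("PWM must have at least one position")
  for (i in seq_len(nrow(matrix))) check_prob_vector(matrix[i, ], sprintf("PWM row %d", i))
  check_prob_vector(background, "background")
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(name = as.character(name), matrix = matrix,
                 background = background, pseudocount = pseudocount),
            class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cons <- paste(colnames(x$matrix)[apply(x$matrix, 1L, which.max)], collapse = "")
  cat(sprintf("motif_pwm '%s': %d bp, consensus %s\n", x$name, nrow(x$matrix), cons))
  invisible(x)
}

#' Read a PWM from MEME minimal motif format
#'
#' Parses the first (or named) motif of a MEME minimal text file:
#' `MOTIF` header, optional `Background letter frequencies` line, and a
#' `letter-probability matrix` block.
#'
#' @param path Path to a MEME-format file.
#' @param name Optional motif name to select; default first motif.
#' @param pseudocount Passed to [motif_pwm()].
#' @return A [motif_pwm()].
#' @export
read_meme_pwm <- function(path, name = NULL, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  bg <- rep(0.25, 4L)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) && bg_at[1L] < length(lines)) {
    toks <- strsplit(lines[bg_at[1L] + 1L], "[ \t]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    nm <- toks[is.na(vals)]
    va <- vals[!is.na(vals)]
    if (length(va) == 4L) bg <- va[match(c("A", "C", "G", "T"), nm)]
  }
  motif_at <- grep("^MOTIF", lines)
  if (length(motif_at) == 0L) stopf("%s: no MOTIF record found", path)
  if (!is.null(name)) {
    nm <- vapply(strsplit(lines[motif_at], "[ \t]+"), function(x) x[2L], "")
    motif_at <- motif_at[nm == name]
    if (length(motif_at) == 0L) stopf("%s: motif '%s' not found", path, name)
  }
  start <- motif_at[1L]
  motif_name <- strsplit(lines[start], "[ \t]+")[[1L]][2L]
  lpm_at <- grep("^letter-probability matrix", lines)
  lpm_at <- lpm_at[lpm_at > start][1L]
  if (is.na(lpm_at)) stopf("%s: no letter-probability matrix after MOTIF", path)
  w <- sub(".*w= *([0-9]+).*", "\\1", lines[lpm_at])
  w <- suppressWarnings(as.integer(w))
  rows <- list(); i <- lpm_at + 1L
  while (i <= length(lines) && grepl("^[0-9.eE+-]", lines[i])) {
    rows[[length(rows) + 1L]] <- as.numeric(strsplit(lines[i], "[ \t]+")[[1L]])
    i <- i + 1L
  }
  if (!is.na(w) && length(rows) > w) rows <- rows[seq_len(w)]
  mat <- do.call(rbind, rows)
  # tolerate rounded rows as MEME files print them
  mat <- mat / rowSums(mat)
  motif_pwm(mat, name = motif_name, background = bg, pseudocount = pseudocount)
}

#' Write a PWM in MEME minimal motif format
#' @param pwm A [motif_pwm()].
#' @param path Output path.
#' @export
write_meme_pwm <- function(pwm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       pwm$background[1L], pwm$background[2L],
                       pwm$background[3L], pwm$background[4L]), "",
               sprintf("MOTIF %s", pwm$name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(pwm$matrix))), con)
  for (i in seq_len(nrow(pwm$matrix))) {
    writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                       pwm$matrix[i, 1L], pwm$matrix[i, 2L],
                       pwm$matrix[i, 3L], pwm$matrix[i, 4L]), con)
  }
  invisible(path)
}

# per-position, per-base log2-odds score table; column 5 (N) is -Inf so
# windows containing N never reach any finite threshold
pwm_score_table <- function(pwm) {
  sc <- log2((pwm$matrix + pwm$pseudocount *
                matrix(pwm$background, nrow(pwm$matrix), 4L, byrow = TRUE)) /
               matrix(pwm$background, nrow(pwm$matrix), 4L, byrow = TRUE))
  cbind(sc, N = -Inf)
}

#' Maximum achievable log-odds score of a PWM
#' @param pwm A [motif_pwm()].
#' @return Numeric score in bits.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(pwm_score_table(pwm)[, 1:4, drop = FALSE], 1L, max))
}

#' Default scan threshold: a fraction of the maximum achievable score
#' @param pwm A [motif_pwm()].
#' @param fraction Fraction of [pwm_max_score()] (default 0.6).
#' @return Numeric threshold in bits.
#' @export
pwm_threshold <- function(pwm, fraction = 0.6) fraction * pwm_max_score(pwm)

encode_dna <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1L]], c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) stopf("sequence contains characters outside A/C/G/T/N")
  codes
}

REV_CODE <- c(4L, 3L, 2L, 1L, 5L) # A<->T, C<->G, N->N

#' Scan a DNA sequence with a PWM on both strands
#'
#' Scores every window of the sequence (and of its reverse complement)
#' with the log2-odds of the PWM against its background; windows
#' containing N are skipped. A hit is a window scoring at least the
#' threshold.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param pwm A [motif_pwm()].
#' @param score_threshold Log-odds threshold in bits; default
#'   `pwm_threshold(pwm, threshold_frac)`.
#' @param threshold_frac Fraction of the maximal score used when
#'   `score_threshold` is not given (default 0.6).
#' @return data.frame with `position` (1-based window start on the
#'   forward strand), `strand` (`"+"`/`"-"`), `score`.
#' @export
scan_sequence <- function(seq, pwm, score_threshold = NULL,
                          threshold_frac = 0.6) {
  stopifnot(inherits(pwm, "motif_pwm"))
  score_threshold <- score_threshold %||% pwm_threshold(pwm, threshold_frac)
  codes <- encode_dna(seq)
  L <- nrow(pwm$matrix)
  n <- length(codes)
  if (n < L) {
    return(data.frame(position = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  sc <- pwm_score_table(pwm)
  nw <- n - L + 1L
  fwd <- numeric(nw)
  rev <- numeric(nw)
  # reverse-strand score of the window starting at i equals scoring the
  # window with the reverse-complemented PWM
  sc_rc <- sc[L:1, c(REV_CODE[1:4], 5L), drop = FALSE]
  colnames(sc_rc) <- colnames(sc)
  for (j in seq_len(L)) {
    b <- codes[j:(j + nw - 1L)]
    fwd <- fwd + sc[j, b]
    rev <- rev + sc_rc[j, b]
  }
  hits_f <- which(fwd >= score_threshold)
  hits_r <- which(rev >= score_threshold)
  out <- data.frame(
    position = c(hits_f, hits_r),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd[hits_f], rev[hits_r]),
    stringsAsFactors = FALSE
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

# fast per-sequence any-hit predicate (same scoring as scan_sequence)
has_motif_hit <- function(seq, sc, sc_rc, L, threshold) {
  codes <- encode_dna(seq)
  n <- length(codes)
  if (n < L) return(FALSE)
  nw <- n - L + 1L
  fwd <- numeric(nw); rev <- numeric(nw)
  for (j in seq_len(L)) {
    b <- codes[j:(j + nw - 1L)]
    fwd <- fwd + sc[j, b]
    rev <- rev + sc_rc[j, b]
  }
  max(fwd, rev) >= threshold
}

#' Relative motif enrichment between two sequence classes
#'
#' A sequence "has the motif" when it contains at least one scan hit.
#' The 2x2 table (has motif x class) is tested with a one-sided Fisher
#' exact test, alternative: enrichment in the first (new-enhancer)
#' class. The odds ratio uses the Haldane 0.5 correction when any cell
#' is zero.
#'
#' @param seqs_new,seqs_constant Character vectors of DNA sequences (or
#'   `Biostrings::DNAStringSet`).
#' @param pwm A [motif_pwm()].
#' @param score_threshold,threshold_frac As in [scan_sequence()].
#' @return Object of class `motif_enrichment`: `hits_new`, `n_new`,
#'   `hits_constant`, `n_constant`, `odds_ratio`, `p_one_sided`.
#' @export
relative_enrichment <- function(seqs_new, seqs_constant, pwm,
                                score_threshold = NULL,
                                threshold_frac = 0.6) {
  seqs_new <- as_dna_character(seqs_new)
  seqs_constant <- as_dna_character(seqs_constant)
  if (length(seqs_new) == 0L || length(seqs_constant) == 0L) {
    stopf("both sequence classes must be non-empty")
  }
  threshold <- score_threshold %||% pwm_threshold(pwm, threshold_frac)
  sc <- pwm_score_table(pwm)
  L <- nrow(pwm$matrix)
  sc_rc <- sc[L:1, c(REV_CODE[1:4], 5L), drop = FALSE]
  hn <- sum(vapply(seqs_new, has_motif_hit, TRUE, sc, sc_rc, L, threshold,
                   USE.NAMES = FALSE))
  hc <- sum(vapply(seqs_constant, has_motif_hit, TRUE, sc, sc_rc, L, threshold,
                   USE.NAMES = FALSE))
  nn <- length(seqs_new); nc <- length(seqs_constant)
  tab <- matrix(c(hn, nn - hn, hc, nc - hc), 2L, byrow = TRUE,
                dimnames = list(class = c("new", "constant"),
                                motif = c("hit", "no_hit")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  a <- hn; b <- nn - hn; c_ <- hc; d <- nc - hc
  or <- if (any(c(a, b, c_, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  structure(
    list(hits_new = a, n_new = nn, hits_constant = c_, n_constant = nc,
         odds_ratio = or, p_one_sided = p, table = tab,
         threshold = threshold, motif = pwm$name),
    class = "motif_enrichment"
  )
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "Motif enrichment (%s): new %d/%d vs constant %d/%d, OR = %.3f, one-sided Fisher p = %.4g\n",
    x$motif, x$hits_new, x$n_new, x$hits_constant, x$n_constant,
    x$odds_ratio, x$p_one_sided))
  invisible(x)
}

as_dna_character <- function(x) {
  if (inherits(x, "XStringSet")) as.character(x) else as.character(x)
}

#' Read / write FASTA sequence sets
#'
#' Thin wrappers over Biostrings returning plain named character
#' vectors, the representation the scanner consumes.
#'
#' @param path FASTA path.
#' @param seqs Named character vector of sequences.
#' @return Named character vector (read); `path` (write).
#' @export
read_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
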