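#' Binned count track for one histone mark
#'
#' @param layout A [genome_layout()].
#' @param mark Mark identifier (e.g. `"H3K27ac"`).
#' @param counts Non-negative integer vector, one count per bin.
#' @return An object of class `count_track`.
#' @export
count_track <- function(layout, mark, counts) {
  stopifnot(inherits(layout, "genome_layout"))
  counts <- as.numeric(counts)
  if (length(counts) != n_bins(layout)) {
    stopf("counts has length %d but the layout has %d bins",
          length(counts), n_bins(layout))
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("counts must be non-negative integers")
  }
  structure(list(layout = layout, mark = as.character(mark), counts = counts),
            class = "count_track")
}

#' Per-bin binary mark calls
#'
#' @param layout A [genome_layout()].
#' @param mark Mark identifier.
#' @param calls 0/1 vector, one call per bin.
#' @return An object of class `binary_mark_track`.
#' @export
binary_mark_track <- function(layout, mark, calls) {
  stopifnot(inherits(layout, "genome_layout"))
  calls <- as.integer(calls)
  if (length(calls) != n_bins(layout)) {
    stopf("calls has length %d but the layout has %d bins",
          length(calls), n_bins(layout))
  }
  if (!all(calls %in% c(0L, 1L))) stopf("calls must be 0/1")
  structure(list(layout = layout, mark = as.character(mark), calls = calls),
            class = "binary_mark_track")
}

#' Binarize a count track against a Poisson background
#'
#' A bin is called present (1) when the Poisson upper-tail probability
#' \eqn{P(X \ge \mathrm{observed} \mid \lambda)} is at most `p_threshold`.
#' With an input-control track, \eqn{\lambda} is the control count scaled
#' so total control mass equals total signal mass (global depth
#' matching); without one, \eqn{\lambda} is the global mean signal count.
#' \eqn{\lambda} is floored at 1e-8 so empty control bins cannot produce
#' spurious certainty.
#'
#' @param signal A [count_track()].
#' @param control Optional [count_track()] on the same layout.
#' @param p_threshold Upper-tail probability cutoff in (0, 1)
#'   (default 1e-4, the dominant convention for 200-bp chromatin bins).
#' @return A [binary_mark_track()].
#' @export
poisson_binarize <- function(signal, control = NULL, p_threshold = 1e-4) {
  stopifnot(inherits(signal, "count_track"))
  if (p_threshold <= 0 || p_threshold >= 1) stopf("p_threshold must be in (0, 1)")
  total <- sum(signal$counts)
  if (total == 0) {
    warnf("signal track '%s' has zero total count; returning all-zero calls",
          signal$mark)
    return(binary_mark_track(signal$layout, signal$mark,
                             integer(n_bins(signal$layout))))
  }
  if (is.null(control)) {
    lambda <- rep(mean(signal$counts), length(signal$counts))
  } else {
    stopifnot(inherits(control, "count_track"))
    if (!identical(control$layout$chrom_names, signal$layout$chrom_names) ||
        !identical(unname(control$layout$chrom_lengths),
                   unname(signal$layout$chrom_lengths)) ||
        control$layout$bin_size != signal$layout$bin_size) {
      stopf("signal and control tracks are on different layouts")
    }
    ctot <- sum(control$counts)
    if (ctot == 0) stopf("control track has zero total count")
    lambda <- control$counts * (total / ctot)
  }
  lambda <- pmax(lambda, 1e-8)
  # P(X >= k | lambda); k = 0 gives 1, so zero-count bins are never called
  tail_p <- stats::ppois(signal$counts - 1, lambda, lower.tail = FALSE)
  binary_mark_track(signal$layout, signal$mark,
                    as.integer(tail_p <= p_threshold))
}

#' Stack binary mark tracks into a bins-by-marks observation matrix
#'
#' @param tracks List of [binary_mark_track()] objects sharing one layout,
#'   with unique mark names.
#' @return Integer matrix (bins x marks); columns in input order, named by
#'   mark; the shared layout is attached as attribute `"layout"`.
#' @export
stack_tracks <- function(tracks) {
  if (length(tracks) == 0L) stopf("no tracks to stack")
  for (t in tracks) stopifnot(inherits(t, "binary_mark_track"))
  marks <- vapply(tracks, function(t) t$mark, "")
  if (anyDuplicated(marks)) stopf("duplicate mark names: %s",
                                  paste(marks[duplicated(marks)], collapse = ", "))
  l0 <- tracks[[1L]]$layout
  for (t in tracks[-1L]) {
    if (!identical(t$layout$chrom_names, l0$chrom_names) ||
        t$layout$bin_size != l0$bin_size ||
        !identical(unname(t$layout$chrom_lengths), unname(l0$chrom_lengths))) {
      stopf("track '%s' is on a different layout", t$mark)
    }
  }
  obs <- vapply(tracks, function(t) t$calls, integer(n_bins(l0)))
  colnames(obs) <- marks
  attr(obs, "layout") <- l0
  obs
}

#' Unstack an observation matrix back into binary mark tracks
#' @param obs Matrix from [stack_tracks()] (layout attached or supplied).
#' @param layout Optional [genome_layout()] override.
#' @return List of [binary_mark_track()] objects.
#' @export
unstack_tracks <- function(obs, layout = NULL) {
  layout <- layout %||% attr(obs, "layout")
  if (is.null(layout)) stopf("no layout attached to the observation matrix")
  lapply(seq_len(ncol(obs)), function(m) {
    binary_mark_track(layout, colnames(obs)[m] %||% paste0("mark", m), obs[, m])
  })
}

#' Read / write binned tracks as bedGraph-like TSV
#'
#' Four tab-separated columns (chrom, start, end, value) with one row per
#' bin in layout order; the final bin of a chromosome is clamped at the
#' chromosome end.
#'
#' @param track A [count_track()] or [binary_mark_track()].
#' @param path File path.
#' @param layout A [genome_layout()] the file must conform to.
#' @param mark Mark name for the returned track.
#' @param binary Read as binary calls (`TRUE`) or counts (`FALSE`).
#' @return `path` (write); a track object (read).
#' @export
write_track_tsv <- function(track, path) {
  vals <- if (inherits(track, "count_track")) track$counts else track$calls
  coords <- layout_bin_coords(track$layout)
  utils::write.table(
    data.frame(coords$chrom,
               format(coords$start, scientific = FALSE, trim = TRUE),
               format(coords$end, scientific = FALSE, trim = TRUE),
               vals),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path, layout, mark, binary = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (nrow(df) != n_bins(layout)) {
    stopf("%s has %d rows but the layout has %d bins", path, nrow(df), n_bins(layout))
  }
  bins <- genome_bin_index(layout, df$chrom, df$start)
  if (anyNA(bins) || any(bins != seq_len(nrow(df)))) {
    stopf("%s: rows are not the layout's bins in order", path)
  }
  if (binary) binary_mark_track(layout, mark, df$value)
  else count_track(layout, mark, df$value)
}
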