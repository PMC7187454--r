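#' Genome-wide per-bin chromatin-state assignment
#'
#' A segmentation binds a vector of 1-based state indices (one per bin,
#' in layout order) to a [genome_layout()], plus the state labels of the
#' model that produced it.
#'
#' @param layout A [genome_layout()].
#' @param states Integer vector of state indices in `1..K`, length
#'   [n_bins()] of the layout.
#' @param state_labels Character labels, one per state.
#' @return An object of class `segmentation`.
#' @export
segmentation <- function(layout, states, state_labels = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  states <- as.integer(states)
  if (length(states) != n_bins(layout)) {
    stopf("states has length %d but the layout has %d bins",
          length(states), n_bins(layout))
  }
  if (any(is.na(states)) || any(states < 1L)) stopf("states must be positive integers")
  K <- max(states)
  labels <- state_labels %||% paste0("S", seq_len(K))
  if (length(labels) < K) stopf("fewer labels (%d) than states (%d)", length(labels), K)
  structure(list(layout = layout, states = states, state_labels = labels),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  tab <- table(factor(x$state_labels[x$states], levels = x$state_labels))
  cat(sprintf("segmentation: %d bins over %d chromosome(s)\n",
              length(x$states), length(x$layout$chrom_names)))
  print(tab)
  invisible(x)
}

#' Write a segmentation as dense BED4 (one line per state run)
#'
#' Maximal runs of one state are collapsed to labelled intervals; the
#' final interval of each chromosome is clamped at the chromosome end.
#' Reading the file back with [read_segmentation_bed()] and re-expanding
#' per bin reproduces the segmentation exactly.
#'
#' @param seg A [segmentation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  layout <- seg$layout
  per_chrom <- split_by_chrom(layout, seg$states)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(layout$chrom_names)) {
    ch <- layout$chrom_names[i]
    r <- rle(per_chrom[[i]])
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    start <- starts_bin * layout$bin_size
    end <- pmin(ends_bin * layout$bin_size, layout$chrom_lengths[ch])
    writeLines(paste(ch,
                     format(start, scientific = FALSE, trim = TRUE),
                     format(end, scientific = FALSE, trim = TRUE),
                     seg$state_labels[r$values], sep = "\t"), con)
  }
  invisible(path)
}

#' Read a dense segmentation BED back onto a layout
#'
#' @param path BED4 path written by [write_segmentation_bed()].
#' @param layout The [genome_layout()] the file is bound to.
#' @param state_labels Label-to-index mapping; defaults to the distinct
#'   labels in file order of first appearance.
#' @return A [segmentation()].
#' @export
read_segmentation_bed <- function(path, layout, state_labels = NULL) {
  set <- read_bed(path, expect_label = TRUE)
  labels <- state_labels %||% unique(set$label)
  idx <- match(set$label, labels)
  if (anyNA(idx)) stopf("%s: label %s not in state_labels",
                        path, set$label[which(is.na(idx))[1L]])
  states <- integer(n_bins(layout))
  for (i in seq_len(nrow(set))) {
    bins <- genome_bin_index(layout, rep(set$chrom[i], 2L),
                             c(set$start[i], set$end[i] - 1L))
    states[bins[1L]:bins[2L]] <- idx[i]
  }
  if (any(states == 0L)) stopf("%s does not cover every bin of the layout", path)
  segmentation(layout, states, state_labels = labels)
}

#' Merged intervals covered by one chromatin state
#'
#' @param seg A [segmentation()].
#' @param state A state label (either the full `"13_EnhS"` form or the
#'   bare `"EnhS"` suffix) or a 1-based state index.
#' @return A merged [interval_set()] covering exactly the bins assigned
#'   to that state (clamped at chromosome ends).
#' @export
state_intervals <- function(seg, state) {
  stopifnot(inherits(seg, "segmentation"))
  idx <- match_state_labels(seg$state_labels, state)
  coords <- layout_bin_coords(seg$layout)
  keep <- seg$states %in% idx
  if (!any(keep)) return(interval_set(merged = TRUE))
  merge_intervals(interval_set(coords$chrom[keep], coords$start[keep],
                               coords$end[keep]))
}

# resolve labels like "EnhS" or "13_EnhS" (or indices) to state indices
match_state_labels <- function(labels, states) {
  if (is.numeric(states)) {
    idx <- as.integer(states)
    if (any(idx < 1L | idx > length(labels))) stopf("state index out of range")
    return(idx)
  }
  suffix <- sub("^[0-9]+_", "", labels)
  idx <- lapply(states, function(s) {
    hit <- which(labels == s | suffix == s)
    if (length(hit) == 0L) stopf("unknown state label: %s", s)
    hit
  })
  sort(unique(unlist(idx)))
}
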