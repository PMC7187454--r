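#' Chromatin-state flow matrix between paired conditions
#'
#' Entry (i, j) counts the bins assigned state i in condition A and
#' state j in condition B — the matrix behind riverplot displays of
#' state dynamics. Row sums equal the condition-A state histogram,
#' column sums the condition-B histogram, and the grand total the bin
#' count.
#'
#' @param segA,segB [segmentation()] objects on the same layout.
#' @return An object of class `state_flow`: integer matrix `counts` with
#'   state labels on both dimensions.
#' @export
flow_matrix <- function(segA, segB) {
  stopifnot(inherits(segA, "segmentation"), inherits(segB, "segmentation"))
  if (!identical(segA$layout$chrom_names, segB$layout$chrom_names) ||
      !identical(unname(segA$layout$chrom_lengths),
                 unname(segB$layout$chrom_lengths)) ||
      segA$layout$bin_size != segB$layout$bin_size) {
    stopf("segmentations are on different layouts")
  }
  Ka <- length(segA$state_labels)
  Kb <- length(segB$state_labels)
  counts <- table(factor(segA$states, levels = seq_len(Ka)),
                  factor(segB$states, levels = seq_len(Kb)))
  counts <- matrix(as.integer(counts), Ka, Kb,
                   dimnames = list(from = segA$state_labels,
                                   to = segB$state_labels))
  structure(list(counts = counts,
                 states_from = segA$state_labels,
                 states_to = segB$state_labels),
            class = "state_flow")
}

#' @export
print.state_flow <- function(x, ...) {
  cat(sprintf("state_flow: %d bins, %d x %d states\n",
              sum(x$counts), nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Row-normalized flow matrix (conditional B-given-A frequencies)
#' @param flow A [flow_matrix()] result.
#' @return Numeric matrix with rows summing to 1 (all-zero rows left 0).
#' @export
flow_frequencies <- function(flow) {
  stopifnot(inherits(flow, "state_flow"))
  rs <- rowSums(flow$counts)
  out <- flow$counts / ifelse(rs > 0, rs, 1)
  out[rs == 0, ] <- 0
  out
}

#' Write a flow matrix as labelled TSV
#' @param flow A [flow_matrix()] result.
#' @param path Output path.
#' @export
write_flow_tsv <- function(flow, path) {
  utils::write.table(flow$counts, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Classify condition-B enhancers as new, constant or other gains
#'
#' A bin in a condition-B enhancer state is "new" when its condition-A
#' state was quiescent or Polycomb-repressed (chromatin activated de
#' novo during differentiation), "constant" when it was already an
#' enhancer state, and "other_gain" otherwise (e.g. promoter or weak
#' enhancer converting) — a residual class kept explicit so the first
#' two stay pure. Bins are classified individually, then collapsed to
#' merged intervals per class, so the three sets partition the
#' condition-B enhancer base pairs exactly.
#'
#' @param segA,segB [segmentation()] objects on one layout.
#' @param enhancer_states Labels counted as enhancer states (default
#'   `"EnhS"`; bare suffixes and full `"13_EnhS"` forms both match).
#' @param source_states_new Condition-A labels that define "new"
#'   (default quiescent and Polycomb-repressed).
#' @return An object of class `enhancer_classification` with merged
#'   [interval_set()]s `new_enhancers`, `constant_enhancers`,
#'   `other_gain`.
#' @export
classify_enhancers <- function(segA, segB,
                               enhancer_states = "EnhS",
                               source_states_new = c("Quies", "ReprPC")) {
  stopifnot(inherits(segA, "segmentation"), inherits(segB, "segmentation"))
  if (length(segA$states) != length(segB$states)) {
    stopf("segmentations are on different layouts")
  }
  enh_b <- match_state_labels(segB$state_labels, enhancer_states)
  enh_a <- match_state_labels(segA$state_labels, enhancer_states)
  new_a <- match_state_labels(segA$state_labels, source_states_new)
  if (length(intersect(enh_a, new_a))) {
    stopf("enhancer_states and source_states_new overlap")
  }
  in_enh_b <- segB$states %in% enh_b
  cls <- rep(NA_character_, length(segB$states))
  cls[in_enh_b & segA$states %in% new_a] <- "new"
  cls[in_enh_b & segA$states %in% enh_a] <- "constant"
  cls[in_enh_b & is.na(cls)] <- "other_gain"

  coords <- layout_bin_coords(segB$layout)
  bins_to_set <- function(keep) {
    if (!any(keep)) return(interval_set(merged = TRUE))
    merge_intervals(interval_set(coords$chrom[keep], coords$start[keep],
                                 coords$end[keep]))
  }
  structure(
    list(new_enhancers = bins_to_set(!is.na(cls) & cls == "new"),
         constant_enhancers = bins_to_set(!is.na(cls) & cls == "constant"),
         other_gain = bins_to_set(!is.na(cls) & cls == "other_gain"),
         bin_class = cls),
    class = "enhancer_classification"
  )
}

#' @export
print.enhancer_classification <- function(x, ...) {
  cat(sprintf(
    "enhancer_classification: new %.0f bp, constant %.0f bp, other gains %.0f bp\n",
    covered_bp(x$new_enhancers), covered_bp(x$constant_enhancers),
    covered_bp(x$other_gain)))
  invisible(x)
}
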