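#' Define the binned coordinate frame shared by all tracks and segmentations
#'
#' A genome layout fixes the ordered chromosomes, their lengths and the bin
#' size. Every count track, binary mark track and segmentation in the
#' package is indexed against one layout, so bin arithmetic is done once,
#' here. The final bin of a chromosome may be shorter than `bin_size`; on
#' disk its interval is clamped at the chromosome end.
#'
#' @param chrom_names Character vector of unique chromosome names, in order.
#' @param chrom_lengths Integer vector of chromosome lengths in bp, parallel
#'   to `chrom_names`.
#' @param bin_size Bin width in bp (default 200, the convention of
#'   chromatin-state segmentation at histone-mark resolution).
#' @return An object of class `genome_layout`.
#' @examples
#' layout <- genome_layout(c("chr1", "chr2"), c(1e6, 5e5), bin_size = 200)
#' n_bins(layout)
#' @export
genome_layout <- function(chrom_names, chrom_lengths, bin_size = 200L) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  bin_size <- as.integer(bin_size)
  if (anyDuplicated(chrom_names)) stopf("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths)) {
    stopf("chrom_names and chrom_lengths differ in length")
  }
  if (length(chrom_names) == 0L) stopf("layout needs at least one chromosome")
  if (any(chrom_lengths <= 0)) stopf("chromosome lengths must be positive")
  if (is.na(bin_size) || bin_size <= 0L) stopf("bin_size must be a positive integer")
  nb <- as.integer(ceiling(chrom_lengths / bin_size))
  structure(
    list(
      chrom_names = chrom_names,
      chrom_lengths = stats::setNames(chrom_lengths, chrom_names),
      bin_size = bin_size,
      n_bins_per_chrom = stats::setNames(nb, chrom_names),
      bin_offsets = stats::setNames(c(0L, cumsum(nb)[-length(nb)]), chrom_names)
    ),
    class = "genome_layout"
  )
}

#' Total number of bins in a layout
#' @param layout A [genome_layout()].
#' @return Integer bin count summed over chromosomes.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$n_bins_per_chrom)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "genome_layout: %d chromosome(s), %.0f bp total, bin %d bp, %d bins\n",
    length(x$chrom_names), sum(x$chrom_lengths), x$bin_size, n_bins(x)
  ))
  invisible(x)
}

# bin index (1-based, genome-wide) for 0-based positions on a chromosome;
# NA when the chromosome is absent or the position is off the end.
genome_bin_index <- function(layout, chrom, pos0) {
  idx <- match(chrom, layout$chrom_names)
  ok <- !is.na(idx) & pos0 >= 0 & pos0 < layout$chrom_lengths[ifelse(is.na(idx), 1L, idx)]
  out <- rep(NA_integer_, length(chrom))
  if (any(ok)) {
    local_bin <- pos0[ok] %/% layout$bin_size
    out[ok] <- as.integer(layout$bin_offsets[idx[ok]] + local_bin + 1L)
  }
  out
}

# data.frame of per-bin genomic coordinates (0-based half-open, clamped)
layout_bin_coords <- function(layout) {
  chrom <- rep(layout$chrom_names, layout$n_bins_per_chrom)
  local <- unlist(lapply(layout$n_bins_per_chrom, function(n) seq_len(n) - 1L),
                  use.names = FALSE)
  start <- local * layout$bin_size
  end <- pmin(start + layout$bin_size, layout$chrom_lengths[chrom])
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE, row.names = NULL)
}

# split a genome-wide per-bin vector (or matrix rows) by chromosome
split_by_chrom <- function(layout, x) {
  f <- rep(seq_along(layout$chrom_names), layout$n_bins_per_chrom)
  if (is.matrix(x)) {
    lapply(seq_along(layout$chrom_names), function(i) x[f == i, , drop = FALSE])
  } else {
    split(x, f)
  }
}
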