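#' Genomic interval sets with exact base-pair algebra
#'
#' An `interval_set` is a sorted table of 0-based half-open genomic
#' intervals (`chrom`, `start`, `end`, optional `label`). It is the common
#' currency for enhancer coordinates, chromatin-state blocks and overlap
#' statistics. Interval arithmetic (merge, intersect, coverage) is exact at
#' base-pair resolution and is delegated internally to IRanges.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors of 0-based half-open coordinates
#'   (`0 <= start < end`).
#' @param label Optional character vector of per-interval labels.
#' @param merged Logical; set by [merge_intervals()] when no two intervals
#'   on one chromosome overlap or abut.
#' @return An `interval_set`: a data.frame sorted by (chrom, start) with a
#'   `merged` attribute.
#' @examples
#' s <- interval_set(c("chr1", "chr1"), c(0, 50), c(100, 150))
#' covered_bp(merge_intervals(s))
#' @export
interval_set <- function(chrom = character(), start = numeric(),
                         end = numeric(), label = NULL, merged = FALSE) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && length(start) > 1L) {
    chrom <- rep(chrom, length(start))
  }
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stopf("chrom, start, end must have equal length")
  }
  if (any(start < 0)) stopf("interval start must be >= 0")
  if (any(start >= end)) stopf("interval start must be < end")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.character(label)
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, merged = isTRUE(merged),
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d interval(s), %.0f bp covered%s\n",
              nrow(x), covered_bp(x),
              if (isTRUE(attr(x, "merged"))) " (merged)" else ""))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

is_empty_set <- function(set) nrow(set) == 0L

# per-chromosome IRanges view (1-based closed, as IRanges represents them)
as_iranges_by_chrom <- function(set) {
  if (nrow(set) == 0L) return(list())
  sp <- split(seq_len(nrow(set)), set$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = set$start[i] + 1L,
                                          end = set$end[i]))
}

from_iranges <- function(ir_by_chrom) {
  if (length(ir_by_chrom) == 0L) return(interval_set(merged = TRUE))
  chrom <- rep(names(ir_by_chrom), vapply(ir_by_chrom, length, 1L))
  start <- unlist(lapply(ir_by_chrom, IRanges::start), use.names = FALSE) - 1
  end <- unlist(lapply(ir_by_chrom, IRanges::end), use.names = FALSE)
  if (length(chrom) == 0L) return(interval_set(merged = TRUE))
  interval_set(chrom, start, end, merged = TRUE)
}

#' Coalesce overlapping or abutting intervals
#'
#' Abutting intervals (`end == next start`) are merged: the semantics are
#' base-pair coverage, so adjacency is continuity.
#'
#' @param set An [interval_set()].
#' @return A merged `interval_set` covering exactly the same base pairs.
#' @export
merge_intervals <- function(set) {
  stopifnot(inherits(set, "interval_set"))
  from_iranges(lapply(as_iranges_by_chrom(set), IRanges::reduce))
}

#' Exact base-pair intersection of two interval sets
#'
#' @param a,b [interval_set()] objects.
#' @return A merged `interval_set` of the shared base pairs.
#' @export
intersect_intervals <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  ia <- as_iranges_by_chrom(a)
  ib <- as_iranges_by_chrom(b)
  shared <- intersect(names(ia), names(ib))
  out <- lapply(shared, function(ch) IRanges::intersect(ia[[ch]], ib[[ch]]))
  names(out) <- shared
  out <- out[vapply(out, length, 1L) > 0L]
  from_iranges(out)
}

#' Base-pair union of two interval sets
#' @param a,b [interval_set()] objects.
#' @return A merged `interval_set` covering base pairs in either input.
#' @export
union_intervals <- function(a, b) {
  stopifnot(inherits(a, "interval_set"), inherits(b, "interval_set"))
  merge_intervals(interval_set(
    c(a$chrom, b$chrom), c(a$start, b$start), c(a$end, b$end)
  ))
}

#' Total covered base pairs of an interval set
#' @param set An [interval_set()].
#' @return Numeric bp count (overlaps counted once).
#' @export
covered_bp <- function(set) {
  stopifnot(inherits(set, "interval_set"))
  if (nrow(set) == 0L) return(0)
  sum(vapply(as_iranges_by_chrom(set),
             function(ir) sum(IRanges::width(IRanges::reduce(ir))), 0))
}

#' Jaccard similarity of two interval sets at base-pair resolution
#'
#' \eqn{J(A,B) = |A \cap B| / |A \cup B|} in covered base pairs — the
#' similarity measure used to compare one chromatin state across
#' epigenomes. When both sets are empty the union is empty and the index
#' is defined as 0 (keeps downstream clustering finite).
#'
#' @param a,b [interval_set()] objects (merged or not; coverage arithmetic
#'   merges internally).
#' @return A ratio in \[0, 1\].
#' @examples
#' a <- interval_set("chr1", 0, 100)
#' b <- interval_set("chr1", 50, 150)
#' jaccard_index(a, b) # 50 / 150
#' @export
jaccard_index <- function(a, b) {
  inter <- covered_bp(intersect_intervals(a, b))
  uni <- covered_bp(a) + covered_bp(b) - inter
  if (uni == 0) return(0)
  inter / uni
}

#' Read a BED3/BED4 file into an interval set
#'
#' Accepts 0-based half-open BED with 3 or 4 columns separated by tabs or
#' spaces. Lines starting with `track`, `browser` or `#` are skipped with a
#' warning. Malformed lines (wrong column count, non-integer coordinates,
#' `start >= end`) raise an error naming the offending line.
#'
#' @param path Path to a BED file.
#' @param expect_label If `TRUE`, require a 4th (name) column.
#' @return An [interval_set()]; labels preserved when present.
#' @export
read_bed <- function(path, expect_label = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (any(grepl("^(track|browser|#)", lines))) {
    warnf("%s: skipped %d track/browser/comment line(s)",
          path, sum(grepl("^(track|browser|#)", lines)))
  }
  lines_kept <- lines[keep]
  lineno <- which(keep)
  if (length(lines_kept) == 0L) return(interval_set())
  fields <- strsplit(lines_kept, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad)) {
    stopf("%s line %d: expected 3 or 4 columns, found %d",
          path, lineno[bad[1L]], nf[bad[1L]])
  }
  if (expect_label && any(nf < 4L)) {
    stopf("%s line %d: label column required but absent",
          path, lineno[which(nf < 4L)[1L]])
  }
  chrom <- vapply(fields, `[`, "", 1L)
  s_chr <- vapply(fields, `[`, "", 2L)
  e_chr <- vapply(fields, `[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_chr))
  end <- suppressWarnings(as.numeric(e_chr))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end) | start < 0)
  if (length(bad)) {
    stopf("%s line %d: non-integer or negative coordinates",
          path, lineno[bad[1L]])
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stopf("%s line %d: start >= end (%s >= %s)",
          path, lineno[bad[1L]], s_chr[bad[1L]], e_chr[bad[1L]])
  }
  label <- if (any(nf == 4L)) {
    vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_, "")
  } else NULL
  interval_set(chrom, start, end, label = label)
}

#' Write an interval set as BED3/BED4
#' @param set An [interval_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path) {
  stopifnot(inherits(set, "interval_set"))
  df <- data.frame(set$chrom,
                   format(set$start, scientific = FALSE, trim = TRUE),
                   format(set$end, scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  if (!is.null(set$label)) df[[4L]] <- set$label
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
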