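#' Pairwise Jaccard similarity of one chromatin state across epigenomes
#'
#' Computes the base-pair Jaccard index between every pair of interval
#' sets (typically [state_intervals()] of the same state in many
#' samples). Samples with empty sets get similarity 0 to everything,
#' including themselves, with a warning — an empty state map carries no
#' evidence of similarity.
#'
#' @param interval_sets Named list of [interval_set()] objects
#'   (>= 2 samples, unique names).
#' @return Symmetric numeric matrix with unit diagonal for non-empty
#'   samples.
#' @export
pairwise_similarity <- function(interval_sets) {
  n <- length(interval_sets)
  if (n < 2L) stopf("need at least 2 samples")
  nms <- names(interval_sets)
  if (is.null(nms) || any(!nzchar(nms))) stopf("samples must be named")
  if (anyDuplicated(nms)) stopf("duplicate sample names: %s",
                                paste(nms[duplicated(nms)], collapse = ", "))
  empty <- vapply(interval_sets, is_empty_set, TRUE)
  if (any(empty)) {
    warnf("sample(s) with empty interval sets get similarity 0: %s",
          paste(nms[empty], collapse = ", "))
  }
  merged <- lapply(interval_sets, merge_intervals)
  sim <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n)) {
    if (!empty[i]) sim[i, i] <- 1
    if (i < n) {
      for (j in seq((i + 1L), n)) {
        v <- if (empty[i] || empty[j]) 0 else jaccard_index(merged[[i]], merged[[j]])
        sim[i, j] <- v
        sim[j, i] <- v
      }
    }
  }
  sim
}

#' Hierarchically cluster samples from a similarity matrix
#'
#' Similarities are converted to distances and clustered
#' agglomeratively. The default conversion is the Euclidean distance
#' between rows of the similarity matrix (each sample's profile of
#' similarities to all samples); `metric = "one_minus_j"` uses
#' \eqn{d = 1 - J} directly instead.
#'
#' @param sim Symmetric similarity matrix from [pairwise_similarity()].
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"average"`).
#' @param metric `"profile"` (Euclidean distance between similarity
#'   rows) or `"one_minus_j"`.
#' @return List of class `epigenome_clustering`: `hclust` (the tree),
#'   `leaf_order` (labels left to right), `newick` (Newick string),
#'   `distance` (the dist object).
#' @export
cluster_samples <- function(sim, linkage = "average",
                            metric = c("profile", "one_minus_j")) {
  metric <- match.arg(metric)
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) stopf("sim must be square")
  if (nrow(sim) < 2L) stopf("need at least 2 samples")
  if (any(is.na(sim)) || any(!is.finite(sim))) stopf("NaN/NA in similarity matrix")
  d <- switch(metric,
              profile = stats::dist(sim),
              one_minus_j = stats::as.dist(1 - sim))
  hc <- stats::hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(
    list(hclust = hc,
         leaf_order = hc$labels[hc$order],
         newick = ape::write.tree(phy),
         distance = d, metric = metric, linkage = linkage),
    class = "epigenome_clustering"
  )
}

#' @export
print.epigenome_clustering <- function(x, ...) {
  cat(sprintf("epigenome_clustering: %d samples, %s linkage, %s metric\n",
              length(x$leaf_order), x$linkage, x$metric))
  cat("leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' Cut the tree into k groups
#' @param clustering An [cluster_samples()] result.
#' @param k Number of groups.
#' @return Named integer group memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stopifnot(inherits(clustering, "epigenome_clustering"))
  stats::cutree(clustering$hclust, k = k)
}

#' Write a similarity matrix as labelled TSV
#' @param sim Matrix from [pairwise_similarity()].
#' @param path Output path.
#' @export
write_similarity_tsv <- function(sim, path) {
  utils::write.table(sim, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
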