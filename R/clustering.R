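# Agglomerative hierarchical clustering of clip features and assignment of
# the semantic labels snoring / normal / uncertain to the three clusters.

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Builds the dendrogram by successively merging the two clusters at
#' minimum linkage distance (average linkage by default).
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal.
#' @param linkage one of `"average"`, `"single"`, `"complete"`, `"ward"`
#'   (`"ward"` maps to `ward.D2`, i.e. squared-Euclidean updating).
#' @return An `hclust` object: `merge` holds the n-1 merges, `height` the
#'   linkage distances.
#' @export
ahc_linkage <- function(d, linkage = "average") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(d < 0) || any(diag(d) != 0))
    stop("distance matrix must be nonnegative with zero diagonal")
  method <- switch(linkage,
                   average = "average", single = "single",
                   complete = "complete", ward = "ward.D2",
                   stop("unknown linkage: ", linkage))
  stats::hclust(stats::as.dist(d), method = method)
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an `hclust` object from [ahc_linkage()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer cluster ids in `1..k`, one per leaf; all clusters
#'   non-empty.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  as.integer(stats::cutree(tree, k = k))
}

#' Assign semantic labels to three clusters by loudness ordering
#'
#' The pipeline's three clip classes have a stable energy ordering: snoring
#' clips are loudest, near-silent clips are unusable ("uncertain"), normal
#' breathing sits between. The cluster with the lowest mean clip RMS becomes
#' `uncertain`; of the remaining two the louder becomes `snoring`, the other
#' `normal`. Ties break by cluster id (lowest id -> snoring, highest ->
#' uncertain).
#'
#' @param ids integer cluster ids in `1..3`, one per clip.
#' @param clips the corresponding list of `clip` objects.
#' @return list with `labels` (per-clip character vector in
#'   `c("snoring","normal","uncertain")`), `semantic` (named map cluster id
#'   -> label) and `cluster_rms` (mean clip RMS per cluster).
#' @export
assign_semantics <- function(ids, clips) {
  k <- length(unique(ids))
  if (k != 3L) stop("semantic assignment requires exactly 3 clusters, got ", k)
  if (length(ids) != length(clips)) stop("ids and clips length mismatch")
  rms <- vapply(clips, clip_rms, numeric(1))
  cl <- sort(unique(ids))
  mean_rms <- vapply(cl, function(c) mean(rms[ids == c]), numeric(1))
  # uncertain: min RMS, tie -> largest cluster id
  unc <- cl[order(mean_rms, -cl)][1]
  rest <- setdiff(cl, unc)
  # snoring: larger RMS of the rest, tie -> smallest cluster id
  sno <- rest[order(-mean_rms[match(rest, cl)], rest)][1]
  nor <- setdiff(rest, sno)
  semantic <- character(3)
  names(semantic) <- as.character(cl)
  semantic[as.character(c(sno, nor, unc))] <- c("snoring", "normal", "uncertain")
  list(labels = unname(semantic[as.character(ids)]),
       semantic = semantic,
       cluster_rms = stats::setNames(mean_rms, cl))
}
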