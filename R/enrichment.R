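#' Hypergeometric upper-tail probability for gene-set overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, m)`: the probability of drawing
#' at least `k` category members when sampling a cluster of `m` genes from a
#' universe of `N` genes of which `K` belong to the category. One-sided
#' over-representation only; computed through the stable log-space tail of
#' the hypergeometric distribution.
#'
#' @param k Observed overlap count(s).
#' @param m Cluster size.
#' @param K Category size on the array.
#' @param N Universe size (annotated genes on the array).
#' @return Upper-tail p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_upper_tail(3, 5, 4, 10)  # 66/252
hypergeom_upper_tail <- function(k, m, K, N) {
  if (any(m > N | K > N)) stop("cluster and category cannot exceed the universe")
  if (any(k > pmin(m, K) | k < 0)) stop("impossible overlap count")
  phyper(k - 1, K, N - K, m, lower.tail = FALSE)
}

#' Fold enrichment of a category in a cluster
#'
#' The cluster's category rate over the array-background rate:
#' `(k/m) / (K/N)`.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Fold enrichment(s).
#' @export
#' @examples
#' fold_enrichment(4, 44, 47, 19040)  # 36.83
fold_enrichment <- function(k, m, K, N) {
  if (any(m <= 0) || any(K <= 0) || any(N <= 0)) {
    stop("cluster, category and universe sizes must be positive")
  }
  (k / m) / (K / N)
}

#' Over-represented categories in one gene cluster
#'
#' Tests every annotation category for over-representation in the cluster
#' with the hypergeometric upper tail, adjusts across all tested categories
#' with Benjamini-Hochberg, and reports the categories present in the
#' cluster (`k >= 1`) that pass the fold-enrichment and adjusted-p filters.
#' Clusters smaller than `min_cluster_size` are skipped (the screen
#' considers only clusters with more than 40 transcripts by default).
#' Cluster genes outside the annotation universe are dropped with a message.
#'
#' @param cluster Character vector of cluster gene ids.
#' @param ann An [annotation_set()].
#' @param min_cluster_size Minimum cluster size to test.
#' @param fold_min Minimum fold enrichment to report.
#' @param adjp_max Maximum BH-adjusted p-value to report.
#' @return Data frame with columns `category`, `description`, `k`, `m`, `K`,
#'   `N`, `fold`, `p`, `adj_p`, ordered by decreasing fold; zero rows if the
#'   cluster is skipped or nothing passes.
#' @export
enrich_cluster <- function(cluster, ann, min_cluster_size = 41,
                           fold_min = 2, adjp_max = 0.05) {
  stopifnot(inherits(ann, "annotation_set"))
  N <- length(ann$universe)
  if (!N) stop("annotation universe is empty")
  outside <- setdiff(cluster, ann$universe)
  if (length(outside)) {
    message(length(outside), " cluster gene(s) outside the annotation universe dropped")
    cluster <- intersect(cluster, ann$universe)
  }
  m <- length(cluster)
  empty <- data.frame(category = character(), description = character(),
                      k = integer(), m = integer(), K = integer(), N = integer(),
                      fold = numeric(), p = numeric(), adj_p = numeric(),
                      stringsAsFactors = FALSE)
  if (m < min_cluster_size) {
    message("cluster of ", m, " genes below the minimum size ",
            min_cluster_size, "; skipped")
    return(empty)
  }
  K <- vapply(ann$sets, length, integer(1))
  k <- vapply(ann$sets, function(s) length(intersect(s, cluster)), integer(1))
  p <- hypergeom_upper_tail(k, m, K, N)
  adj <- benjamini_hochberg(p)
  rows <- data.frame(
    category = names(ann$sets),
    description = unname(ann$description[names(ann$sets)]),
    k = unname(k), m = m, K = unname(K), N = N,
    fold = unname(fold_enrichment(k, m, K, N)),
    p = unname(p), adj_p = unname(adj),
    stringsAsFactors = FALSE
  )
  rows <- rows[rows$k >= 1 & rows$fold >= fold_min & rows$adj_p <= adjp_max, ,
               drop = FALSE]
  rows <- rows[order(-rows$fold, rows$adj_p, rows$category), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Enrichment screen over all profile clusters
#'
#' Runs [enrich_cluster()] on every pattern class of a profile assignment
#' and stacks the results with a `cluster` column (the class id).
#'
#' @param assignments Profile assignments from [assign_profiles()].
#' @param ann An [annotation_set()].
#' @inheritParams enrich_cluster
#' @return Data frame of enrichment rows across clusters.
#' @export
enrich_profiles <- function(assignments, ann, min_cluster_size = 41,
                            fold_min = 2, adjp_max = 0.05) {
  out <- list()
  for (id in sort(unique(assignments$class_id))) {
    genes <- assignments$gene[assignments$class_id == id]
    rows <- suppressMessages(
      enrich_cluster(genes, ann, min_cluster_size, fold_min, adjp_max)
    )
    if (nrow(rows)) {
      out[[length(out) + 1L]] <- cbind(cluster = id, rows)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster = integer(), category = character(),
                      description = character(), k = integer(), m = integer(),
                      K = integer(), N = integer(), fold = numeric(),
                      p = numeric(), adj_p = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
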