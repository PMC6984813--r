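# Unsupervised cell typing: z-scoring of the 15-property table, Ward
# agglomerative clustering (merge cost = increase in within-cluster error
# sum of squares, computed by the exact Lance-Williams recurrence), and the
# Thorndike criterion choosing the cluster count at the largest jump in
# merge height across agglomeration stages.

#' Z-score the columns of a feature table
#'
#' Each column is centred to mean 0 and scaled to sample standard deviation
#' 1, so properties with large absolute values (e.g. membrane resistance in
#' MOhm) do not dominate properties with small ones (e.g. halfwidth in ms).
#'
#' @param table data frame or matrix of numeric features.
#' @return matrix of z-scores with the input's dimnames.
#' @export
zscore_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) stop("feature table must be numeric")
  if (anyNA(m)) stop("feature table submitted to clustering must not contain missing values")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0] %||% which(sds == 0)
    stop("constant column(s) cannot be z-scored: ", paste(bad, collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Ward hierarchical clustering with exact ESS merge costs
#'
#' Agglomerates the rows of a z-scored table, at each stage merging the pair
#' of clusters whose union minimally increases the within-cluster error sum
#' of squares (ESS). Merge heights are the ESS increments themselves, so
#' they can be checked against brute-force enumeration, and they are
#' non-decreasing (Ward is monotone). The result is also a valid `hclust`
#' object, so `stats::cutree()` and `plot()` work on it.
#'
#' @param ztable numeric matrix (rows = neurons), typically from
#'   [zscore_table()].
#' @return an object of classes `phys_ward` and `hclust` with `merge`,
#'   `height` (ESS increments), `order`, `labels`.
#' @export
ward_cluster <- function(ztable) {
  x <- as.matrix(ztable)
  if (anyNA(x)) stop("missing values in the clustering table")
  n <- nrow(x)
  if (n < 2L) stop("need at least two rows to cluster")
  # D[i,j] = ESS increase of merging clusters i and j; singleton pairs:
  # ||xi - xj||^2 / 2
  D <- as.matrix(stats::dist(x))^2 / 2
  diag(D) <- Inf
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -(1:n)                       # hclust convention: negatives = singletons
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    k <- arrayInd(which.min(sub), dim(sub))
    i <- idx[min(k[1], k[2])]; j <- idx[max(k[1], k[2])]
    height[s] <- D[i, j]
    merge[s, ] <- sort(c(id[i], id[j]))
    # Lance-Williams update of ESS increments for the union, stored at i
    ni <- size[i]; nj <- size[j]
    for (k2 in idx) {
      if (k2 == i || k2 == j) next
      nk <- size[k2]
      D[i, k2] <- D[k2, i] <-
        ((ni + nk) * D[k2, i] + (nj + nk) * D[k2, j] - nk * D[i, j]) / (ni + nj + nk)
    }
    size[i] <- ni + nj
    active[j] <- FALSE
    id[i] <- s
  }
  ord <- .dendrogram_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = rownames(x), method = "ward.ess",
                 call = match.call(), dist.method = "squared euclidean / 2"),
            class = c("phys_ward", "hclust"))
}

# leaf ordering by recursive traversal of the merge matrix
.dendrogram_order <- function(merge, n) {
  rec <- function(k) {
    if (k < 0L) return(-k)
    c(rec(merge[k, 1L]), rec(merge[k, 2L]))
  }
  rec(n - 1L)
}

#' Thorndike cluster-count criterion
#'
#' Scans the merge heights of the agglomeration and places the cut at the
#' stage with the largest jump in merge height relative to the preceding
#' stage: a large distance between group centroids at one stage relative to
#' the others indicates genuinely distinct groups. If the largest jump is at
#' stage \eqn{s} of \eqn{n-1}, the chosen number of clusters is
#' \eqn{k = n - s + 1}.
#'
#' @param result a `phys_ward` (or any `hclust`) object.
#' @return list: `chosen_k`, `labels` (cluster assignment 1..k, ordered by
#'   cluster size, largest first), `gap_profile` (height increments per
#'   stage).
#' @export
thorndike_cut <- function(result) {
  h <- result$height
  n <- length(h) + 1L
  if (n < 3L) stop("Thorndike cut needs at least 3 observations")
  gaps <- diff(c(0, h))
  s <- which.max(gaps)
  k <- n - s + 1L
  lab <- stats::cutree(result, k = k)
  # relabel so cluster 1 is the largest (ties: first encountered)
  sizes <- sort(table(lab), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(relab[as.character(lab)])
  names(labels) <- names(lab)
  list(chosen_k = k, labels = labels, gap_profile = gaps)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 for identical
#' partitions (up to label permutation), ~0 for independent ones.
#'
#' @param a,b integer/factor vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == maxi, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}
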