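# Random forest classifier built on the in-package CART grower: per tree, a
# bootstrap sample of neurons (with replacement) and a random subset of
# floor(sqrt(p)) features at every split; trees are grown to purity.
# Reports the out-of-bag error (majority of OOB votes), per-feature mean
# decrease in Gini impurity, and the proximity matrix (fraction of trees in
# which two neurons share a terminal node), plus its 2-D principal-component
# embedding.

#' Fit a random forest
#'
#' @param table feature data frame/matrix.
#' @param labels class labels.
#' @param n_trees number of trees (study default 10000).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed RNG seed.
#' @param proximity accumulate the proximity matrix (O(n^2) per tree).
#' @param nodesize minimal node size to split (default 1: grow to purity).
#' @return object of class `phys_forest`: `oob_error` (fraction),
#'   `oob_votes`, `gini_importance` (named, mean decrease per tree),
#'   `proximity`, `classes`, `n_trees`, `trees`.
#' @export
fit_forest <- function(table, labels, n_trees = 10000L, mtry = NULL, seed = NULL,
                       proximity = TRUE, nodesize = 1L) {
  X <- as.matrix(table)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  yi <- as.integer(y); K <- nlevels(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  with_seed(seed, {
    votes <- matrix(0L, n, K)
    imp <- numeric(p)
    prox <- if (proximity) matrix(0, n, n) else NULL
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      boot <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(boot))
      tr <- .grow_tree(X[boot, , drop = FALSE], yi[boot], K,
                       minsplit = max(2L, nodesize + 1L), mtry = mtry)
      trees[[b]] <- tr
      split_nodes <- which(!is.na(tr$var))
      if (length(split_nodes)) {
        for (j in split_nodes) imp[tr$var[j]] <- imp[tr$var[j]] + tr$gdec[j]
      }
      if (length(oob)) {
        pred <- .tree_predict_code(tr, X[oob, , drop = FALSE])
        votes[cbind(oob, pred)] <- votes[cbind(oob, pred)] + 1L
      }
      if (proximity) {
        leaf <- .tree_node_of(tr, X)
        prox <- prox + outer(leaf, leaf, `==`)
      }
    }
    voted <- rowSums(votes) > 0L
    oob_pred <- max.col(votes, ties.method = "first")
    oob_error <- mean(oob_pred[voted] != yi[voted])
    if (proximity) prox <- prox / n_trees
    structure(list(oob_error = oob_error, oob_votes = votes,
                   gini_importance = stats::setNames(imp / n_trees, colnames(X)),
                   proximity = prox, classes = levels(y), n_trees = n_trees,
                   mtry = mtry, feature_names = colnames(X), trees = trees,
                   y = y),
              class = "phys_forest")
  })
}

#' @export
predict.phys_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  K <- length(object$classes)
  votes <- matrix(0L, nrow(X), K)
  for (tr in object$trees) {
    pred <- .tree_predict_code(tr, X)
    votes[cbind(seq_len(nrow(X)), pred)] <- votes[cbind(seq_len(nrow(X)), pred)] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")], levels = object$classes)
}

#' @export
print.phys_forest <- function(x, ...) {
  cat(sprintf("<phys_forest> %d trees, mtry %d, OOB error %.2f%%\n",
              x$n_trees, x$mtry, 100 * x$oob_error))
  invisible(x)
}

#' 2-D principal-component embedding of the forest proximity matrix
#'
#' @param forest a `phys_forest` with a proximity matrix, or the matrix
#'   itself.
#' @return data frame `pc1`, `pc2` (one row per sample) with attribute
#'   `sdev`.
#' @export
proximity_pca <- function(forest) {
  prox <- if (inherits(forest, "phys_forest")) forest$proximity else as.matrix(forest)
  if (is.null(prox)) stop("forest was fitted without a proximity matrix")
  if (stats::sd(prox) == 0) stop("degenerate proximity matrix (all entries equal)")
  pc <- stats::prcomp(prox, center = TRUE, scale. = FALSE)
  out <- data.frame(pc1 = pc$x[, 1L], pc2 = pc$x[, 2L])
  attr(out, "sdev") <- pc$sdev
  out
}

#' Bootstrap validation of the tree or forest classifier
#'
#' Tree: `n_draws` (study default 500) stratified 80/20 train/test splits
#' without replacement; on each draw a tree is fitted (with internal CV
#' pruning) on the training 80% and scored on the held-out 20%. Forest:
#' `n_draws` (study default 20) runs where the training set is a bootstrap
#' (with replacement) of the 80% split and the model is scored on the
#' held-out 20%.
#'
#' @param model_kind `"tree"` or `"forest"`.
#' @param table,labels data.
#' @param n_draws number of draws (defaults 500 / 20 by kind).
#' @param seed RNG seed; the same seed reproduces the same accuracy.
#' @param n_trees forest size per draw (default 500; the OOB/importance run
#'   is where the full 10000 are used).
#' @param cv_folds tree internal CV folds.
#' @return mean test-set accuracy in percent, with attribute `per_draw`.
#' @export
bootstrap_validate <- function(model_kind = c("tree", "forest"), table, labels,
                               n_draws = NULL, seed = NULL, n_trees = 500L,
                               cv_folds = 10L, minsplit = 5L) {
  model_kind <- match.arg(model_kind)
  if (is.null(n_draws)) n_draws <- if (model_kind == "tree") 500L else 20L
  X <- as.matrix(table)
  y <- factor(labels)
  n <- nrow(X)
  with_seed(seed, {
    acc <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      # stratified 80/20 split without replacement
      test <- unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix, max(1L, round(0.2 * length(ix))))))
      train <- setdiff(seq_len(n), test)
      if (length(unique(y[train])) < 2L) { acc[d] <- NA_real_; next }
      if (model_kind == "tree") {
        fit <- fit_tree(X[train, , drop = FALSE], y[train], minsplit = minsplit,
                        cv_folds = cv_folds)
        pred <- predict(fit, X[test, , drop = FALSE])
      } else {
        boot <- sample(train, length(train), replace = TRUE)
        for (try in 1:10) {           # tiny cohorts: redraw single-class boots
          if (length(unique(y[boot])) >= 2L) break
          boot <- sample(train, length(train), replace = TRUE)
        }
        if (length(unique(y[boot])) < 2L) { acc[d] <- NA_real_; next }
        fit <- fit_forest(X[boot, , drop = FALSE], y[boot], n_trees = n_trees,
                          proximity = FALSE)
        pred <- predict(fit, X[test, , drop = FALSE])
      }
      acc[d] <- mean(as.character(pred) == as.character(y[test]))
    }
    out <- 100 * mean(acc, na.rm = TRUE)
    attr(out, "per_draw") <- 100 * acc
    out
  })
}

#' Concordance between cluster labels and synaptic-response status
#'
#' Cross-tabulates the cluster assignment against uEPSC response status and
#' reports the percentage of responders falling in the designated
#' (fast-spiking) cluster.
#'
#' @param labels cluster labels.
#' @param response_status logical (TRUE = uEPSC present) or factor.
#' @param positive_cluster the cluster counted as concordant (default `1`,
#'   the largest / fast-spiking cluster from [thorndike_cut()]).
#' @return list: `table` (contingency), `percent_concordant`.
#' @export
responder_concordance <- function(labels, response_status, positive_cluster = 1L) {
  if (length(labels) != length(response_status))
    stop("labels and response_status must cover the same neurons")
  resp <- if (is.logical(response_status)) response_status
          else response_status %in% c("uEPSC present", "present", "responder", "TRUE", "1")
  tab <- table(cluster = labels, responder = resp)
  n_resp <- sum(resp)
  if (n_resp == 0L) stop("no responders")
  pc <- 100 * sum(labels == positive_cluster & resp) / n_resp
  list(table = tab, percent_concordant = pc)
}
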