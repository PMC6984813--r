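# Classification trees (CART): recursive binary partitioning on the Gini
# criterion, minimal cost-complexity (weakest-link) pruning, and k-fold
# cross-validated selection of the complexity parameter. The same node
# grower, with per-split random feature subsampling, backs the random
# forest. Implemented in-package: no recursive-partitioning library is part
# of this toolchain.

# grow one tree; X numeric matrix, y integer codes 1..K
# returns parallel node vectors; children always have larger ids than parents
.grow_tree <- function(X, y, K, minsplit = 5L, mtry = ncol(X), maxdepth = 30L) {
  p <- ncol(X)
  var <- integer(0); cut <- numeric(0); left <- integer(0); right <- integer(0)
  pred <- integer(0); nn <- integer(0); nwrong <- integer(0); gdec <- numeric(0)
  depth <- integer(0)
  new_node <- function(counts, d) {
    var[length(var) + 1L] <<- NA_integer_; cut[length(cut) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- NA_integer_; right[length(right) + 1L] <<- NA_integer_
    pred[length(pred) + 1L] <<- which.max(counts)
    nn[length(nn) + 1L] <<- sum(counts)
    nwrong[length(nwrong) + 1L] <<- sum(counts) - max(counts)
    gdec[length(gdec) + 1L] <<- 0
    depth[length(depth) + 1L] <<- d
    length(var)
  }
  stack <- list(list(idx = seq_len(nrow(X)), d = 0L, node = NULL, side = NULL))
  root <- new_node(tabulate(y, K), 0L)
  stack[[1]]$node <- root
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    idx <- fr$idx; j <- fr$node
    counts <- tabulate(y[idx], K)
    n1 <- length(idx)
    if (n1 < minsplit || max(counts) == n1 || fr$d >= maxdepth) next
    imp_parent <- n1 - sum(counts^2) / n1
    vars <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    best <- NULL
    for (v in vars) {
      xs <- X[idx, v]
      o <- order(xs)
      xo <- xs[o]; yo <- y[idx][o]
      if (xo[1] == xo[n1]) next
      cum <- vapply(seq_len(K), function(k) cumsum(yo == k), numeric(n1))
      nl <- seq_len(n1 - 1L); nr <- n1 - nl
      cuml <- cum[nl, , drop = FALSE]
      ssl <- rowSums(cuml^2)
      cumr <- matrix(counts, n1 - 1L, K, byrow = TRUE) - cuml
      ssr <- rowSums(cumr^2)
      dec <- imp_parent - (nl - ssl / nl) - (nr - ssr / nr)
      valid <- xo[nl] < xo[nl + 1L]
      if (!any(valid)) next
      dec[!valid] <- -Inf
      i <- which.max(dec)
      if (is.null(best) || dec[i] > best$dec)
        best <- list(v = v, cut = (xo[i] + xo[i + 1L]) / 2, dec = dec[i])
    }
    if (is.null(best) || best$dec <= 1e-12) next
    goleft <- X[idx, best$v] < best$cut
    lid <- new_node(tabulate(y[idx[goleft]], K), fr$d + 1L)
    rid <- new_node(tabulate(y[idx[!goleft]], K), fr$d + 1L)
    var[j] <- best$v; cut[j] <- best$cut; left[j] <- lid; right[j] <- rid
    gdec[j] <- best$dec
    stack[[length(stack) + 1L]] <- list(idx = idx[goleft], d = fr$d + 1L, node = lid)
    stack[[length(stack) + 1L]] <- list(idx = idx[!goleft], d = fr$d + 1L, node = rid)
  }
  list(var = var, cut = cut, left = left, right = right, pred = pred,
       n = nn, nwrong = nwrong, gdec = gdec, depth = depth)
}

# terminal node id for each row; `pruned` marks collapsed internal nodes
.tree_node_of <- function(tr, X, pruned = NULL) {
  node <- rep(1L, nrow(X))
  is_leaf <- is.na(tr$var)
  if (!is.null(pruned)) is_leaf[pruned] <- TRUE
  for (j in seq_along(tr$var)) {
    if (is_leaf[j]) next
    at <- which(node == j)
    if (!length(at)) next
    goleft <- X[at, tr$var[j]] < tr$cut[j]
    node[at[goleft]] <- tr$left[j]
    node[at[!goleft]] <- tr$right[j]
  }
  node
}

.tree_predict_code <- function(tr, X, pruned = NULL)
  tr$pred[.tree_node_of(tr, X, pruned)]

# weakest-link quantities for the current (possibly partially pruned) tree:
# for each active internal node, g = (R(t) - R(T_t)) / (leaves(T_t) - 1)
.weakest_link <- function(tr, pruned) {
  nn <- length(tr$var)
  is_leaf <- is.na(tr$var); is_leaf[pruned] <- TRUE
  leaves <- integer(nn); rsub <- numeric(nn)
  active <- rep(FALSE, nn); active[1L] <- TRUE   # reachable given pruning
  for (j in seq_len(nn)) if (active[j] && !is_leaf[j]) {
    active[tr$left[j]] <- TRUE; active[tr$right[j]] <- TRUE
  }
  # children have larger ids: accumulate bottom-up
  for (j in rev(seq_len(nn))) {
    if (is_leaf[j]) { leaves[j] <- 1L; rsub[j] <- tr$nwrong[j] }
    else { leaves[j] <- leaves[tr$left[j]] + leaves[tr$right[j]]
           rsub[j] <- rsub[tr$left[j]] + rsub[tr$right[j]] }
  }
  internal <- which(!is_leaf & active)
  g <- (tr$nwrong[internal] - rsub[internal]) / pmax(leaves[internal] - 1L, 1L)
  list(internal = internal, g = g, leaves = leaves, rsub = rsub, active = active)
}

# collapse all weakest links with g <= alpha; returns the pruned-node set
.prune_at <- function(tr, alpha) {
  pruned <- integer(0)
  repeat {
    wl <- .weakest_link(tr, pruned)
    if (!length(wl$internal)) break
    gmin <- min(wl$g)
    if (gmin > alpha + 1e-12) break
    pruned <- c(pruned, wl$internal[wl$g <= gmin + 1e-12])
  }
  pruned
}

# alpha sequence of the minimal cost-complexity subtree family
.alpha_sequence <- function(tr) {
  alphas <- 0; pruned <- integer(0)
  wl <- .weakest_link(tr, pruned)
  sizes <- wl$leaves[1L]
  while (length(wl$internal)) {
    gmin <- min(wl$g)
    pruned <- c(pruned, wl$internal[wl$g <= gmin + 1e-12])
    alphas <- c(alphas, gmin)
    wl <- .weakest_link(tr, pruned)
    sizes <- c(sizes, wl$leaves[1L])
  }
  list(alpha = alphas, nleaf = sizes)
}

#' Fit a cross-validated, pruned classification tree
#'
#' Grows a CART on the Gini criterion, derives the nested cost-complexity
#' subtree sequence, estimates each subtree's misclassification error by
#' k-fold cross-validation, and prunes at the complexity value with the
#' lowest cross-validated error (ties resolved toward the smaller tree).
#'
#' @param table feature data frame/matrix (rows = neurons).
#' @param labels class labels (factor or coercible).
#' @param minsplit minimal node size to attempt a split (default 5).
#' @param cv_folds internal cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return object of class `phys_tree`: `tree` (full), `pruned_nodes`,
#'   `cptable` (alpha, n_leaves, rel_error, cv_error), `chosen_alpha`,
#'   `feature_names`, `classes`, `root_feature`, `pruned_depth`.
#' @export
fit_tree <- function(table, labels, minsplit = 5L, cv_folds = 10L, seed = NULL) {
  X <- as.matrix(table)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least two classes")
  yi <- as.integer(y)
  K <- nlevels(y)
  tr <- .grow_tree(X, yi, K, minsplit = minsplit)
  seqs <- .alpha_sequence(tr)
  alphas <- seqs$alpha
  # subtree k is optimal for alpha in [a_k, a_{k+1}); evaluate it at the
  # geometric mean of that interval (root subtree at a_m itself)
  m_a <- length(alphas)
  betas <- if (m_a == 1L) 0 else c(sqrt(alphas[-m_a] * alphas[-1]), alphas[m_a])
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_err <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    err <- matrix(0, length(betas), 1L)
    for (f in seq_len(cv_folds)) {
      tri <- which(folds != f); tei <- which(folds == f)
      if (!length(tei) || length(unique(yi[tri])) < 2L) next
      trf <- .grow_tree(X[tri, , drop = FALSE], yi[tri], K, minsplit = minsplit)
      for (b in seq_along(betas)) {
        pr <- .prune_at(trf, betas[b])
        pred <- .tree_predict_code(trf, X[tei, , drop = FALSE], pr)
        err[b] <- err[b] + sum(pred != yi[tei])
      }
    }
    err[, 1L]
  })
  root_err <- tr$nwrong[1L]
  rel_err <- vapply(seq_along(betas), function(b) {
    pr <- .prune_at(tr, betas[b])
    wl <- .weakest_link(tr, pr)
    wl$rsub[1L] / max(root_err, 1L)
  }, numeric(1))
  cp <- data.frame(alpha = alphas, n_leaves = seqs$nleaf,
                   rel_error = rel_err, cv_error = cv_err / max(root_err, 1L))
  b <- max(which(cp$cv_error <= min(cp$cv_error) + 1e-12))  # smallest tree on ties
  chosen <- betas[b]
  pruned <- .prune_at(tr, chosen)
  wl <- .weakest_link(tr, pruned)
  act_internal <- setdiff(which(!is.na(tr$var) & wl$active), pruned)
  pruned_depth <- if (length(act_internal)) max(tr$depth[act_internal]) + 1L else 0L
  structure(list(tree = tr, pruned_nodes = pruned, cptable = cp,
                 chosen_alpha = chosen, feature_names = colnames(X),
                 classes = levels(y),
                 root_feature = if (!is.na(tr$var[1L]) && !(1L %in% pruned))
                   colnames(X)[tr$var[1L]] else NA_character_,
                 pruned_depth = pruned_depth),
            class = "phys_tree")
}

#' @export
predict.phys_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  factor(object$classes[.tree_predict_code(object$tree, X, object$pruned_nodes)],
         levels = object$classes)
}

#' @export
print.phys_tree <- function(x, ...) {
  wl <- .weakest_link(x$tree, x$pruned_nodes)
  cat(sprintf("<phys_tree> %d-leaf pruned tree (depth %d), root split on %s\n",
              wl$leaves[1L], x$pruned_depth, x$root_feature))
  invisible(x)
}
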