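# Z-scoring, Ward clustering with the Thorndike cut, decision tree and
# random forest validation.

test_that("zscore_table standardizes, is idempotent, and names bad columns", {
  set.seed(90)
  tab <- data.frame(a = rnorm(40, 100, 20), b = runif(40), c = rexp(40))
  z <- zscore_table(tab)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(zscore_table(z), z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(zscore_table(data.frame(x = 1:3))[, 1]), c(-1, 0, 1))
  expect_error(zscore_table(data.frame(a = 1:5, flat = rep(2, 5))), "flat")
  expect_error(zscore_table(data.frame(a = c(1, NA, 3))), "missing")
})

test_that("ward heights equal the brute-force ESS oracle on small instances", {
  set.seed(91)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * sample(2:4, 1)), n)
    wc <- ward_cluster(x)
    expect_equal(sort(wc$height), sort(brute_ward_heights(x)), tolerance = 1e-9)
    expect_true(all(diff(wc$height) >= -1e-12))    # monotone merges
    # 2-cluster labels agree with the oracle up to label permutation
    expect_equal(adjusted_rand_index(cutree(wc, 2), brute_ward_k2(x)), 1)
  }
})

test_that("ward handles duplicates and planted triads", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5))
  wc <- ward_cluster(x)
  expect_equal(wc$height[1], 0)
  set.seed(92)
  triads <- rbind(matrix(rnorm(9, 0, 0.05), 3), matrix(rnorm(9, 10, 0.05), 3))
  wc2 <- ward_cluster(triads)
  expect_gt(wc2$height[5], 10 * max(wc2$height[1:4]))
  expect_equal(adjusted_rand_index(cutree(wc2, 2), rep(1:2, each = 3)), 1)
})

test_that("clustering is invariant to row and column order", {
  set.seed(93)
  x <- matrix(rnorm(60), 12)
  cut0 <- thorndike_cut(ward_cluster(x))
  ro <- sample(12); co <- sample(5)
  cutr <- thorndike_cut(ward_cluster(x[ro, ]))
  expect_equal(cutr$chosen_k, cut0$chosen_k)
  expect_equal(adjusted_rand_index(cutr$labels, cut0$labels[ro]), 1)
  cutc <- thorndike_cut(ward_cluster(x[, co]))
  expect_equal(adjusted_rand_index(cutc$labels, cut0$labels), 1)
})

test_that("thorndike_cut finds 2 and 3 well-separated blobs", {
  set.seed(94)
  two <- rbind(matrix(rnorm(50 * 15, 0), 50), matrix(rnorm(50 * 15, 6), 50))
  c2 <- thorndike_cut(ward_cluster(two))
  expect_equal(c2$chosen_k, 2L)
  expect_equal(adjusted_rand_index(c2$labels, rep(1:2, each = 50)), 1)
  # three equidistant blobs (simplex corners)
  mu <- 8 * rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  three <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(30 * 3, 0), 30) + matrix(mu[k, ], 30, 3, byrow = TRUE)))
  c3 <- thorndike_cut(ward_cluster(three))
  expect_equal(c3$chosen_k, 3L)
  expect_error(thorndike_cut(ward_cluster(matrix(rnorm(4), 2))), "at least 3")
})

test_that("a perfectly separating feature yields a single-split zero-error tree", {
  set.seed(95)
  tab <- data.frame(good = c(rnorm(30, 0), rnorm(30, 10)),
                    noise = rnorm(60))
  y <- rep(c("a", "b"), each = 30)
  tm <- fit_tree(tab, y, seed = 1)
  expect_equal(tm$root_feature, "good")
  expect_equal(tm$pruned_depth, 1L)
  expect_equal(as.character(predict(tm, tab)), y)
  expect_error(fit_tree(tab, rep("a", 60)), "two classes")
})

test_that("tree prefers the planted dominant feature and pruning never deepens", {
  tab <- sim_feature_table(seed = 96)
  lab <- attr(tab, "labels")
  tm <- fit_tree(tab, lab, seed = 2)
  expect_true(tm$root_feature %in% c("max_firing_rate", "sag", "ap_halfwidth"))
  full_depth <- max(tm$tree$depth[!is.na(tm$tree$var)]) + 1L
  expect_lte(tm$pruned_depth, full_depth)
  expect_true(all(diff(tm$cptable$alpha) >= 0))
})

test_that("bootstrap_validate is deterministic under a seed and saturates on separable data", {
  tab <- data.frame(x = c(rnorm(40, 0, 0.1), rnorm(40, 10, 0.1)))
  y <- rep(c("a", "b"), each = 40)
  a1 <- bootstrap_validate("tree", tab, y, n_draws = 20, seed = 9)
  a2 <- bootstrap_validate("tree", tab, y, n_draws = 20, seed = 9)
  expect_equal(as.numeric(a1), as.numeric(a2))
  expect_equal(as.numeric(a1), 100)
  f1 <- bootstrap_validate("forest", tab, y, n_draws = 3, seed = 9, n_trees = 50)
  expect_equal(as.numeric(f1), 100)
})

test_that("forest: proximity contract, planted importance, chance-level OOB on noise", {
  tab <- sim_feature_table(separation_sd = 0, seed = 97)
  # one informative feature among 14 noise features
  lab <- rep(c("a", "b"), c(60, 45))
  tab$max_firing_rate <- rnorm(105, ifelse(lab == "a", 0, 4))
  fo <- fit_forest(tab, lab, n_trees = 400, seed = 3)
  expect_equal(names(which.max(fo$gini_importance)), "max_firing_rate")
  expect_true(isSymmetric(fo$proximity))
  expect_equal(unname(diag(fo$proximity)), rep(1, 105))
  expect_true(all(fo$proximity >= 0 & fo$proximity <= 1))
  expect_true(all(fo$gini_importance >= 0))
  # pure noise, balanced labels: OOB error near chance
  set.seed(98)
  noise <- matrix(rnorm(200 * 15), 200)
  fn <- fit_forest(noise, rep(c("a", "b"), each = 100), n_trees = 300, seed = 4,
                   proximity = FALSE)
  expect_gt(fn$oob_error, 0.4); expect_lt(fn$oob_error, 0.6)
})

test_that("forest OOB error falls as planted separation grows", {
  oob <- vapply(c(0, 1, 2, 4), function(s) {
    tab <- sim_feature_table(separation_sd = s, seed = 99)
    fit_forest(tab, attr(tab, "labels"), n_trees = 300, seed = 5,
               proximity = FALSE)$oob_error
  }, numeric(1))
  expect_true(all(diff(oob) <= 0.05))   # monotone within noise
  expect_lt(oob[4], 0.1)
})

test_that("proximity embedding separates planted clusters", {
  tab <- sim_feature_table(seed = 100)
  lab <- attr(tab, "labels")
  fo <- fit_forest(tab, lab, n_trees = 400, seed = 6)
  emb <- proximity_pca(fo)
  expect_equal(dim(emb), c(105L, 2L))
  # silhouette-style check: mean within-class embedding distance smaller
  # than between-class
  d <- as.matrix(dist(emb))
  same <- outer(lab, lab, `==`); diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
  # identical samples have proximity 1 and coincide in the embedding
  tab2 <- tab[c(1, 1, 1:103), ]
  fo2 <- fit_forest(tab2, lab, n_trees = 200, seed = 7)
  expect_equal(fo2$proximity[1, 2], 1)
  emb2 <- proximity_pca(fo2)
  expect_equal(unlist(emb2[1, ]), unlist(emb2[2, ]), tolerance = 1e-9)
})

test_that("responder concordance cross-tabulates cluster and response", {
  lab <- rep(c(1, 2), c(20, 20))
  all_in <- responder_concordance(lab, c(rep(TRUE, 10), rep(FALSE, 30)))
  expect_equal(all_in$percent_concordant, 100)
  # 14 of 16 responders in cluster 1
  resp <- rep(FALSE, 40); resp[c(1:14, 21:22)] <- TRUE
  rc <- responder_concordance(lab, resp)
  expect_equal(rc$percent_concordant, 87.5)
  expect_equal(sum(rc$table), 40)
  expect_error(responder_concordance(lab, resp[1:10]), "same neurons")
  # independence: concordance approaches cluster 1's marginal share
  set.seed(101)
  lab2 <- sample(rep(1:2, c(600, 400)))
  resp2 <- runif(1000) < 0.3
  rc2 <- responder_concordance(lab2, resp2)
  expect_equal(rc2$percent_concordant, 60, tolerance = 8)
})
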