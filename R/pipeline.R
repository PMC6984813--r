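# End-to-end orchestration: recordings (or a ready feature table) ->
# per-cell membrane properties -> z-score -> Ward + Thorndike -> decision
# tree and random forest validation -> stats report. Every constant the
# detection and classification stages use is surfaced in the config with
# its study default; overrides are recorded in the run manifest.

#' Pipeline configuration with all study constants
#'
#' @param ... overrides of the defaults (partial lists are merged).
#' @return nested list of class `phys_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    detection = list(
      evoked_mad_mult = 6,        # evoked/uEPSC threshold, x baseline MAD
      sepsc_mad_mult = 5,         # spontaneous threshold, x rolling MAD
      mad_scale = 1,              # raw MAD (no 1.4826 consistency factor)
      baseline_s = 0.5,           # pre-stimulus baseline, s
      epsc_half_width_ms = 5, ipsc_half_width_ms = 7.5,
      uepsc_window_ms = 3, search_ms = 20, epsp_window_ms = 40,
      sepsc_baseline_ms = 50, artifact_ms = 2, nci_cutoff = 0.5,
      smooth = TRUE),
    intrinsic = list(isi_mode = "min", atten_amp_mv = 40),
    classifier = list(n_trees = 10000L, tree_bootstraps = 500L,
                      forest_cv_runs = 20L, tree_minsplit = 5L,
                      tree_cv_folds = 10L, forest_bootstrap_trees = 500L),
    stats = list(alpha = 0.05),
    seed = 1L,
    out_dir = "phystype-run")
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  attr(cfg, "overrides") <- over
  structure(cfg, class = "phys_config")
}

#' Extract the feature table of a simulated or loaded cohort
#'
#' @param cohort list of per-neuron lists with `fine` and `coarse` sweep
#'   sets (e.g. from [sim_cohort()] or loaded recordings).
#' @param isi_mode passed to [assemble_feature_vector()].
#' @return data frame (neurons x 15 properties); failures per cell yield NA
#'   rows with a warning, never abort the run.
#' @export
cohort_features <- function(cohort, isi_mode = "min") {
  rows <- lapply(seq_along(cohort), function(i) {
    tryCatch(assemble_feature_vector(cohort[[i]]$fine, cohort[[i]]$coarse,
                                     isi_mode = isi_mode),
             error = function(e) {
               warning(sprintf("cell %d: %s", i, conditionMessage(e)), call. = FALSE)
               stats::setNames(rep(NA_real_, 15L), membrane_property_names())
             })
  })
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- sprintf("cell%03d", seq_along(cohort))
  tab
}

#' Run the classification stage on a feature table
#'
#' Z-scores, clusters (Ward + Thorndike), then validates the partition with
#' the pruned decision tree and the random forest.
#'
#' @param features data frame of the 15 properties (complete rows only are
#'   clustered).
#' @param config a [pipeline_config()].
#' @param response_status optional logical vector for responder concordance.
#' @return list: `cluster` (thorndike result + dendrogram), `tree`,
#'   `tree_accuracy`, `forest`, `forest_cv_accuracy`, `embedding`,
#'   `concordance` (when response status given), `kept_rows`.
#' @export
classify_features <- function(features, config = pipeline_config(),
                              response_status = NULL) {
  keep <- stats::complete.cases(features)
  tab <- features[keep, , drop = FALSE]
  z <- zscore_table(tab)
  hc <- ward_cluster(z)
  cut <- thorndike_cut(hc)
  cl <- config$classifier
  seed <- config$seed
  tree <- fit_tree(tab, cut$labels, minsplit = cl$tree_minsplit,
                   cv_folds = cl$tree_cv_folds, seed = seed)
  tree_acc <- bootstrap_validate("tree", tab, cut$labels,
                                 n_draws = cl$tree_bootstraps, seed = seed + 1L,
                                 cv_folds = cl$tree_cv_folds)
  forest <- fit_forest(tab, cut$labels, n_trees = cl$n_trees, seed = seed + 2L)
  forest_acc <- bootstrap_validate("forest", tab, cut$labels,
                                   n_draws = cl$forest_cv_runs, seed = seed + 3L,
                                   n_trees = cl$forest_bootstrap_trees)
  conc <- NULL
  if (!is.null(response_status)) {
    rs <- response_status[keep]
    tested <- !is.na(rs)
    if (any(tested & rs))
      conc <- responder_concordance(cut$labels[tested], rs[tested])
  }
  list(cluster = cut, dendrogram = hc, tree = tree, tree_accuracy = tree_acc,
       forest = forest, forest_cv_accuracy = forest_acc,
       embedding = proximity_pca(forest), concordance = conc, kept_rows = keep)
}

#' Run the full pipeline on a directory or in-memory inputs
#'
#' Accepts either a directory of interchange recordings (pairs
#' `<cell>_fine.csv/json` and `<cell>_coarse.csv/json`), an in-memory
#' cohort, or a ready feature CSV/data frame. Writes stage outputs (feature
#' table, cluster labels, model report, embedding) and a manifest with the
#' config and seeds into `config$out_dir`.
#'
#' @param input directory path, feature CSV path, cohort list, or feature
#'   data frame.
#' @param config a [pipeline_config()].
#' @param response_status optional response vector aligned with the neurons.
#' @param write write output CSV/JSON files (default TRUE).
#' @return the [classify_features()] result, plus `features` and `paths`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), response_status = NULL,
                         write = TRUE) {
  if (is.character(input) && length(input) == 1L) {
    if (dir.exists(input)) {
      stems <- unique(sub("_(fine|coarse)\\.(csv|json)$", "",
                          list.files(input, pattern = "_(fine|coarse)\\.csv$",
                                     full.names = TRUE)))
      if (length(stems) == 0L) stop("empty input directory: no interchange recordings found")
      cohort <- lapply(stems, function(s)
        list(fine = read_recording(paste0(s, "_fine")),
             coarse = read_recording(paste0(s, "_coarse"))))
      features <- cohort_features(cohort, isi_mode = config$intrinsic$isi_mode)
    } else if (file.exists(input)) {
      features <- utils::read.csv(input, row.names = 1L, check.names = FALSE)
      extra <- setdiff(c("label", "group", "response"), colnames(features))
      features <- features[, intersect(colnames(features), membrane_property_names()),
                           drop = FALSE]
    } else stop("input not found: ", input)
  } else if (is.list(input) && !is.data.frame(input) && !is.null(input[[1]]$coarse)) {
    features <- cohort_features(input, isi_mode = config$intrinsic$isi_mode)
  } else {
    features <- as.data.frame(input)
  }
  if (!all(membrane_property_names() %in% colnames(features)))
    stop("feature table must contain the 15 membrane property columns")
  features <- features[, membrane_property_names(), drop = FALSE]
  res <- classify_features(features, config, response_status)
  res$features <- features
  if (write) res$paths <- .write_run(res, config)
  res
}

.write_run <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  feat <- cbind(res$features,
                cluster = NA_integer_)
  feat$cluster[res$kept_rows] <- res$cluster$labels
  utils::write.csv(feat, p("feature_table.csv"))
  utils::write.csv(data.frame(cell = rownames(res$features)[res$kept_rows],
                              cluster = res$cluster$labels,
                              pc1 = res$embedding$pc1, pc2 = res$embedding$pc2),
                   p("clusters_embedding.csv"), row.names = FALSE)
  report <- list(
    chosen_k = res$cluster$chosen_k,
    cluster_sizes = as.list(table(res$cluster$labels)),
    tree_bootstrap_accuracy = as.numeric(res$tree_accuracy),
    tree_root_feature = res$tree$root_feature,
    forest_oob_error = res$forest$oob_error,
    forest_cv_accuracy = as.numeric(res$forest_cv_accuracy),
    gini_importance = as.list(res$forest$gini_importance),
    concordance = if (!is.null(res$concordance)) res$concordance$percent_concordant,
    manifest = list(seed = config$seed, config = unclass(config),
                    package_version = as.character(utils::packageVersion("phystype")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  jsonlite::write_json(report, p("model_report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  vapply(c("feature_table.csv", "clusters_embedding.csv", "model_report.json"),
         p, character(1))
}

#' Plain-text run report
#'
#' @param res a [run_pipeline()] / [classify_features()] result.
#' @return character vector of report lines (also printed).
#' @export
generate_report <- function(res) {
  if (is.null(res$cluster)) stop("missing run artifacts: no cluster result")
  sizes <- table(res$cluster$labels)
  imp <- sort(res$forest$gini_importance, decreasing = TRUE)
  lines <- c(
    sprintf("Clusters (Thorndike): k = %d [%s]", res$cluster$chosen_k,
            paste(sprintf("group %s: n=%d", names(sizes), as.integer(sizes)),
                  collapse = ", ")),
    sprintf("Largest merge-height gaps: %s",
            paste(sprintf("%.2f", utils::tail(sort(res$cluster$gap_profile), 3)),
                  collapse = ", ")),
    sprintf("Decision tree: root split on %s; bootstrap accuracy %.1f%%",
            res$tree$root_feature, as.numeric(res$tree_accuracy)),
    sprintf("Random forest: OOB error %.2f%%; cv accuracy %.1f%%",
            100 * res$forest$oob_error, as.numeric(res$forest_cv_accuracy)),
    "Gini importance ranking:",
    sprintf("  %2d. %-24s %.3f", seq_along(imp), names(imp), unname(imp)),
    if (!is.null(res$concordance))
      sprintf("Responder concordance: %.1f%% of uEPSC-positive neurons in group 1",
              res$concordance$percent_concordant))
  cat(lines, sep = "\n")
  invisible(lines)
}
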