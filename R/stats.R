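# Statistical reporting layer: normality is assessed per group with the
# Anderson-Darling test; normal data go to the t-family (one-sample, paired,
# unpaired, one-way ANOVA with Tukey post hoc), non-normal data to rank
# tests (Wilcoxon signed-rank, Mann-Whitney U, Kruskal-Wallis with
# Mann-Whitney post hocs corrected by the Benjamini-Hochberg false
# discovery rate). All tests two-tailed, alpha 0.05.

#' Anderson-Darling test of composite normality
#'
#' Case with mean and variance estimated from the sample; the statistic is
#' modified by the small-sample factor \eqn{(1 + 0.75/n + 2.25/n^2)} and the
#' p-value uses the D'Agostino-Stephens piecewise-exponential approximation.
#'
#' @param x numeric sample (n >= 8 for a trustworthy approximation; n >= 4
#'   required).
#' @return list: `statistic` (A-squared, modified), `p_value`.
#' @export
ad_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4L) stop("Anderson-Darling test needs at least 4 observations")
  z <- (x - mean(x)) / stats::sd(x)
  p <- stats::pnorm(z)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  a <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  pv <- if (a >= 0.6) exp(1.2937 - 5.709 * a + 0.0186 * a^2)
  else if (a >= 0.34) exp(0.9177 - 4.279 * a - 1.38 * a^2)
  else if (a > 0.2) 1 - exp(-8.318 + 42.796 * a - 59.938 * a^2)
  else 1 - exp(-13.436 + 101.14 * a - 223.73 * a^2)
  list(statistic = a, p_value = min(max(pv, 0), 1))
}

.group_normal <- function(x, alpha = 0.05) {
  # AD where the approximation holds; Shapiro-Wilk fallback for tiny groups
  if (length(x) >= 8L) ad_test(x)$p_value > alpha
  else stats::shapiro.test(x)$p.value > alpha
}

.summarise_group <- function(x, normal) {
  if (normal)
    sprintf("%.4g ± %.4g (mean ± sem, n=%d)", mean(x),
            stats::sd(x) / sqrt(length(x)), length(x))
  else
    sprintf("%.4g [%.4g/%.4g] (median [IQR], n=%d)", stats::median(x),
            stats::quantile(x, 0.25), stats::quantile(x, 0.75), length(x))
}

#' Normality-driven test selection and execution
#'
#' Routes a comparison to the test family the data support: if every group
#' passes the Anderson-Darling normality check at 0.05, parametric tests
#' are used (one-sample/paired/unpaired t, one-way ANOVA with Tukey HSD post
#' hoc); otherwise rank tests (Wilcoxon signed-rank, Mann-Whitney U,
#' Kruskal-Wallis with FDR-corrected pairwise Mann-Whitney post hocs).
#' `design = "distribution"` runs a two-sample Kolmogorov-Smirnov test
#' regardless of normality. All tests are two-tailed.
#'
#' @param groups named list of numeric vectors (one element for
#'   `one_sample`).
#' @param paired paired design (two groups of equal length).
#' @param design `"auto"` (from the number of groups), `"one_sample"`,
#'   `"two_group"`, `"k_group"` or `"distribution"`.
#' @param alpha significance level (default 0.05).
#' @param mu null value for the one-sample design (default 0).
#' @return list of class `phys_comparison`: `test_name`, `statistic`,
#'   `p_value`, `normal`, `significant`, `alpha_used`, `summary` (per
#'   group), `posthoc` (data frame or NULL).
#' @export
select_and_run <- function(groups, paired = FALSE,
                           design = c("auto", "one_sample", "two_group", "k_group",
                                      "distribution"),
                           alpha = 0.05, mu = 0) {
  design <- match.arg(design)
  if (!is.list(groups)) groups <- list(x = groups)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  ng <- length(groups)
  if (design == "auto")
    design <- if (ng == 1L) "one_sample" else if (ng == 2L) "two_group" else "k_group"
  if (paired) {
    if (ng != 2L) stop("paired designs need exactly two groups")
    if (length(groups[[1]]) != length(groups[[2]]))
      stop("paired groups must have equal lengths")
  }
  if (any(vapply(groups, length, integer(1)) < 3L))
    stop("need at least 3 observations per group")
  normal <- all(vapply(groups, .group_normal, logical(1), alpha = alpha))
  posthoc <- NULL
  if (design == "distribution") {
    ht <- stats::ks.test(groups[[1]], groups[[2]])
    test_name <- "two-sample Kolmogorov-Smirnov"
  } else if (design == "one_sample") {
    ht <- if (normal) stats::t.test(groups[[1]], mu = mu)
          else stats::wilcox.test(groups[[1]], mu = mu)
    test_name <- if (normal) "one-sample t-test" else "Wilcoxon signed-rank"
  } else if (design == "two_group") {
    if (normal) {
      ht <- stats::t.test(groups[[1]], groups[[2]], paired = paired, var.equal = !paired)
      test_name <- if (paired) "paired t-test" else "unpaired t-test"
    } else {
      ht <- stats::wilcox.test(groups[[1]], groups[[2]], paired = paired, exact = FALSE)
      test_name <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
    }
  } else {
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
    if (normal) {
      fit <- stats::aov(y ~ g)
      ht <- list(statistic = summary(fit)[[1]]$`F value`[1],
                 p.value = summary(fit)[[1]]$`Pr(>F)`[1])
      test_name <- "one-way ANOVA"
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- data.frame(comparison = rownames(tk), p = tk[, "p adj"],
                            test = "Tukey HSD", row.names = NULL)
      posthoc$significant <- posthoc$p < alpha
      posthoc$alpha_used <- alpha
    } else {
      ht <- stats::kruskal.test(y, g)
      test_name <- "Kruskal-Wallis"
      prs <- utils::combn(names(groups), 2, simplify = FALSE)
      pv <- vapply(prs, function(pr)
        stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]], exact = FALSE)$p.value,
        numeric(1))
      fdr <- fdr_adjust(pv, alpha)
      posthoc <- data.frame(comparison = vapply(prs, paste, character(1), collapse = "-"),
                            p = pv, test = "Mann-Whitney U (FDR-corrected)",
                            significant = fdr$significant, alpha_used = fdr$alpha_fdr,
                            row.names = NULL)
    }
  }
  stat <- unname(if (!is.null(ht$statistic)) ht$statistic else NA_real_)
  structure(list(test_name = test_name, statistic = as.numeric(stat)[1],
                 p_value = ht$p.value, normal = normal,
                 significant = ht$p.value < alpha, alpha_used = alpha,
                 summary = vapply(groups, .summarise_group, character(1),
                                  normal = normal),
                 posthoc = posthoc),
            class = "phys_comparison")
}

#' @export
print.phys_comparison <- function(x, ...) {
  cat(sprintf("<phys_comparison> %s: p = %.4g (%ssignificant at alpha = %g)\n",
              x$test_name, x$p_value, if (x$significant) "" else "not ", x$alpha_used))
  for (nm in names(x$summary)) cat(" ", nm, ": ", x$summary[[nm]], "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: with ordered p-values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, find the largest \eqn{i} with \eqn{p_{(i)} \le (i/m)\alpha};
#' that test and all smaller p-values are significant, and
#' \eqn{\alpha_{FDR} = (i/m)\alpha} is reported as the effective threshold.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list: `significant` (logical, original order), `alpha_fdr`,
#'   `adjusted_p` (BH-adjusted p-values).
#' @export
fdr_adjust <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("need at least one p-value")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= (seq_len(m) / m) * alpha)
  k <- if (length(pass)) max(pass) else 0L
  sig <- rep(FALSE, m)
  if (k > 0L) sig[o[seq_len(k)]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adj <- pmin(adj, 1)[order(o)]
  list(significant = sig, alpha_fdr = if (k > 0L) (k / m) * alpha else alpha / m,
       adjusted_p = adj)
}
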