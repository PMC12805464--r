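#' Empirical ROC area (Mann-Whitney estimator)
#'
#' Nonparametric AUC with the midrank tie convention:
#' \eqn{P(Y_+ > Y_-) + \frac12 P(Y_+ = Y_-)}, computed from rank sums. Equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param values Numeric biomarker values.
#' @param labels POS/NEG (or logical) reference labels, same length; no
#'   missing values.
#' @return AUC as a probability.
#' @export
auc_empirical <- function(values, labels) {
  d <- as_pos(labels)
  if (length(values) != length(d)) abort("`values` and `labels` must have equal length.")
  if (anyNA(values) || anyNA(d)) abort("missing values/labels: drop incomplete records first.")
  m <- as.numeric(sum(d)) # numeric: m * n overflows integers at large n
  n <- as.numeric(sum(!d))
  if (m == 0) abort("no POS records: AUC requires at least one of each class.")
  if (n == 0) abort("no NEG records: AUC requires at least one of each class.")
  r <- rank(values) # midranks
  (sum(r[d]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components, rank-based.
# V10[i] = mean_j psi(X_i, Y_j) for positives X, negatives Y;
# V01[j] = mean_i psi(X_i, Y_j); psi = 1, 1/2, 0 for >, =, <.
delong_components <- function(values, d) {
  m <- sum(d)
  n <- sum(!d)
  r_all <- rank(values)
  v10 <- (r_all[d] - rank(values[d])) / n
  v01 <- 1 - (r_all[!d] - rank(values[!d])) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong confidence interval
#'
#' Point estimate from [auc_empirical()] and a normal-approximation interval
#' with the DeLong structural-components variance
#' \eqn{S_{10}/n_+ + S_{01}/n_-}, clipped to \[0, 1\]. With perfect
#' separation the variance estimate is zero; a degenerate interval
#' `[auc, auc]` is returned with a warning and `degenerate = TRUE`.
#'
#' @inheritParams auc_empirical
#' @param level Confidence level in (0, 1), default 0.95.
#' @param label Optional cohort/stratum tag carried into the result.
#' @return One-row tibble (class `auc_estimate`): `label`, `n_pos`, `n_neg`,
#'   `auc`, `se`, `ci_low`, `ci_high`, `level`, `degenerate`.
#' @export
auc_delong <- function(values, labels, level = 0.95, label = NA_character_) {
  check_prob(level, "level")
  auc <- auc_empirical(values, labels)
  d <- as_pos(labels)
  comp <- delong_components(values, d)
  se <- sqrt(var(comp$v10) / comp$m + var(comp$v01) / comp$n)
  degenerate <- !is.finite(se) || se == 0
  if (degenerate) {
    warn(sprintf(
      "zero DeLong variance (perfect separation%s): returning degenerate interval.",
      if (!is.na(label)) paste0(" in ", label) else ""
    ))
    se <- 0
  }
  z <- qnorm(1 - (1 - level) / 2)
  out <- tibble::tibble(
    label = label,
    n_pos = comp$m,
    n_neg = comp$n,
    auc = auc,
    se = se,
    ci_low = max(0, auc - z * se),
    ci_high = min(1, auc + z * se),
    level = level,
    degenerate = degenerate
  )
  class(out) <- c("auc_estimate", class(out))
  out
}

#' Stratified bootstrap AUC interval
#'
#' Percentile interval from resampling positives and negatives separately
#' (class sizes fixed). Provided as an independent cross-check on
#' [auc_delong()]; it is not the default interval.
#'
#' @inheritParams auc_delong
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional integer seed for the resampling.
#' @return Named list: `auc`, `ci_low`, `ci_high`, `level`, `n_boot`.
#' @export
auc_boot_ci <- function(values, labels, n_boot = 2000, level = 0.95, seed = NULL) {
  check_prob(level, "level")
  d <- as_pos(labels)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- values[d]
  y <- values[!d]
  if (length(x) == 0 || length(y) == 0) abort("both classes are required.")
  stats <- vapply(seq_len(n_boot), function(b) {
    xb <- x[sample.int(length(x), replace = TRUE)]
    yb <- y[sample.int(length(y), replace = TRUE)]
    auc_empirical(c(xb, yb), c(rep(TRUE, length(xb)), rep(FALSE, length(yb))))
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stats, c(alpha, 1 - alpha), type = 7))
  list(auc = auc_empirical(values, labels), ci_low = ci[1], ci_high = ci[2],
       level = level, n_boot = n_boot)
}

#' Per-cohort and pooled AUC forest table
#'
#' One DeLong AUC estimate per cohort plus a pooled estimate computed on the
#' concatenated subjects (not a meta-analytic average). Records with a
#' missing reference label are excluded.
#'
#' @param data Cohort tibble.
#' @param value Biomarker column (default `ptau217`).
#' @param truth Reference label column, POS/NEG (default `visual_read`).
#' @param by Grouping column for the per-cohort rows (default `cohort`).
#' @param pooled_label Tag for the pooled row (default `"Combined"`).
#' @param level Confidence level.
#' @return Tibble (class `auc_forest`) with one row per cohort plus the
#'   pooled row: `label`, `n_pos`, `n_neg`, `auc`, `se`, `ci_low`, `ci_high`,
#'   `level`, `degenerate`.
#' @export
auc_forest <- function(data, value = ptau217, truth = visual_read,
                       by = cohort, pooled_label = "Combined", level = 0.95) {
  y <- pull_col(data, {{ value }}, "value")
  lab <- pull_col(data, {{ truth }}, "truth")
  grp <- as.character(pull_col(data, {{ by }}, "by"))
  keep <- !is.na(lab)
  y <- y[keep]; lab <- lab[keep]; grp <- grp[keep]
  if (length(y) == 0) abort("no records with a non-missing reference label.")
  per <- purrr::map_dfr(unique(grp), function(g) {
    sel <- grp == g
    tryCatch(
      auc_delong(y[sel], lab[sel], level = level, label = g),
      error = function(e) {
        abort(sprintf("cohort `%s`: %s", g, conditionMessage(e)))
      }
    )
  })
  pooled <- auc_delong(y, lab, level = level, label = pooled_label)
  out <- dplyr::bind_rows(per, pooled)
  class(out) <- c("auc_forest", class(out))
  out
}

#' Forest plot of AUC estimates
#'
#' Point-and-interval display of an [auc_forest()] table, pooled row last.
#'
#' @param object An `auc_forest` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot auc_forest
#' @export
autoplot.auc_forest <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                             shape = 15) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted", colour = "grey50") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = sprintf("AUC (%d%% CI)", round(100 * df$level[1])), y = NULL) +
    ggplot2::theme_minimal()
}
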