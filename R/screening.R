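# Confusion matrices, raw and prevalence-adjusted screening metrics,
# cutoff grids, rule-out cutoff selection and screening-economics quantities.
#
# Boundary convention throughout: a biomarker value >= cutoff screens in
# (test-positive); a value < cutoff is ruled out. Ties at the cutoff screen
# in, matching the "< cutoff rules out" reading.

#' Confusion matrix at a rule-out cutoff
#'
#' Counts records against a binary reference with the screen-in convention
#' `value >= cutoff`: TP are reference-positive screen-ins, FN
#' reference-positive rule-outs, FP reference-negative screen-ins, TN
#' reference-negative rule-outs. Records with a missing reference label are
#' excluded.
#'
#' @param data Cohort tibble.
#' @param cutoff Positive biomarker cutoff (pg/mL).
#' @param value Biomarker column (default `ptau217`).
#' @param truth Reference label column, POS/NEG (default `visual_read`).
#' @return One-row tibble: `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_at_cutoff <- function(data, cutoff, value = ptau217, truth = visual_read) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff)) {
    abort("`cutoff` must be a single number.")
  }
  y <- pull_col(data, {{ value }}, "value")
  d <- as_pos(pull_col(data, {{ truth }}, "truth"), "truth")
  keep <- !is.na(d) & !is.na(y)
  y <- y[keep]
  d <- d[keep]
  if (length(y) == 0) abort("no records with a non-missing reference label.")
  pos_test <- y >= cutoff
  tibble::tibble(
    tp = sum(d & pos_test),
    fn = sum(d & !pos_test),
    fp = sum(!d & pos_test),
    tn = sum(!d & !pos_test)
  )
}

#' Raw (count-based) performance metrics
#'
#' Sensitivity, specificity, raw PPV/NPV and overall percent agreement from
#' a confusion matrix, with no prevalence adjustment.
#'
#' @param cm One-row data frame or named list with `tp`, `fn`, `fp`, `tn`.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv_raw`,
#'   `npv_raw`, `opa_raw`.
#' @export
raw_metrics <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  if (tp + fn < 1) abort("empty positive margin (tp + fn = 0): sensitivity undefined.")
  if (fp + tn < 1) abort("empty negative margin (fp + tn = 0): specificity undefined.")
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv_raw = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv_raw = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    opa_raw = (tp + tn) / (tp + fn + fp + tn)
  )
}

# Bayes-form adjusted metrics; s = 0 yields NA for the quantities that
# require ruling in at least one true positive.
adjusted_metrics_impl <- function(s, p, pi) {
  ppv_den <- s * pi + (1 - p) * (1 - pi)
  npv_den <- p * (1 - pi) + (1 - s) * pi
  screen_out <- (1 - s) * pi + p * (1 - pi)
  tibble::tibble(
    sensitivity = s,
    specificity = p,
    prevalence = pi,
    ppv = ifelse(ppv_den > 0, s * pi / ppv_den, NA_real_),
    npv = ifelse(npv_den > 0, p * (1 - pi) / npv_den, NA_real_),
    opa_adjusted = s * pi + p * (1 - pi),
    screen_out = screen_out,
    additional_screening = ifelse(s > 0, 1 / s - 1, NA_real_),
    scans_saved = ifelse(s > 0, 1 - (1 - screen_out) / s, NA_real_)
  )
}

#' Prevalence-adjusted screening metrics
#'
#' Bayes-form performance metrics at an externally specified disease
#' prevalence \eqn{\pi}, as used when the sample's case fraction is not
#' representative of the screened population:
#' \deqn{PPV = \frac{s\pi}{s\pi + (1-p)(1-\pi)}, \qquad
#'       NPV = \frac{p(1-\pi)}{p(1-\pi) + (1-s)\pi},}
#' screen-out rate \eqn{(1-s)\pi + p(1-\pi)} (the fraction of the screened
#' population ruled out), additional screening required \eqn{1/s - 1} (the
#' relative enrollment inflation needed to replace true positives lost to
#' the pre-screen), and confirmatory scans saved
#' \eqn{1 - (1 - \mathrm{screen\_out})/s}. These satisfy the identity
#' `scans_saved == 1 - (1 + additional_screening) * (1 - screen_out)`.
#'
#' @param sensitivity Sensitivity in (0, 1\]; 0 is an error (the
#'   additional-screening quantity is undefined).
#' @param specificity Specificity in \[0, 1\].
#' @param prevalence Adjustment prevalence \eqn{\pi} in (0, 1).
#' @return One-row tibble (vectorized over equal-length inputs):
#'   `sensitivity`, `specificity`, `prevalence`, `ppv`, `npv`,
#'   `opa_adjusted`, `screen_out`, `additional_screening`, `scans_saved`.
#' @export
adjusted_metrics <- function(sensitivity, specificity, prevalence) {
  if (any(!is.finite(sensitivity)) || any(sensitivity <= 0) || any(sensitivity > 1)) {
    abort("`sensitivity` must lie in (0, 1]; at 0 the additional-screening quantity is undefined.")
  }
  if (any(!is.finite(specificity)) || any(specificity < 0) || any(specificity > 1)) {
    abort("`specificity` must lie in [0, 1].")
  }
  if (any(!is.finite(prevalence)) || any(prevalence <= 0) || any(prevalence >= 1)) {
    abort("`prevalence` must lie in (0, 1).")
  }
  adjusted_metrics_impl(sensitivity, specificity, prevalence)
}

#' Full screening summary at a cutoff
#'
#' Table-style one-row report combining the confusion matrix, the raw
#' count-based metrics and the prevalence-adjusted metrics at a rule-out
#' cutoff. OPA is reported raw (from counts); the adjusted OPA is included
#' as `opa_adjusted`.
#'
#' @inheritParams confusion_at_cutoff
#' @param prevalence Adjustment prevalence in (0, 1), or `NULL` for the
#'   sample case fraction (in which case adjusted and raw PPV/NPV coincide).
#' @return One-row tibble: `n`, `n_pos`, `n_neg`, `cutoff`, `tp`, `fn`,
#'   `fp`, `tn`, `sensitivity`, `specificity`, `ppv`, `npv`, `opa` (raw),
#'   `opa_adjusted`, `screen_out`, `additional_screening`, `scans_saved`,
#'   `prevalence`.
#' @export
screening_summary <- function(data, cutoff, prevalence = NULL,
                              value = ptau217, truth = visual_read) {
  cm <- confusion_at_cutoff(data, cutoff, {{ value }}, {{ truth }})
  raw <- raw_metrics(cm)
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$fp + cm$tn
  pi <- prevalence %||% (n_pos / (n_pos + n_neg))
  adj <- adjusted_metrics(raw$sensitivity, raw$specificity, pi)
  tibble::tibble(
    n = n_pos + n_neg, n_pos = n_pos, n_neg = n_neg,
    cutoff = cutoff,
    tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
    sensitivity = raw$sensitivity,
    specificity = raw$specificity,
    ppv = adj$ppv,
    npv = adj$npv,
    opa = raw$opa_raw,
    opa_adjusted = adj$opa_adjusted,
    screen_out = adj$screen_out,
    additional_screening = adj$additional_screening,
    scans_saved = adj$scans_saved,
    prevalence = pi
  )
}

#' Performance over a grid of cutoffs
#'
#' One row per cutoff with the confusion matrix, raw metrics and
#' prevalence-adjusted metrics, sorted by ascending cutoff. With
#' `grid = "all"` the cutoffs are every distinct observed value plus
#' `-Inf`/`Inf` sentinels (rule nobody / everybody out). Along the grid,
#' sensitivity is non-increasing and specificity non-decreasing.
#'
#' @inheritParams screening_summary
#' @param grid Numeric vector of cutoffs, or `"all"`.
#' @return Tibble with columns `cutoff`, `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity`, `ppv_raw`, `npv_raw`, `opa_raw`, `ppv`,
#'   `npv`, `screen_out`, `additional_screening`, `scans_saved`. Quantities
#'   undefined at a sentinel (e.g. additional screening when sensitivity is
#'   0) are `NA`.
#' @export
cutoff_grid <- function(data, prevalence = NULL, grid = "all",
                        value = ptau217, truth = visual_read) {
  y <- pull_col(data, {{ value }}, "value")
  d <- as_pos(pull_col(data, {{ truth }}, "truth"), "truth")
  keep <- !is.na(d) & !is.na(y)
  y <- y[keep]
  d <- d[keep]
  if (length(y) == 0) abort("no records with a non-missing reference label.")
  n_pos <- sum(d)
  n_neg <- sum(!d)
  if (n_pos == 0 || n_neg == 0) abort("both POS and NEG reference records are required.")
  cutoffs <- if (identical(grid, "all")) {
    c(-Inf, sort(unique(y)), Inf)
  } else {
    sort(as.numeric(grid))
  }
  pi <- prevalence %||% (n_pos / (n_pos + n_neg))
  check_prob(pi, "prevalence")
  tp <- vapply(cutoffs, function(cc) sum(d & y >= cc), numeric(1))
  fp <- vapply(cutoffs, function(cc) sum(!d & y >= cc), numeric(1))
  fn <- n_pos - tp
  tn <- n_neg - fp
  s <- tp / n_pos
  p <- tn / n_neg
  adj <- adjusted_metrics_impl(s, p, pi)
  tibble::tibble(
    cutoff = cutoffs,
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = s,
    specificity = p,
    ppv_raw = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    npv_raw = ifelse(tn + fn > 0, tn / (tn + fn), NA_real_),
    opa_raw = (tp + tn) / (n_pos + n_neg),
    ppv = adj$ppv,
    npv = adj$npv,
    screen_out = adj$screen_out,
    additional_screening = adj$additional_screening,
    scans_saved = adj$scans_saved
  )
}

#' Select a rule-out cutoff meeting an NPV floor in both strata
#'
#' Searches candidate cutoffs (midpoints between adjacent distinct biomarker
#' values pooled across both tables) for the largest cutoff -- i.e. the one
#' maximizing the screen-out rate -- whose prevalence-adjusted NPV is at
#' least `npv_min` in both the cognitively impaired and unimpaired tables at
#' their respective prevalences. Returns `NA_real_` when no candidate
#' qualifies; infeasibility is an analytical outcome, not an error.
#'
#' @param ci_data,cu_data Cohort tibbles for the two strata.
#' @param npv_min NPV floor in (0, 1\], default 0.90.
#' @param prevalence_ci Adjustment prevalence for `ci_data` (default 0.6994,
#'   the full-cohort estimate for cognitively impaired participants).
#' @param prevalence_cu Adjustment prevalence for `cu_data`, or `NULL` for
#'   its sample case fraction.
#' @inheritParams confusion_at_cutoff
#' @return The selected cutoff (pg/mL), or `NA_real_`.
#' @export
select_rule_out_cutoff <- function(ci_data, cu_data, npv_min = 0.90,
                                   prevalence_ci = 0.6994, prevalence_cu = NULL,
                                   value = ptau217, truth = visual_read) {
  if (!is.numeric(npv_min) || length(npv_min) != 1 || is.na(npv_min) ||
      npv_min <= 0 || npv_min > 1) {
    abort("`npv_min` must be a single value in (0, 1].")
  }
  y_all <- sort(unique(c(pull_col(ci_data, {{ value }}, "value"),
                         pull_col(cu_data, {{ value }}, "value"))))
  if (length(y_all) < 2) return(NA_real_)
  candidates <- (head(y_all, -1) + tail(y_all, -1)) / 2
  npv_at <- function(data, cc, pi) {
    cm <- confusion_at_cutoff(data, cc, {{ value }}, {{ truth }})
    s <- cm$tp / (cm$tp + cm$fn)
    p <- cm$tn / (cm$tn + cm$fp)
    den <- p * (1 - pi) + (1 - s) * pi
    if (den > 0) p * (1 - pi) / den else NA_real_
  }
  pi_cu <- prevalence_cu %||% {
    d <- as_pos(pull_col(cu_data, {{ truth }}, "truth"), "truth")
    mean(d, na.rm = TRUE)
  }
  ok <- vapply(candidates, function(cc) {
    n1 <- npv_at(ci_data, cc, prevalence_ci)
    n2 <- npv_at(cu_data, cc, pi_cu)
    isTRUE(n1 >= npv_min) && isTRUE(n2 >= npv_min)
  }, logical(1))
  if (!any(ok)) NA_real_ else max(candidates[ok])
}

#' Sensitivity/specificity plot data over the percentile axis
#'
#' Count-based sensitivity and specificity as functions of the biomarker
#' risk percentile, on the same (re-weighted) percentile grid as
#' [risk_curve()]: the point at percentile v corresponds to ruling out all
#' values at or below the v-th quantile. Percentile 0 rules nobody out
#' (sensitivity 1); percentile 1 rules everybody out (specificity 1).
#'
#' @inheritParams screening_summary
#' @return Tibble (class `sens_spec_curves`) with columns `percentile`,
#'   `value` (biomarker value at the grid point; `NA` at percentile 0),
#'   `sensitivity`, `specificity`.
#' @export
sens_spec_curves <- function(data, prevalence = NULL,
                             value = ptau217, truth = visual_read) {
  y <- pull_col(data, {{ value }}, "value")
  d <- as_pos(pull_col(data, {{ truth }}, "truth"), "truth")
  keep <- !is.na(d) & !is.na(y)
  y <- y[keep]
  d <- d[keep]
  n_pos <- sum(d)
  n_neg <- sum(!d)
  if (n_pos == 0 || n_neg == 0) abort("both POS and NEG reference records are required.")
  pi_hat <- n_pos / (n_pos + n_neg)
  pi <- prevalence %||% pi_hat
  check_prob(pi, "prevalence")
  w <- ifelse(d, pi / pi_hat, (1 - pi) / (1 - pi_hat))
  ys <- sort(unique(y))
  idx <- match(y, ys)
  W <- as.numeric(rowsum(w, idx)[, 1])
  v <- cumsum(W) / sum(W)
  pos_counts <- as.numeric(rowsum(as.numeric(d), idx)[, 1])
  neg_counts <- as.numeric(rowsum(as.numeric(!d), idx)[, 1])
  sens <- 1 - cumsum(pos_counts) / n_pos # P(Y > y_k | POS)
  spec <- cumsum(neg_counts) / n_neg     # P(Y <= y_k | NEG)
  out <- tibble::tibble(
    percentile = c(0, v),
    value = c(NA_real_, ys),
    sensitivity = c(1, sens),
    specificity = c(0, spec)
  )
  structure(out, prevalence = pi, class = c("sens_spec_curves", class(out)))
}

#' Sensitivity/specificity plot
#'
#' @param object A [sens_spec_curves()] table.
#' @param cutoff Optional rule-out cutoff (pg/mL) marked as a vertical line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sens_spec_curves
#' @export
autoplot.sens_spec_curves <- function(object, cutoff = NULL, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("percentile", "sensitivity", "specificity")],
    -"percentile", names_to = "series", values_to = "value"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile, y = .data$value,
                                        linetype = .data$series)) +
    ggplot2::geom_step(colour = "red3") +
    ggplot2::labs(x = "Risk percentile of pTau217", y = "Proportion",
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    vals <- object$value[-1]
    below <- vals < cutoff
    vc <- if (!any(below)) 0 else object$percentile[-1][max(which(below))]
    p <- p + ggplot2::geom_vline(xintercept = vc, colour = "black")
  }
  p
}
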