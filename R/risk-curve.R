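# Predictiveness-curve ("integrated risk") estimation.
#
# The curve reports, as a function of the biomarker's risk percentile v:
#   risk(v)          P(D = POS | Y at quantile v)      (predictiveness)
#   ppv(v)           P(D = POS | Y > quantile v)
#   one_minus_npv(v) P(D = POS | Y <= quantile v)
# Prevalence adjustment is case/control importance re-weighting: cases get
# weight pi/pi_hat and controls (1-pi)/(1-pi_hat), so the effective case
# fraction equals the supplied prevalence and the curve's PPV / 1-NPV agree
# exactly with the Bayes-form adjusted metrics at every cutoff.

# Weighted pool-adjacent-violators: isotonic (non-decreasing) weighted
# least-squares fit. Returns fitted values, one per input point.
pava <- function(y, w) {
  n <- length(y)
  if (n == 0) return(numeric(0))
  bm <- numeric(n) # block means
  bw <- numeric(n) # block weights
  bn <- integer(n) # block sizes
  k <- 0L
  for (j in seq_len(n)) {
    k <- k + 1L
    bm[k] <- y[j]
    bw[k] <- w[j]
    bn[k] <- 1L
    while (k > 1L && bm[k - 1L] > bm[k]) {
      tot <- bw[k - 1L] + bw[k]
      bm[k - 1L] <- (bw[k - 1L] * bm[k - 1L] + bw[k] * bm[k]) / tot
      bw[k - 1L] <- tot
      bn[k - 1L] <- bn[k - 1L] + bn[k]
      k <- k - 1L
    }
  }
  rep(bm[seq_len(k)], bn[seq_len(k)])
}

#' Predictiveness (integrated risk) curve
#'
#' Estimates risk, PPV and 1-NPV as functions of the biomarker risk
#' percentile, with optional prevalence re-weighting. The percentile grid has
#' one point per distinct biomarker value (tied values share a midpoint-free
#' cumulative percentile) plus the 0 endpoint; the largest value sits at
#' percentile 1, so the cutoff-to-percentile mapping stays invertible.
#'
#' Two estimators are available:
#' * `"empirical"`: risk at a grid point is the (re-weighted) case fraction
#'   among records tied at that biomarker value; PPV and 1-NPV are the
#'   re-weighted conditional case fractions above/below the point. With
#'   continuous data the pointwise risk is 0/1-valued and only the
#'   cumulative PPV / 1-NPV series are informative.
#' * `"monotone"`: risk is the weighted isotonic (non-decreasing)
#'   least-squares fit of case status on biomarker rank -- the nonparametric
#'   maximum-likelihood monotone risk estimator, computed by
#'   pool-adjacent-violators; PPV and 1-NPV average the fitted risk
#'   above/below each grid point.
#'
#' @param data Cohort tibble; records with a missing reference label are
#'   excluded.
#' @param value Biomarker column (default `ptau217`).
#' @param truth Reference label column, POS/NEG (default `visual_read`).
#' @param prevalence Disease prevalence used for re-weighting, in (0, 1), or
#'   `NULL` to use the sample case fraction (no re-weighting).
#' @param estimator `"empirical"` or `"monotone"`.
#' @return A `risk_curve` tibble with columns `percentile`, `value` (the
#'   biomarker value at the grid point; `NA` for the 0 endpoint), `risk`,
#'   `ppv`, `one_minus_npv`. `ppv` is `NA` at percentile 1 and
#'   `one_minus_npv` is `NA` at percentile 0 (empty conditioning set).
#'   Attributes: `prevalence`, `sample_prevalence`, `estimator`, `n`,
#'   `n_pos`, `n_neg`.
#' @seealso [risk_at_cutoff()], [integrated_risk_data()], [adjusted_metrics()]
#' @export
risk_curve <- function(data, value = ptau217, truth = visual_read,
                       prevalence = NULL,
                       estimator = c("empirical", "monotone")) {
  estimator <- match.arg(estimator)
  y <- pull_col(data, {{ value }}, "value")
  d <- as_pos(pull_col(data, {{ truth }}, "truth"), "truth")
  keep <- !is.na(d) & !is.na(y)
  y <- y[keep]
  d <- d[keep]
  if (sum(d) == 0 || sum(!d) == 0) {
    abort("both POS and NEG reference records are required.")
  }
  pi_hat <- mean(d)
  pi <- prevalence %||% pi_hat
  check_prob(pi, "prevalence")
  w <- ifelse(d, pi / pi_hat, (1 - pi) / (1 - pi_hat))

  ys <- sort(unique(y))
  idx <- match(y, ys)
  W <- as.numeric(rowsum(w, idx)[, 1])
  Wpos <- as.numeric(rowsum(w * d, idx)[, 1])
  total <- sum(W)
  cumW <- cumsum(W)
  v <- cumW / total
  risk_emp <- Wpos / W

  if (estimator == "monotone") {
    risk <- pava(risk_emp, W)
    cum_pos <- cumsum(risk * W)
  } else {
    risk <- risk_emp
    cum_pos <- cumsum(Wpos)
  }
  total_pos <- cum_pos[length(cum_pos)]
  one_minus_npv <- cum_pos / cumW
  above <- total - cumW
  ppv <- ifelse(above > 0, (total_pos - cum_pos) / above, NA_real_)

  out <- tibble::tibble(
    percentile = c(0, v),
    value = c(NA_real_, ys),
    risk = c(risk[1], risk),
    ppv = c(total_pos / total, ppv),
    one_minus_npv = c(NA_real_, one_minus_npv)
  )
  structure(
    out,
    prevalence = pi,
    sample_prevalence = pi_hat,
    estimator = estimator,
    n = length(y),
    n_pos = sum(d),
    n_neg = sum(!d),
    class = c("risk_curve", class(out))
  )
}

#' Map a biomarker cutoff to its risk percentile
#'
#' The percentile of cutoff c is the (re-weighted) fraction of records with
#' biomarker value strictly below c, matching the screening convention that
#' values at or above the cutoff screen in. A cutoff at or below the data
#' minimum maps to percentile 0.
#'
#' @param curve A [risk_curve()] object.
#' @param cutoff Biomarker cutoff in pg/mL.
#' @return Percentile in \[0, 1\].
#' @export
percentile_at_cutoff <- function(curve, cutoff) {
  stopifnot(inherits(curve, "risk_curve"))
  vals <- curve$value[-1]
  v <- curve$percentile[-1]
  below <- vals < cutoff
  if (!any(below)) 0 else v[max(which(below))]
}

#' Curve readout at a biomarker cutoff
#'
#' PPV and 1-NPV of a predictiveness curve at the percentile corresponding
#' to a rule-out cutoff (values below the cutoff ruled out).
#'
#' @inheritParams percentile_at_cutoff
#' @return One-row tibble: `cutoff`, `percentile`, `risk`, `ppv`,
#'   `one_minus_npv`.
#' @export
risk_at_cutoff <- function(curve, cutoff) {
  stopifnot(inherits(curve, "risk_curve"))
  v <- percentile_at_cutoff(curve, cutoff)
  row <- which(curve$percentile == v)[1]
  tibble::tibble(
    cutoff = cutoff,
    percentile = v,
    risk = curve$risk[row],
    ppv = curve$ppv[row],
    one_minus_npv = curve$one_minus_npv[row]
  )
}

perfect_assay_series <- function(v, pi) {
  tibble::tibble(
    percentile = rep(v, 3),
    series = rep(c("perfect_risk", "perfect_ppv", "perfect_one_minus_npv"),
                 each = length(v)),
    estimator = "reference",
    value = c(
      ifelse(v <= 1 - pi, 0, 1),
      ifelse(v >= 1, NA_real_, pmin(1, pi / (1 - v))),
      ifelse(v <= 0, NA_real_, pmax(0, (v - (1 - pi)) / v))
    )
  )
}

#' Integrated-risk plot data
#'
#' Long-format export of one or two predictiveness curves together with the
#' reference layers of an integrated risk plot: the prevalence horizontal
#' line, the perfect-assay step curves, and the rule-out cutoff's percentile
#' marker.
#'
#' @param curve A [risk_curve()] object (typically the empirical estimator).
#' @param monotone Optional second [risk_curve()] on the same data (typically
#'   the monotone estimator); must share the percentile grid and prevalence.
#' @param cutoff Optional rule-out cutoff (pg/mL); must lie within the
#'   observed biomarker range.
#' @return Tibble with columns `percentile`, `series`, `estimator`, `value`.
#'   Series are `risk`, `ppv`, `one_minus_npv` (per estimator),
#'   `prevalence`, `perfect_*` and, if `cutoff` is given, a single `cutoff`
#'   row whose `value` is the cutoff and whose `percentile` is its grid
#'   position.
#' @export
integrated_risk_data <- function(curve, monotone = NULL, cutoff = NULL) {
  stopifnot(inherits(curve, "risk_curve"))
  pi <- attr(curve, "prevalence")
  curves <- list(curve)
  if (!is.null(monotone)) {
    stopifnot(inherits(monotone, "risk_curve"))
    if (!isTRUE(all.equal(curve$percentile, monotone$percentile)) ||
        !isTRUE(all.equal(pi, attr(monotone, "prevalence")))) {
      abort("the two curves must share the percentile grid and prevalence.")
    }
    curves <- c(curves, list(monotone))
  }
  est_part <- purrr::map_dfr(curves, function(cv) {
    tidyr::pivot_longer(
      tibble::as_tibble(cv)[, c("percentile", "risk", "ppv", "one_minus_npv")],
      -"percentile", names_to = "series", values_to = "value"
    ) |>
      dplyr::mutate(estimator = attr(cv, "estimator"), .before = "value")
  })
  v <- curve$percentile
  ref <- dplyr::bind_rows(
    tibble::tibble(percentile = range(v), series = "prevalence",
                   estimator = "reference", value = pi),
    perfect_assay_series(v, pi)
  )
  out <- dplyr::bind_rows(est_part, ref)
  if (!is.null(cutoff)) {
    vals <- curve$value[-1]
    if (cutoff < min(vals) || cutoff > max(vals)) {
      abort("`cutoff` lies outside the observed biomarker range.")
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      percentile = percentile_at_cutoff(curve, cutoff),
      series = "cutoff", estimator = "reference", value = cutoff
    ))
  }
  out
}

#' @method tidy risk_curve
#' @export
tidy.risk_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @method glance risk_curve
#' @export
glance.risk_curve <- function(x, ...) {
  tibble::tibble(
    n = attr(x, "n"),
    n_pos = attr(x, "n_pos"),
    n_neg = attr(x, "n_neg"),
    prevalence = attr(x, "prevalence"),
    sample_prevalence = attr(x, "sample_prevalence"),
    estimator = attr(x, "estimator"),
    n_grid = nrow(x)
  )
}

#' Integrated risk plot
#'
#' Figure-style display of a predictiveness curve: risk (pink), PPV (red),
#' 1-NPV (blue), the prevalence line (dashed), the perfect-assay reference
#' (grey) and, optionally, the rule-out cutoff's percentile (black vertical
#' line).
#'
#' @param object A [risk_curve()] object.
#' @param cutoff Optional rule-out cutoff in pg/mL.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_curve
#' @export
autoplot.risk_curve <- function(object, cutoff = NULL, ...) {
  pi <- attr(object, "prevalence")
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("percentile", "risk", "ppv", "one_minus_npv")],
    -"percentile", names_to = "series", values_to = "value"
  )
  perf <- perfect_assay_series(object$percentile, pi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile, y = .data$value,
                                        colour = .data$series)) +
    ggplot2::geom_line(data = perf,
                       ggplot2::aes(group = .data$series),
                       colour = "grey70", na.rm = TRUE) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = pi, linetype = "dashed", colour = "grey30") +
    ggplot2::scale_colour_manual(values = c(risk = "violetred1", ppv = "red3",
                                            one_minus_npv = "blue3")) +
    ggplot2::labs(x = "Risk percentile of pTau217", y = "Probability of amyloid positivity",
                  colour = NULL,
                  subtitle = sprintf("%s estimator, prevalence %.1f%%",
                                     attr(object, "estimator"), 100 * pi)) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = percentile_at_cutoff(object, cutoff),
                                 colour = "black")
  }
  p
}
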