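# Trial-enrollment planning: expected screening and confirmatory-scan
# workload with and without a biomarker rule-out pre-screen.

#' Pre-screening trial plan
#'
#' Expected workload to fully enroll `n_enroll` amyloid-positive
#' participants from a referral population with amyloid prevalence
#' \eqn{\pi}, when a confirmatory PET scan is required for enrollment.
#' Without a pre-screen, `n_enroll / pi` scans are expected. With a
#' biomarker pre-screen of sensitivity s and specificity p gating the scan,
#' `n_enroll / (pi * s)` referrals must be pre-screened (the pre-screen
#' loses a fraction 1 - s of true positives) and only screened-in referrals
#' are scanned, so the expected number of scans is
#' `prescreened * (1 - screen_out)`. The saved fraction equals the
#' `scans_saved` quantity of [adjusted_metrics()]. Counts are expectations
#' (real-valued); rounding is left to the report layer.
#'
#' @param n_enroll Target number of enrolled (amyloid-positive) participants.
#' @param sensitivity,specificity Pre-screen operating characteristics;
#'   sensitivity must be positive.
#' @param prevalence Amyloid prevalence \eqn{\pi} of the referral population,
#'   in (0, 1).
#' @return One-row tibble: `n_enroll`, `scans_without`, `prescreened`,
#'   `scans_with`, `saved_fraction`.
#' @export
trial_plan <- function(n_enroll, sensitivity, specificity, prevalence) {
  if (!is.numeric(n_enroll) || length(n_enroll) != 1 || is.na(n_enroll) ||
      n_enroll < 1) {
    abort("`n_enroll` must be a single count >= 1.")
  }
  adj <- adjusted_metrics(sensitivity, specificity, prevalence)
  scans_without <- n_enroll / prevalence
  prescreened <- n_enroll / (prevalence * sensitivity)
  scans_with <- prescreened * (1 - adj$screen_out)
  tibble::tibble(
    n_enroll = n_enroll,
    scans_without = scans_without,
    prescreened = prescreened,
    scans_with = scans_with,
    saved_fraction = 1 - scans_with / scans_without
  )
}

#' Trial plan across a cognitive-status mixture sweep
#'
#' The referral population of an early-AD trial is a mixture of cognitively
#' impaired (CI) and unimpaired (CU) participants in unknown proportion.
#' For each CI fraction f, the mixture's prevalence is
#' \eqn{\pi_f = f\pi_{CI} + (1-f)\pi_{CU}} and the pre-screen's mixture
#' sensitivity/specificity are the case- and control-weighted averages of
#' the per-stratum values; [trial_plan()] is evaluated at each mixture. The
#' endpoints f = 1 and f = 0 reproduce the pure-stratum plans.
#'
#' @inheritParams trial_plan
#' @param ci,cu Named lists with per-stratum `sensitivity`, `specificity`,
#'   `prevalence`.
#' @param ci_fraction Vector of CI mixture fractions in \[0, 1\].
#' @return Tibble with one row per fraction: `ci_fraction`, `prevalence`,
#'   `sensitivity`, `specificity`, plus the [trial_plan()] columns.
#' @export
trial_plan_sweep <- function(n_enroll, ci, cu,
                             ci_fraction = seq(0, 1, by = 0.05)) {
  for (nm in c("sensitivity", "specificity", "prevalence")) {
    if (is.null(ci[[nm]]) || is.null(cu[[nm]])) {
      abort(sprintf("`ci` and `cu` must both supply `%s`.", nm))
    }
  }
  if (any(ci_fraction < 0 | ci_fraction > 1)) {
    abort("`ci_fraction` values must lie in [0, 1].")
  }
  purrr::map_dfr(ci_fraction, function(f) {
    pi_mix <- f * ci$prevalence + (1 - f) * cu$prevalence
    s_mix <- (f * ci$prevalence * ci$sensitivity +
                (1 - f) * cu$prevalence * cu$sensitivity) / pi_mix
    p_mix <- (f * (1 - ci$prevalence) * ci$specificity +
                (1 - f) * (1 - cu$prevalence) * cu$specificity) / (1 - pi_mix)
    dplyr::bind_cols(
      tibble::tibble(ci_fraction = f, prevalence = pi_mix,
                     sensitivity = s_mix, specificity = p_mix),
      trial_plan(n_enroll, s_mix, p_mix, pi_mix)
    )
  })
}
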