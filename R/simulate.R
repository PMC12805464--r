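#' Moment-matched lognormal parameters
#'
#' Inverts the lognormal mean/SD relations so that a lognormal with the
#' returned log-scale parameters has exactly the requested arithmetic mean
#' and standard deviation:
#' \deqn{\sigma^2 = \log(1 + (sd/mean)^2), \quad \mu = \log(mean) - \sigma^2/2.}
#' Plasma pTau217 concentrations are positive and right-skewed, so a
#' lognormal calibrated to a stratum's printed mean/SD is the generator's
#' distributional family.
#'
#' @param mean Target arithmetic mean (pg/mL), > 0.
#' @param sd Target arithmetic standard deviation (pg/mL), > 0. A zero SD is
#'   an error (use a point mass instead).
#' @return Named list with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(mean, sd) {
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) || mean <= 0) {
    abort("`mean` must be a single positive number.")
  }
  if (!is.numeric(sd) || length(sd) != 1 || is.na(sd) || sd < 0) {
    abort("`sd` must be a single non-negative number.")
  }
  if (sd == 0) {
    abort("`sd` = 0 is degenerate: a lognormal cannot be a point mass; handle that stratum as a constant.")
  }
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Default stratum calibration
#'
#' The four cognitive-status by amyloid-status strata with their published
#' plasma pTau217 summary statistics (arithmetic mean and SD in pg/mL) and
#' sample sizes: CI A+ (0.835, 0.381, n = 394), CI A- (0.361, 0.294,
#' n = 144), CU A+ (0.516, 0.235, n = 224), CU A- (0.220, 0.157, n = 1386).
#' These imply amyloid-positivity prevalences of 73.2% (CI) and 13.9% (CU).
#'
#' @return Tibble with columns `cognitive_status`, `amyloid_status`,
#'   `target_mean`, `target_sd`, `n`.
#' @export
default_strata <- function() {
  tibble::tribble(
    ~cognitive_status, ~amyloid_status, ~target_mean, ~target_sd, ~n,
    "CI", "POS", 0.835, 0.381, 394L,
    "CI", "NEG", 0.361, 0.294, 144L,
    "CU", "POS", 0.516, 0.235, 224L,
    "CU", "NEG", 0.220, 0.157, 1386L
  )
}

check_strata <- function(strata) {
  req <- c("cognitive_status", "amyloid_status", "target_mean", "target_sd", "n")
  miss <- setdiff(req, names(strata))
  if (length(miss) > 0) {
    abort(sprintf("`strata` is missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (any(strata$target_mean <= 0) || any(strata$target_sd < 0) || any(strata$n < 0)) {
    abort("each stratum needs `target_mean` > 0, `target_sd` >= 0 and `n` >= 0.")
  }
  if (sum(strata$n) < 1) abort("total stratum size must be at least 1.")
  invisible(strata)
}

#' Generate a synthetic cohort
#'
#' Draws a per-subject cohort with the statistical structure the screening
#' analysis assumes: within each cognitive-status by amyloid-status stratum,
#' biomarker values are sampled from the lognormal moment-matched to the
#' stratum's target mean/SD ([lognormal_params()]), then censored at the
#' lower limit of quantification (values below `lloq` are floored to `lloq`
#' and flagged `bloq`). Each record's `visual_read` is its stratum's amyloid
#' status, so stratum sizes control the amyloid prevalence exactly.
#'
#' Randomness is reproducible: each stratum gets its own deterministic
#' sub-stream derived from `seed` and the stratum's row position, so changing
#' one stratum's `n` does not perturb the draws of the others.
#'
#' @param strata Stratum calibration tibble as from [default_strata()];
#'   subsets (e.g. only the CI rows) are fine.
#' @param seed Integer seed.
#' @param lloq Lower limit of quantification (pg/mL) used for censoring.
#' @param cohort_label Value for the `cohort` column (default "SYNTH").
#' @return Cohort tibble in the [read_cohort()] schema, rows ordered by
#'   stratum, with attribute `"lloq"`.
#' @export
generate_cohort <- function(strata = default_strata(), seed = 1L,
                            lloq = 0.0693, cohort_label = "SYNTH") {
  check_strata(strata)
  if (!is.numeric(lloq) || lloq <= 0) abort("`lloq` must be positive.")
  rows <- purrr::imap(split(strata, seq_len(nrow(strata))), function(st, i) {
    i <- as.integer(i)
    n <- st$n
    if (n == 0) return(NULL)
    p <- lognormal_params(st$target_mean, st$target_sd)
    # independent per-stratum sub-stream (kept under 2^31)
    set.seed((as.integer(seed) + 7919L * i) %% .Machine$integer.max)
    y <- rlnorm(n, p$meanlog, p$sdlog)
    below <- y < lloq
    tibble::tibble(
      subject_id = sprintf("%s-%s%s-%05d", cohort_label, st$cognitive_status,
                           st$amyloid_status, seq_len(n)),
      cohort = cohort_label,
      cognitive_status = st$cognitive_status,
      ptau217 = pmax(y, lloq),
      bloq = below,
      visual_read = st$amyloid_status,
      centiloid = NA_real_,
      age = NA_real_,
      sex = NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "lloq") <- lloq
  out
}

#' Closed-form AUC of the generator's two-stratum model
#'
#' For moment-matched lognormal positive and negative strata the probability
#' that a positive subject's biomarker exceeds a negative subject's is
#' \deqn{\Phi\!\left((\mu_+ - \mu_-)/\sqrt{\sigma_+^2 + \sigma_-^2}\right),}
#' i.e. the ROC area of the (uncensored) generator. Used as the independent
#' check on simulated cohorts.
#'
#' @param mean_pos,sd_pos Target mean/SD of the amyloid-positive stratum.
#' @param mean_neg,sd_neg Target mean/SD of the amyloid-negative stratum.
#' @return AUC as a probability.
#' @export
analytic_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  pp <- lognormal_params(mean_pos, sd_pos)
  pn <- lognormal_params(mean_neg, sd_neg)
  pnorm((pp$meanlog - pn$meanlog) / sqrt(pp$sdlog^2 + pn$sdlog^2))
}
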