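make_cohort <- function(values, labels, status = "CI") {
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_along(values)),
    cohort = "T", cognitive_status = status,
    ptau217 = values, bloq = FALSE, visual_read = labels,
    centiloid = NA_real_, age = NA_real_, sex = NA_character_
  )
}

test_that("weighted PAVA matches the exhaustive monotone-step oracle", {
  # hand-crafted violation instance
  y <- c(0.1, 0.4, 0.2, 0.3, 0.9, 0.5, 0.6, 1.0)
  w <- c(1, 2, 1, 3, 1, 2, 1, 1)
  fit <- ptauscreen:::pava(y, w)
  expect_equal(fit, exhaustive_isotonic(y, w), tolerance = 1e-12)
  expect_true(all(diff(fit) >= -1e-12))
  expect_equal(sum(w * fit), sum(w * y), tolerance = 1e-12)

  set.seed(17)
  for (rep in 1:40) {
    y <- runif(8)
    w <- runif(8, 0.2, 3)
    expect_equal(ptauscreen:::pava(y, w), exhaustive_isotonic(y, w),
                 tolerance = 1e-10)
  }

  # already-monotone input is a fixed point
  y_mono <- sort(runif(8))
  expect_equal(ptauscreen:::pava(y_mono, w), y_mono)
})

test_that("sample-prevalence curves equal unweighted conditional frequencies", {
  set.seed(23)
  inst <- rand_instance(60, tie_values = seq(0.1, 0.6, by = 0.05))
  tab <- make_cohort(inst$values, inst$labels)
  rc <- risk_curve(tab) # prevalence = sample fraction, weights all 1
  ys <- sort(unique(inst$values))
  for (k in seq_along(ys)) {
    above <- inst$values > ys[k]
    below <- !above
    expect_equal(rc$percentile[k + 1], mean(below))
    expect_equal(rc$one_minus_npv[k + 1], mean(inst$d[below]))
    if (any(above)) expect_equal(rc$ppv[k + 1], mean(inst$d[above]))
    at <- inst$values == ys[k]
    expect_equal(rc$risk[k + 1], mean(inst$d[at]))
  }
})

test_that("mixture identity and mean preservation hold at supplied prevalence", {
  set.seed(29)
  inst <- rand_instance(80, tie_values = seq(0.05, 0.9, by = 0.05))
  tab <- make_cohort(inst$values, inst$labels)
  for (est in c("empirical", "monotone")) {
    rc <- risk_curve(tab, prevalence = 0.3, estimator = est)
    interior <- which(!is.na(rc$ppv) & !is.na(rc$one_minus_npv))
    v <- rc$percentile[interior]
    mix <- v * rc$one_minus_npv[interior] + (1 - v) * rc$ppv[interior]
    expect_true(all(abs(mix - 0.3) < 1e-9))

    # prevalence-weighted average of risk equals the supplied prevalence
    dv <- diff(c(0, rc$percentile[-1]))
    expect_equal(sum(dv * rc$risk[-1]), 0.3, tolerance = 1e-9)
  }
})

test_that("monotone estimator produces a non-decreasing, prevalence-bounded curve", {
  set.seed(37)
  inst <- rand_instance(150)
  tab <- make_cohort(inst$values, inst$labels)
  rc <- risk_curve(tab, prevalence = 0.25, estimator = "monotone")
  expect_true(all(diff(rc$risk[-1]) >= -1e-12))
  interior <- which(!is.na(rc$ppv) & !is.na(rc$one_minus_npv))
  expect_true(all(rc$ppv[interior] >= 0.25 - 1e-9))
  expect_true(all(rc$one_minus_npv[interior] <= 0.25 + 1e-9))
  # PPV non-decreasing in the percentile for the monotone fit
  expect_true(all(diff(rc$ppv[interior]) >= -1e-9))
  expect_true(all(rc$risk >= 0 & rc$risk <= 1))
})

test_that("perfect separation gives PPV 1 above the gap and 1-NPV 0 below", {
  values <- c(seq(0.1, 0.15, length.out = 10), seq(0.4, 0.6, length.out = 5))
  labels <- c(rep("NEG", 10), rep("POS", 5))
  rc <- risk_curve(make_cohort(values, labels))
  gap_v <- 10 / 15
  below_gap <- which(rc$percentile <= gap_v & rc$percentile > 0)
  expect_true(all(rc$one_minus_npv[below_gap] == 0))
  ppv_above <- rc$ppv[rc$percentile >= gap_v]
  expect_true(all(is.na(ppv_above) | ppv_above == 1))
})

test_that("curve readout at the rule-out cutoff equals the adjusted screening metrics", {
  ci <- generate_cohort(default_strata()[1:2, ], seed = 19)
  rc <- risk_curve(ci, prevalence = 0.6994)
  at <- risk_at_cutoff(rc, 0.189)
  sm <- screening_summary(ci, 0.189, prevalence = 0.6994)
  expect_equal(at$ppv, sm$ppv, tolerance = 1e-12)
  expect_equal(at$one_minus_npv, 1 - sm$npv, tolerance = 1e-12)
  expect_equal(at$percentile, sm$screen_out, tolerance = 1e-12)
})

test_that("empirical and monotone cumulative curves coincide for large monotone-risk data", {
  # equal log-scale SDs => monotone likelihood ratio => increasing true risk
  set.seed(41)
  n <- 5e4
  d <- runif(n) < 0.35
  values <- ifelse(d, rlnorm(n, log(0.8) - 0.25^2 / 2, 0.25),
                   rlnorm(n, log(0.4) - 0.25^2 / 2, 0.25))
  tab <- make_cohort(values, ifelse(d, "POS", "NEG"))
  emp <- risk_curve(tab)
  mono <- risk_curve(tab, estimator = "monotone")
  ok <- which(!is.na(emp$ppv) & !is.na(mono$ppv))
  expect_lt(max(abs(emp$ppv[ok] - mono$ppv[ok])), 0.02)
  ok2 <- which(!is.na(emp$one_minus_npv) & !is.na(mono$one_minus_npv))
  expect_lt(max(abs(emp$one_minus_npv[ok2] - mono$one_minus_npv[ok2])), 0.02)
})

test_that("integrated-risk export carries reference layers and is deterministic", {
  ci <- generate_cohort(default_strata()[1:2, ], seed = 9)
  emp <- risk_curve(ci, prevalence = 0.6994)
  mono <- risk_curve(ci, prevalence = 0.6994, estimator = "monotone")
  out <- integrated_risk_data(emp, mono, cutoff = 0.189)
  expect_setequal(unique(out$series),
                  c("risk", "ppv", "one_minus_npv", "prevalence",
                    "perfect_risk", "perfect_ppv", "perfect_one_minus_npv",
                    "cutoff"))
  expect_equal(out$value[out$series == "prevalence"], rep(0.6994, 2))
  marker <- out[out$series == "cutoff", ]
  expect_equal(marker$value, 0.189)
  expect_equal(marker$percentile, percentile_at_cutoff(emp, 0.189))
  out2 <- integrated_risk_data(risk_curve(ci, prevalence = 0.6994), mono,
                               cutoff = 0.189)
  expect_identical(out, out2)

  expect_equal(percentile_at_cutoff(emp, min(ci$ptau217)), 0)
  expect_error(integrated_risk_data(emp, mono, cutoff = 99), "range")

  # perfect-assay series coincides with the estimated series on separated data
  values <- c(seq(0.1, 0.15, length.out = 30), seq(0.4, 0.6, length.out = 20))
  labels <- c(rep("NEG", 30), rep("POS", 20))
  sep <- risk_curve(make_cohort(values, labels))
  exp_sep <- integrated_risk_data(sep)
  ppv_est <- exp_sep[exp_sep$series == "ppv", ]
  ppv_perf <- exp_sep[exp_sep$series == "perfect_ppv", ]
  expect_equal(ppv_est$value, ppv_perf$value, tolerance = 1e-12)
})

test_that("tidy and glance expose the curve and its metadata", {
  ci <- generate_cohort(default_strata()[1:2, ], seed = 2)
  rc <- risk_curve(ci, prevalence = 0.6994, estimator = "monotone")
  td <- tidy(rc)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("percentile", "value", "risk", "ppv", "one_minus_npv"))
  gl <- glance(rc)
  expect_equal(gl$n, 538)
  expect_equal(gl$prevalence, 0.6994)
  expect_equal(gl$estimator, "monotone")
  p <- autoplot(rc, cutoff = 0.189)
  expect_s3_class(p, "ggplot")
})

test_that("prevalence outside the open unit interval is rejected", {
  ci <- generate_cohort(default_strata()[1:2, ], seed = 2)
  expect_error(risk_curve(ci, prevalence = 1.2), "probability")
  expect_error(risk_curve(ci, prevalence = 0), "probability")
})
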