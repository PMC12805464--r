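pct2 <- function(x) ptauscreen:::round_half_up(100 * x, 2)

test_that("published CI-column metrics are reproduced from the confusion counts", {
  cm <- list(tp = 390, fn = 4, fp = 102, tn = 42)
  raw <- raw_metrics(cm)
  expect_equal(pct2(raw$sensitivity), 98.98)
  expect_equal(pct2(raw$specificity), 29.17)
  expect_equal(pct2(raw$opa_raw), 80.30)
  adj <- adjusted_metrics(raw$sensitivity, raw$specificity, 0.6994)
  expect_equal(pct2(adj$ppv), 76.48)
  expect_equal(pct2(adj$npv), 92.51)
  expect_equal(pct2(adj$screen_out), 9.48)
  expect_equal(pct2(adj$additional_screening), 1.03)
  expect_equal(pct2(adj$scans_saved), 8.55)
})

test_that("published CU-column metrics are reproduced at the sample prevalence", {
  cm <- list(tp = 214, fn = 10, fp = 683, tn = 703)
  raw <- raw_metrics(cm)
  expect_equal(pct2(raw$sensitivity), 95.54)
  expect_equal(pct2(raw$specificity), 50.72)
  expect_equal(pct2(raw$opa_raw), 56.96)
  adj <- adjusted_metrics(raw$sensitivity, raw$specificity, 224 / 1610)
  expect_equal(pct2(adj$ppv), 23.86)
  expect_equal(pct2(adj$npv), 98.60)
  expect_equal(pct2(adj$screen_out), 44.29)
  expect_equal(pct2(adj$additional_screening), 4.67)
  expect_equal(pct2(adj$scans_saved), 41.68)
  # at the sample prevalence the adjusted values collapse to raw counts
  expect_equal(adj$npv, 703 / 713, tolerance = 1e-12)
  expect_equal(adj$ppv, raw$ppv_raw, tolerance = 1e-12)
  expect_equal(adj$screen_out, 713 / 1610, tolerance = 1e-12)
})

test_that("confusion counting follows the screen-in-at-cutoff boundary convention", {
  tab <- make_table2_cohort(1, 0, 0, 1)
  tab$ptau217 <- c(0.20, 0.10)
  cm <- confusion_at_cutoff(tab, 0.189)
  expect_equal(unlist(cm), c(tp = 1, fn = 0, fp = 0, tn = 1))

  # a value exactly at the cutoff screens in
  tab$ptau217 <- c(0.189, 0.189)
  cm <- confusion_at_cutoff(tab, 0.189)
  expect_equal(unlist(cm), c(tp = 1, fn = 0, fp = 1, tn = 0))

  set.seed(71)
  for (rep in 1:10) {
    inst <- rand_instance(30, tie_values = seq(0.1, 0.4, by = 0.05))
    tab <- tibble::tibble(ptau217 = inst$values, visual_read = inst$labels)
    cutoff <- sample(inst$values, 1)
    cm <- confusion_at_cutoff(tab, cutoff)
    expect_equal(unlist(cm), brute_confusion(inst$values, inst$d, cutoff))
  }
})

test_that("degenerate confusion margins raise named errors", {
  expect_error(raw_metrics(list(tp = 0, fn = 0, fp = 1, tn = 1)), "positive margin")
  expect_error(raw_metrics(list(tp = 1, fn = 1, fp = 0, tn = 0)), "negative margin")
  expect_error(adjusted_metrics(0, 0.5, 0.5), "additional-screening")
  out <- raw_metrics(list(tp = 1, fn = 0, fp = 0, tn = 1))
  expect_true(all(unlist(out) == 1))
})

test_that("perfect assay adjusted metrics behave as expected", {
  adj <- adjusted_metrics(1, 1, 0.3)
  expect_equal(adj$ppv, 1)
  expect_equal(adj$npv, 1)
  expect_equal(adj$screen_out, 0.7)
  expect_equal(adj$additional_screening, 0)
  expect_equal(adj$scans_saved, 0.7)
})

test_that("screening-economics identities hold across random parameter draws", {
  set.seed(83)
  s <- runif(1000, 0.01, 1)
  p <- runif(1000)
  pi <- runif(1000, 0.01, 0.99)
  adj <- adjusted_metrics(s, p, pi)
  expect_true(all(abs(
    adj$scans_saved - (1 - (1 + adj$additional_screening) * (1 - adj$screen_out))
  ) < 1e-12))
  # adjusted metrics at the sample prevalence reproduce raw count metrics
  for (rep in 1:20) {
    inst <- rand_instance(40, tie_values = seq(0.1, 0.5, by = 0.05))
    tab <- tibble::tibble(ptau217 = inst$values, visual_read = inst$labels)
    cutoff <- sample(inst$values, 1)
    cm <- confusion_at_cutoff(tab, cutoff)
    if (cm$tp == 0 || cm$tp + cm$fp == 0 || cm$tn + cm$fn == 0) next
    raw <- raw_metrics(cm)
    adj <- adjusted_metrics(raw$sensitivity, raw$specificity, mean(inst$d))
    expect_equal(adj$ppv, raw$ppv_raw, tolerance = 1e-12)
    expect_equal(adj$npv, raw$npv_raw, tolerance = 1e-12)
  }
})

test_that("the full cutoff grid is ordered, monotone and compositionally correct", {
  set.seed(89)
  inst <- rand_instance(10, tie_values = seq(0.1, 0.3, by = 0.05))
  tab <- tibble::tibble(ptau217 = inst$values, visual_read = inst$labels)
  grid <- cutoff_grid(tab, prevalence = 0.4)
  expect_equal(nrow(grid), length(unique(inst$values)) + 2)
  expect_true(!is.unsorted(grid$cutoff))
  expect_true(all(diff(grid$sensitivity) <= 1e-12))
  expect_true(all(diff(grid$specificity) >= -1e-12))
  expect_equal(grid$sensitivity[1], 1)
  expect_equal(grid$specificity[nrow(grid)], 1)

  for (i in seq_len(nrow(grid))) {
    cm <- confusion_at_cutoff(tab, grid$cutoff[i])
    expect_equal(unlist(cm), unlist(grid[i, c("tp", "fn", "fp", "tn")]))
    if (grid$sensitivity[i] > 0) {
      adj <- adjusted_metrics(grid$sensitivity[i], grid$specificity[i], 0.4)
      expect_equal(grid$ppv[i], adj$ppv)
      expect_equal(grid$npv[i], adj$npv)
      expect_equal(grid$scans_saved[i], adj$scans_saved)
    }
  }

  one <- cutoff_grid(tab, grid = min(inst$values))
  expect_equal(one$sensitivity, 1)
})

test_that("rule-out cutoff selection maximizes screen-out under the NPV floor", {
  # perfectly separated strata: selected cutoff sits in the separation gap
  ci <- tibble::tibble(
    ptau217 = c(seq(0.08, 0.12, length.out = 6), seq(0.5, 0.9, length.out = 14)),
    visual_read = c(rep("NEG", 6), rep("POS", 14))
  )
  cu <- tibble::tibble(
    ptau217 = c(seq(0.09, 0.14, length.out = 17), seq(0.55, 0.95, length.out = 3)),
    visual_read = c(rep("NEG", 17), rep("POS", 3))
  )
  sel <- select_rule_out_cutoff(ci, cu, npv_min = 0.9,
                                prevalence_ci = 0.6994, prevalence_cu = 0.15)
  expect_gt(sel, 0.14)
  expect_lt(sel, 0.5)
  # largest NEG value + half the gap to the smallest POS value
  gap_mid <- (0.14 + 0.5) / 2
  expect_equal(sel, gap_mid)

  # exhaustive-grid oracle on synthetic cohorts
  ci_syn <- generate_cohort(default_strata()[1:2, ], seed = 33)
  cu_syn <- generate_cohort(default_strata()[3:4, ], seed = 33)
  sel_syn <- select_rule_out_cutoff(ci_syn, cu_syn, npv_min = 0.9,
                                    prevalence_ci = 0.6994)
  expect_false(is.na(sel_syn))
  npv_of <- function(tab, cc, pi) {
    cm <- confusion_at_cutoff(tab, cc)
    s <- cm$tp / (cm$tp + cm$fn)
    p <- cm$tn / (cm$tn + cm$fp)
    den <- p * (1 - pi) + (1 - s) * pi
    if (den > 0) p * (1 - pi) / den else NA_real_
  }
  pi_cu <- mean(cu_syn$visual_read == "POS")
  expect_gte(npv_of(ci_syn, sel_syn, 0.6994), 0.9)
  expect_gte(npv_of(cu_syn, sel_syn, pi_cu), 0.9)
  # oracle: largest feasible midpoint over the pooled value grid
  vals <- sort(unique(c(ci_syn$ptau217, cu_syn$ptau217)))
  mids <- (head(vals, -1) + tail(vals, -1)) / 2
  feas <- vapply(mids, function(cc) {
    n1 <- npv_of(ci_syn, cc, 0.6994)
    n2 <- npv_of(cu_syn, cc, pi_cu)
    isTRUE(n1 >= 0.9) && isTRUE(n2 >= 0.9)
  }, logical(1))
  expect_equal(sel_syn, max(mids[feas]))

  # unreachable floor with overlapping strata: NONE sentinel
  overlap <- tibble::tibble(
    ptau217 = rep(c(0.1, 0.2, 0.3), each = 4),
    visual_read = rep(c("POS", "NEG"), 6)
  )
  expect_true(is.na(select_rule_out_cutoff(overlap, overlap, npv_min = 1,
                                           prevalence_ci = 0.5,
                                           prevalence_cu = 0.5)))
})

test_that("sensitivity/specificity curves endpoints and grid mapping are exact", {
  set.seed(97)
  inst <- rand_instance(50, tie_values = seq(0.1, 0.5, by = 0.05))
  tab <- tibble::tibble(ptau217 = inst$values, visual_read = inst$labels)
  ss <- sens_spec_curves(tab)
  expect_equal(ss$sensitivity[1], 1)
  expect_equal(ss$percentile[1], 0)
  expect_equal(ss$specificity[nrow(ss)], 1)
  expect_equal(ss$sensitivity[nrow(ss)], 0)

  # agreement with cutoff_grid through the percentile <-> cutoff mapping:
  # the grid point at value y_k equals any cutoff in (y_k, next value]
  grid_vals <- sort(unique(inst$values))
  for (k in seq_along(grid_vals[-length(grid_vals)])) {
    cc <- (grid_vals[k] + grid_vals[k + 1]) / 2
    cm <- confusion_at_cutoff(tab, cc)
    expect_equal(ss$sensitivity[k + 1], cm$tp / (cm$tp + cm$fn))
    expect_equal(ss$specificity[k + 1], cm$tn / (cm$tn + cm$fp))
  }
  p <- autoplot(ss, cutoff = 0.2)
  expect_s3_class(p, "ggplot")
})
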