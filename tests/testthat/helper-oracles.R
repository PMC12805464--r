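# Independent brute-force oracles and in-code fixtures used across tests.

# Pair-counting AUC: P(pos > neg) + 1/2 P(pos = neg) over all pos x neg pairs.
brute_auc <- function(values, d) {
  x <- values[d]
  y <- values[!d]
  total <- 0
  for (xi in x) {
    for (yj in y) {
      total <- total + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  total / (length(x) * length(y))
}

# DeLong variance via explicit structural components (double loop).
brute_delong_var <- function(values, d) {
  x <- values[d]
  y <- values[!d]
  m <- length(x)
  n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  var(v10) / m + var(v01) / n
}

# Per-record confusion counting at a cutoff (screen-in when value >= cutoff).
brute_confusion <- function(values, d, cutoff) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(values)) {
    pos_test <- values[i] >= cutoff
    if (d[i] && pos_test) tp <- tp + 1
    if (d[i] && !pos_test) fn <- fn + 1
    if (!d[i] && pos_test) fp <- fp + 1
    if (!d[i] && !pos_test) tn <- tn + 1
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Exhaustive isotonic fit for small n: enumerate all partitions of 1..n into
# contiguous blocks, fit each block at its weighted mean, keep fits whose
# block means are non-decreasing, return the one minimizing weighted SSE.
exhaustive_isotonic <- function(y, w) {
  n <- length(y)
  stopifnot(n <= 10)
  best <- NULL
  best_sse <- Inf
  # each of the n-1 gaps is either a block boundary or not
  for (mask in 0:(2^(n - 1) - 1)) {
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    starts <- c(1, bounds + 1)
    ends <- c(bounds, n)
    fit <- numeric(n)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- sum(w[idx] * y[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Cohort tibble engineered to reproduce a given confusion matrix at the
# 0.189 pg/mL rule-out cutoff: screen-ins at 0.30, rule-outs at 0.10.
make_table2_cohort <- function(tp, fn, fp, tn, cognitive_status = "CI") {
  n <- tp + fn + fp + tn
  tibble::tibble(
    subject_id = sprintf("T2-%04d", seq_len(n)),
    cohort = "FIXTURE",
    cognitive_status = cognitive_status,
    ptau217 = c(rep(0.30, tp), rep(0.10, fn), rep(0.30, fp), rep(0.10, tn)),
    bloq = FALSE,
    visual_read = c(rep("POS", tp + fn), rep("NEG", fp + tn)),
    centiloid = NA_real_,
    age = NA_real_,
    sex = NA_character_
  )
}

# Random labelled instance with optional ties.
rand_instance <- function(n, tie_values = NULL, p_pos = 0.5) {
  d <- runif(n) < p_pos
  if (!any(d)) d[1] <- TRUE
  if (all(d)) d[1] <- FALSE
  values <- if (is.null(tie_values)) {
    rlnorm(n, ifelse(d, -0.3, -1.0), 0.5)
  } else {
    sample(tie_values, n, replace = TRUE)
  }
  list(values = values, d = d,
       labels = ifelse(d, "POS", "NEG"))
}
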