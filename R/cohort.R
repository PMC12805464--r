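#' Read a per-subject cohort table from CSV
#'
#' Reads a cohort CSV with one row per participant, validates it, and applies
#' lower-limit-of-quantification (LLoQ) handling: biomarker values below
#' `lloq` are flagged `bloq` and substituted with the LLoQ value itself, so
#' that after loading `ptau217 >= lloq` holds for every record. This mirrors
#' assay practice where below-LLoQ measurements are reported at the observed
#' quantification floor and counted separately.
#'
#' Required columns (case-insensitive): `subject_id`, `cohort`,
#' `cognitive_status` (CI/CU), `ptau217` (pg/mL, > 0), `visual_read`
#' (POS/NEG, may be missing). Optional: `bloq`, `centiloid`, `age`, `sex`.
#' Missing values are encoded as empty strings or `NA`.
#'
#' @param path Path to a CSV file.
#' @param lloq Lower limit of quantification in pg/mL (default 0.0693, the
#'   observed assay floor).
#' @return A tibble with columns `subject_id`, `cohort`, `cognitive_status`,
#'   `ptau217`, `bloq`, `visual_read`, `centiloid`, `age`, `sex`, in input row
#'   order, with the LLoQ stored in attribute `"lloq"`.
#' @seealso [write_cohort()], [generate_cohort()]
#' @export
read_cohort <- function(path, lloq = 0.0693) {
  if (!file.exists(path)) {
    abort(sprintf("cohort file `%s` does not exist.", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = c("", "NA"))
  names(raw) <- tolower(names(raw))
  validate_cohort(raw, lloq = lloq)

  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    cohort = as.character(raw$cohort),
    cognitive_status = toupper(as.character(raw$cognitive_status)),
    ptau217 = as.numeric(raw$ptau217),
    bloq = if ("bloq" %in% names(raw)) as.logical(raw$bloq) else FALSE,
    visual_read = if ("visual_read" %in% names(raw)) {
      toupper(as.character(raw$visual_read))
    } else NA_character_,
    centiloid = if ("centiloid" %in% names(raw)) as.numeric(raw$centiloid) else NA_real_,
    age = if ("age" %in% names(raw)) as.numeric(raw$age) else NA_real_,
    sex = if ("sex" %in% names(raw)) toupper(as.character(raw$sex)) else NA_character_
  )
  out$bloq <- dplyr::coalesce(out$bloq, FALSE) | out$ptau217 < lloq
  out$ptau217 <- pmax(out$ptau217, lloq)
  attr(out, "lloq") <- lloq
  out
}

#' Validate a cohort table
#'
#' Checks the schema and row-level invariants of a per-subject cohort table
#' and raises an informative error on the first violation. Returns (invisibly)
#' a validation report suitable for JSON export.
#'
#' @param data A data frame of subject records (pre- or post-LLoQ handling).
#' @param lloq Lower limit of quantification in pg/mL; must be positive.
#' @return Invisibly, a list with counts: `n`, `n_bloq` (values below `lloq`
#'   or flagged), `n_missing_visual_read`, `n_missing_centiloid`, `lloq`.
#' @export
validate_cohort <- function(data, lloq = 0.0693) {
  if (!is.numeric(lloq) || length(lloq) != 1 || is.na(lloq) || lloq <= 0) {
    abort("`lloq` must be a single positive number.")
  }
  names(data) <- tolower(names(data))
  required <- c("subject_id", "cohort", "cognitive_status", "ptau217", "visual_read")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  y <- suppressWarnings(as.numeric(data$ptau217))
  bad <- which(is.na(y) | y <= 0)
  if (length(bad) > 0) {
    abort(sprintf("`ptau217` must be a positive number; invalid at row(s) %s.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  cs <- toupper(as.character(data$cognitive_status))
  bad_cs <- which(is.na(cs) | !cs %in% c("CI", "CU"))
  if (length(bad_cs) > 0) {
    abort(sprintf("`cognitive_status` must be CI or CU; invalid at row(s) %s.",
                  paste(head(bad_cs, 5), collapse = ", ")))
  }
  vr <- toupper(as.character(data$visual_read))
  bad_vr <- which(!is.na(vr) & !vr %in% c("POS", "NEG"))
  if (length(bad_vr) > 0) {
    abort(sprintf("`visual_read` must be POS, NEG or missing; invalid at row(s) %s.",
                  paste(head(bad_vr, 5), collapse = ", ")))
  }
  if (anyDuplicated(data$subject_id) > 0) {
    abort("`subject_id` values must be unique within a cohort table.")
  }
  bloq <- if ("bloq" %in% names(data)) {
    dplyr::coalesce(as.logical(data$bloq), FALSE)
  } else {
    rep(FALSE, nrow(data))
  }
  cl <- if ("centiloid" %in% names(data)) as.numeric(data$centiloid) else rep(NA_real_, nrow(data))
  invisible(list(
    n = nrow(data),
    n_bloq = sum(bloq | y < lloq),
    n_missing_visual_read = sum(is.na(vr)),
    n_missing_centiloid = sum(is.na(cl)),
    lloq = lloq
  ))
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes the standard cohort schema so that a
#' read/write/read round trip reproduces the records field-wise. Missing
#' values are written as `NA`.
#'
#' @param data A cohort tibble as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  cols <- c("subject_id", "cohort", "cognitive_status", "ptau217", "bloq",
            "visual_read", "centiloid", "age", "sex")
  readr::write_csv(data[, intersect(cols, names(data))], path, na = "NA")
  invisible(path)
}

#' Classify Centiloid values at a positivity threshold
#'
#' Binary amyloid classification on the Centiloid (CL) scale with a closed
#' lower bound: a scan is positive iff `cl >= threshold`. Conventional
#' thresholds are 24 and 40 CL.
#'
#' @param cl Numeric vector of Centiloid values; missing values are an error
#'   (unclassifiable records must be removed first).
#' @param threshold Positive scalar threshold in CL units.
#' @return Factor with levels `NEG < POS`.
#' @export
classify_centiloid <- function(cl, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0) {
    abort("`threshold` must be a single positive number (conventionally 24 or 40).")
  }
  if (length(cl) == 0) abort("`cl` is empty.")
  if (anyNA(cl)) {
    abort("`cl` contains missing values: records without a Centiloid value are unclassifiable.")
  }
  factor(ifelse(cl >= threshold, "POS", "NEG"), levels = c("NEG", "POS"))
}

#' Overall percent agreement between two binary classifications
#'
#' Fraction of positions where two POS/NEG label sequences agree. Pairs with
#' a missing label on either side must be dropped before calling.
#'
#' @param labels_a,labels_b Equal-length POS/NEG (or logical) vectors.
#' @return Agreement proportion in \[0, 1\].
#' @export
concordance_opa <- function(labels_a, labels_b) {
  if (length(labels_a) == 0) abort("inputs are empty.")
  if (length(labels_a) != length(labels_b)) {
    abort("`labels_a` and `labels_b` must have equal length.")
  }
  a <- as_pos(labels_a, "labels_a")
  b <- as_pos(labels_b, "labels_b")
  if (anyNA(a) || anyNA(b)) {
    abort("missing labels: drop incomplete pairs before computing concordance.")
  }
  mean(a == b)
}

#' Visual-read / Centiloid concordance table
#'
#' Overall percent agreement between the amyloid PET visual read and
#' Centiloid-threshold classification, for each requested threshold. Records
#' missing either reference are dropped per threshold.
#'
#' @param data Cohort tibble with `visual_read` and `centiloid` columns.
#' @param thresholds Numeric vector of CL thresholds (default `c(24, 40)`).
#' @return Tibble with columns `threshold`, `n`, `concordance`.
#' @export
cl_concordance <- function(data, thresholds = c(24, 40)) {
  purrr::map_dfr(thresholds, function(th) {
    keep <- !is.na(data$centiloid) & !is.na(data$visual_read)
    if (!any(keep)) {
      abort("no records with both `visual_read` and `centiloid` available.")
    }
    cls <- classify_centiloid(data$centiloid[keep], th)
    tibble::tibble(
      threshold = th,
      n = sum(keep),
      concordance = concordance_opa(data$visual_read[keep], cls)
    )
  })
}

#' Linear SUVr to Centiloid conversion
#'
#' Generic linear map from a tracer standardized uptake value ratio (SUVr) to
#' the Centiloid scale, `CL = slope * suvr + intercept`. Tracer-specific
#' calibration coefficients are supplied by the user.
#'
#' @param suvr Numeric vector of SUVr values.
#' @param slope CL change per SUVr unit; must be non-zero.
#' @param intercept CL value at SUVr = 0.
#' @return Numeric vector of Centiloid values.
#' @export
suvr_to_centiloid <- function(suvr, slope, intercept) {
  if (!is.numeric(slope) || length(slope) != 1 || is.na(slope) || slope == 0) {
    abort("`slope` must be a single non-zero number.")
  }
  slope * suvr + intercept
}

#' @rdname suvr_to_centiloid
#' @param cl Numeric vector of Centiloid values to map back to SUVr.
#' @export
centiloid_to_suvr <- function(cl, slope, intercept) {
  if (!is.numeric(slope) || length(slope) != 1 || is.na(slope) || slope == 0) {
    abort("`slope` must be a single non-zero number.")
  }
  (cl - intercept) / slope
}
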