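# Internal helpers shared across modules.

# Round half away from zero (Table-style percent formatting), as opposed to
# base round()'s round-half-even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a proportion as a percentage string with half-up rounding.
fmt_percent <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f"), round_half_up(100 * x, digits))
}

# Coerce an amyloid-status vector (character/factor "POS"/"NEG", case
# insensitive, or logical) to logical is-positive. NA passes through.
as_pos <- function(x, arg = "labels") {
  if (is.logical(x)) {
    return(x)
  }
  x <- toupper(as.character(x))
  bad <- !is.na(x) & !x %in% c("POS", "NEG")
  if (any(bad)) {
    abort(sprintf(
      "`%s` must be POS/NEG (or logical); found %s.",
      arg, paste(unique(x[bad]), collapse = ", ")
    ))
  }
  x == "POS"
}

# Pull a column by tidy-eval expression and check it exists.
pull_col <- function(data, col, arg) {
  nm <- as_name(enquo(col))
  if (!nm %in% names(data)) {
    abort(sprintf("column `%s` (for `%s`) not found in `data`.", nm, arg))
  }
  data[[nm]]
}

check_prob <- function(x, arg, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) {
    abort(sprintf("`%s` must be a single probability in %s.",
                  arg, if (open) "(0, 1)" else "[0, 1]"))
  }
  invisible(x)
}
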