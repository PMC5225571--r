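# Shared helpers: age convention, safe sampling, report-style formatting.

# Age everywhere in the package is completed years under a 365.25-day-year
# convention: floor(days_between / 365.25). Internally consistent for the
# generator, matching and demographics; avoids calendar edge cases.
age_at <- function(birth_date, at_date) {
  floor(as.numeric(as.Date(at_date) - as.Date(birth_date)) / 365.25)
}

# sample() without the length-1 surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format an odds ratio the way the study tables print them
#'
#' Three significant figures; values of 100 or more rendered as integers;
#' undefined values (zero cells) rendered as \code{"--"}.
#'
#' @param x numeric vector of odds ratios (NA for undefined).
#' @return character vector.
#' @export
fmt_or <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    if (is.na(v)) {
      out[i] <- "--"
    } else {
      v3 <- signif(v, 3)
      out[i] <- if (v3 >= 100) {
        sprintf("%d", round(v3))
      } else if (v3 >= 10) {
        sprintf("%.1f", v3)
      } else {
        sprintf("%.2f", v3)
      }
    }
  }
  out
}

#' Format a proportion as a percentage with one decimal
#'
#' @param p numeric vector of proportions in [0, 1].
#' @return character vector like \code{"82.2"}.
#' @export
fmt_pct <- function(p) {
  ifelse(is.na(p), "--", sprintf("%.1f", 100 * p))
}

# validate probability-in-(0,1) arguments with a useful message
check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 1)) {
    stop(what, " must lie strictly in (0, 1)", call. = FALSE)
  }
  invisible(x)
}
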