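# 2x2 machinery: exposure tables, cross-product odds ratios with Wald
# intervals, demographic group comparisons, and median/IQR summaries.

#' Build a 2x2 exposure table from counts
#'
#' Cell convention: \code{a} = exposed members of group 1, \code{b} = exposed
#' members of group 2, \code{c} = unexposed group 1, \code{d} = unexposed
#' group 2, so OR = (a d)/(b c).
#'
#' @param a,b,c,d non-negative counts.
#' @param groups length-2 character: group names.
#' @param exposure exposure (category) name.
#' @return an object of class \code{two_by_two}.
#' @export
as_two_by_two <- function(a, b, c, d, groups = c("case", "control"),
                          exposure = "exposure") {
  stopifnot(length(a) == 1, a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = a, b = b, c = c, d = d,
                 groups = groups, exposure = exposure),
            class = "two_by_two")
}

#' Tabulate category exposure for two groups of transactions
#'
#' @param transactions a [build_transactions()] table (or any data frame with
#'   \code{items} list column).
#' @param category the exposure category name.
#' @param group grouping vector aligned with rows (default the
#'   \code{group} column); must have exactly two non-empty levels. The first
#'   level (factor order, or \code{"case"} first when present) is group 1.
#' @return a \code{two_by_two}.
#' @export
two_by_two <- function(transactions, category, group = transactions$group) {
  if (!is.factor(group)) {
    lev <- unique(group)
    if (all(c("case", "control") %in% lev)) lev <- c("case", "control")
    group <- factor(group, levels = lev)
  }
  group <- droplevels(group)
  if (nlevels(group) != 2) stop("exactly two non-empty groups required")
  has <- vapply(transactions$items, function(it) category %in% it, logical(1))
  g1 <- group == levels(group)[1]
  as_two_by_two(
    a = sum(g1 & has), b = sum(!g1 & has),
    c = sum(g1 & !has), d = sum(!g1 & !has),
    groups = levels(group), exposure = category
  )
}

#' Cross-product odds ratio with Wald confidence interval
#'
#' OR = (a d)/(b c); the CI is Wald on the log scale,
#' exp(ln OR ± z sqrt(1/a + 1/b + 1/c + 1/d)). Any zero cell makes the
#' estimate undefined (NA, rendered \code{"--"}) unless the
#' Haldane-Anscombe continuity correction (+0.5 to every cell) is requested.
#' A zero cell is a defined outcome, not an error. For a single binary
#' exposure this estimator coincides with the exponentiated coefficient of a
#' univariable logistic regression of group on exposure.
#'
#' @param t a \code{two_by_two}.
#' @param level confidence level (default 0.95).
#' @param correction add 0.5 to all cells (default FALSE).
#' @return an object of class \code{or_estimate} with fields \code{or},
#'   \code{ci_low}, \code{ci_high}, \code{level}, \code{significant} (CI
#'   excludes 1) and the source \code{table}.
#' @export
odds_ratio <- function(t, level = 0.95, correction = FALSE) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0) && !correction) {
    est <- list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                level = level, significant = NA, table = t)
    class(est) <- "or_estimate"
    return(est)
  }
  if (correction) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * cc)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * z * se)
  est <- list(or = or, ci_low = ci[1], ci_high = ci[2], level = level,
              significant = ci[1] > 1 || ci[2] < 1, table = t)
  class(est) <- "or_estimate"
  est
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(x$table$exposure, ": OR = ", fmt_or(x$or), sep = "")
  if (!is.na(x$or)) {
    cat(", ", format(100 * x$level), "% CI = ", fmt_or(x$ci_low), "-",
        fmt_or(x$ci_high), if (isTRUE(x$significant)) " *" else "", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Compare demographics between the two cohort groups
#'
#' Chi-squared tests (without continuity correction) for sex and for the
#' banded age distribution (0-19, 20-39, 40-59, 60+), and a two-sample t test
#' for age. With exact age/sex matching all P values are 1 by construction.
#' Degenerate variables (a single observed level, or zero age variance) are
#' reported as P = 1 with a warning.
#'
#' @param cohort a [match_controls()] cohort (needs \code{group}, \code{sex},
#'   \code{age}).
#' @return data frame with columns \code{variable}, \code{test},
#'   \code{statistic}, \code{p_value}.
#' @export
compare_demographics <- function(cohort) {
  g <- factor(cohort$group)
  if (nlevels(g) != 2 || any(table(g) < 2)) {
    stop("two groups with at least 2 members each required")
  }
  chisq_p <- function(v, what) {
    v <- factor(v)
    v <- droplevels(v)
    if (nlevels(v) < 2) {
      warning(what, " has a single level; P reported as 1")
      return(c(0, 1))
    }
    ct <- suppressWarnings(stats::chisq.test(table(g, v), correct = FALSE))
    c(unname(ct$statistic), ct$p.value)
  }
  sex_res <- chisq_p(cohort$sex, "sex")
  bands <- cut(cohort$age, breaks = c(-Inf, 19, 39, 59, Inf),
               labels = c("0-19", "20-39", "40-59", "60+"))
  band_res <- chisq_p(bands, "age band")
  age_res <- tryCatch({
    tt <- stats::t.test(cohort$age ~ g)
    c(unname(tt$statistic), tt$p.value)
  }, error = function(e) {
    warning("degenerate age distribution; P reported as 1")
    c(0, 1)
  })
  data.frame(
    variable = c("sex", "age", "age_band"),
    test = c("chi-squared", "t", "chi-squared"),
    statistic = c(sex_res[1], age_res[1], band_res[1]),
    p_value = c(sex_res[2], age_res[2], band_res[2]),
    stringsAsFactors = FALSE
  )
}

#' Median and interquartile range
#'
#' Linear-interpolation quantiles (R type 7).
#'
#' @param x non-empty numeric vector.
#' @return named numeric: \code{median}, \code{q1}, \code{q3}.
#' @export
median_iqr <- function(x) {
  if (length(x) == 0 || all(is.na(x))) stop("empty age vector")
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
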