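# Matched bootstrap: resample cases with replacement, re-match controls by
# exact age/sex from the eligible pool, re-evaluate a fixed rule list, and
# aggregate metrics over B replicates.

percentile_ci <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(c(NA_real_, NA_real_))
  xs <- sort(x)
  alpha <- (1 - level) / 2
  # order statistics (inverse-ECDF quantile): x_(ceil(B p)), p > 0; the tiny
  # epsilon keeps ceil() stable against floating-point products like
  # 40 * 0.025 = 1 + 2e-16
  lo <- xs[max(1L, ceiling(length(xs) * alpha - 1e-9))]
  hi <- xs[min(length(xs), ceiling(length(xs) * (1 - alpha) - 1e-9))]
  c(lo, hi)
}

#' Matched bootstrap of rule metrics
#'
#' Each replicate draws \code{nrow(cases)} cases with replacement (duplicates
#' kept as distinct transactions), matches every drawn case to \code{ratio}
#' controls of identical sex and age drawn from the pool (without replacement
#' within a case, with replacement across cases and replicates), rebuilds the
#' transaction set and recomputes support, confidence, lift and the
#' case-control odds ratio for every input rule. After \code{B} replicates
#' the per-rule means, percentile confidence intervals (2.5/97.5 order
#' statistics at the default level) and the Monte-Carlo standard error of
#' each mean are reported. Replicates with an undefined OR (zero cell) are
#' excluded from the OR mean and CI; \code{n_defined_or} counts the rest. A
#' metric is flagged significant when its percentile CI excludes the null
#' (1 for lift and OR).
#'
#' @param cases data frame \code{person_id}, \code{sex}, \code{age},
#'   \code{items} (list column), e.g. from [person_attributes()].
#' @param control_pool same shape; the eligible control pool (no index
#'   carriers). Every case (sex, age) stratum must hold at least
#'   \code{ratio} pool members.
#' @param rules a \code{rule_set} restricted to index-antecedent rules.
#' @param B number of replicates (default 1000).
#' @param ratio controls matched per drawn case (default 4).
#' @param seed RNG seed for the whole B-replicate run.
#' @param ci_level percentile CI level (default 0.95).
#' @param resample_cases set FALSE to skip case resampling (each replicate
#'   then uses the original cases once); a diagnostic mode under which a
#'   forced-pool single replicate reproduces the point evaluation exactly.
#' @param keep_replicates if TRUE the per-replicate metric matrices (B x
#'   rules) are attached as attribute \code{"replicates"}.
#' @param policy,age_band stratum-thinness handling as in [match_controls()]:
#'   \code{"fail"} (default) refuses a case stratum with fewer than
#'   \code{ratio} pool members; \code{"relax"} widens it to \code{± age_band}
#'   years.
#' @return a \code{bootstrap_summary} data frame, one row per rule:
#'   mean/CI/SE for support, confidence and lift, mean/CI for the OR over
#'   defined replicates, \code{n_defined_or}, and significance flags.
#' @export
bootstrap_rules <- function(cases, control_pool, rules, B = 1000L, ratio = 4L,
                            seed = 1L, ci_level = 0.95, resample_cases = TRUE,
                            keep_replicates = FALSE,
                            policy = c("fail", "relax"), age_band = 1L) {
  policy <- match.arg(policy)
  stopifnot(B >= 1, ratio >= 1, nrow(rules) >= 1, nrow(cases) >= 1)
  nc <- nrow(cases)
  np <- nrow(control_pool)
  # per-case eligible pool indices: exact (sex, age), widened to ±age_band
  # for thin strata under policy = "relax"
  key_pools <- lapply(seq_len(nc), function(i) {
    elig <- which(control_pool$sex == cases$sex[i] &
                    control_pool$age == cases$age[i])
    if (length(elig) < ratio && policy == "relax") {
      elig <- which(control_pool$sex == cases$sex[i] &
                      abs(control_pool$age - cases$age[i]) <= age_band)
    }
    elig
  })
  short <- which(lengths(key_pools) < ratio)
  if (length(short) > 0) {
    stop("control pool has fewer than ", ratio,
         " members for stratum (sex age): ",
         paste(unique(paste(cases$sex[short], cases$age[short])), collapse = ", "))
  }

  R <- nrow(rules)
  ys <- rules$consequent_items
  case_has_y <- vapply(ys, function(y) {
    vapply(cases$items, function(it) all(y %in% it), logical(1))
  }, logical(nc))
  ctrl_has_y <- vapply(ys, function(y) {
    vapply(control_pool$items, function(it) all(y %in% it), logical(1))
  }, logical(np))
  case_has_y <- matrix(case_has_y, nrow = nc, ncol = R)
  ctrl_has_y <- matrix(ctrl_has_y, nrow = np, ncol = R)

  set.seed(seed)
  n_total <- nc + nc * ratio
  n_ctrl <- nc * ratio
  s_mat <- c_mat <- l_mat <- or_mat <- matrix(NA_real_, B, R)
  for (b in seq_len(B)) {
    ci <- if (resample_cases) sample.int(nc, nc, replace = TRUE) else seq_len(nc)
    di <- integer(n_ctrl)
    for (j in seq_len(nc)) {
      pk <- key_pools[[ci[j]]]
      di[((j - 1L) * ratio + 1L):(j * ratio)] <- if (length(pk) == ratio) pk else
        pk[sample.int(length(pk), ratio)]
    }
    a <- colSums(case_has_y[ci, , drop = FALSE])
    bb <- colSums(ctrl_has_y[di, , drop = FALSE])
    s_mat[b, ] <- a / n_total
    c_mat[b, ] <- a / nc
    sy <- (a + bb) / n_total
    l_mat[b, ] <- ifelse(sy > 0, (a / nc) / sy, NA_real_)
    ok <- a > 0 & bb > 0 & a < nc & bb < n_ctrl
    or_mat[b, ok] <- (a[ok] * (n_ctrl - bb[ok])) / (bb[ok] * (nc - a[ok]))
  }

  summarise_metric <- function(mat, j) {
    v <- mat[, j]
    vd <- v[!is.na(v)]
    ci <- percentile_ci(v, ci_level)
    c(mean = if (length(vd)) mean(vd) else NA_real_,
      lo = ci[1], hi = ci[2],
      se = if (length(vd) > 1) stats::sd(vd) / sqrt(length(vd)) else 0,
      n_def = length(vd))
  }
  out <- do.call(rbind, lapply(seq_len(R), function(j) {
    s <- summarise_metric(s_mat, j)
    cf <- summarise_metric(c_mat, j)
    lf <- summarise_metric(l_mat, j)
    or <- summarise_metric(or_mat, j)
    data.frame(
      antecedent = rules$antecedent[j], consequent = rules$consequent[j],
      relations = rules$relations[j],
      mean_support = s["mean"], support_lo = s["lo"], support_hi = s["hi"],
      support_se = s["se"],
      mean_confidence = cf["mean"], confidence_lo = cf["lo"],
      confidence_hi = cf["hi"], confidence_se = cf["se"],
      mean_lift = lf["mean"], lift_lo = lf["lo"], lift_hi = lf["hi"],
      lift_se = lf["se"],
      lift_significant = !is.na(lf["lo"]) && (lf["lo"] > 1 || lf["hi"] < 1),
      mean_or = or["mean"], or_lo = or["lo"], or_hi = or["hi"],
      or_significant = if (or["n_def"] > 0) (or["lo"] > 1 || or["hi"] < 1) else NA,
      n_defined_or = as.integer(or["n_def"]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "B") <- as.integer(B)
  attr(out, "ratio") <- as.integer(ratio)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "ci_level") <- ci_level
  attr(out, "ci_method") <- "percentile (order statistics of the replicate metrics)"
  if (keep_replicates) {
    attr(out, "replicates") <- list(support = s_mat, confidence = c_mat,
                                    lift = l_mat, or = or_mat)
  }
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("Matched bootstrap over B = ", attr(x, "B"), " replicates (",
      attr(x, "ratio"), " controls per case); ",
      attr(x, "ci_method"), "\n", sep = "")
  show <- data.frame(
    rule = paste(x$antecedent, "->", x$consequent),
    support = sprintf("%s [%s-%s]", fmt_pct(x$mean_support),
                      fmt_pct(x$support_lo), fmt_pct(x$support_hi)),
    lift = sprintf("%.2f [%.2f-%.2f]", x$mean_lift, x$lift_lo, x$lift_hi),
    or = ifelse(x$n_defined_or == 0, "--",
                sprintf("%s [%s-%s]", fmt_or(x$mean_or), fmt_or(x$or_lo),
                        fmt_or(x$or_hi))),
    stringsAsFactors = FALSE
  )
  print.data.frame(utils::head(show, 15), row.names = FALSE)
  invisible(x)
}
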