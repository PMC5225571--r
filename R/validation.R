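# Train/test partition and held-out re-evaluation of discovered rules with
# per-rule case-control odds ratios.

#' Split a cohort (or its transactions) into training and testing sets
#'
#' Person-level random split, stratified by case/control group: the training
#' set holds \code{round(train_fraction * n)} members in total, of which
#' \code{round(train_fraction * n_cases)} are cases and the remainder
#' controls. (For the study sizes 292/1168 at 2/3 this yields 195/778 train
#' and 97/390 test, the sizes under which the source tables' per-rule odds
#' ratios are internally consistent.)
#'
#' @param x a cohort or transactions data frame with a \code{group} column.
#' @param train_fraction fraction in (0, 1), default 2/3.
#' @param seed RNG seed; the partition is deterministic given it.
#' @return list with elements \code{train} and \code{test}, each ordered by
#'   person id and preserving the input's class and attributes.
#' @export
split_cohort <- function(x, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, nrow(x) > 0,
            "group" %in% names(x))
  is_case <- x$group == "case"
  n <- nrow(x)
  n_case <- sum(is_case)
  n_ctrl <- n - n_case
  n_train <- round(train_fraction * n)
  n_case_train <- round(train_fraction * n_case)
  n_ctrl_train <- n_train - n_case_train
  if (n_case_train < 1 || n_case_train >= n_case ||
      n_ctrl_train < 1 || n_ctrl_train >= n_ctrl) {
    stop("partition would leave an empty group")
  }
  set.seed(seed)
  case_rows <- which(is_case)
  ctrl_rows <- which(!is_case)
  train_rows <- c(resample(case_rows, n_case_train),
                  resample(ctrl_rows, n_ctrl_train))
  take <- function(rows) {
    out <- x[sort(rows), , drop = FALSE]
    out <- out[order(out$person_id), , drop = FALSE]
    rownames(out) <- NULL
    for (at in setdiff(names(attributes(x)), c("names", "row.names", "class"))) {
      attr(out, at) <- attr(x, at)
    }
    class(out) <- class(x)
    out
  }
  list(train = take(train_rows), test = take(setdiff(seq_len(n), train_rows)))
}

#' Evaluate discovered rules on a transaction set
#'
#' For each index-antecedent rule, recomputes support, confidence and lift on
#' the given transactions, counts the cases and controls carrying the full
#' consequent set, and estimates the case-control odds ratio of the
#' consequent pattern via [odds_ratio()] (undefined, \code{NA}, when a cell
#' is zero).
#'
#' @param rules a \code{rule_set} (or data frame with
#'   \code{consequent_items}); antecedents must equal the index item.
#' @param transactions a [build_transactions()] table with case and control
#'   rows.
#' @param level confidence level for the per-rule OR (default 0.95).
#' @return a \code{rule_evaluation} data frame: \code{relations},
#'   \code{support}, \code{confidence}, \code{lift}, \code{antecedent},
#'   \code{consequent}, \code{n_cases_with}, \code{n_controls_with},
#'   \code{or}, \code{ci_low}, \code{ci_high}, \code{significant}.
#' @export
evaluate_rules <- function(rules, transactions, level = 0.95) {
  index_label <- attr(transactions, "index_label") %||% "BPD"
  stopifnot(all(vapply(rules$antecedent_items, identical, logical(1), index_label)))
  is_case <- transactions$group == "case"
  n <- nrow(transactions)
  n_cases <- sum(is_case)
  n_ctrl <- n - n_cases
  if (n_cases == 0 || n_ctrl == 0) stop("both groups must be non-empty")
  rows <- lapply(seq_len(nrow(rules)), function(i) {
    y <- rules$consequent_items[[i]]
    has_y <- vapply(transactions$items, function(it) all(y %in% it), logical(1))
    has_xy <- has_y & vapply(transactions$items, function(it) index_label %in% it,
                             logical(1))
    a <- sum(has_y & is_case)
    b <- sum(has_y & !is_case)
    s <- sum(has_xy) / n
    cf <- s / (n_cases / n)
    sy <- (a + b) / n
    lf <- if (sy > 0) cf / sy else NA_real_
    est <- odds_ratio(as_two_by_two(a, b, n_cases - a, n_ctrl - b,
                                    exposure = paste(y, collapse = " & ")),
                      level = level)
    data.frame(
      relations = 1 + length(y), support = s, confidence = cf, lift = lf,
      antecedent = index_label, consequent = paste(y, collapse = " & "),
      n_cases_with = a, n_controls_with = b,
      or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
      significant = est$significant, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows) %||%
    data.frame(relations = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_cases") <- n_cases
  attr(out, "n_controls") <- n_ctrl
  class(out) <- c("rule_evaluation", "data.frame")
  out
}

#' Evaluate a single rule
#'
#' @param rule one-row \code{rule_set} slice, or a list with elements
#'   \code{antecedent_items} and \code{consequent_items}.
#' @inheritParams evaluate_rules
#' @return one-row \code{rule_evaluation}.
#' @export
evaluate_rule <- function(rule, transactions, level = 0.95) {
  if (!is.data.frame(rule)) {
    x_items <- as.character(rule$antecedent_items)
    y_items <- as.character(rule$consequent_items)
    rule <- data.frame(antecedent = paste(x_items, collapse = " & "),
                       consequent = paste(y_items, collapse = " & "),
                       stringsAsFactors = FALSE)
    rule$antecedent_items <- list(x_items)
    rule$consequent_items <- list(y_items)
  }
  evaluate_rules(rule, transactions, level = level)
}
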