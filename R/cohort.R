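# Cohort construction: incident case selection, complete-case filtering,
# exact 1:ratio age/sex matching, and the transaction table for rule mining.

#' Select incident index-disorder cases
#'
#' A person is a case if their first-ever occurrence of the index code falls
#' inside the enrollment window; the index date is that first occurrence.
#' Persons whose first occurrence predates the window are excluded (incidence
#' requirement).
#'
#' @param diagnoses data frame with \code{person_id}, \code{icd9_code},
#'   \code{diagnosis_date}.
#' @param enrollment_window Date vector of length 2 (closed range).
#' @param index_code the index diagnosis code (default \code{"301.83"}).
#' @return data frame \code{person_id}, \code{index_date}, ordered by id.
#' @export
select_cases <- function(diagnoses, enrollment_window, index_code = "301.83") {
  enrollment_window <- as.Date(enrollment_window)
  stopifnot(length(enrollment_window) == 2,
            enrollment_window[1] <= enrollment_window[2])
  d <- diagnoses[!is.na(diagnoses$icd9_code) & diagnoses$icd9_code == index_code &
                   !is.na(diagnoses$diagnosis_date), , drop = FALSE]
  if (nrow(d) == 0) {
    return(data.frame(person_id = character(0), index_date = as.Date(character(0)),
                      stringsAsFactors = FALSE))
  }
  first <- tapply(as.numeric(as.Date(d$diagnosis_date)), d$person_id, min)
  first_date <- as.Date(as.numeric(first), origin = "1970-01-01")
  keep <- first_date >= enrollment_window[1] & first_date <= enrollment_window[2]
  out <- data.frame(person_id = names(first)[keep], index_date = first_date[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop records with any missing required field (complete-case analysis)
#'
#' @param x data frame.
#' @param required_fields columns that must be non-missing (default: all).
#' @return \code{x} restricted to complete rows; the number dropped is
#'   reported via \code{message()} and attached as attribute
#'   \code{"n_dropped"}.
#' @export
filter_complete_cases <- function(x, required_fields = names(x)) {
  stopifnot(all(required_fields %in% names(x)))
  miss <- rep(FALSE, nrow(x))
  for (f in required_fields) {
    v <- x[[f]]
    miss <- miss | is.na(v) | (is.character(v) & !is.na(v) & v == "")
  }
  out <- x[!miss, , drop = FALSE]
  rownames(out) <- NULL
  message("complete-case filter dropped ", sum(miss), " of ", nrow(x), " records")
  attr(out, "n_dropped") <- sum(miss)
  out
}

#' Match controls to cases by exact age and sex
#'
#' For each case, \code{ratio} controls are drawn uniformly at random without
#' replacement (across the whole cohort: a person serves as control for at
#' most one case) from pool members of identical sex and identical age in
#' completed years at the case's index date. Controls inherit the matched
#' case's index date for comorbidity windowing.
#'
#' @param cases data frame \code{person_id}, \code{sex}, \code{birth_date},
#'   \code{index_date}.
#' @param pool data frame \code{person_id}, \code{sex}, \code{birth_date};
#'   must exclude all index-code carriers (checked against case ids only).
#' @param ratio controls per case (default 4).
#' @param seed RNG seed; the cohort is a deterministic function of it.
#' @param policy \code{"fail"} (default) stops when a case lacks enough exact
#'   matches; \code{"relax"} widens to \code{± age_band} years and records the
#'   relaxation.
#' @param age_band age tolerance used under \code{policy = "relax"}.
#' @return a \code{cohort}: data frame \code{person_id}, \code{group},
#'   \code{matched_case_id}, \code{sex}, \code{age}, \code{index_date},
#'   ordered by person id, with attributes \code{match_ratio}, \code{seed}
#'   and \code{n_relaxed}.
#' @export
match_controls <- function(cases, pool, ratio = 4L, seed = 1L,
                           policy = c("fail", "relax"), age_band = 1L) {
  policy <- match.arg(policy)
  stopifnot(ratio >= 1)
  if (any(cases$person_id %in% pool$person_id)) {
    stop("pool must exclude the cases themselves")
  }
  if (anyDuplicated(cases$person_id) || anyDuplicated(pool$person_id)) {
    stop("duplicate person ids")
  }
  cases <- cases[order(cases$person_id), , drop = FALSE]
  set.seed(seed)
  n_case <- nrow(cases)
  if (n_case == 0) {
    empty <- data.frame(person_id = character(0), group = character(0),
                        matched_case_id = character(0), sex = character(0),
                        age = integer(0), index_date = as.Date(character(0)),
                        stringsAsFactors = FALSE)
    attr(empty, "match_ratio") <- as.integer(ratio)
    attr(empty, "seed") <- as.integer(seed)
    attr(empty, "n_relaxed") <- 0L
    class(empty) <- c("cohort", "data.frame")
    return(empty)
  }
  case_age <- age_at(cases$birth_date, cases$index_date)
  if (n_case > 0 && any(case_age < 0)) stop("negative age at index date")
  pool_birth <- as.numeric(as.Date(pool$birth_date))
  available <- rep(TRUE, nrow(pool))
  ctrl_rows <- vector("list", n_case)
  n_relaxed <- 0L
  for (i in seq_len(n_case)) {
    idx_num <- as.numeric(as.Date(cases$index_date[i]))
    pool_age <- floor((idx_num - pool_birth) / 365.25)
    elig <- which(available & pool$sex == cases$sex[i] & pool_age == case_age[i])
    if (length(elig) < ratio) {
      if (policy == "fail") {
        stop("insufficient exact matches for case ", cases$person_id[i],
             " (sex ", cases$sex[i], ", age ", case_age[i], "): ",
             length(elig), " eligible, ", ratio, " needed; ",
             "use policy = \"relax\" to widen the age band")
      }
      elig <- which(available & pool$sex == cases$sex[i] &
                      abs(pool_age - case_age[i]) <= age_band)
      if (length(elig) < ratio) {
        stop("insufficient matches for case ", cases$person_id[i],
             " even within ±", age_band, " years")
      }
      n_relaxed <- n_relaxed + 1L
    }
    sel <- resample(elig, ratio)
    available[sel] <- FALSE
    ctrl_rows[[i]] <- data.frame(
      person_id = pool$person_id[sel], group = "control",
      matched_case_id = cases$person_id[i], sex = pool$sex[sel],
      age = pool_age[sel], index_date = as.Date(cases$index_date[i]),
      stringsAsFactors = FALSE
    )
  }
  case_df <- data.frame(
    person_id = cases$person_id, group = "case",
    matched_case_id = NA_character_, sex = cases$sex, age = case_age,
    index_date = as.Date(cases$index_date), stringsAsFactors = FALSE
  )
  cohort <- rbind(case_df, do.call(rbind, ctrl_rows))
  if (is.null(cohort)) {
    cohort <- case_df
  }
  cohort <- cohort[order(cohort$person_id), , drop = FALSE]
  rownames(cohort) <- NULL
  attr(cohort, "match_ratio") <- as.integer(ratio)
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "n_relaxed") <- n_relaxed
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Build the transaction table for rule mining
#'
#' One transaction per cohort member: the index item for cases, plus the
#' member's diagnosis categories within the comorbidity window. By the
#' matched-design convention the window anchor is the (matched case's) index
#' date stored on the cohort row; \code{anchor = "own_index"} instead anchors
#' each member at a date supplied in \code{own_index_dates} (useful when the
#' ground-truth generation dated each person's comorbidities around their own
#' pseudo-index date).
#'
#' @param cohort a [match_controls()] cohort (or any data frame with
#'   \code{person_id}, \code{group}, \code{index_date}).
#' @param diagnoses claims diagnosis records for at least the cohort members.
#' @param map a \code{category_map}.
#' @param window_years comorbidity window half-width (default 3, closed).
#' @param anchor \code{"case_index"} (default) or \code{"own_index"}.
#' @param own_index_dates named Date vector (names = person ids) used when
#'   \code{anchor = "own_index"}.
#' @return a \code{transactions} data frame: \code{person_id}, \code{group},
#'   \code{items} (list column of category-name vectors), ordered by id.
#' @export
build_transactions <- function(cohort, diagnoses, map = default_category_map(),
                               window_years = 3, anchor = c("case_index", "own_index"),
                               own_index_dates = NULL) {
  anchor <- match.arg(anchor)
  idx <- as.Date(cohort$index_date)
  if (anchor == "own_index") {
    stopifnot(!is.null(own_index_dates), !is.null(names(own_index_dates)))
    idx <- as.Date(own_index_dates[cohort$person_id])
    if (any(is.na(idx))) stop("own_index_dates missing for some cohort members")
  }
  d <- diagnoses[diagnoses$person_id %in% cohort$person_id &
                   !is.na(diagnoses$icd9_code) & !is.na(diagnoses$diagnosis_date),
                 , drop = FALSE]
  ok <- is_icd9_code(d$icd9_code)
  d <- d[ok, , drop = FALSE]
  items <- rep(list(character(0)), nrow(cohort))
  if (nrow(d) > 0) {
    row_of <- match(d$person_id, cohort$person_id)
    in_win <- abs(as.numeric(as.Date(d$diagnosis_date) - idx[row_of])) <=
      round(window_years * 365.25)
    d <- d[in_win, , drop = FALSE]
    row_of <- row_of[in_win]
    if (nrow(d) > 0) {
      cl <- categorize_codes(d$icd9_code, map)
      lens <- lengths(cl)
      per_row <- split(unlist(cl, use.names = FALSE), rep(row_of, lens))
      hit <- as.integer(names(per_row))
      for (k in seq_along(hit)) {
        items[[hit[k]]] <- sort(unique(per_row[[k]]))
      }
    }
  }
  is_case <- cohort$group == "case"
  for (i in which(is_case)) {
    items[[i]] <- sort(unique(c(map$index_label, items[[i]])))
  }
  for (i in which(!is_case)) {
    items[[i]] <- setdiff(items[[i]], map$index_label)
  }
  out <- data.frame(person_id = cohort$person_id, group = cohort$group,
                    stringsAsFactors = FALSE)
  out$items <- items
  out <- out[order(out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "index_label") <- map$index_label
  class(out) <- c("transactions", "data.frame")
  out
}

#' Per-person attributes for bootstrap matching
#'
#' Convenience builder for [bootstrap_rules()] inputs: sex, completed-years
#' age at the person's own (pseudo-)index date, and the person's category
#' item set anchored at that date.
#'
#' @param persons person records (\code{person_id}, \code{sex},
#'   \code{birth_date}).
#' @param diagnoses diagnosis records.
#' @param index_dates named Date vector (names = person ids).
#' @param map a \code{category_map}.
#' @param window_years comorbidity window half-width.
#' @param is_case logical vector aligned with \code{persons} rows; case rows
#'   get the index item added to their item set.
#' @return data frame \code{person_id}, \code{sex}, \code{age}, \code{items}.
#' @export
person_attributes <- function(persons, diagnoses, index_dates,
                              map = default_category_map(), window_years = 3,
                              is_case = rep(FALSE, nrow(persons))) {
  idx <- as.Date(index_dates[persons$person_id])
  if (any(is.na(idx))) stop("index_dates missing for some persons")
  pseudo <- data.frame(person_id = persons$person_id,
                       group = ifelse(is_case, "case", "control"),
                       index_date = idx, stringsAsFactors = FALSE)
  tr <- build_transactions(pseudo, diagnoses, map, window_years)
  ord <- match(tr$person_id, persons$person_id)
  out <- data.frame(person_id = tr$person_id,
                    sex = persons$sex[ord],
                    age = age_at(persons$birth_date[ord], idx[ord]),
                    stringsAsFactors = FALSE)
  out$items <- tr$items
  out
}

#' @export
print.cohort <- function(x, ...) {
  n_case <- sum(x$group == "case")
  cat("Matched cohort: ", n_case, " cases, ", sum(x$group == "control"),
      " controls (ratio ", attr(x, "match_ratio"), ":1, ",
      attr(x, "n_relaxed"), " relaxed matches)\n", sep = "")
  invisible(x)
}
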