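# End-to-end driver: generate (or load) claims, build the matched cohort,
# compute the six report tables, and write a reproducible bundle.

#' Run the full comorbidity analysis pipeline
#'
#' Generates a synthetic claims population (unless one is supplied), selects
#' incident index cases, applies complete-case filtering, matches controls
#' 1:\code{ratio} on exact age/sex, builds category transactions, and produces
#' the six study-style tables: demographics (1), physical-category odds
#' ratios (2), psychiatric odds ratios (3) — both with within-case
#' female-vs-male subgroup estimates — training-set rules (4), their held-out
#' test-set evaluation (5), and the matched-bootstrap aggregation (6).
#'
#' @param config a [claims_config()]; its seed drives generation, and the
#'   matching/split/bootstrap seeds are derived from it unless given.
#' @param claims optional list(persons, diagnoses) to analyse instead of
#'   generating (e.g. from [read_claims()]).
#' @param out_dir if non-NULL, tables are written there as CSV plus a
#'   \code{metadata.json} sidecar.
#' @param ratio controls per case (default 4).
#' @param window_years comorbidity window half-width (default 3).
#' @param train_fraction training fraction for rule validation (default 2/3).
#' @param k,min_lift,consequent_sizes rule-mining controls (see
#'   [mine_rules()]).
#' @param B bootstrap replicates (default 1000).
#' @param map a \code{category_map}.
#' @param seeds named list with any of \code{match}, \code{split},
#'   \code{bootstrap}; defaults derived from \code{config$seed}.
#' @param arm_items item universe for mining; defaults to the psychiatric
#'   categories (with their unions) plus the index label.
#' @param match_policy,age_band thin-stratum handling forwarded to
#'   [match_controls()] and [bootstrap_rules()].
#' @return an object of class \code{comorbidity_report}: list with the
#'   cohort, transactions, rules, \code{tables} (table1..table6) and run
#'   \code{metadata}.
#' @export
run_pipeline <- function(config = claims_config(), claims = NULL, out_dir = NULL,
                         ratio = 4L, window_years = 3, train_fraction = 2 / 3,
                         k = 10000L, min_lift = 1, consequent_sizes = 2:3,
                         B = 1000L, map = default_category_map(),
                         seeds = list(), arm_items = NULL,
                         match_policy = c("fail", "relax"), age_band = 1L) {
  match_policy <- match.arg(match_policy)
  seeds <- list(
    match = seeds$match %||% (config$seed + 1L),
    split = seeds$split %||% (config$seed + 2L),
    bootstrap = seeds$bootstrap %||% (config$seed + 3L)
  )
  if (is.null(claims)) {
    claims <- generate_population(config)
  }
  persons <- claims$persons
  diagnoses <- claims$diagnoses

  persons_cc <- suppressMessages(
    filter_complete_cases(persons, c("person_id", "sex", "birth_date"))
  )
  diagnoses_cc <- suppressMessages(
    filter_complete_cases(diagnoses, c("person_id", "icd9_code", "diagnosis_date"))
  )
  n_dropped <- c(persons = attr(persons_cc, "n_dropped"),
                 diagnoses = attr(diagnoses_cc, "n_dropped"))

  cases <- select_cases(diagnoses_cc, config$enrollment_window, map$index_code)
  if (nrow(cases) < 2) stop("fewer than 2 incident cases in the population")
  carrier_ids <- unique(diagnoses_cc$person_id[diagnoses_cc$icd9_code == map$index_code])
  pool <- persons_cc[!(persons_cc$person_id %in% carrier_ids), , drop = FALSE]
  case_persons <- merge(cases, persons_cc, by = "person_id")
  cohort <- match_controls(case_persons, pool, ratio = ratio, seed = seeds$match,
                           policy = match_policy, age_band = age_band)
  transactions <- build_transactions(cohort, diagnoses_cc, map, window_years)

  # --- table 1: demographics -------------------------------------------
  tab1 <- local({
    cmp <- compare_demographics(cohort)
    per_group <- function(g) {
      a <- cohort$age[cohort$group == g]
      s <- cohort$sex[cohort$group == g]
      bands <- table(cut(a, c(-Inf, 19, 39, 59, Inf),
                         labels = c("0-19", "20-39", "40-59", "60+")))
      mi <- median_iqr(a)
      c(n = length(a), female = sum(s == "female"), male = sum(s == "male"),
        setNames(as.numeric(bands), paste0("age_", names(bands))),
        age_median = unname(mi["median"]), age_q1 = unname(mi["q1"]),
        age_q3 = unname(mi["q3"]))
    }
    cs <- per_group("case")
    ct <- per_group("control")
    df <- data.frame(statistic = names(cs), case = as.numeric(cs),
                     control = as.numeric(ct), stringsAsFactors = FALSE)
    attr(df, "p_values") <- cmp
    df
  })

  # --- tables 2 and 3: category odds ratios ----------------------------
  or_table <- function(categories) {
    is_case <- transactions$group == "case"
    fem <- transactions$person_id %in% cohort$person_id[cohort$sex == "female"]
    case_tr <- transactions[is_case, , drop = FALSE]
    case_sex <- ifelse(fem[is_case], "female", "male")
    do.call(rbind, lapply(categories, function(g) {
      has <- vapply(transactions$items, function(it) g %in% it, logical(1))
      cc <- odds_ratio(two_by_two(transactions, g))
      fm <- odds_ratio(two_by_two(case_tr, g, group = factor(case_sex,
                                  levels = c("female", "male"))))
      data.frame(
        category = g,
        pct_female_cases = mean(has[is_case & fem]),
        pct_male_cases = mean(has[is_case & !fem]),
        or_female_vs_male = fm$or, fm_ci_low = fm$ci_low, fm_ci_high = fm$ci_high,
        fm_significant = fm$significant,
        pct_cases = mean(has[is_case]), pct_controls = mean(has[!is_case]),
        or_case_vs_control = cc$or, cc_ci_low = cc$ci_low, cc_ci_high = cc$ci_high,
        cc_significant = cc$significant,
        stringsAsFactors = FALSE
      )
    }))
  }
  tab2 <- or_table(unique(map$physical$name))
  psych_names <- c(names(map$psychiatric), names(map$unions))
  tab3 <- or_table(psych_names)

  # --- tables 4-6: rule mining, validation, bootstrap ------------------
  if (is.null(arm_items)) arm_items <- c(map$index_label, psych_names)
  parts <- split_cohort(transactions, train_fraction, seed = seeds$split)
  rules <- mine_rules(parts$train, k = k, min_lift = min_lift,
                      antecedent = map$index_label,
                      consequent_sizes = consequent_sizes, items = arm_items)
  if (nrow(rules) > 0) {
    tab4 <- evaluate_rules(rules, parts$train)
    tab5 <- evaluate_rules(rules, parts$test)
    case_ids <- cohort$person_id[cohort$group == "case"]
    # own (pseudo-)index date per person: the generator's ground truth when
    # available, else the case index date / enrollment-window midpoint
    own_idx <- if (!is.null(claims$truth)) {
      setNames(as.Date(claims$truth$index_date), claims$truth$person_id)
    } else {
      mid <- config$enrollment_window[1] +
        floor(as.numeric(diff(config$enrollment_window)) / 2)
      ids <- persons_cc$person_id
      v <- setNames(rep(mid, length(ids)), ids)
      v[cases$person_id] <- as.Date(cases$index_date)
      v
    }
    case_attr <- person_attributes(
      persons_cc[persons_cc$person_id %in% case_ids, , drop = FALSE],
      diagnoses_cc, own_idx, map, window_years, is_case = TRUE
    )
    pool_attr <- person_attributes(pool, diagnoses_cc, own_idx, map, window_years)
    tab6 <- bootstrap_rules(case_attr, pool_attr, rules, B = B, ratio = ratio,
                            seed = seeds$bootstrap, policy = match_policy,
                            age_band = age_band)
  } else {
    tab4 <- tab5 <- tab6 <- NULL
  }

  metadata <- list(
    package_version = as.character(utils::packageVersion("comorbidARM")),
    seeds = c(generation = config$seed, seeds),
    n_persons = nrow(persons), n_cases = nrow(cases),
    n_controls = sum(cohort$group == "control"),
    match_ratio = ratio, window_years = window_years,
    train_fraction = train_fraction, B = B,
    complete_case_dropped = as.list(n_dropped),
    bootstrap_ci_method = if (!is.null(tab6)) attr(tab6, "ci_method") else NULL,
    n_rules = if (is.null(tab4)) 0L else nrow(rules)
  )
  report <- list(
    cohort = cohort, transactions = transactions, rules = rules,
    tables = list(table1_demographics = tab1, table2_physical_or = tab2,
                  table3_psychiatric_or = tab3, table4_rules_train = tab4,
                  table5_rules_test = tab5, table6_bootstrap = tab6),
    metadata = metadata
  )
  class(report) <- "comorbidity_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a report bundle to CSV files plus a JSON metadata sidecar
#'
#' Percentages are rendered to one decimal and odds ratios to three
#' significant figures (\code{"--"} for undefined), mirroring the study's
#' table precision so diffs between runs are meaningful.
#'
#' @param report a \code{comorbidity_report}.
#' @param out_dir output directory (created if needed).
#' @return the output paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, na = "--")
    paths <<- c(paths, p)
  }
  t1 <- report$tables$table1_demographics
  w(t1, "table1_demographics")
  w(attr(t1, "p_values"), "table1_p_values")
  fmt_cat <- function(df) {
    out <- df
    for (col in grep("^pct_", names(df), value = TRUE)) out[[col]] <- fmt_pct(df[[col]])
    for (col in grep("^(or_|fm_ci|cc_ci)", names(df), value = TRUE)) {
      out[[col]] <- fmt_or(df[[col]])
    }
    out
  }
  w(fmt_cat(report$tables$table2_physical_or), "table2_physical_or")
  w(fmt_cat(report$tables$table3_psychiatric_or), "table3_psychiatric_or")
  fmt_rules <- function(df) {
    if (is.null(df)) return(data.frame())
    data.frame(
      relations = df$relations, support = fmt_pct(df$support),
      confidence = fmt_pct(df$confidence), lift = sprintf("%.2f", df$lift),
      rule = paste(df$antecedent, "->", df$consequent),
      n_cases = df$n_cases_with, n_controls = df$n_controls_with,
      or = fmt_or(df$or), ci_low = fmt_or(df$ci_low), ci_high = fmt_or(df$ci_high),
      significant = df$significant, stringsAsFactors = FALSE
    )
  }
  w(fmt_rules(report$tables$table4_rules_train), "table4_rules_train")
  w(fmt_rules(report$tables$table5_rules_test), "table5_rules_test")
  t6 <- report$tables$table6_bootstrap
  if (!is.null(t6)) {
    w(data.frame(
      relations = t6$relations,
      rule = paste(t6$antecedent, "->", t6$consequent),
      mean_support = fmt_pct(t6$mean_support),
      support_ci = paste0(fmt_pct(t6$support_lo), "-", fmt_pct(t6$support_hi)),
      mean_confidence = fmt_pct(t6$mean_confidence),
      confidence_ci = paste0(fmt_pct(t6$confidence_lo), "-", fmt_pct(t6$confidence_hi)),
      mean_lift = sprintf("%.2f", t6$mean_lift),
      lift_ci = sprintf("%.2f-%.2f", t6$lift_lo, t6$lift_hi),
      mean_or = fmt_or(t6$mean_or),
      or_ci = ifelse(t6$n_defined_or == 0, "--",
                     paste0(fmt_or(t6$or_lo), "-", fmt_or(t6$or_hi))),
      n_defined_or = t6$n_defined_or, stringsAsFactors = FALSE
    ), "table6_bootstrap")
  } else {
    w(data.frame(), "table6_bootstrap")
  }
  meta_path <- file.path(out_dir, "metadata.json")
  jsonlite::write_json(report$metadata, meta_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, meta_path))
}

#' @export
print.comorbidity_report <- function(x, ...) {
  m <- x$metadata
  cat("comorbidity_report: ", m$n_cases, " cases / ", m$n_controls,
      " controls (1:", m$match_ratio, " matched), ",
      m$n_rules, " rules mined, B = ", m$B, " bootstrap replicates\n", sep = "")
  invisible(x)
}
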