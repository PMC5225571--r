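tiny_diag <- function(...) {
  rows <- list(...)
  data.frame(
    person_id = vapply(rows, `[[`, character(1), 1),
    icd9_code = vapply(rows, `[[`, character(1), 2),
    diagnosis_date = as.Date(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
}

test_that("select_cases applies the first-occurrence incidence rule", {
  win <- as.Date(c("2003-01-01", "2006-12-31"))
  d <- tiny_diag(
    list("in_window", "301.83", "2004-05-01"),
    list("in_window", "301.83", "2005-01-01"),       # later repeat ignored
    list("prevalent", "301.83", "2002-06-01"),       # before window: excluded
    list("prevalent", "301.83", "2004-06-01"),
    list("no_index", "296.20", "2004-01-01"),
    list("late", "301.83", "2007-03-01")             # after window: excluded
  )
  sel <- select_cases(d, win)
  expect_equal(sel$person_id, "in_window")
  expect_equal(sel$index_date, as.Date("2004-05-01"))
  expect_equal(nrow(select_cases(d[d$person_id == "no_index", ], win)), 0)
})

test_that("complete-case filtering drops exactly the rows with missing fields", {
  df <- data.frame(person_id = sprintf("p%02d", 1:20),
                   sex = rep(c("female", "male"), 10),
                   birth_date = as.Date("1980-01-01") + 1:20,
                   stringsAsFactors = FALSE)
  expect_message(out <- filter_complete_cases(df), "dropped 0")
  expect_equal(nrow(out), 20)
  df$sex[3] <- NA
  df$birth_date[c(3, 7)] <- NA
  expect_message(out <- filter_complete_cases(df), "dropped 2")
  expect_equal(out$person_id, df$person_id[-c(3, 7)])
  # independent tally on randomly blanked fields
  set.seed(42)
  big <- data.frame(a = as.character(1:2000), b = as.character(1:2000),
                    stringsAsFactors = FALSE)
  big$a[runif(2000) < 0.05] <- NA
  big$b[runif(2000) < 0.05] <- NA
  keep <- sum(!is.na(big$a) & !is.na(big$b))
  expect_equal(nrow(suppressMessages(filter_complete_cases(big))), keep)
})

test_that("matching yields ratio controls per case with exact age/sex marginals", {
  st <- make_matched_study(test_config(seed = 2), match_seed = 5)
  coh <- st$cohort
  n_case <- sum(coh$group == "case")
  expect_equal(sum(coh$group == "control"), 4 * n_case)
  # exact marginal preservation
  cs <- coh[coh$group == "case", ]
  ct <- coh[coh$group == "control", ]
  expect_equal(as.vector(table(ct$sex)), 4 * as.vector(table(cs$sex)))
  expect_equal(as.vector(table(factor(ct$age, levels = sort(unique(cs$age))))),
               4 * as.vector(table(factor(cs$age, levels = sort(unique(cs$age))))))
  # per-case match quality: same sex, same age, inherited index date
  for (i in sample(which(coh$group == "control"), 50)) {
    case_row <- coh[coh$person_id == coh$matched_case_id[i] &
                      coh$group == "case", ]
    expect_equal(coh$sex[i], case_row$sex)
    expect_equal(coh$age[i], case_row$age)
    expect_equal(coh$index_date[i], case_row$index_date)
  }
  # no person twice
  expect_false(anyDuplicated(coh$person_id) > 0)
  # determinism
  st2 <- make_matched_study(test_config(seed = 2), match_seed = 5)
  expect_identical(coh, st2$cohort)
})

test_that("matching policies: deterministic forced pools, failure, relaxation", {
  cases <- data.frame(person_id = c("c1", "c2"), sex = c("female", "male"),
                      birth_date = as.Date(c("1980-06-01", "1975-06-01")),
                      index_date = as.Date("2004-01-01"), stringsAsFactors = FALSE)
  # pool with exactly 4 eligible per case: selection is forced for any seed
  mk_pool <- function() {
    data.frame(
      person_id = sprintf("k%02d", 1:8),
      sex = rep(c("female", "male"), each = 4),
      birth_date = rep(as.Date(c("1980-03-01", "1975-03-01")), each = 4),
      stringsAsFactors = FALSE
    )
  }
  c1 <- match_controls(cases, mk_pool(), ratio = 4, seed = 1)
  c2 <- match_controls(cases, mk_pool(), ratio = 4, seed = 999)
  expect_setequal(c1$person_id, c2$person_id)
  expect_equal(sum(c1$group == "control"), 8)
  # 0 cases -> empty cohort
  c0 <- match_controls(cases[0, ], mk_pool(), ratio = 4, seed = 1)
  expect_equal(nrow(c0), 0)
  # insufficient pool: fail by default, relax within the age band on request
  short_pool <- mk_pool()[c(1:2, 5:8), ]
  expect_error(match_controls(cases, short_pool, ratio = 4, seed = 1),
               "insufficient")
  near <- mk_pool()
  near$birth_date[1:2] <- as.Date("1981-03-01")  # one year younger
  relaxed <- match_controls(cases, near, ratio = 4, seed = 1,
                            policy = "relax", age_band = 1)
  expect_equal(attr(relaxed, "n_relaxed"), 1L)
  expect_equal(sum(relaxed$group == "control"), 8)
})

test_that("transactions match an independent per-person recount", {
  st <- make_matched_study(test_config(n_persons = 2500, seed = 4),
                           match_seed = 7, policy = "relax")
  tr <- st$transactions
  coh <- st$cohort
  expect_equal(tr$person_id, sort(coh$person_id))
  # independent recount: per-member person_category_set at the cohort anchor
  idx <- sample(nrow(tr), 40)
  for (i in idx) {
    row <- coh[coh$person_id == tr$person_id[i], ]
    d <- st$pop$diagnoses[st$pop$diagnoses$person_id == tr$person_id[i], ]
    want <- person_category_set(d, row$index_date, 3)
    if (row$group == "case") want <- sort(unique(c("BPD", want)))
    expect_equal(tr$items[[i]], want, label = tr$person_id[i])
  }
  # cases carry the index item, controls never do
  has_bpd <- vapply(tr$items, function(it) "BPD" %in% it, logical(1))
  expect_equal(has_bpd, tr$group == "case", ignore_attr = TRUE)
  # per-category counts equal an independent tally
  g <- "Anxiety disorder"
  n_tally <- sum(vapply(tr$items, function(it) g %in% it, logical(1)))
  own <- vapply(seq_len(nrow(tr)), function(i) {
    row <- coh[coh$person_id == tr$person_id[i], ]
    d <- st$pop$diagnoses[st$pop$diagnoses$person_id == tr$person_id[i], ]
    g %in% person_category_set(d, row$index_date, 3)
  }, logical(1))
  expect_equal(n_tally, sum(own))
})
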