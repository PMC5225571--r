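test_that("the generator is a deterministic function of its seed", {
  cfg <- test_config(n_persons = 800, seed = 7)
  pop1 <- generate_population(cfg)
  pop2 <- generate_population(cfg)
  expect_identical(pop1, pop2)
  pop3 <- generate_population(test_config(n_persons = 800, seed = 8))
  expect_false(identical(pop1$diagnoses, pop3$diagnoses))
})

test_that("generated populations satisfy their structural invariants", {
  cfg <- test_config(n_persons = 1500, seed = 3)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop$persons), 1500)
  expect_false(anyDuplicated(pop$persons$person_id) > 0)
  expect_true(all(is_icd9_code(pop$diagnoses$icd9_code)))
  # index carriers get 301.83 dated at their index date, inside the window
  idx_rec <- pop$diagnoses[pop$diagnoses$icd9_code == "301.83", ]
  expect_setequal(idx_rec$person_id, pop$truth$person_id[pop$truth$is_case])
  expect_true(all(idx_rec$diagnosis_date >= cfg$enrollment_window[1] &
                    idx_rec$diagnosis_date <= cfg$enrollment_window[2]))
  # ages non-negative at every diagnosis date
  bd <- pop$persons$birth_date[match(pop$diagnoses$person_id, pop$persons$person_id)]
  expect_true(all(pop$diagnoses$diagnosis_date > bd))
  # every emitted code maps back to its intended category; comorbidity dates
  # stay within the offset window of the person's own index date
  own_idx <- pop$truth$index_date[match(pop$diagnoses$person_id, pop$truth$person_id)]
  off <- abs(as.numeric(pop$diagnoses$diagnosis_date - own_idx))
  expect_true(all(off <= cfg$comorbidity_offset_years * 365.25))
  # truth membership equals what the emitted codes imply (own-index anchor)
  g <- "Depressive disorder"
  with_code <- unique(pop$diagnoses$person_id[
    vapply(comorbidARM:::categorize_codes(pop$diagnoses$icd9_code),
           function(cc) g %in% cc, logical(1))])
  expect_setequal(with_code, pop$truth$person_id[pop$truth[[g]]])
})

test_that("marginal prevalences and odds ratios are recovered in-sample", {
  # moderate n here; the full 3-SE recovery at n = 2e5 runs in the
  # acceptance suite
  cfg <- test_config(n_persons = 30000, index_prevalence = 0.02, seed = 5,
                     prevalences = c("Anxiety disorder" = 0.10,
                                     "Sleep disorder" = 0.15),
                     ors = c("Anxiety disorder" = 1, "Sleep disorder" = 6))
  pop <- generate_population(cfg)
  tr <- pop$truth
  p0 <- mean(tr$`Sleep disorder`[!tr$is_case])
  se <- sqrt(0.15 * 0.85 / sum(!tr$is_case))
  expect_lt(abs(p0 - 0.15), 3 * se)
  emp_or <- function(g) {
    a <- sum(tr[[g]] & tr$is_case); b <- sum(tr[[g]] & !tr$is_case)
    cc <- sum(!tr[[g]] & tr$is_case); d <- sum(!tr[[g]] & !tr$is_case)
    list(or = (a * d) / (b * cc), se = sqrt(1 / a + 1 / b + 1 / cc + 1 / d))
  }
  null_or <- emp_or("Anxiety disorder")
  expect_lt(abs(log(null_or$or)), 3 * null_or$se)
  strong <- emp_or("Sleep disorder")
  expect_lt(abs(log(strong$or) - log(6)), 3 * strong$se)
})

test_that("auto-logistic couplings induce positive association between categories", {
  cfg <- test_config(
    n_persons = 20000, seed = 9,
    prevalences = c("Anxiety disorder" = 0.10, "Sleep disorder" = 0.10),
    ors = c("Anxiety disorder" = 1, "Sleep disorder" = 1),
    couplings = data.frame(a = "Anxiety disorder", b = "Sleep disorder",
                           gamma = 1.5)
  )
  tr <- generate_population(cfg)$truth
  tab <- table(tr$`Anxiety disorder`, tr$`Sleep disorder`)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(or, exp(1.0))
  # couplings must respect the category ordering
  expect_error(test_config(
    prevalences = c("Anxiety disorder" = 0.1, "Sleep disorder" = 0.1),
    ors = c("Anxiety disorder" = 1, "Sleep disorder" = 1),
    couplings = data.frame(a = "Sleep disorder", b = "Anxiety disorder",
                           gamma = 1)), "earlier")
})

test_that("configuration validation rejects degenerate inputs", {
  expect_error(claims_config(n_persons = 0), "positive")
  expect_error(claims_config(index_prevalence = 1.2), "\\(0, 1\\)")
  expect_error(test_config(ors = c("Anxiety disorder" = -2)), "positive")
  expect_error(claims_config(category_prevalences = c("No codes here" = 0.1),
                             category_ors = c("No codes here" = 2)),
               "representative code")
  expect_error(claims_config(missing_fraction = 1), "missing_fraction")
})

test_that("claims round-trip through CSV and JSONL files", {
  cfg <- test_config(n_persons = 120, seed = 21)
  pop <- generate_population(cfg)
  for (fmt in c("csv", "jsonl")) {
    dir <- file.path(tempdir(), paste0("claims_", fmt))
    write_claims(pop$persons, pop$diagnoses, dir, format = fmt)
    back <- read_claims(dir, format = fmt)
    expect_equal(back$persons, pop$persons, ignore_attr = TRUE)
    d1 <- pop$diagnoses[order(pop$diagnoses$person_id, pop$diagnoses$diagnosis_date,
                              pop$diagnoses$icd9_code), ]
    d2 <- back$diagnoses[order(back$diagnoses$person_id, back$diagnoses$diagnosis_date,
                               back$diagnoses$icd9_code), ]
    rownames(d1) <- rownames(d2) <- NULL
    expect_equal(d2, d1, ignore_attr = TRUE)
  }
})

test_that("empty populations round-trip as header-only files", {
  persons <- data.frame(person_id = character(0), sex = character(0),
                        birth_date = as.Date(character(0)), stringsAsFactors = FALSE)
  diagnoses <- data.frame(person_id = character(0), icd9_code = character(0),
                          diagnosis_date = as.Date(character(0)), stringsAsFactors = FALSE)
  dir <- file.path(tempdir(), "claims_empty")
  write_claims(persons, diagnoses, dir)
  back <- read_claims(dir)
  expect_equal(nrow(back$persons), 0)
  expect_equal(nrow(back$diagnoses), 0)
})

test_that("malformed rows are rejected with line and field named", {
  dir <- file.path(tempdir(), "claims_bad")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("person_id,sex,birth_date", "p1,female,1980-02-30"),
             file.path(dir, "persons.csv"))
  writeLines("person_id,sex,birth_date,icd9_code,diagnosis_date",
             file.path(dir, "diagnoses.csv"))
  expect_error(read_claims(dir), "birth_date.*line 1")
  writeLines(c("person_id,sex,birth_date", "p1,female,1980-01-30"),
             file.path(dir, "persons.csv"))
  writeLines(c("person_id,sex,birth_date,icd9_code,diagnosis_date",
               "p1,female,1980-01-30,abc,2004-01-01"),
             file.path(dir, "diagnoses.csv"))
  expect_error(read_claims(dir), "icd9_code.*line 1")
})

test_that("missing-data injection blanks roughly the configured fraction", {
  cfg <- test_config(n_persons = 5000, seed = 13, missing_fraction = 0.05)
  pop <- generate_population(cfg)
  frac <- mean(is.na(pop$diagnoses$icd9_code))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  # default config injects nothing
  expect_false(anyNA(generate_population(test_config(n_persons = 500))$diagnoses))
})
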