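# Synthetic claims generator.  Emulates a claims registry slice with a rare
# index disorder (301.83), an age structure targeting median 25 / IQR 21-33,
# 65% female, and per-category case-vs-non-case odds ratios encoded directly
# in a logistic membership model, so that every downstream stage can be
# exercised against known ground truth.

#' Default baseline category prevalences (among non-cases)
#'
#' Control-arm comorbidity rates of the emulated study population. Categories
#' whose control-arm rate is printed as zero in the source tables are given
#' small plausible stand-in rates.
#'
#' @return named numeric vector of probabilities.
#' @export
default_category_prevalences <- function() {
  c(
    "Depressive disorder" = 0.0205,
    "Bipolar disorder" = 0.0223,
    "Anxiety disorder" = 0.0634,
    "Sleep disorder" = 0.0882,
    "Alcohol use disorder" = 0.0026,
    "Opioid use disorder" = 0.002,
    "Amphetamine use disorder" = 0.002,
    "ADHD" = 0.002,
    "Mental retardation" = 0.0026,
    "Autistic spectrum disorder" = 0.0005,
    "Eating disorder" = 0.001,
    "Respiratory system" = 0.882,
    "Nervous system and sense organs" = 0.529,
    "Digestive system" = 0.819,
    "Skin and subcutaneous tissue" = 0.560,
    "Injury and poisoning" = 0.532,
    "Infectious and parasitic" = 0.356,
    "Genitourinary system" = 0.463,
    "Musculoskeletal system" = 0.421,
    "Congenital anomalies" = 0.0163,
    "Endocrine, metabolic and immunity" = 0.143,
    "Neoplasm" = 0.115,
    "Circulatory system" = 0.111,
    "Blood and blood-forming organs" = 0.0479
  )
}

#' Default target case-vs-non-case odds ratios per category
#'
#' Magnitudes follow the emulated study's univariable estimates; categories
#' with undefined printed estimates (zero control cells) carry stand-in values
#' chosen to reproduce the printed case-arm rates.
#'
#' @return named numeric vector of odds ratios.
#' @export
default_category_ors <- function() {
  c(
    "Depressive disorder" = 220,
    "Bipolar disorder" = 261,
    "Anxiety disorder" = 13.2,
    "Sleep disorder" = 6.82,
    "Alcohol use disorder" = 56.3,
    "Opioid use disorder" = 10.5,
    "Amphetamine use disorder" = 12.3,
    "ADHD" = 9,
    "Mental retardation" = 6.11,
    "Autistic spectrum disorder" = 7,
    "Eating disorder" = 24.6,
    "Respiratory system" = 2.04,
    "Nervous system and sense organs" = 2.15,
    "Digestive system" = 2.85,
    "Skin and subcutaneous tissue" = 1.85,
    "Injury and poisoning" = 4.84,
    "Infectious and parasitic" = 1.71,
    "Genitourinary system" = 1.78,
    "Musculoskeletal system" = 2.45,
    "Congenital anomalies" = 2.14,
    "Endocrine, metabolic and immunity" = 2.07,
    "Neoplasm" = 2.21,
    "Circulatory system" = 3.01,
    "Blood and blood-forming organs" = 2.97
  )
}

#' Representative ICD-9-CM codes emitted per category
#'
#' A small fixed list per category; category mapping, not code identity,
#' drives the analysis. Codes are chosen so that each maps back to exactly its
#' intended category (plus the substance-use union for the subtype lists).
#'
#' @return named list of character vectors.
#' @export
default_category_codes <- function() {
  list(
    "Depressive disorder" = c("296.22", "296.32", "300.4", "311"),
    "Bipolar disorder" = c("296.00", "296.40", "296.62", "296.7"),
    "Anxiety disorder" = c("300.00", "300.02", "300.21", "308.3", "309.81"),
    "Sleep disorder" = c("307.42", "307.45", "780.52"),
    "Alcohol use disorder" = c("303.90", "305.00"),
    "Opioid use disorder" = c("304.00", "305.50"),
    "Amphetamine use disorder" = c("304.40", "305.70"),
    "ADHD" = c("314.00", "314.01"),
    "Mental retardation" = c("317", "318.0", "319"),
    "Autistic spectrum disorder" = c("299.00"),
    "Eating disorder" = c("307.1", "307.50", "307.51"),
    "Respiratory system" = c("460", "465.9", "486", "493.90"),
    "Nervous system and sense organs" = c("346.90", "367.1", "382.9"),
    "Digestive system" = c("521.00", "535.50", "558.9"),
    "Skin and subcutaneous tissue" = c("682.9", "691.8", "706.1"),
    "Injury and poisoning" = c("845.00", "884.0", "959.9"),
    "Infectious and parasitic" = c("008.8", "034.0", "079.99"),
    "Genitourinary system" = c("595.0", "599.0", "626.2"),
    "Musculoskeletal system" = c("715.90", "724.2", "729.1"),
    "Congenital anomalies" = c("745.5", "750.9"),
    "Endocrine, metabolic and immunity" = c("244.9", "250.00", "272.4"),
    "Neoplasm" = c("174.9", "210.9", "239.9"),
    "Circulatory system" = c("401.9", "427.9", "455.6"),
    "Blood and blood-forming organs" = c("280.9", "285.9")
  )
}

# age distribution targeting the study demographics: piecewise-linear inverse
# CDF through quantile anchors, placed so that after flooring to integer years
# the median is 25, the IQR 21-33, and the 0-19 / 20-39 / 40-59 band fractions
# are 12.7% / 77.4% / 9.9% (quartile anchors sit mid-bin; band anchors sit on
# the band boundary)
default_age_quantiles <- function() {
  data.frame(
    p = c(0, 0.127, 0.25, 0.5, 0.75, 0.901, 1),
    age = c(12, 20, 21.5, 25.5, 33.5, 40, 60)
  )
}

#' Configuration for the synthetic claims generator
#'
#' @param n_persons number of persons to simulate.
#' @param female_fraction probability a person is female (default 0.65).
#' @param age_quantiles data frame with columns \code{p} (probabilities,
#'   starting at 0 and ending at 1) and \code{age}; ages are drawn by
#'   piecewise-linear inverse-CDF interpolation and floored to integer years.
#' @param index_prevalence probability of carrying the index disorder.
#' @param category_prevalences named vector: baseline category membership
#'   probability among non-cases.
#' @param category_ors named vector: target case-vs-non-case odds ratio per
#'   category (names must be a subset of \code{category_prevalences}; missing
#'   categories get OR 1).
#' @param couplings optional data frame with columns \code{a}, \code{b},
#'   \code{gamma}: an auto-logistic pairwise dependence in which membership in
#'   category \code{a} adds \code{gamma} to the log-odds of the
#'   later-in-order category \code{b}.
#' @param category_codes named list of representative ICD-9-CM codes emitted
#'   per category.
#' @param enrollment_window Date vector of length 2: index (enrollment) dates
#'   are uniform in this closed range.
#' @param comorbidity_offset_years comorbidity diagnosis dates are uniform
#'   within this many years of the person's own (pseudo-)index date.
#' @param missing_fraction fraction of person/diagnosis fields blanked
#'   completely at random, to exercise complete-case filtering (default 0).
#' @param seed integer; fully determines the generated population.
#' @return an object of class \code{claims_config}.
#' @export
claims_config <- function(n_persons = 20000L,
                          female_fraction = 0.65,
                          age_quantiles = default_age_quantiles(),
                          index_prevalence = 0.015,
                          category_prevalences = default_category_prevalences(),
                          category_ors = default_category_ors(),
                          couplings = NULL,
                          category_codes = default_category_codes(),
                          enrollment_window = as.Date(c("2003-01-01", "2006-12-31")),
                          comorbidity_offset_years = 3,
                          missing_fraction = 0,
                          seed = 1L) {
  if (!is.numeric(n_persons) || length(n_persons) != 1 || n_persons < 1) {
    stop("n_persons must be a positive integer")
  }
  check_prob(female_fraction, "female_fraction")
  check_prob(index_prevalence, "index_prevalence")
  check_prob(category_prevalences, "category_prevalences")
  if (any(category_ors <= 0) || any(!is.finite(category_ors))) {
    stop("all target odds ratios must be positive and finite")
  }
  if (!all(names(category_ors) %in% names(category_prevalences))) {
    stop("category_ors names must be a subset of category_prevalences names")
  }
  cats <- names(category_prevalences)
  ors <- setNames(rep(1, length(cats)), cats)
  ors[names(category_ors)] <- category_ors
  # the conditional case-arm probability implied by (prevalence, OR) must be a
  # probability; with finite positive ORs it always is, but fail loudly if a
  # degenerate combination sneaks through
  p1 <- stats::plogis(stats::qlogis(category_prevalences) + log(ors))
  if (any(!is.finite(p1)) || any(p1 <= 0) || any(p1 >= 1)) {
    bad <- cats[!is.finite(p1) | p1 <= 0 | p1 >= 1]
    stop("unsatisfiable prevalence/OR combination for: ", paste(bad, collapse = ", "))
  }
  missing_codes <- setdiff(cats, names(category_codes))
  if (length(missing_codes) > 0 || any(lengths(category_codes[cats]) == 0)) {
    stop("every category needs a non-empty representative code list; missing: ",
         paste(c(missing_codes, cats[lengths(category_codes[cats]) == 0]), collapse = ", "))
  }
  if (!is.null(couplings)) {
    stopifnot(is.data.frame(couplings),
              all(c("a", "b", "gamma") %in% names(couplings)))
    if (!all(couplings$a %in% cats) || !all(couplings$b %in% cats)) {
      stop("coupling categories must appear in category_prevalences")
    }
    if (any(match(couplings$a, cats) >= match(couplings$b, cats))) {
      stop("couplings must point from an earlier to a later category in the ",
           "category_prevalences ordering (auto-logistic scheme)")
    }
  }
  enrollment_window <- as.Date(enrollment_window)
  stopifnot(length(enrollment_window) == 2, enrollment_window[1] <= enrollment_window[2])
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("missing_fraction must be in [0, 1)")
  }
  cfg <- list(
    n_persons = as.integer(n_persons), female_fraction = female_fraction,
    age_quantiles = age_quantiles, index_prevalence = index_prevalence,
    category_prevalences = category_prevalences, category_ors = ors,
    couplings = couplings, category_codes = category_codes,
    enrollment_window = enrollment_window,
    comorbidity_offset_years = comorbidity_offset_years,
    missing_fraction = missing_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "claims_config"
  cfg
}

sample_ages <- function(n, q) {
  stopifnot(is.data.frame(q), q$p[1] == 0, q$p[nrow(q)] == 1,
            !is.unsorted(q$p), !is.unsorted(q$age))
  u <- stats::runif(n)
  as.integer(floor(stats::approx(q$p, q$age, xout = u, ties = "ordered")$y))
}

#' Generate a synthetic claims population
#'
#' Persons get a sex, an integer age, an index (cases) or pseudo-index
#' (non-cases) date uniform in the enrollment window, and a birth date
#' consistent with the age at that date. Index carriers receive one 301.83
#' record dated at the index date. Category membership is sampled from a
#' logistic model whose case-status coefficient is \code{log(target OR)} (plus
#' any auto-logistic couplings); each membership is emitted as one concrete
#' representative code dated uniformly within \code{comorbidity_offset_years}
#' of the person's own (pseudo-)index date.
#'
#' @param config a [claims_config()].
#' @return list with components \code{persons} (person_id, sex, birth_date),
#'   \code{diagnoses} (person_id, icd9_code, diagnosis_date), and
#'   \code{truth} (person_id, is_case, index_date, age, plus one logical
#'   column per category: the generated membership ground truth).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "claims_config"))
  set.seed(config$seed)
  n <- config$n_persons
  cats <- names(config$category_prevalences)

  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  age <- sample_ages(n, config$age_quantiles)
  w0 <- config$enrollment_window[1]
  span <- as.integer(config$enrollment_window[2] - w0)
  index_date <- w0 + sample.int(span + 1L, n, replace = TRUE) - 1L
  is_case <- stats::runif(n) < config$index_prevalence
  # birth date giving exactly `age` completed 365.25-day years at index_date
  lo <- ceiling(age * 365.25)
  hi <- ceiling((age + 1) * 365.25) - 1
  birth_date <- index_date - (lo + floor(stats::runif(n) * (hi - lo + 1)))

  # category membership: sequential logistic with case effect + couplings
  M <- matrix(FALSE, n, length(cats), dimnames = list(NULL, cats))
  beta <- log(config$category_ors)
  alpha <- stats::qlogis(config$category_prevalences)
  for (j in seq_along(cats)) {
    eta <- alpha[j] + beta[j] * is_case
    if (!is.null(config$couplings)) {
      cp <- config$couplings[config$couplings$b == cats[j], , drop = FALSE]
      for (r in seq_len(nrow(cp))) {
        eta <- eta + cp$gamma[r] * M[, cp$a[r]]
      }
    }
    M[, j] <- stats::runif(n) < stats::plogis(eta)
  }

  person_id <- sprintf("P%07d", seq_len(n))
  persons <- data.frame(person_id = person_id, sex = sex,
                        birth_date = birth_date, stringsAsFactors = FALSE)

  off_days <- round(config$comorbidity_offset_years * 365.25) - 1L
  pieces <- vector("list", length(cats) + 1L)
  if (any(is_case)) {
    pieces[[1]] <- data.frame(
      person_id = person_id[is_case], icd9_code = "301.83",
      diagnosis_date = index_date[is_case], stringsAsFactors = FALSE
    )
  }
  for (j in seq_along(cats)) {
    idx <- which(M[, j])
    if (length(idx) == 0) next
    codes <- resample(config$category_codes[[cats[j]]], length(idx), replace = TRUE)
    offs <- sample.int(2L * off_days + 1L, length(idx), replace = TRUE) - off_days - 1L
    pieces[[j + 1L]] <- data.frame(
      person_id = person_id[idx], icd9_code = codes,
      diagnosis_date = index_date[idx] + offs, stringsAsFactors = FALSE
    )
  }
  diagnoses <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(person_id = character(0), icd9_code = character(0),
                            diagnosis_date = as.Date(character(0)),
                            stringsAsFactors = FALSE)
  }
  diagnoses <- diagnoses[order(diagnoses$person_id, diagnoses$diagnosis_date,
                               diagnoses$icd9_code), , drop = FALSE]
  rownames(diagnoses) <- NULL

  if (config$missing_fraction > 0) {
    blank <- function(x) {
      x[stats::runif(length(x)) < config$missing_fraction] <- NA
      x
    }
    persons$sex <- blank(persons$sex)
    persons$birth_date <- blank(persons$birth_date)
    diagnoses$icd9_code <- blank(diagnoses$icd9_code)
    diagnoses$diagnosis_date <- blank(diagnoses$diagnosis_date)
  }

  truth <- data.frame(person_id = person_id, is_case = is_case,
                      index_date = index_date, age = age,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(M))

  list(persons = persons, diagnoses = diagnoses, truth = truth)
}

#' Write a claims population to delimited files
#'
#' Writes \code{persons.<ext>} and \code{diagnoses.<ext>} under \code{dir}.
#' CSV headers are \code{person_id,sex,birth_date} and
#' \code{person_id,sex,birth_date,icd9_code,diagnosis_date} (demographics
#' joined onto each diagnosis row); dates are ISO-8601; missing fields are
#' empty. The JSONL variant writes one object per line with the same fields.
#'
#' @param persons,diagnoses data frames as returned by [generate_population()].
#' @param dir output directory (created if needed).
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @return the two file paths, invisibly.
#' @export
write_claims <- function(persons, diagnoses, dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dj <- merge(diagnoses, persons, by = "person_id", sort = FALSE)
  dj <- dj[, c("person_id", "sex", "birth_date", "icd9_code", "diagnosis_date")]
  dj <- dj[order(dj$person_id, dj$diagnosis_date, dj$icd9_code), , drop = FALSE]
  pf <- file.path(dir, paste0("persons.", format))
  df <- file.path(dir, paste0("diagnoses.", format))
  if (format == "csv") {
    utils::write.csv(persons, pf, row.names = FALSE, na = "")
    utils::write.csv(dj, df, row.names = FALSE, na = "")
  } else {
    writeLines(vapply(seq_len(nrow(persons)), function(i) {
      jsonlite::toJSON(lapply(persons[i, , drop = FALSE], as.character),
                       auto_unbox = TRUE, null = "null", na = "null")
    }, character(1)), pf)
    writeLines(vapply(seq_len(nrow(dj)), function(i) {
      jsonlite::toJSON(lapply(dj[i, , drop = FALSE], as.character),
                       auto_unbox = TRUE, null = "null", na = "null")
    }, character(1)), df)
  }
  invisible(c(persons = pf, diagnoses = df))
}

parse_iso_date <- function(x, file, field) {
  x[!is.na(x) & x == ""] <- NA
  d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad) > 0) {
    stop("malformed ", field, " in ", file, " at data line ", bad[1],
         ": ", x[bad[1]], call. = FALSE)
  }
  d
}

#' Read a claims population written by [write_claims()]
#'
#' Round-trips exactly: \code{read_claims(write_claims(x))} reproduces the
#' persons and diagnoses tables. Malformed rows (unparseable dates, codes that
#' match neither the ICD grammar nor a missing field) raise an error naming
#' the file, line and field.
#'
#' @param dir directory containing the claims files.
#' @param format \code{"csv"} or \code{"jsonl"}.
#' @return list with \code{persons} and \code{diagnoses} data frames.
#' @export
read_claims <- function(dir, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  pf <- file.path(dir, paste0("persons.", format))
  df <- file.path(dir, paste0("diagnoses.", format))
  if (!file.exists(pf) || !file.exists(df)) {
    stop("claims files not found under ", dir)
  }
  if (format == "csv") {
    persons <- utils::read.csv(pf, colClasses = "character")
    dj <- utils::read.csv(df, colClasses = "character")
  } else {
    read_jsonl <- function(path) {
      lines <- readLines(path)
      if (length(lines) == 0) return(NULL)
      do.call(rbind, lapply(lines, function(l) {
        as.data.frame(lapply(jsonlite::fromJSON(l), function(v) {
          if (is.null(v)) NA_character_ else as.character(v)
        }), stringsAsFactors = FALSE)
      }))
    }
    persons <- read_jsonl(pf) %||%
      data.frame(person_id = character(0), sex = character(0),
                 birth_date = character(0), stringsAsFactors = FALSE)
    dj <- read_jsonl(df) %||%
      data.frame(person_id = character(0), sex = character(0),
                 birth_date = character(0), icd9_code = character(0),
                 diagnosis_date = character(0), stringsAsFactors = FALSE)
  }
  for (nm in names(persons)) persons[[nm]][persons[[nm]] %in% ""] <- NA
  for (nm in names(dj)) dj[[nm]][dj[[nm]] %in% ""] <- NA
  need_p <- c("person_id", "sex", "birth_date")
  need_d <- c("person_id", "sex", "birth_date", "icd9_code", "diagnosis_date")
  if (!all(need_p %in% names(persons))) stop("persons file missing fields")
  if (!all(need_d %in% names(dj))) stop("diagnoses file missing fields")
  persons$birth_date <- parse_iso_date(persons$birth_date, basename(pf), "birth_date")
  dj$diagnosis_date <- parse_iso_date(dj$diagnosis_date, basename(df), "diagnosis_date")
  bad <- which(!is.na(dj$icd9_code) & !is_icd9_code(dj$icd9_code) &
                 !grepl("^[VE]", dj$icd9_code))
  if (length(bad) > 0) {
    stop("malformed icd9_code in ", basename(df), " at data line ", bad[1],
         ": ", dj$icd9_code[bad[1]], call. = FALSE)
  }
  diagnoses <- dj[, c("person_id", "icd9_code", "diagnosis_date")]
  rownames(persons) <- rownames(diagnoses) <- NULL
  list(persons = persons, diagnoses = diagnoses)
}
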