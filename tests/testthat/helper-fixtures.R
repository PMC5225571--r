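# Fixtures and independent oracles used across the suite.
# The oracles deliberately use naive character-set logic (no bitmasks, no
# shared code with the miner) so they stay independent of the paths they
# check.

# a compact, densely matchable study configuration: ages 18-44, a handful of
# categories, prevalence high enough to yield a few hundred cases at small n
test_config <- function(n_persons = 4000, index_prevalence = 0.05, seed = 1,
                        prevalences = c("Depressive disorder" = 0.05,
                                        "Bipolar disorder" = 0.04,
                                        "Anxiety disorder" = 0.10,
                                        "Sleep disorder" = 0.12),
                        ors = c("Depressive disorder" = 30,
                                "Bipolar disorder" = 40,
                                "Anxiety disorder" = 8,
                                "Sleep disorder" = 5),
                        ...) {
  claims_config(
    n_persons = n_persons, index_prevalence = index_prevalence,
    age_quantiles = data.frame(p = c(0, 0.25, 0.5, 0.75, 1),
                               age = c(18, 21, 25, 33, 44)),
    category_prevalences = prevalences, category_ors = ors,
    seed = seed, ...
  )
}

# generator -> incident cases -> exact-matched cohort -> transactions
make_matched_study <- function(config = test_config(), ratio = 4,
                               match_seed = 11, policy = "fail") {
  pop <- generate_population(config)
  cases <- select_cases(pop$diagnoses, config$enrollment_window)
  case_persons <- merge(cases, pop$persons, by = "person_id")
  pool <- pop$persons[!pop$persons$person_id %in% cases$person_id, , drop = FALSE]
  cohort <- match_controls(case_persons, pool, ratio = ratio, seed = match_seed,
                           policy = policy)
  list(pop = pop, cases = cases, pool = pool, cohort = cohort,
       transactions = build_transactions(cohort, pop$diagnoses))
}

# random transaction lists over letter items
random_transactions <- function(n, n_items, p = 0.35) {
  items <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n), function(i) items[runif(n_items) < p])
}

# ---- independent ARM oracle ------------------------------------------------

oracle_support <- function(itemset, tlist) {
  hits <- 0
  for (t in tlist) if (all(itemset %in% t)) hits <- hits + 1
  hits / length(tlist)
}

# exhaustive enumeration over all disjoint (X, Y) pairs with |X|+|Y| <= max_size
oracle_rules <- function(tlist, min_lift = 0, minsup = 0, minconf = 0,
                         antecedent = NULL, consequent_sizes = 1:3,
                         max_size = 4) {
  items <- sort(unique(unlist(tlist)))
  subsets <- list()
  for (s in seq_len(min(length(items), max_size))) {
    cmb <- combn(items, s, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  # support of every subset, computed once by the naive scan
  supp_of <- vapply(subsets, oracle_support, numeric(1), tlist = tlist)
  names(supp_of) <- vapply(subsets, function(s) paste(sort(s), collapse = "|"),
                           character(1))
  lookup <- function(s) supp_of[[paste(sort(s), collapse = "|")]]
  rows <- list()
  for (x in subsets) {
    if (!is.null(antecedent) && !setequal(x, antecedent)) next
    for (y in subsets) {
      if (length(intersect(x, y)) > 0) next
      if (length(x) + length(y) > max_size) next
      if (!(length(y) %in% consequent_sizes)) next
      sx <- lookup(x)
      sy <- lookup(y)
      if (sx == 0 || sy == 0) next
      sxy <- lookup(c(x, y))
      cf <- sxy / sx
      lf <- cf / sy
      if (sxy <= minsup || cf <= minconf || lf <= min_lift) next
      rows[[length(rows) + 1]] <- data.frame(
        antecedent = paste(sort(x), collapse = " & "),
        consequent = paste(sort(y), collapse = " & "),
        support = sxy, confidence = cf, lift = lf,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$antecedent, out$consequent), , drop = FALSE]
}

# construct a one-row rule object usable by evaluate_rules / bootstrap_rules
manual_rule <- function(consequent, antecedent = "BPD") {
  r <- data.frame(
    relations = length(antecedent) + length(consequent),
    support = NA_real_, confidence = NA_real_, lift = NA_real_,
    antecedent = paste(antecedent, collapse = " & "),
    consequent = paste(consequent, collapse = " & "),
    stringsAsFactors = FALSE
  )
  r$antecedent_items <- list(antecedent)
  r$consequent_items <- list(consequent)
  r
}

# transactions data frame from explicit item lists
make_transactions_df <- function(case_items, control_items, index_label = "BPD") {
  n1 <- length(case_items); n2 <- length(control_items)
  df <- data.frame(
    person_id = sprintf("T%05d", seq_len(n1 + n2)),
    group = c(rep("case", n1), rep("control", n2)),
    stringsAsFactors = FALSE
  )
  df$items <- c(lapply(case_items, function(it) sort(unique(c(index_label, it)))),
                lapply(control_items, function(it) sort(unique(it))))
  attr(df, "index_label") <- index_label
  class(df) <- c("transactions", "data.frame")
  df
}

# rule-pattern transactions: n1 cases of which a carry the consequent set,
# n2 controls of which b carry it (the shape behind the study's rule tables)
rule_count_transactions <- function(a, n1, b, n2, consequent = c("Bipolar disorder", "Anxiety disorder")) {
  make_transactions_df(
    case_items = c(replicate(a, consequent, simplify = FALSE),
                   replicate(n1 - a, character(0), simplify = FALSE)),
    control_items = c(replicate(b, consequent, simplify = FALSE),
                      replicate(n2 - b, character(0), simplify = FALSE))
  )
}
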