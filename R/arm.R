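# Association rule mining in the lift-only regime: minimum support and
# confidence are conceptually zero, rules are ranked by lift, only lift above
# the threshold (default 1, strict) is kept, output truncated to the top k.
# The itemset universe is expected to be small and curated (a dozen or so
# diagnosis categories); enumeration is level-wise and bounded both by the
# maximum rule size and an explicit itemset budget.

# normalise transaction input: list of character vectors
as_transaction_list <- function(transactions) {
  if (is.data.frame(transactions)) {
    stopifnot("items" %in% names(transactions))
    transactions$items
  } else if (is.list(transactions)) {
    transactions
  } else {
    stop("transactions must be a transactions data frame or a list of item vectors")
  }
}

#' Support of an itemset
#'
#' Fraction of transactions containing every item of the set. The empty set
#' has support 1.
#'
#' @param itemset character vector of items.
#' @param transactions transaction table or list of item vectors.
#' @return fraction in [0, 1].
#' @export
support <- function(itemset, transactions) {
  tl <- as_transaction_list(transactions)
  if (length(tl) == 0) stop("support undefined for an empty transaction set")
  mean(vapply(tl, function(t) all(itemset %in% t), logical(1)))
}

#' Confidence of the rule X -> Y
#'
#' \code{support(X u Y) / support(X)}, i.e. P(Y | X). Undefined (NA) when X
#' has zero support.
#'
#' @param antecedent,consequent character vectors of items.
#' @param transactions transaction table or list of item vectors.
#' @return fraction, or NA when support(X) = 0.
#' @export
confidence <- function(antecedent, consequent, transactions) {
  sx <- support(antecedent, transactions)
  if (sx == 0) return(NA_real_)
  support(union(antecedent, consequent), transactions) / sx
}

#' Lift of the rule X -> Y
#'
#' \code{confidence(X -> Y) / support(Y)} = P(X, Y) / (P(X) P(Y)). Symmetric
#' in X and Y; 1 under independence, above 1 for positive association.
#' Undefined (NA) when either side has zero support.
#'
#' @inheritParams confidence
#' @return positive real, or NA.
#' @export
lift <- function(antecedent, consequent, transactions) {
  sy <- support(consequent, transactions)
  cf <- confidence(antecedent, consequent, transactions)
  if (is.na(cf) || sy == 0) return(NA_real_)
  cf / sy
}

# encode transactions over `items` as integer bitmasks (|items| <= 30)
encode_masks <- function(tl, items) {
  vapply(tl, function(t) {
    ix <- match(intersect(t, items), items)
    if (length(ix) == 0) 0L else as.integer(sum(2^(ix - 1)))
  }, integer(1))
}

#' Mine association rules ranked by lift
#'
#' Level-wise enumeration of all itemsets up to \code{max_size} items over the
#' transaction universe (admissible at zero minimum support), followed by rule
#' generation over every split of each itemset into disjoint non-empty
#' antecedent and consequent. Rules are kept when support and confidence
#' strictly exceed \code{minsup}/\code{minconf} (both default 0) and lift
#' strictly exceeds \code{min_lift} (default 1), optionally restricted to a
#' fixed antecedent and to given consequent sizes, then sorted by lift
#' descending and truncated to the top \code{k}. Ties are broken
#' deterministically by support, then confidence (both descending), then the
#' rule label.
#'
#' @param transactions transaction table or list of item vectors.
#' @param k maximum number of rules returned (default 10000).
#' @param min_lift strict lower bound on lift (default 1).
#' @param minsup,minconf strict lower bounds on support and confidence
#'   (default 0: any rule with positive joint support qualifies).
#' @param antecedent if non-NULL, keep only rules whose antecedent equals this
#'   item set exactly.
#' @param consequent_sizes allowed consequent sizes (default \code{2:3},
#'   mirroring the two- and three-disorder comorbidity patterns).
#' @param max_size maximum \code{|X| + |Y|} (default 4).
#' @param items optional item universe; transactions are restricted to it.
#'   Defaults to all items observed.
#' @param itemset_budget hard cap on the number of enumerated itemsets;
#'   exceeding it is an error instructing to constrain the universe.
#' @return an object of class \code{rule_set}: a data frame with columns
#'   \code{relations} (|X|+|Y|), \code{support}, \code{confidence},
#'   \code{lift}, \code{antecedent}, \code{consequent} (item labels joined
#'   with \code{" & "}), plus list columns \code{antecedent_items} and
#'   \code{consequent_items}.
#' @export
mine_rules <- function(transactions, k = 10000L, min_lift = 1, minsup = 0,
                       minconf = 0, antecedent = NULL, consequent_sizes = 2:3,
                       max_size = 4L, items = NULL, itemset_budget = 200000) {
  tl <- as_transaction_list(transactions)
  if (length(tl) == 0) stop("cannot mine an empty transaction set")
  stopifnot(k >= 1, minsup >= 0, minsup <= 1, minconf >= 0, minconf <= 1,
            max_size >= 2)
  if (is.null(items)) {
    items <- sort(unique(unlist(tl)))
  } else {
    items <- sort(unique(items))
    tl <- lapply(tl, function(t) intersect(t, items))
  }
  m <- length(items)
  if (m < 2) {
    return(empty_rule_set(length(tl), items))
  }
  if (m > 30) {
    stop("item universe of ", m, " exceeds the 30-item encoding limit; ",
         "constrain the universe with `items`")
  }
  n_itemsets <- sum(choose(m, seq_len(min(m, max_size))))
  if (n_itemsets > itemset_budget) {
    stop("level-wise enumeration would visit ", n_itemsets, " itemsets ",
         "(budget ", itemset_budget, "); constrain the universe or max_size")
  }
  n <- length(tl)
  tmask <- encode_masks(tl, items)

  # supports of all itemsets up to max_size, keyed by bitmask
  supp <- new.env(parent = emptyenv(), size = as.integer(n_itemsets * 2))
  sets_by_size <- vector("list", min(m, max_size))
  for (s in seq_len(min(m, max_size))) {
    cmb <- utils::combn(m, s)
    sets_by_size[[s]] <- cmb
    for (j in seq_len(ncol(cmb))) {
      mk <- as.integer(sum(2^(cmb[, j] - 1)))
      assign(as.character(mk), sum(bitwAnd(tmask, mk) == mk) / n, envir = supp)
    }
  }
  get_supp <- function(mk) get(as.character(mk), envir = supp)

  ant_ix <- if (!is.null(antecedent)) sort(match(antecedent, items)) else NULL
  if (!is.null(antecedent) && anyNA(ant_ix)) {
    return(empty_rule_set(n, items))  # constrained antecedent not in universe
  }

  rows <- list()
  nr <- 0L
  for (s in 2:min(m, max_size)) {
    cmb <- sets_by_size[[s]]
    for (j in seq_len(ncol(cmb))) {
      z <- cmb[, j]
      zmask <- as.integer(sum(2^(z - 1)))
      sxy <- get_supp(zmask)
      if (sxy <= minsup) next   # support must strictly exceed minsup
      # every split into non-empty antecedent X and consequent Y
      for (bits in seq_len(2^s - 2)) {
        sel <- as.logical(bitwAnd(bits, 2^(seq_len(s) - 1)))
        x <- z[sel]
        y <- z[!sel]
        if (!is.null(ant_ix) && !identical(x, ant_ix)) next
        if (!(length(y) %in% consequent_sizes)) next
        sx <- get_supp(as.integer(sum(2^(x - 1))))
        sy <- get_supp(as.integer(sum(2^(y - 1))))
        if (sx == 0 || sy == 0) next
        cf <- sxy / sx
        lf <- cf / sy
        if (cf <= minconf || lf <= min_lift) next
        nr <- nr + 1L
        rows[[nr]] <- list(x = x, y = y, s = sxy, c = cf, l = lf)
      }
    }
  }
  if (nr == 0L) return(empty_rule_set(n, items))
  df <- data.frame(
    relations = vapply(rows, function(r) length(r$x) + length(r$y), numeric(1)),
    support = vapply(rows, `[[`, numeric(1), "s"),
    confidence = vapply(rows, `[[`, numeric(1), "c"),
    lift = vapply(rows, `[[`, numeric(1), "l"),
    antecedent = vapply(rows, function(r) paste(items[r$x], collapse = " & "), character(1)),
    consequent = vapply(rows, function(r) paste(items[r$y], collapse = " & "), character(1)),
    stringsAsFactors = FALSE
  )
  df$antecedent_items <- lapply(rows, function(r) items[r$x])
  df$consequent_items <- lapply(rows, function(r) items[r$y])
  label <- paste(df$antecedent, "->", df$consequent)
  ord <- order(-df$lift, -df$support, -df$confidence, label, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- utils::head(df, k)
  rownames(df) <- NULL
  attr(df, "n_transactions") <- n
  attr(df, "items") <- items
  class(df) <- c("rule_set", "data.frame")
  df
}

empty_rule_set <- function(n, items) {
  df <- data.frame(relations = numeric(0), support = numeric(0),
                   confidence = numeric(0), lift = numeric(0),
                   antecedent = character(0), consequent = character(0),
                   stringsAsFactors = FALSE)
  df$antecedent_items <- list()
  df$consequent_items <- list()
  attr(df, "n_transactions") <- n
  attr(df, "items") <- items
  class(df) <- c("rule_set", "data.frame")
  df
}

#' @export
print.rule_set <- function(x, n = 10L, ...) {
  cat("rule_set: ", nrow(x), " rule(s) over ", length(attr(x, "items")),
      " items, ", attr(x, "n_transactions"), " transactions\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(x, n)
    out <- data.frame(
      relations = show$relations,
      support = fmt_pct(show$support),
      confidence = fmt_pct(show$confidence),
      lift = sprintf("%.2f", show$lift),
      rule = paste(show$antecedent, "->", show$consequent),
      stringsAsFactors = FALSE
    )
    print.data.frame(out, row.names = FALSE)
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  }
  invisible(x)
}
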