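test_that("support, confidence and lift match their definitions on small sets", {
  tl <- list(c("A", "B"), c("A", "B", "C"), "C", c("B", "C"), character(0))
  expect_equal(support(character(0), tl), 1)       # every transaction holds {}
  expect_equal(support("Z", tl), 0)
  expect_equal(support("B", tl), 3 / 5)
  expect_equal(support(c("A", "B"), tl), 2 / 5)
  expect_equal(confidence("A", "B", tl), 1)
  expect_equal(confidence("B", "C", tl), 2 / 3)
  expect_true(is.na(confidence("Z", "A", tl)))     # zero-support antecedent
  expect_equal(confidence(c("A", "B"), "A", tl), 1)  # Y subset of X
  expect_equal(lift("B", "C", tl), (2 / 3) / (3 / 5))
  expect_error(support("A", list()), "empty")
})

test_that("lift is symmetric, 1 under exact independence, and sign-coherent", {
  # counts chosen to factorise: n=20, X in 10, Y in 10, both in 5
  tl <- c(replicate(5, c("X", "Y"), simplify = FALSE),
          replicate(5, "X", simplify = FALSE),
          replicate(5, "Y", simplify = FALSE),
          replicate(5, character(0), simplify = FALSE))
  expect_equal(lift("X", "Y", tl), 1)
  set.seed(4)
  for (i in 1:30) {
    tl <- random_transactions(n = sample(20:80, 1), n_items = sample(3:6, 1))
    its <- sort(unique(unlist(tl)))
    if (length(its) < 2) next
    xy <- resample(its, 2)
    l1 <- lift(xy[1], xy[2], tl)
    l2 <- lift(xy[2], xy[1], tl)
    if (is.na(l1)) next
    expect_equal(l1, l2)
    sxy <- support(xy, tl)
    prod <- support(xy[1], tl) * support(xy[2], tl)
    expect_equal(l1 > 1, sxy > prod)
    expect_equal(l1 < 1, sxy < prod)
    # brute-force P(X,Y)/(P(X)P(Y))
    expect_equal(l1, sxy / prod)
  }
})

test_that("mine_rules equals exhaustive enumeration on random small instances", {
  set.seed(5)
  for (i in 1:20) {
    tl <- random_transactions(n = sample(20:100, 1), n_items = sample(4:6, 1))
    mined <- mine_rules(tl, min_lift = 0, consequent_sizes = 1:3, max_size = 4,
                        k = 100000)
    want <- oracle_rules(tl, min_lift = 0, consequent_sizes = 1:3, max_size = 4)
    got <- as.data.frame(mined)[, c("antecedent", "consequent", "support",
                                    "confidence", "lift")]
    got <- got[order(got$antecedent, got$consequent), , drop = FALSE]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ranking is by lift with deterministic tie-breaking and k-truncation", {
  tl <- c(replicate(6, c("A", "B"), simplify = FALSE),
          replicate(2, c("C", "D"), simplify = FALSE),
          replicate(2, "E", simplify = FALSE))
  rs <- mine_rules(tl, min_lift = 0, consequent_sizes = 1:2, max_size = 2,
                   k = 1000)
  expect_false(is.unsorted(rev(rs$lift)))
  # equal lift blocks ordered by support desc, then label
  ties <- rs[rs$lift == rs$lift[1], ]
  expect_false(is.unsorted(rev(ties$support)))
  # k = 1 returns exactly the single top rule
  top <- mine_rules(tl, min_lift = 0, consequent_sizes = 1:2, max_size = 2, k = 1)
  expect_equal(nrow(top), 1)
  expect_equal(top$lift, max(rs$lift))
  # identical re-run gives identical ordering
  expect_identical(as.data.frame(rs),
                   as.data.frame(mine_rules(tl, min_lift = 0,
                                            consequent_sizes = 1:2,
                                            max_size = 2, k = 1000)))
})

test_that("degenerate and guarded inputs behave as specified", {
  # all transactions identical: all rules have confidence 1 and lift 1,
  # so none strictly exceeds min_lift = 1
  same <- replicate(10, c("A", "B", "C"), simplify = FALSE)
  expect_equal(nrow(mine_rules(same, min_lift = 1, consequent_sizes = 1:2)), 0)
  at_zero <- mine_rules(same, min_lift = 0, consequent_sizes = 1:2)
  expect_true(all(at_zero$confidence == 1))
  expect_true(all(at_zero$lift == 1))
  # antecedent constraint restricts exactly
  tl <- random_transactions(60, 5)
  rs <- mine_rules(tl, min_lift = 0, antecedent = "A", consequent_sizes = 1:3)
  expect_true(all(rs$antecedent == "A"))
  want <- oracle_rules(tl, min_lift = 0, antecedent = "A", consequent_sizes = 1:3)
  expect_equal(nrow(rs), nrow(want))
  # over-large universes are refused with guidance
  wide <- list(paste0("I", 1:40))
  expect_error(mine_rules(wide), "constrain the universe")
  expect_error(mine_rules(replicate(3, LETTERS[1:20], simplify = FALSE),
                          itemset_budget = 100), "constrain the universe")
})

test_that("support is anti-monotone over random instances", {
  set.seed(6)
  for (i in 1:15) {
    tl <- random_transactions(50, 6)
    its <- sort(unique(unlist(tl)))
    if (length(its) < 3) next
    big <- resample(its, 3)
    small <- big[1:2]
    expect_gte(support(small, tl), support(big, tl))
    expect_gte(support(big[1], tl), support(small, tl))
  }
})

test_that("rules recover planted case-comorbidity structure", {
  st <- make_matched_study(test_config(n_persons = 3500, seed = 10),
                           policy = "relax")
  rs <- mine_rules(st$transactions, antecedent = "BPD", consequent_sizes = 2:3,
                   items = c("BPD", "Depressive disorder", "Bipolar disorder",
                             "Anxiety disorder", "Sleep disorder"))
  expect_gt(nrow(rs), 0)
  expect_true(all(rs$lift > 1))
  expect_true(all(rs$support <= rs$confidence))
  expect_true(all(rs$relations %in% 3:4))
  # the strongly associated pair should surface among the rules
  expect_true(any(grepl("Bipolar", rs$consequent) & grepl("Depressive", rs$consequent) |
                    grepl("Bipolar", rs$consequent) & grepl("Anxiety", rs$consequent)))
})
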