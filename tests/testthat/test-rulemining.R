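# incidence matrix from a character basket like c("AB", "AC")
basket_matrix <- function(baskets) {
  vocab <- sort(unique(unlist(strsplit(baskets, ""))))
  t(vapply(strsplit(baskets, ""), function(s) vocab %in% s,
           logical(length(vocab)))) |> `colnames<-`(vocab)
}

test_that("frequent itemsets match hand enumeration on the toy basket", {
  M <- basket_matrix(c("AB", "AB", "AC", "BC", "AB"))
  fi <- apriori_frequent_itemsets(M, 0.4)
  got <- setNames(fi$support, vapply(fi$items, paste, "", collapse = ""))
  expect_mapequal(as.list(got), list(A = 0.8, B = 0.8, C = 0.4, AB = 0.6))
})

test_that("support-1 elements survive a min_support of 1", {
  M <- basket_matrix(c("ZA", "ZB", "Z"))
  fi <- apriori_frequent_itemsets(M, 1.0)
  expect_equal(unname(unlist(fi$items)), "Z")
  expect_equal(fi$support, 1)
})

test_that("every subset of a frequent itemset is frequent (anti-monotonicity)", {
  set.seed(29)
  for (rep in 1:5) {
    M <- matrix(runif(80 * 8) < runif(8, 0.2, 0.9), 80, 8,
                dimnames = list(NULL, letters[1:8]))
    fi <- apriori_frequent_itemsets(M, 0.1)
    keys <- vapply(fi$items, paste, "", collapse = ",")
    for (i in which(fi$size > 1)) {
      s <- fi$items[[i]]
      subs <- vapply(seq_along(s), function(d) paste(s[-d], collapse = ","), "")
      expect_true(all(subs %in% keys))
      # conservation: superset support never exceeds subset support
      expect_true(all(fi$support[match(subs, keys)] >= fi$support[i]))
    }
  }
})

test_that("lift threshold is strict and independence is rejected", {
  # P(X)=0.5, P(Y)=0.25, P(X,Y)=0.25: confidence 0.5, lift exactly 2
  M <- basket_matrix(c("XY", "X", "A", "B"))
  fi <- apriori_frequent_itemsets(M, 0.1)
  rules <- generate_rules(fi, M, consequents = "Y", min_confidence = 0.5,
                          min_lift = 2)
  expect_equal(nrow(rules), 0)
  # at min_lift just below 2 the same rule is admitted
  rules <- generate_rules(fi, M, consequents = "Y", min_confidence = 0.5,
                          min_lift = 1.999)
  expect_equal(nrow(rules), 1)
  expect_equal(rules$lift, 2)

  # X and Y statistically independent: lift 1, rejected
  M <- basket_matrix(c("XY", "X", "Y", ""))
  fi <- apriori_frequent_itemsets(M, 0.1)
  rules <- generate_rules(fi, M, consequents = "Y", min_confidence = 0.1,
                          min_lift = 1.5)
  expect_equal(nrow(rules), 0)
})

test_that("rule set equals brute-force enumeration on a toy table", {
  set.seed(33)
  M <- matrix(runif(60 * 8) < runif(8, 0.3, 0.8), 60, 8,
              dimnames = list(NULL, c(paste0("d", 1:6), "Y", "Z")))
  fi <- apriori_frequent_itemsets(M, 0.05)
  rules <- generate_rules(fi, M, consequents = c("Y", "Z"),
                          min_confidence = 0.5, min_lift = 1.1)
  oracle <- bf_rules(M, c("Y", "Z"), 0.05, 0.5, 1.1)
  expect_equal(
    rule_signature(rules$antecedent, rules$consequent, rules$support,
                   rules$confidence, rules$lift),
    rule_signature(lapply(oracle, `[[`, "antecedent"),
                   vapply(oracle, `[[`, "", "consequent"),
                   vapply(oracle, `[[`, 0, "support"),
                   vapply(oracle, `[[`, 0, "confidence"),
                   vapply(oracle, `[[`, 0, "lift")))
})

test_that("raising any threshold never adds a rule", {
  spec <- tiny_instrument()
  d <- generate_responses(ground_truth(spec), 250, seed = 35)
  tt <- build_transactions(d, spec)
  base <- mine_rules(tt, 0.05, 0.4, 1.2)
  sig <- function(r) rule_signature(r$antecedent, r$consequent, r$support,
                                    r$confidence, r$lift)
  expect_true(all(sig(mine_rules(tt, 0.10, 0.4, 1.2)) %in% sig(base)))
  expect_true(all(sig(mine_rules(tt, 0.05, 0.6, 1.2)) %in% sig(base)))
  expect_true(all(sig(mine_rules(tt, 0.05, 0.4, 1.6)) %in% sig(base)))
})

test_that("partitioning eliminates middle levels except listed exceptions", {
  rules <- data.frame(
    consequent = c("BEH-1=H", "BEH-1=H", "BEH-3=L", "BEH-2=M"),
    support = 0.1, confidence = 0.6, lift = 2.5)
  rules$antecedent <- list(c("PN=M", "VAL=H"), c("VAL=H"), c("KS=M"),
                           c("VAL=H"))
  class(rules) <- c("assoc_rules", "data.frame")

  parts <- partition_and_filter(rules)
  expect_named(parts, c("BEH-1=H", "BEH-3=L"))   # M consequent dropped
  expect_equal(parts[["BEH-1=H"]]$n_after, 1)    # PN=M antecedent eliminated
  expect_equal(parts[["BEH-3=L"]]$n_after, 0)

  # exception keeps KS=M inside BEH-3=L only
  parts <- partition_and_filter(rules, exceptions = list("BEH-3=L" = "KS"))
  expect_equal(parts[["BEH-3=L"]]$n_after, 1)
  expect_equal(parts[["BEH-1=H"]]$n_after, 1)

  # no middle-level dropping: partitioning only
  parts <- partition_and_filter(rules, drop_middle = FALSE)
  expect_equal(parts[["BEH-1=H"]]$n_after, 2)

  expect_error(partition_and_filter(rules, exceptions = list("BEH-9=Q" = "KS")),
               "unknown partition")
})

test_that("strong-rule ranking follows the documented tie-break order", {
  rules <- data.frame(
    consequent = "BEH-1=H",
    support = c(0.10, 0.12, 0.08, 0.08),
    confidence = c(0.6, 0.7, 0.6, 0.6),
    lift = c(2.5, 2.5, 2.5, 3.0))
  rules$antecedent <- list("B=H", "A=H", "C=H", "D=H")
  class(rules) <- c("assoc_rules", "data.frame")
  parts <- top_strong_rules(partition_and_filter(rules), n = 3)
  got <- unlist(parts[["BEH-1=H"]]$strong$antecedent)
  # lift first (D), then confidence (A), then support (B over C)
  expect_equal(got, c("D=H", "A=H", "B=H"))
  expect_true(parts[["BEH-1=H"]]$tie_at_boundary)

  # fewer rules than n: all retained
  parts <- top_strong_rules(partition_and_filter(rules), n = 10)
  expect_equal(nrow(parts[["BEH-1=H"]]$strong), 4)
})

test_that("domain frequency counts antecedent domains and flags at threshold", {
  rules <- data.frame(consequent = "BEH-1=H", support = 0.1,
                      confidence = 0.6, lift = rev(seq(2.1, 3, length.out = 10)))
  rules$antecedent <- c(replicate(6, c("VAL=H", "PN=H"), simplify = FALSE),
                        replicate(4, c("VAL=H", "KS=L"), simplify = FALSE))
  class(rules) <- c("assoc_rules", "data.frame")
  parts <- top_strong_rules(partition_and_filter(rules), n = 10)
  freq <- domain_frequency(parts[["BEH-1=H"]], threshold = 5)
  expect_equal(freq$count[freq$domain == "VAL"], 10)
  expect_equal(freq$count[freq$domain == "PN"], 6)
  expect_equal(freq$count[freq$domain == "KS"], 4)
  expect_equal(freq$domain[freq$flagged], c("VAL", "PN"))

  # empty partition profiles to an empty table
  empty <- list(key = "BEH-2=H",
                rules = rules[0, ], strong = rules[0, ])
  expect_equal(nrow(domain_frequency(empty)), 0)
})

test_that("strong opportunity coupling surfaces opportunity domains in H rules", {
  spec <- default_instrument()
  params <- ground_truth(spec,
                         paths = c(c_m = 0.1, o_m = 0.2, m_b = 0.25,
                                   o_b = 0.65, c_b = 0))
  d <- generate_responses(params, 484, seed = 77)
  tt <- build_transactions(d, spec)
  rules <- mine_rules(tt, 0.05, 0.5, 2)
  parts <- top_strong_rules(partition_and_filter(rules))
  freq <- domain_frequency(parts)
  opp <- spec$domains$Opportunity; cap <- spec$domains$Capability
  hparts <- names(parts)[grepl("=H$", names(parts))]
  opp_n <- sum(vapply(hparts, function(k) {
    f <- freq[[k]]; sum(f$count[f$domain %in% opp]) }, 0))
  cap_n <- sum(vapply(hparts, function(k) {
    f <- freq[[k]]; sum(f$count[f$domain %in% cap]) }, 0))
  expect_gt(opp_n, cap_n)
})
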