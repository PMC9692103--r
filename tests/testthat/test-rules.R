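example_ruleset_json <- '{
  "rules": {
    "kurtosis_sqi": {"boundaries": [{"op": "<", "value": 1.5, "decision": "reject"},
                                    {"op": ">", "value": 6.0, "decision": "reject"}],
                     "na_decision": "reject"},
    "skewness_sqi": {"boundaries": [{"op": ">", "value": 2.0, "decision": "reject"}],
                     "na_decision": "reject"},
    "entropy_sqi":  {"boundaries": [{"op": "<", "value": 5.0, "decision": "reject"}],
                     "na_decision": "reject"}
  },
  "order": ["kurtosis_sqi", "skewness_sqi", "entropy_sqi"]
}'

test_that("ruleset JSON parses with rules in the stated order", {
  rs <- parse_ruleset(example_ruleset_json)
  expect_length(rs$rules, 3)
  expect_equal(rs$order, c("kurtosis_sqi", "skewness_sqi", "entropy_sqi"))
  expect_equal(rs$rules$kurtosis_sqi$boundaries[[2]]$value, 6.0)
})

test_that("schema violations are configuration errors naming the node", {
  expect_error(parse_ruleset('{"rules": {}}'), class = "sqikit_config_error")
  expect_error(parse_ruleset('{"rules": {"a": {"boundaries": []}}}'),
               class = "sqikit_config_error")
  expect_error(
    parse_ruleset('{"rules": {"a": {"boundaries": [{"op": "~", "value": 1, "decision": "reject"}]}}}'),
    regexp = "operator", class = "sqikit_config_error")
  expect_error(
    sqi_ruleset(list(sqi_rule("a", list(list(op = "<", value = 1,
                                             decision = "reject")))),
                order = c("a", "ghost")),
    class = "sqikit_config_error")
})

test_that("parse-serialize-parse round-trips the structure", {
  rs <- parse_ruleset(example_ruleset_json)
  rs2 <- parse_ruleset(serialize_ruleset(rs))
  expect_equal(rs, rs2)
})

test_that("single-rule evaluation honors boundary order and NA decisions", {
  r <- sqi_rule("x", list(list(op = "<", value = 2.0, decision = "reject")))
  expect_equal(apply_rule(r, 3.5), "accept")
  expect_equal(apply_rule(r, 1.0), "reject")
  expect_equal(apply_rule(r, NA), "reject")
  r2 <- sqi_rule("x", list(list(op = "<", value = 2.0, decision = "reject")),
                 na_decision = "accept")
  expect_equal(apply_rule(r2, NA), "accept")
  ordered <- sqi_rule("x", list(list(op = "<", value = 10, decision = "accept"),
                                list(op = "<", value = 5, decision = "reject")))
  expect_equal(apply_rule(ordered, 3), "accept")  # first match wins
})

test_that("ruleset evaluation short-circuits on the first reject", {
  rs <- parse_ruleset(example_ruleset_json)
  ok <- apply_ruleset(rs, list(kurtosis_sqi = 3, skewness_sqi = 0,
                               entropy_sqi = 7))
  expect_equal(ok$label, "accept")
  expect_true(is.na(ok$triggered_rule))
  bad <- apply_ruleset(rs, list(kurtosis_sqi = 3, skewness_sqi = 0,
                                entropy_sqi = 2))
  expect_equal(bad$label, "reject")
  expect_equal(bad$triggered_rule, "entropy_sqi")
  expect_error(apply_ruleset(rs, list(kurtosis_sqi = 3)),
               class = "sqikit_config_error")
})

test_that("decisions on a hand-crafted table match enumerated truth", {
  rs <- parse_ruleset(example_ruleset_json)
  tab <- data.frame(
    kurtosis_sqi = c(3, 1.0, 3, 3, 7, 3, NA, 2, 5.9, 1.5),
    skewness_sqi = c(0, 0, 2.5, 0, 0, 0, 0, 1.9, 0, 0),
    entropy_sqi = c(7, 7, 7, 4, 7, 7, 7, 7, 5.1, 4.9))
  truth_label <- c("accept", "reject", "reject", "reject", "reject",
                   "accept", "reject", "accept", "accept", "reject")
  truth_rule <- c(NA, "kurtosis_sqi", "skewness_sqi", "entropy_sqi",
                  "kurtosis_sqi", NA, "kurtosis_sqi", NA, NA, "entropy_sqi")
  dec <- classify_pipeline(tab, rs)
  expect_equal(dec$label, truth_label)
  expect_equal(dec$triggered_rule, truth_rule)
})

test_that("adding a rule never flips a reject to an accept", {
  set.seed(42)
  sqis <- paste0("s", 1:4)
  random_rule <- function(nm) {
    nb <- sample(1:2, 1)
    sqi_rule(nm, lapply(seq_len(nb), function(i) {
      list(op = sample(c("<", "<=", ">", ">="), 1), value = runif(1, -2, 2),
           decision = sample(c("accept", "reject"), 1))
    }), na_decision = sample(c("accept", "reject"), 1))
  }
  for (trial in 1:1000) {
    base_names <- sample(sqis, sample(1:3, 1))
    rs_small <- sqi_ruleset(lapply(base_names, random_rule))
    extra <- random_rule(paste0("s", 4 + trial %% 2))
    rs_big <- sqi_ruleset(c(rs_small$rules, list(extra)))
    row <- as.list(stats::setNames(runif(6, -2, 2), c(sqis, "s4", "s5")))
    if (trial %% 7 == 0) row[[sample(seq_along(row), 1)]] <- NA
    small <- apply_ruleset(rs_small, row)$label
    big <- apply_ruleset(rs_big, row)$label
    if (small == "reject") expect_equal(big, "reject")
  }
})

test_that("rule order never changes the label, only the triggered rule", {
  rs <- parse_ruleset(example_ruleset_json)
  rev_rs <- sqi_ruleset(rs$rules, order = rev(rs$order))
  set.seed(43)
  for (i in 1:50) {
    row <- list(kurtosis_sqi = runif(1, 0, 8), skewness_sqi = runif(1, -1, 3),
                entropy_sqi = runif(1, 3, 9))
    expect_equal(apply_ruleset(rs, row)$label, apply_ruleset(rev_rs, row)$label)
  }
})

test_that("percentile threshold uses linear interpolation", {
  res <- threshold_percentile(1:100, 95)
  expect_equal(res$threshold, 95.05)
  expect_equal(threshold_percentile(rep(7, 30), 95)$threshold, 7)
  sym <- c(1:50, 51:100)
  expect_equal(threshold_percentile(sym, 50)$threshold, stats::median(sym))
  expect_error(threshold_percentile(1:10, 95), class = "sqikit_input_error")
})

test_that("grid search separates separable classes and picks the direction", {
  set.seed(44)
  a <- runif(100)
  r <- 2 + runif(100)
  res <- threshold_search(a, r)
  expect_equal(res$balanced_accuracy, 1.0)
  expect_gt(res$threshold, 1)
  expect_lt(res$threshold, 2)
  expect_equal(res$direction, "reject_above")
  res2 <- threshold_search(2 + runif(100), runif(100))
  expect_equal(res2$balanced_accuracy, 1.0)
  expect_equal(res2$direction, "reject_below")
  expect_error(threshold_search(rep(1, 30), rep(1, 30)),
               class = "sqikit_input_error")
})

test_that("grid search stays near chance on identical distributions", {
  for (seed in 1:20) {
    set.seed(seed)
    res <- threshold_search(rnorm(500), rnorm(500))
    expect_lte(res$balanced_accuracy, 0.6)
  }
})

test_that("pair search enumerates pairs and ranks by AUC", {
  set.seed(45)
  n <- 120
  labels <- rep(c("accept", "reject"), each = n / 2)
  is_acc <- labels == "accept"
  tab <- data.frame(
    sqi_a = ifelse(is_acc, rnorm(n, 5, 0.3), rnorm(n, 1, 0.3)),  # separates
    sqi_b = rnorm(n),                                            # useless
    sqi_c = ifelse(is_acc, rnorm(n, 0, 1), rnorm(n, 1.5, 1)))    # partial
  res2 <- pair_search(tab, labels, c("sqi_a", "sqi_b"))
  expect_equal(nrow(res2), 1)
  res3 <- pair_search(tab, labels, c("sqi_a", "sqi_b", "sqi_c"))
  expect_equal(nrow(res3), 3)  # k(k-1)/2
  expect_equal(res3$roc_auc, sort(res3$roc_auc, decreasing = TRUE))
  # a pair containing the perfect member keeps all-reject detection perfect,
  # so its balanced accuracy dominates the other member used alone
  with_a <- res3[grepl("sqi_a", res3$sqi_pair), ]
  expect_true(all(with_a$reject_accuracy == 1))
  ba_pair <- (with_a$accept_accuracy + with_a$reject_accuracy) / 2
  for (i in seq_len(nrow(with_a))) {
    other <- setdiff(strsplit(with_a$sqi_pair[i], "\\+")[[1]], "sqi_a")
    ba_alone <- threshold_search(tab[[other]][is_acc],
                                 tab[[other]][!is_acc])$balanced_accuracy
    expect_gte(ba_pair[i], ba_alone - 1e-9)
  }
  expect_error(pair_search(tab, rep("accept", n), c("sqi_a", "sqi_b")),
               class = "sqikit_input_error")
})

test_that("pair AUC agrees with a rank-comparison oracle on a perfect pair", {
  set.seed(46)
  n <- 80
  labels <- rep(c("accept", "reject"), each = n / 2)
  is_acc <- labels == "accept"
  tab <- data.frame(sqi_a = ifelse(is_acc, 10 + rnorm(n), rnorm(n)),
                    sqi_b = ifelse(is_acc, 10 + rnorm(n), rnorm(n)))
  res <- pair_search(tab, labels, c("sqi_a", "sqi_b"))
  comb <- pmin(rank(tab$sqi_a), rank(tab$sqi_b))
  expect_equal(res$roc_auc, oracle_rank_auc(comb, is_acc), tolerance = 1e-9)
})

test_that("derive_ruleset builds rules that reproduce the search thresholds", {
  set.seed(47)
  labels <- rep(c("accept", "reject"), each = 50)
  tab <- data.frame(sqi_a = c(runif(50), 2 + runif(50)))
  rs <- derive_ruleset(tab, labels, "sqi_a", method = "search")
  expect_s3_class(rs, "sqi_ruleset")
  b <- rs$rules$sqi_a$boundaries[[1]]
  expect_equal(b$op, ">")
  expect_equal(b$decision, "reject")
  dec <- classify_pipeline(tab, rs)
  expect_equal(dec$label, labels)
})
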