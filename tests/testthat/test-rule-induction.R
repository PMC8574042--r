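# a small labeled dataset driven by one planted rule, used across blocks
induction_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        chrom_sizes = c(chrA = 3e5), n_marks = 4,
        planted_rules = rule_base(
          list(fuzzy_rule(c("H3K4me1", "H4K16ac"), c("high", "high"),
                          "enhancer"),
               fuzzy_rule("H3K4me1", "low", "non_enhancer")),
          lapply(setNames(c("H3K4me1", "H4K16ac"),
                          c("H3K4me1", "H4K16ac")), fuzzy_partition)),
        noise_sd = 0, label_noise_rate = 0, seed = 31)
      sim <- generate_tracks(cfg)
      icfg <- induction_config(pop_size = 40, generations = 40,
                               fit_sample = 10000, patience = 15, seed = 8)
      rb <- induce_rulebase(sim$dataset, icfg)
      cache <<- list(sim = sim, icfg = icfg, rb = rb)
    }
    cache
  }
})

test_that("initialize_partitions anchors at empirical quantiles", {
  set.seed(21)
  bins <- tile_genome(c(A = 1e6), width = 10)
  u <- runif(length(bins))
  ds <- bin_dataset(bins, list(m1 = u, m2 = runif(length(bins))),
                    runif(length(bins)) < 0.1)
  parts <- initialize_partitions(ds)
  # quantile oracle at n = 1e5: anchors within 0.02 of 0.25/0.50/0.75
  expect_equal(parts$m1$anchors, c(0.25, 0.5, 0.75), tolerance = 0.02)
  expect_equal(parts$m1$anchors,
               unname(quantile(u, c(0.25, 0.5, 0.75))), tolerance = 1e-12)
  # overlap = 0 limit: supports touch without interior intersection
  p0 <- initialize_partitions(ds, overlap = 0, fou = 0)
  expect_equal(p0$m1$sets$low$upper[4], p0$m1$sets$medium$upper[1])
  # coverage invariant
  grid <- seq(0, 1, by = 0.01)
  cover <- Reduce(`pmax`, lapply(parts$m1$sets, function(s)
    membership(s, grid)[, "upper"]))
  expect_true(all(cover > 0))
  # constant feature flagged and excluded
  ds2 <- bin_dataset(bins, list(m1 = u, flat = rep(0.5, length(bins))),
                     runif(length(bins)) < 0.1)
  expect_warning(parts2 <- initialize_partitions(ds2), "flat")
  expect_false("flat" %in% names(parts2))
  expect_equal(attr(parts2, "degenerate"), "flat")
})

test_that("induce_rulebase recovers a planted rule on clean data", {
  fx <- induction_fixture()
  rb <- fx$rb
  expect_lte(length(rb$rules), 50L)
  # held-out style check on the full genome
  ev <- evaluate_rulebase(rb, fx$sim$dataset)
  expect_gte(ev$report$average_recall, 0.95)
  learned_sets <- lapply(Filter(function(r) r$consequent == "enhancer",
                                rb$rules), function(r) sort(r$marks))
  expect_true(any(vapply(learned_sets, identical, logical(1),
                         c("H3K4me1", "H4K16ac"))))
  # constraint satisfaction and dominance bounds
  for (r in rb$rules) {
    expect_lte(length(r$marks), 3L)
    expect_false(anyDuplicated(r$marks) > 0)
    expect_true(r$dominance >= 0 && r$dominance <= 10)
  }
  cls <- vapply(rb$rules, `[[`, character(1), "consequent")
  expect_true(all(c("enhancer", "non_enhancer") %in% cls))
  # elitism: best fitness never decreases
  expect_true(all(diff(attr(rb, "history")) >= 0))
})

test_that("induction is deterministic under a fixed seed", {
  fx <- induction_fixture()
  sub <- sample_training_set(fx$sim$dataset, n = 8000, test_fraction = 0.3,
                             seed = 2)
  icfg <- induction_config(pop_size = 20, generations = 10, patience = 5,
                           fit_sample = 4000, seed = 77)
  rb1 <- induce_rulebase(sub$train, icfg)
  rb2 <- induce_rulebase(sub$train, icfg)
  expect_equal(vapply(rb1$rules, format, character(1)),
               vapply(rb2$rules, format, character(1)))
  expect_equal(vapply(rb1$rules, `[[`, numeric(1), "dominance"),
               vapply(rb2$rules, `[[`, numeric(1), "dominance"))
  expect_error(induce_rulebase(
    .subset_ds <- local({
      d <- sub$train; d$labels[] <- FALSE; d
    }), icfg), "both classes")
})

test_that("classification metrics match the brute-force oracle", {
  set.seed(33)
  p <- round(runif(2000), 3)  # ties included
  y <- runif(2000) < 0.3
  got <- classification_metrics(p, y)
  want <- metrics_oracle(p, y)
  expect_equal(unname(got$confusion),
               c(want$TP, want$TN, want$FP, want$FN))
  expect_equal(got$report$accuracy, want$accuracy)
  expect_equal(got$report$precision, want$precision)
  expect_equal(got$report$recall, want$recall)
  expect_equal(got$report$average_recall, want$average_recall)
  expect_equal(got$report$auc, want$auc, tolerance = 1e-12)
  expect_equal(got$report$gini, 2 * got$report$auc - 1)
  # formula spot checks: one of each cell -> all 0.5
  p4 <- c(0.9, 0.1, 0.9, 0.1); y4 <- c(TRUE, FALSE, FALSE, TRUE)
  m4 <- classification_metrics(p4, y4)
  expect_equal(m4$report$accuracy, 0.5)
  expect_equal(m4$report$precision, 0.5)
  expect_equal(m4$report$recall, 0.5)
  # perfect separation -> AUC 1, gini 1; AUC 0.75 -> gini 0.5
  ms <- classification_metrics(c(0.9, 0.8, 0.2, 0.1),
                               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ms$report$auc, 1)
  expect_equal(ms$report$gini, 1)
  m75 <- classification_metrics(c(0.9, 0.4, 0.6, 0.2),
                                c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m75$report$auc, 0.75)
  expect_equal(m75$report$gini, 0.5)
  expect_error(classification_metrics(p, y, threshold = 1), "inside")
  expect_error(classification_metrics(p, y, threshold = 0), "inside")
})

test_that("expert rules are parsed, weighted and appended safely", {
  fx <- induction_fixture()
  rb <- fx$rb
  train <- fx$sim$dataset
  r <- parse_rule("H3K4me1=high & H4K16ac=high => enhancer")
  expect_equal(sort(r$marks), c("H3K4me1", "H4K16ac"))
  expect_equal(r$consequent, "enhancer")
  expect_error(parse_rule("H3K4me1=high"), "=>")
  expect_error(parse_rule("H3K4me1:high => enhancer"), "antecedent")

  n0 <- length(rb$rules)
  # this exact rule is typically already learned -> duplicate warning
  keys <- vapply(rb$rules, enhancerRules:::.rule_key, character(1))
  if (enhancerRules:::.rule_key(r) %in% keys) {
    expect_warning(rb_same <- add_expert_rule(rb, r, train), "duplicate")
    expect_equal(length(rb_same$rules), n0)
  }
  # a fresh rule is appended with data-driven dominance
  r2 <- fuzzy_rule(c("H3K4me1", "H4K16ac"), c("high", "medium"),
                   "non_enhancer")
  rb2 <- add_expert_rule(rb, r2, train)
  expect_equal(length(rb2$rules), n0 + 1L)
  expect_true(tail(rb2$rules, 1)[[1]]$dominance >= 0)
  expect_equal(vapply(rb2$rules[seq_len(n0)], format, character(1)),
               vapply(rb$rules, format, character(1)))
  # appending changes evaluation by a measurable, reported delta
  ev0 <- evaluate_rulebase(rb, train)
  ev2 <- evaluate_rulebase(rb2, train)
  expect_true(is.finite(ev2$report$average_recall - ev0$report$average_recall))
  # a rule that never fires leaves all predictions unchanged
  dead <- fuzzy_rule(c("H3K4me1", "H4K16ac"), c("low", "high"), "enhancer")
  rb3 <- add_expert_rule(rb, dead, train)
  p_dead <- predict_probability(rb3, train$features)
  fir <- enhancerRules:::.firing_matrix(list(dead), train$features,
                                        rb$partitions)
  if (all(fir$upper == 0))
    expect_equal(p_dead, predict_probability(rb, train$features))
})

test_that("removing a zero-dominance rule never changes predictions", {
  fx <- induction_fixture()
  rb <- fx$rb
  zero <- fuzzy_rule("H4K16ac", "medium", "enhancer", dominance = 0)
  rb_plus <- rb
  rb_plus$rules <- c(rb_plus$rules, list(zero))
  X <- fx$sim$dataset$features[1:2000, ]
  expect_equal(predict_probability(rb_plus, X), predict_probability(rb, X))
})

test_that("cross_cell_apply is pure inference with mark checks", {
  fx <- induction_fixture()
  rb <- fx$rb
  ds <- fx$sim$dataset
  p_train <- predict_probability(rb, ds$features)
  expect_identical(cross_cell_apply(rb, ds), p_train)
  # a second genome from the same planted rules generalizes
  cfg2 <- fx$sim$config
  cfg2$seed <- 555
  sim2 <- generate_tracks(cfg2)
  ev1 <- classification_metrics(p_train, ds$labels)
  ev2 <- classification_metrics(cross_cell_apply(rb, sim2$dataset),
                                sim2$dataset$labels)
  expect_lt(abs(ev1$report$average_recall - ev2$report$average_recall), 0.05)
  # missing referenced mark errors by name; extra marks warn
  used <- enhancerRules:::.rulebase_marks(rb)[1]
  ds_missing <- ds
  keep <- setdiff(colnames(ds$features), used)
  ds_missing$features <- ds$features[, keep, drop = FALSE]
  ds_missing$feature_order <- keep
  expect_error(cross_cell_apply(rb, ds_missing), used)
  ds_extra <- ds
  ds_extra$features <- cbind(ds$features, novelmark = 0.5)
  ds_extra$feature_order <- c(ds$feature_order, "novelmark")
  expect_warning(cross_cell_apply(rb, ds_extra), "novelmark")
})
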