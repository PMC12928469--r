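test_that("stratified splits have exact class arithmetic and determinism", {
  pop <- labeled_population(random_genotypes(600, 10),
                            rep(c("Case", "Control"), each = 300))
  parts <- split_population(pop, 2 / 3, seed = 1)
  expect_equal(sum(parts$train$labels == "Case"), 200)
  expect_equal(sum(parts$train$labels == "Control"), 200)
  expect_equal(nrow(parts$test$genotypes), 200)
  expect_identical(parts$train$genotypes,
                   split_population(pop, 2 / 3, seed = 1)$train$genotypes)
  expect_error(split_population(pop, 1, seed = 1), "empty")
  solo <- labeled_population(random_genotypes(10, 4), rep("Case", 10))
  expect_error(split_population(solo, 0.5), "absent")
})

test_that("rank-based AUC agrees with pair counting and pROC", {
  labs <- factor(rep(c("Case", "Control"), each = 3), levels = c("Control", "Case"))
  expect_equal(auc_score(c(4, 5, 6, 1, 2, 3), labs), 1)
  expect_equal(auc_score(rep(1, 6), labs), 0.5)
  toy <- c(0.9, 0.4, 0.4, 0.7, 0.4, 0.1)
  expect_equal(auc_score(toy, labs), brute_auc(toy, labs))
  set.seed(2)
  s <- sample(seq(0, 1, by = 0.05), 40, TRUE)
  l <- factor(sample(c("Case", "Control"), 40, TRUE), levels = c("Control", "Case"))
  expect_equal(auc_score(s, l), brute_auc(s, l))
  expect_equal(auc_score(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<", levels = c("Control", "Case")))))
  # complementing the scores complements the AUC
  expect_equal(auc_score(s, l) + auc_score(-s, l), 1)
  expect_error(auc_score(1:3, factor(rep("Case", 3), levels = c("Control", "Case"))),
               "both classes")
})

test_that("every classifier kind trains and scores a separable fixture", {
  set.seed(5)
  g <- random_genotypes(900, 48)
  labs <- ifelse(rowSums(g) + rnorm(900, 0, 1) > 48, "Case", "Control")
  # guard against degenerate draws
  stopifnot(min(table(labs)) > 100)
  pop <- labeled_population(g, labs)
  parts <- split_population(pop, seed = 6)
  for (kind in c("NB", "LR", "DT", "RF")) {
    tc <- suppressWarnings(train_and_score(parts$train, parts$test, kind, seed = 7))
    # the rule is linear in the doses: additive models should excel, the
    # axis-splitting tree merely beats chance
    expect_gte(tc$auc, if (kind == "DT") 0.6 else 0.85)
    expect_lte(tc$auc, 1)
  }
})

test_that("the 25-unit sigmoid network separates a linear rule almost perfectly", {
  set.seed(8)
  g <- random_genotypes(900, 48)
  labs <- ifelse(rowSums(g) > 48, "Case", "Control")
  pop <- labeled_population(g, labs)
  parts <- split_population(pop, seed = 9)
  tc <- suppressWarnings(train_and_score(parts$train, parts$test,
                                         classifier_spec("NN", maxit = 300),
                                         seed = 10))
  expect_gt(tc$auc, 0.95)
  # label permutation drives the same scores to chance level
  set.seed(11)
  null_auc <- replicate(20, auc_score(tc$scores, sample(parts$test$labels)))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
})

test_that("Welch comparison matches the closed-form statistic", {
  expect_equal(compare_models(c(0.8, 0.8, 0.8), c(0.8, 0.8, 0.8)), 0.5)
  expect_equal(compare_models(c(0.9, 0.9), c(0.2, 0.2)), 0)
  # frozen hand evaluation: t = 2.44949, Welch df = 4, one-tailed
  p <- compare_models(c(0.80, 0.85, 0.90), c(0.70, 0.75, 0.80))
  expect_equal(p, 0.035242, tolerance = 1e-4)
  big <- compare_models(seq(0.9, 0.95, length.out = 5) + 10,
                        seq(0.9, 0.95, length.out = 5))
  expect_lt(big, 1e-6)
  expect_error(compare_models(0.5, c(0.4, 0.5)), "replicates")
})

test_that("replicated experiments are bitwise reproducible end to end", {
  prof <- core_profile(n_case = 150, n_control = 100)
  model <- simple_model(P = 2, R = 3, Mg = 2, Mp = 1)
  r1 <- run_experiment(model, prof, sizes = 1, classifiers = c("NB", "DT"),
                       replicates = 2, seed = 42)
  r2 <- run_experiment(model, prof, sizes = 1, classifiers = c("NB", "DT"),
                       replicates = 2, seed = 42)
  expect_identical(r1$results, r2$results)
  expect_true(all(r1$results$auc >= 0 & r1$results$auc <= 1))
  sm <- summary(r1)
  expect_equal(nrow(sm), 2)
  expect_true(all(c("mean_auc", "se") %in% names(sm)))
  # mislabelling perturbation runs through the pipeline
  r3 <- run_experiment(model, prof, sizes = 1, classifiers = "DT",
                       replicates = 1, seed = 1,
                       perturbation = list(kind = "mislabel_cases", fraction = 0.2))
  expect_equal(nrow(r3$results), 1)
})
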