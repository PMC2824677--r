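sep_toy <- function(n = 200, seed = 131) {
  set.seed(seed)
  lab <- rep(c("true", "false"), each = n / 2)
  data.frame(comp_score = ifelse(lab == "true", 1, -1) * runif(n, 0.5, 5),
             pct_mismatch = runif(n, 0, 0.05),
             label = lab, stringsAsFactors = FALSE)
}

test_that("a separable feature yields a perfect tree split on that feature", {
  toy <- sep_toy()
  model <- trainClassifier(toy, algorithm = "decision_tree", seed = 1L)
  pred <- predictLabels(model, toy[setdiff(names(toy), "label")])
  expect_identical(as.character(pred), toy$label)
  expect_identical(as.character(model@fit$frame$var[1L]), "comp_score")
})

test_that("training is deterministic and validates its inputs", {
  toy <- sep_toy()
  for (alg in c("decision_tree", "naive_bayes_gaussian", "naive_bayes_kde",
                "random_forest")) {
    m1 <- trainClassifier(toy, algorithm = alg, seed = 9L)
    m2 <- trainClassifier(toy, algorithm = alg, seed = 9L)
    expect_identical(predictLabels(m1, toy[-3L]), predictLabels(m2, toy[-3L]),
                     info = alg)
  }
  expect_error(trainClassifier(toy, algorithm = "svm"), "unknown algorithm")
  one <- toy[toy$label == "true", ]
  expect_error(trainClassifier(one, algorithm = "decision_tree"),
               "single class")
  expect_error(trainClassifier(toy[1:10, ], rep("true", 9)),
               "differ in length")
})

test_that("prediction enforces the feature schema", {
  toy <- sep_toy()
  model <- trainClassifier(toy, algorithm = "decision_tree", seed = 1L)
  expect_error(predictLabels(model, toy["pct_mismatch"]),
               "lacks model features: comp_score")
  extra <- toy[-3L]
  extra$bogus <- 1
  expect_error(predictLabels(model, extra), "unknown feature columns: bogus")
  # empty table gives empty predictions
  expect_identical(length(predictLabels(model, toy[0, -3L])), 0L)
})

test_that("missing comparative scores are handled by every algorithm", {
  toy <- sep_toy(400)
  # make the comparative score missing for a third of the training rows
  toy$comp_score[seq(1, 400, by = 3)] <- NA
  toy$pct_mismatch <- toy$pct_mismatch +
    ifelse(toy$label == "true", 0, 0.05)  # weak second signal
  for (alg in c("decision_tree", "naive_bayes_gaussian", "naive_bayes_kde",
                "random_forest")) {
    m <- trainClassifier(toy, algorithm = alg, seed = 2L)
    allna <- toy[-3L]
    allna$comp_score <- NA_real_
    p <- predictLabels(m, allna)
    expect_identical(length(p), nrow(allna), info = alg)
    expect_false(anyNA(p), info = alg)
  }
})

test_that("classification metrics implement the stated definitions", {
  perfect <- evaluateClassification(rep(c("true", "false"), each = 5),
                                    rep(c("true", "false"), each = 5))
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$false_positive_rate, 0)
  expect_identical(perfect$false_negative_rate, 0)

  allpos <- evaluateClassification(rep("true", 10),
                                   rep(c("true", "false"), c(7, 3)))
  expect_identical(allpos$accuracy, 0.7)
  expect_identical(allpos$false_positive_rate, 1)
  expect_identical(allpos$false_negative_rate, 0)

  m <- evaluateClassification(
    c(rep("true", 95), rep("false", 5)),
    c(rep("true", 90), rep("false", 5), rep("false", 5)))
  expect_identical(m$TP, 90L)
  expect_identical(m$FP, 5L)
  expect_identical(m$TN, 5L)
  expect_identical(m$FN, 0L)
  expect_identical(m$accuracy, 0.95)
  expect_identical(m$false_positive_rate, 0.5)
  expect_identical(m$false_negative_rate, 0)

  expect_error(evaluateClassification("true", c("true", "false")),
               "differ in length")
})

test_that("metrics identities hold and survive duplication", {
  set.seed(141)
  p <- sample(c("true", "false"), 300, replace = TRUE)
  a <- sample(c("true", "false"), 300, replace = TRUE)
  m <- evaluateClassification(p, a)
  expect_equal(m$accuracy, 1 - (m$FP + m$FN) / 300)
  d <- evaluateClassification(rep(p, 2), rep(a, 2))
  expect_equal(d$false_positive_rate, m$false_positive_rate)
  expect_equal(d$false_negative_rate, m$false_negative_rate)
  expect_equal(d$accuracy, m$accuracy)
})

test_that("a tree recovers a known decision rule under label noise", {
  set.seed(151)
  n <- 5000
  eps <- 0.05
  x <- data.frame(kmer_q2 = runif(n, 0, 6), pct_mismatch = runif(n, 0, 0.06))
  rule <- ifelse(x$kmer_q2 > 2.5 & x$pct_mismatch > 0.02, "false", "true")
  flip <- runif(n) < eps
  y <- ifelse(flip, ifelse(rule == "true", "false", "true"), rule)
  idx <- seq_len(n / 2)
  m <- trainClassifier(x[idx, ], y[idx], algorithm = "decision_tree",
                       seed = 3L)
  pred <- predictLabels(m, x[-idx, ])
  acc <- mean(as.character(pred) == y[-idx])
  expect_gte(acc, 1 - eps - 0.03)
})
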