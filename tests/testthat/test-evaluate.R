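test_that("confusion counts match an independent tally", {
  cm <- confusion(c("a", "b", "a"), c("a", "b", "b"), c("a", "b"))
  expect_equal(cm@counts["a", "b"], 1)
  expect_equal(sum(cm@counts), 3)
  cmPerfect <- confusion(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(sum(diag(cmPerfect@counts)), 3)
  set.seed(55)
  truth <- sample(letters[1:4], 100, replace = TRUE)
  pred <- sample(letters[1:4], 100, replace = TRUE)
  cmBig <- confusion(truth, pred, letters[1:4])
  # oracle: explicit double loop
  for (i in letters[1:4]) for (j in letters[1:4])
    expect_equal(cmBig@counts[i, j], sum(truth == i & pred == j))
  expect_error(confusion("a", c("a", "b")), "equal length")
})

test_that("per-class one-vs-rest metrics follow the binary definitions", {
  cm <- confusion(c(rep("pos", 100), rep("neg", 50)),
                  c(rep("pos", 90), rep("neg", 10), rep("neg", 50)),
                  c("neg", "pos"))
  pm <- perClassMetrics(cm)
  expect_equal(pm$sensitivity[pm$class == "pos"], 0.9)
  expect_equal(pm$ppv[pm$class == "pos"], 1.0)
  # a class never true and never predicted: PPV undefined, flagged
  cm2 <- confusion(c("a", "a"), c("a", "a"), c("a", "ghost"))
  pm2 <- perClassMetrics(cm2)
  expect_true(is.na(pm2$ppv[pm2$class == "ghost"]))
  expect_true(pm2$undefined_ppv[pm2$class == "ghost"])
})

test_that("kappa reproduces the hand-worked binary example exactly", {
  # TP=40, FN=10, FP=20, TN=30: Io = 0.70, Ie = 0.50, K = 0.40
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 40), rep("neg", 10), rep("pos", 20), rep("neg", 30))
  k <- kappaStatistic(confusion(truth, pred, c("neg", "pos")))
  expect_equal(k$Io, 0.70)
  expect_equal(k$Ie, 0.50)
  expect_equal(k$kappa, 0.40)
  expect_equal(kappaStatistic(confusion(c("a", "b"), c("a", "b")))$kappa, 1)
})

test_that("kappa is near zero when predictions are independent of truth", {
  set.seed(77)
  truth <- sample(c("a", "b", "c"), 10000, replace = TRUE, prob = c(.6, .3, .1))
  pred <- sample(c("a", "b", "c"), 10000, replace = TRUE, prob = c(.5, .25, .25))
  expect_lt(abs(kappaStatistic(confusion(truth, pred))$kappa), 0.03)
})

test_that("kappa handles degenerate marginals with a flag, not a zero", {
  k <- kappaStatistic(confusion(c("a", "a"), c("a", "a"), c("a", "b")))
  expect_equal(k$kappa, 1)
  # disjoint marginals: expected agreement is 0, so kappa equals raw agreement
  k2 <- kappaStatistic(confusion(c("a", "a"), c("b", "b"), c("a", "b")))
  expect_equal(k2$Ie, 0)
  expect_equal(k2$kappa, 0)
})

test_that("AUC matches the Mann-Whitney rank oracle, including ties", {
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  sc <- c(0.9, 0.8, 0.8, 0.7, 0.5, 0.5, 0.5, 0.1)  # tie groups
  scores <- cbind(yes = sc, no = -sc)
  got <- rocAuc(scores, ifelse(pos, "yes", "no"))
  expect_equal(unname(got$perClass["yes"]), mannWhitneyAuc(sc, pos))
  expect_equal(unname(got$perClass["no"]), mannWhitneyAuc(-sc, !pos))
  # perfect ordering and all-tied limits
  perfect <- cbind(yes = c(.9, .8, .2, .1), no = c(.1, .2, .8, .9))
  labs <- c("yes", "yes", "no", "no")
  expect_equal(unname(rocAuc(perfect, labs)$perClass["yes"]), 1.0)
  flat <- cbind(yes = rep(0.5, 4), no = rep(0.5, 4))
  expect_equal(unname(rocAuc(flat, labs)$perClass["yes"]), 0.5)
  # invariance under strictly monotone transforms of the scores
  expect_equal(rocAuc(exp(3 * scores), ifelse(pos, "yes", "no"))$perClass,
               got$perClass)
})

test_that("AUC agrees with pROC and flags one-sided classes", {
  skip_if_not_installed("pROC")
  set.seed(88)
  sc <- runif(40)
  y <- rep(c("p", "n"), each = 20)
  ours <- rocAuc(cbind(p = sc, n = -sc), y)$perClass[["p"]]
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(y == "p", sc, levels = c(FALSE, TRUE), direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-12)
  out <- rocAuc(cbind(p = sc, ghost = sc), rep("p", 40))
  expect_equal(out$excluded, c("p", "ghost"))
})

test_that("accuracy is trace over n", {
  expect_equal(overallAccuracy(confusion(c("a", "b"), c("a", "b"))), 1)
  expect_equal(overallAccuracy(confusion(c("a", "b"), c("b", "a"))), 0)
  truth <- rep("a", 10)
  pred <- c(rep("a", 7), rep("b", 3))
  expect_equal(overallAccuracy(confusion(truth, pred, c("a", "b"))), 0.7)
})

test_that("stratified folds balance sizes and class proportions", {
  y <- c(rep("a", 53), rep("b", 27), rep("c", 20))
  fold <- stratifiedFolds(y, 10, seed = 3)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  for (cl in unique(y)) {
    perFold <- table(factor(fold[y == cl], levels = 1:10))
    expect_lte(max(perFold) - min(perFold), 1)
  }
  expect_error(stratifiedFolds(y, 1), "folds")
  expect_identical(stratifiedFolds(y, 10, seed = 3), fold)
})

test_that("cross-validation is perfect on a separable corpus and deterministic", {
  g <- separableCorpus(nDocs = 80, seed = 2)
  cfg <- pipelineConfig(preprocess = plainPreprocess(), reduce = FALSE,
                        weighting = "binary", method = "none",
                        mode = "memory", target = "external_cause")
  cv <- crossValidate(g$corpus, cfg, folds = 5, seed = 1)
  expect_equal(unname(cv$mean["accuracy"]), 1.0)
  expect_equal(nrow(cv$perFold), 5L)
  cv2 <- crossValidate(g$corpus, cfg, folds = 5, seed = 1)
  expect_identical(cv$perFold, cv2$perFold)
})
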