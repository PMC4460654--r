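test_that("cosine 1-NN assigns the label of the most similar training document", {
  train <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  clf <- memoryClassifier(train, c("a", "b", "c"))
  out <- memoryClassify(clf, rbind(c(2, 0, 0)))   # scaled copy of row 1
  expect_equal(out$labels, "a")
  expect_equal(unname(out$scores[1, "a"]), 1)
  # orthogonal to everything: majority class, zero scores
  clf2 <- memoryClassifier(rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 1, 0, 0)),
                           c("a", "a", "b"))
  out2 <- memoryClassify(clf2, rbind(c(0, 0, 1, 0)))
  expect_equal(out2$labels, "a")
  expect_true(all(out2$scores == 0))
  expect_error(memoryClassify(clf, matrix(1, 1, 5)), "mismatch")
})

test_that("memory classification agrees with the brute-force cosine oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- matrix(rnorm(15 * 3), 15, 3)
    te <- matrix(rnorm(6 * 3), 6, 3)
    y <- sample(letters[1:3], 15, replace = TRUE)
    out <- memoryClassify(memoryClassifier(tr, y), te)
    expect_equal(out$labels, bruteForceCosine1nn(tr, y, te))
  }
})

test_that("cosine ties break to the lowest training index", {
  train <- rbind(c(1, 0), c(2, 0), c(0, 1))  # rows 1 and 2 are colinear
  clf <- memoryClassifier(train, c("first", "second", "other"))
  expect_equal(memoryClassify(clf, rbind(c(3, 0)))$labels, "first")
})

test_that("the model route trains, predicts and validates its contract", {
  set.seed(41)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  y <- rep(c("lo", "hi"), each = 20)
  m <- modelTrain(x, y, classifierSpec("svm", seed = 1))
  pr <- modelPredict(m, x)
  expect_gte(mean(pr$labels == y), 0.975)
  expect_equal(colnames(pr$scores), c("hi", "lo"))
  expect_error(modelTrain(x, rep("one", 40)), "single class")
  expect_error(modelPredict(m, matrix(0, 2, 5)), "width")
  # determinism under a fixed seed
  m2 <- modelTrain(x, y, classifierSpec("svm", seed = 1))
  expect_identical(modelPredict(m2, x)$labels, pr$labels)
  expect_error(classifierSpec("no-such-family"), "unknown")
})

test_that("one-hot augmentation appends exactly the label block", {
  f <- matrix(0.5, 2, 4)
  aug <- augmentWithCode(f, c("b", "a"), c("a", "b", "c"))
  expect_equal(ncol(aug), 7)
  expect_equal(unname(aug[1, 5:7]), c(0, 1, 0))
  expect_equal(unname(aug[2, 5:7]), c(1, 0, 0))
  expect_equal(unname(rowSums(aug[, 5:7])), c(1, 1))
  expect_equal(unname(augmentWithCode(f, c("z", "z"), "z")[, 5]), c(1, 1))
  expect_error(augmentWithCode(f, c("a", "q"), c("a", "b")), "outside")
})

test_that("enhancement with perfect stage-1 predictions equals gold augmentation", {
  g <- separableCorpus(nDocs = 90, seed = 4)
  toks <- preprocessCorpus(g$corpus, plainPreprocess())
  vocab <- termFrequencyProfile(toks[1:60])$terms
  tr <- as.matrix(buildDtm(toks[1:60], vocab, "binary")@D)
  te <- as.matrix(buildDtm(toks[61:90], vocab, "binary")@D)
  yTr <- codes(g$corpus, "injury_factor")[1:60]
  aTr <- codes(g$corpus, "external_cause")[1:60]
  aTe <- codes(g$corpus, "external_cause")[61:90]
  # 1-NN stage 1 is exact on disjoint-support classes
  spec <- classifierSpec("knn1", seed = 2)
  aux <- codeLabels(g$corpus, "external_cause")
  pred <- enhancedClassify(tr, yTr, aTr, aux, te, spec, "predicted")
  # the separable corpus makes stage 1 perfect, so both modes must agree
  expect_equal(pred$auxPredicted, aTe)
  gold <- enhancedClassify(tr, yTr, aTr, aux, te, spec, "gold", testAux = aTe)
  expect_identical(pred$labels, gold$labels)
  expect_error(enhancedClassify(tr, yTr, yTr, aux, te, spec), "must differ")
})

test_that("1-NN baseline is memory classification on raw weighted features", {
  g <- separableCorpus(nDocs = 40, seed = 6)
  toks <- preprocessCorpus(g$corpus, plainPreprocess())
  vocab <- termFrequencyProfile(toks[1:30])$terms
  tr <- buildDtm(toks[1:30], vocab, "binary")
  te <- buildDtm(toks[31:40], vocab, "binary")
  y <- codes(g$corpus, "external_cause")[1:30]
  base <- knnBaseline(tr, y, te)
  direct <- memoryClassify(memoryClassifier(tr, y), te)
  expect_identical(base, direct)
  # disjoint-support class-pure vocabularies: perfect accuracy
  expect_equal(base$labels, codes(g$corpus, "external_cause")[31:40])
})
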