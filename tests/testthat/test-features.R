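mixtureProfile <- function(x, terms = sprintf("t%05d", seq_along(x))) {
  structure(list(terms = terms, x = as.integer(x)),
            class = "term_frequency_profile")
}

test_that("EM recovers a well-separated two-Gaussian mixture on the log scale", {
  set.seed(101)
  z <- c(rnorm(500, 2, 0.3), rnorm(500, 7, 0.3))
  prof <- mixtureProfile(pmax(1L, as.integer(round(exp(z)))))
  fit <- fitFrequencyMixture(prof)
  expect_true(fit@converged)
  expect_lt(abs(fit@mean[1] - 2), 0.1)
  expect_lt(abs(fit@mean[2] - 7), 0.1)
  # responsibilities are a proper posterior and the likelihood never drops
  expect_equal(rowSums(fit@responsibilities), rep(1, 1000), tolerance = 1e-10)
  expect_true(all(diff(fit@logLik) >= -1e-9))
})

test_that("two perfectly separated frequency values give a hard assignment", {
  prof <- mixtureProfile(c(rep(1L, 40), rep(100L, 20)))
  fit <- fitFrequencyMixture(prof)
  expect_lt(abs(fit@mean[1] - log(1)), 1e-3)
  expect_lt(abs(fit@mean[2] - log(100)), 1e-3)
  lab <- assignTermClusters(fit, prof)
  expect_true(all(lab[prof$x == 1] == "infrequent"))
  expect_true(all(lab[prof$x == 100] == "frequent"))
  expect_error(fitFrequencyMixture(mixtureProfile(rep(5L, 10))), "degenerate")
})

test_that("cluster assignment is argmax with ties going to frequent", {
  prof <- mixtureProfile(c(1L, 2L), c("a", "b"))
  m <- new("TermMixtureModel", mean = c(0, 1), sd = c(1, 1),
           responsibilities = rbind(c(0.9, 0.1), c(0.5, 0.5)),
           logLik = 0, nIter = 1L, converged = TRUE, epsilon = 1e-6,
           logScale = TRUE)
  lab <- assignTermClusters(m, prof)
  expect_equal(unname(lab), c("infrequent", "frequent"))
})

test_that("vocabulary reduction drops the infrequent cluster and guards top-N", {
  prof <- mixtureProfile(c(rep(1L, 4), rep(50L, 6)))
  labels <- setNames(c(rep("infrequent", 4), rep("frequent", 6)), prof$terms)
  expect_length(reduceVocabulary(prof, labels), 6L)
  expect_warning(
    v <- reduceVocabulary(prof, labels, topNRemove = prof$terms[10]),
    "domain guidance")
  expect_length(v, 5L)
  allInf <- setNames(rep("infrequent", 10), prof$terms)
  expect_error(reduceVocabulary(prof, allInf), "every term")
})

test_that("DTM weighting schemes agree with their definitions", {
  toks <- list(d1 = c("fall", "fall", "chair"), d2 = c("fall", "stove"))
  vocab <- c("fall", "chair")
  bin <- buildDtm(toks, vocab, "binary")
  expect_equal(as.matrix(bin@D), matrix(c(1, 1, 1, 0), 2, 2,
               dimnames = NULL), ignore_attr = TRUE)
  tf <- buildDtm(toks, vocab, "tf")
  expect_equal(as.matrix(tf@D)[1, ], c(2, 1), ignore_attr = TRUE)
  # a term present in every document gets idf 0
  tfidf <- buildDtm(toks, vocab, "tfidf")
  expect_equal(as.matrix(tfidf@D)[, 1], c(0, 0), ignore_attr = TRUE)
  expect_equal(unname(tfidf@idf["chair"]), log(2))
  # binary entries are exactly the indicator of tf entries
  expect_equal(as.matrix(bin@D) > 0, as.matrix(tf@D) > 0)
})

test_that("training idf is reusable on test documents", {
  trainToks <- list(a = c("fall", "chair"), b = c("fall", "stove"))
  vocab <- c("fall", "chair", "stove")
  tr <- buildDtm(trainToks, vocab, "tfidf")
  te <- buildDtm(list(z = c("chair", "chair")), vocab, "tfidf", idf = tr@idf)
  expect_equal(as.matrix(te@D)[1, 2], 2 * log(2))
  expect_error(buildDtm(list(z = "x"), vocab, "tfidf", idf = c(bad = 1)),
               "cover the vocabulary")
})

test_that("DTM round-trips through Matrix Market with sidecars", {
  toks <- list(d1 = c("fall", "chair"), d2 = "stove")
  dtm <- buildDtm(toks, c("fall", "chair", "stove"), "tf")
  base <- file.path(withr::local_tempdir(), "dtm.mtx")
  writeDtm(dtm, base)
  back <- readDtm(base)
  expect_equal(as.matrix(back@D), as.matrix(dtm@D))
  expect_equal(back@vocabulary, dtm@vocabulary)
  expect_equal(back@docIds, dtm@docIds)
  expect_equal(back@weighting, dtm@weighting)
  # corrupt the vocabulary sidecar
  writeLines(dtm@vocabulary[1:2], paste0(base, ".vocab"))
  expect_error(readDtm(base), "does not match")
})
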