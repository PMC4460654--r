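# Fixtures and independent oracles shared across the suite. All data are
# built in code; nothing is loaded from disk except the packaged word lists.

tinyCorpus <- function() {
  narrativeCorpus(
    recordId = c("r1", "r2", "r3", "r4"),
    narrative = c("fell off ladder at home",
                  "burnt hand on hot stove",
                  "cut finger with kitchen knife",
                  "fell from high chair"),
    externalCause = c("fall", "fire", "cutting", "fall"),
    injuryFactor = c("structure", "appliance", "utensil", "furnishing")
  )
}

# brute-force cosine 1-NN: the independent oracle for memoryClassify
bruteForceCosine1nn <- function(train, labels, test) {
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
  }
  majority <- names(sort(table(labels), decreasing = TRUE))[1]
  out <- character(nrow(test))
  for (i in seq_len(nrow(test))) {
    sims <- vapply(seq_len(nrow(train)),
                   function(j) cosine(test[i, ], train[j, ]), 0)
    if (sqrt(sum(test[i, ]^2)) == 0) out[i] <- majority
    else out[i] <- labels[which.max(sims)]
  }
  out
}

# rank-statistic (Mann-Whitney) AUC: the independent oracle for rocAuc
mannWhitneyAuc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# a corpus whose classes have disjoint signature vocabularies and no noise:
# classification in any faithful representation must be perfect
separableCorpus <- function(nDocs = 60, nClasses = 3, seed = 1) {
  generateCorpus(generatorConfig(
    nDocs = nDocs, nExternal = nClasses, nInjury = 2,
    externalProbs = rep(1 / nClasses, nClasses), injuryProbs = c(0.5, 0.5),
    gamma = 0, signatureSize = 4, backgroundSize = 10,
    mixWeights = c(1.0, 0.0, 0.0), meanLength = 10,
    misspellingRate = 0, abbreviationRate = 0, seed = seed))
}

# preprocessing with no dictionary and no spelling stage: deterministic and
# cheap, for pipeline-level tests
plainPreprocess <- function() {
  defaultPreprocessConfig(dictionary = character(0),
                          stages = c(spelling = FALSE))
}
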