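## Canned experiments at desk scale: the cross-code enhancement contrast and
## the planted-rank latent-dimension sweep. Both are deterministic given
## their seed vectors and are the basis of the package's reproducibility
## checks (see the methods vignette for the design rationale).

#' Paired enhancement-vs-plain experiment
#'
#' For each seed, generates a corpus at the given code-coupling strength,
#' trains an RBF-SVM on binary term features for the external-cause code
#' with and without gold one-hot augmentation by the injury-factor code,
#' and records both held-out accuracies. Gold augmentation is used because
#' under a deterministic coupling the predicted-label variant is
#' information-equivalent to the plain classifier (see vignette).
#'
#' @param gamma coupling strength passed to the generator.
#' @param seeds integer vector of replicate seeds.
#' @param nDocs,trainN corpus and training-split sizes (defaults 300/200).
#' @param meanLength mean narrative length in tokens (default 16).
#' @return data.frame with seed, plain and enhanced held-out accuracy.
#' @export
enhancementExperiment <- function(gamma, seeds, nDocs = 300L, trainN = 200L,
                                  meanLength = 16) {
  rows <- lapply(seeds, function(seed) {
    g <- generateCorpus(generatorConfig(nDocs = nDocs, gamma = gamma,
                                        meanLength = meanLength, seed = seed))
    cfg <- defaultPreprocessConfig(dictionary = g$truth$dictionary)
    toks <- preprocessCorpus(g$corpus, cfg)
    trIdx <- seq_len(trainN); teIdx <- (trainN + 1):nDocs
    vocab <- termFrequencyProfile(toks[trIdx])$terms
    dtr <- as.matrix(buildDtm(toks[trIdx], vocab, "binary")@D)
    dte <- as.matrix(buildDtm(toks[teIdx], vocab, "binary")@D)
    yTr <- codes(g$corpus, "external_cause")[trIdx]
    yTe <- codes(g$corpus, "external_cause")[teIdx]
    aTr <- codes(g$corpus, "injury_factor")[trIdx]
    aTe <- codes(g$corpus, "injury_factor")[teIdx]
    spec <- classifierSpec("svm", seed = seed + 37L)
    plain <- modelPredict(modelTrain(dtr, yTr, spec), dte)$labels
    enh <- enhancedClassify(dtr, yTr, aTr, codeLabels(g$corpus, "injury_factor"),
                            dte, spec, auxSource = "gold", testAux = aTe)$labels
    data.frame(seed = seed, plain = mean(plain == yTe),
               enhanced = mean(enh == yTe))
  })
  do.call(rbind, rows)
}

#' Latent-dimension sweep on corpora with planted rank 5
#'
#' Generates replicate corpora whose expected document-term matrix has rank
#' exactly 5: five equiprobable classes, each with a small saturated
#' signature vocabulary that every document of the class contains, plus a
#' class-independent background and no misspellings (which would leak class
#' signal into extra dimensions). Runs a cross-validated SVD + SVM pipeline
#' at each `k` and averages accuracy over the replicates.
#'
#' @param seeds integer vector of replicate corpus seeds.
#' @param ks latent dimensions to sweep (default `c(2, 5, 10)`).
#' @param folds CV folds per run (default 5).
#' @return data.frame with k and meanAccuracy.
#' @export
plantedRankSweep <- function(seeds, ks = c(2L, 5L, 10L), folds = 5L) {
  acc <- sapply(seeds, function(seed) {
    g <- generateCorpus(generatorConfig(
      nDocs = 100, nExternal = 5, nInjury = 2,
      externalProbs = rep(0.2, 5), injuryProbs = c(0.5, 0.5),
      gamma = 0, signatureSize = 4, backgroundSize = 60,
      mixWeights = c(0.5, 0, 0.5), meanLength = 14,
      misspellingRate = 0, seed = seed))
    cfg <- pipelineConfig(
      preprocess = defaultPreprocessConfig(dictionary = character(0),
                                           stages = c(spelling = FALSE)),
      reduce = FALSE, weighting = "tf", method = "svd",
      mode = "model", target = "external_cause")
    sweepAxis(g$corpus, cfg, "k", ks, folds = folds, seed = seed)$accuracy
  })
  data.frame(k = as.integer(ks), meanAccuracy = rowMeans(acc))
}
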