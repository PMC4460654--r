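## Orchestration: a single configuration object drives preprocess ->
## vocabulary reduction -> vectorization -> factorization -> classification
## -> evaluation, with every learned component fitted on training documents
## only. A thin command-line front end over these functions ships in
## inst/cli/narrafact.R.

#' Pipeline configuration
#'
#' @param preprocess a `preprocess_config` (default [defaultPreprocessConfig()]).
#' @param reduce apply the EM mixture vocabulary cutoff (default TRUE).
#' @param weighting DTM weighting, `"binary"` (default; works best on short
#'   narratives), `"tf"` or `"tfidf"`.
#' @param method representation: `"none"` (raw weighted DTM), `"svd"`
#'   (truncated SVD coordinates) or `"nnmf"` (NNMF document coordinates).
#' @param k latent dimension for `"svd"`/`"nnmf"` (capped at min(m, n) - 1
#'   of the training fold at fit time).
#' @param loss NNMF loss (`"frobenius"` or `"kl"`).
#' @param mode `"memory"` (cosine 1-NN in the representation) or `"model"`
#'   (registered downstream classifier).
#' @param family downstream classifier family for `"model"` mode.
#' @param hyperparameters named list for the downstream family.
#' @param target code axis to classify, `"external_cause"` or
#'   `"injury_factor"`.
#' @param enhance apply cross-code learning enhancement (model mode only):
#'   the other code axis is appended as one-hot supplementary features.
#' @param auxSource `"predicted"` (stage-1 predictions at test time, the
#'   deployable default) or `"gold"` (oracle upper bound; requires gold
#'   auxiliary labels at prediction).
#' @param topNRemove optional curated character vector of frequent terms to
#'   drop on top of the mixture cutoff.
#' @return a `pipeline_config` list.
#' @export
pipelineConfig <- function(preprocess = defaultPreprocessConfig(),
                           reduce = TRUE,
                           weighting = c("binary", "tf", "tfidf"),
                           method = c("none", "svd", "nnmf"),
                           k = 10L, loss = "frobenius",
                           mode = c("memory", "model"),
                           family = "svm", hyperparameters = list(),
                           target = c("external_cause", "injury_factor"),
                           enhance = FALSE,
                           auxSource = c("predicted", "gold"),
                           topNRemove = NULL) {
  weighting <- match.arg(weighting)
  method <- match.arg(method)
  mode <- match.arg(mode)
  target <- match.arg(target)
  auxSource <- match.arg(auxSource)
  if (enhance && mode != "model")
    stop("learning enhancement requires mode = 'model'")
  structure(list(
    preprocess = preprocess, reduce = reduce, weighting = weighting,
    method = method, k = as.integer(k), loss = loss, mode = mode,
    family = family, hyperparameters = hyperparameters, target = target,
    enhance = enhance, auxSource = auxSource, topNRemove = topNRemove
  ), class = "pipeline_config")
}

.otherAxis <- function(axis) {
  if (axis == "external_cause") "injury_factor" else "external_cause"
}

#' Fit the classification pipeline on training documents
#'
#' All learned components — the mixture vocabulary cutoff, IDF statistics,
#' the factorization basis and the classifier — are fitted here from the
#' training documents only; [predictPipeline()] reuses them unchanged on new
#' documents, so no test-side information can leak into fitting.
#'
#' @param tokens list of preprocessed token vectors (training documents).
#' @param trainCorpus the training [NarrativeCorpus-class] (supplies both
#'   code axes and their label vocabularies).
#' @param config a `pipeline_config`.
#' @param seed integer seed fanned out to the stochastic stages.
#' @return a `fitted_pipeline` (for [predictPipeline()]); its `artifacts`
#'   element records the fitted vocabulary, idf, mixture parameters and
#'   factorization basis.
#' @export
fitPipeline <- function(tokens, trainCorpus, config, seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- codes(trainCorpus, config$target)
  profile <- termFrequencyProfile(tokens)
  mixture <- NULL
  if (config$reduce && length(unique(profile$x)) >= 2) {
    mixture <- fitFrequencyMixture(profile)
    labels <- assignTermClusters(mixture, profile)
    vocab <- reduceVocabulary(profile, labels, config$topNRemove)
  } else {
    vocab <- profile$terms
    if (!is.null(config$topNRemove)) vocab <- setdiff(vocab, config$topNRemove)
  }
  dtm <- buildDtm(tokens, vocab, config$weighting)

  k <- min(config$k, dim(dtm@D) - 1L)
  k <- max(k, 1L)
  fact <- NULL
  repr <- switch(config$method,
    none = as.matrix(dtm@D),
    svd = {
      fact <- svdTruncate(dtm, k)
      .asDense(dtm) %*% fact@V
    },
    nnmf = {
      fact <- nnmfFit(dtm, k, loss = config$loss, seed = seed + 23L)
      fact@A
    })

  clf <- NULL; stage1 <- NULL; stage2 <- NULL
  auxAxis <- .otherAxis(config$target)
  if (config$mode == "memory") {
    clf <- memoryClassifier(repr, y)
  } else {
    spec <- classifierSpec(config$family, config$hyperparameters,
                           seed = seed + 37L)
    if (config$enhance) {
      aux <- codes(trainCorpus, auxAxis)
      auxSet <- codeLabels(trainCorpus, auxAxis)
      stage1 <- modelTrain(repr, aux, spec)
      stage2 <- modelTrain(augmentWithCode(repr, aux, auxSet), y, spec)
    } else {
      clf <- modelTrain(repr, y, spec)
    }
  }

  structure(list(
    config = config, vocabulary = vocab, idf = dtm@idf,
    factorization = fact, classifier = clf,
    stage1 = stage1, stage2 = stage2,
    auxLabelSet = codeLabels(trainCorpus, auxAxis),
    targetLabelSet = codeLabels(trainCorpus, config$target),
    artifacts = list(
      vocabulary = vocab, idf = dtm@idf,
      mixture = if (!is.null(mixture)) c(mixture@mean, mixture@sd),
      basis = if (!is.null(fact)) {
        if (is(fact, "SvdFactorization")) fact@V else fact@H
      }
    )
  ), class = "fitted_pipeline")
}

#' Predict with a fitted pipeline
#'
#' @param fit a `fitted_pipeline`.
#' @param tokens list of preprocessed token vectors (new documents).
#' @param testAux gold auxiliary labels, required only when the fitted
#'   config uses enhancement with `auxSource = "gold"`.
#' @return list with `labels` and per-class `scores`.
#' @export
predictPipeline <- function(fit, tokens, testAux = NULL) {
  stopifnot(inherits(fit, "fitted_pipeline"))
  config <- fit$config
  idf <- if (config$weighting == "tfidf") fit$idf else NULL
  dtm <- buildDtm(tokens, fit$vocabulary, config$weighting, idf = idf)
  repr <- switch(config$method,
    none = as.matrix(dtm@D),
    svd = .asDense(dtm) %*% fit$factorization@V,
    nnmf = nnmfTransform(dtm, fit$factorization, seed = 7L))
  if (config$mode == "memory") {
    memoryClassify(fit$classifier, repr)
  } else if (!config$enhance) {
    modelPredict(fit$classifier, repr)
  } else {
    auxTest <- if (config$auxSource == "gold") {
      if (is.null(testAux)) stop("auxSource = 'gold' requires testAux")
      as.character(testAux)
    } else {
      modelPredict(fit$stage1, repr)$labels
    }
    modelPredict(fit$stage2, augmentWithCode(repr, auxTest, fit$auxLabelSet))
  }
}

#' Run the pipeline end-to-end on a train/test split
#'
#' @param corpus a [NarrativeCorpus-class].
#' @param config a `pipeline_config`.
#' @param trainIdx integer indices of the training documents (default: first
#'   two thirds).
#' @param seed integer seed.
#' @return list with `report` (a `metric_report` including AUC), `labels`,
#'   `scores`, `confusion` and `fit`.
#' @export
runPipeline <- function(corpus, config, trainIdx = NULL, seed = 1L) {
  n <- length(corpus)
  if (is.null(trainIdx)) trainIdx <- seq_len(floor(2 * n / 3))
  testIdx <- setdiff(seq_len(n), trainIdx)
  tokens <- preprocessCorpus(corpus, config$preprocess)
  fit <- fitPipeline(tokens[trainIdx], corpus[trainIdx], config, seed = seed)
  testAux <- if (config$enhance && config$auxSource == "gold")
    codes(corpus, .otherAxis(config$target))[testIdx] else NULL
  pred <- predictPipeline(fit, tokens[testIdx], testAux = testAux)
  truth <- codes(corpus, config$target)[testIdx]
  cm <- confusion(truth, pred$labels, codeLabels(corpus, config$target))
  list(report = metricReport(cm, pred$scores, truth),
       labels = pred$labels, scores = pred$scores, confusion = cm, fit = fit)
}

#' Sweep one experimental axis
#'
#' Reruns the pipeline across values of one axis with a shared seed and
#' tabulates the resulting metrics — the synthetic analogue of the
#' classical experiment sweeps (latent dimension, term weighting, training
#' size, top-N removal).
#'
#' @param corpus a [NarrativeCorpus-class].
#' @param config base `pipeline_config`.
#' @param axis one of `"k"`, `"weighting"`, `"train_size"`, `"topn"`.
#' @param values vector of axis values: ranks for `"k"`, weighting names for
#'   `"weighting"`, training fractions in (0, 1) for `"train_size"`, counts
#'   of most-frequent terms to drop for `"topn"`.
#' @param folds folds for the cross-validated axes (`k`, `weighting`,
#'   `topn`); `train_size` uses a fixed held-out test third.
#' @param seed shared integer seed.
#' @return data.frame with one row per value: value, accuracy, kappa,
#'   macroAuc.
#' @export
sweepAxis <- function(corpus, config, axis = c("k", "weighting", "train_size", "topn"),
                      values, folds = 5L, seed = 1L) {
  axis <- match.arg(axis)
  if (!length(values)) stop("empty value list")
  rows <- lapply(values, function(v) {
    cfg <- config
    if (axis == "k") cfg$k <- as.integer(v)
    if (axis == "weighting") cfg$weighting <- match.arg(v, c("binary", "tf", "tfidf"))
    if (axis == "topn") {
      tokens <- preprocessCorpus(corpus, config$preprocess)
      prof <- termFrequencyProfile(tokens)
      cfg$topNRemove <- if (v > 0)
        prof$terms[order(-prof$x)][seq_len(v)] else NULL
    }
    if (axis == "train_size") {
      n <- length(corpus)
      testIdx <- seq.int(floor(2 * n / 3) + 1L, n)
      pool <- seq_len(floor(2 * n / 3))
      m <- max(2L, floor(v * length(pool)))
      res <- runPipeline(corpus, cfg, trainIdx = pool[seq_len(m)], seed = seed)
      cm <- res$confusion
      data.frame(value = v, accuracy = overallAccuracy(cm),
                 kappa = kappaStatistic(cm)$kappa,
                 macroAuc = res$report$auc$macro,
                 label = as.character(v))
    } else {
      cv <- crossValidate(corpus, cfg, folds = folds, seed = seed)
      data.frame(value = if (is.numeric(v)) v else NA, accuracy = cv$mean[["accuracy"]],
                 kappa = cv$mean[["kappa"]], macroAuc = cv$mean[["macroAuc"]],
                 label = as.character(v))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
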