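## Classifiers over raw or latent document representations: the cosine
## nearest-neighbour ("memory-based") classifier, a pluggable model-based
## classifier registry (RBF-kernel SVM by default), and the cross-code
## one-hot feature augmentation.

#' Memory-based (cosine 1-nearest-neighbour) classifier
#'
#' @param trainRepr matrix of training document representations (raw DTM
#'   rows, SVD coordinates, or NNMF coordinates).
#' @param trainLabels per-document class labels (length = rows).
#' @return a `memory_classifier` object for [memoryClassify()].
#' @export
memoryClassifier <- function(trainRepr, trainLabels) {
  trainRepr <- .asDense(trainRepr)
  trainLabels <- as.character(trainLabels)
  if (nrow(trainRepr) < 1) stop("need at least one training document")
  if (nrow(trainRepr) != length(trainLabels))
    stop("label count must equal training row count")
  norms <- sqrt(rowSums(trainRepr^2))
  out <- list(repr = trainRepr, labels = trainLabels, norms = norms,
              labelSet = sort(unique(trainLabels)))
  class(out) <- "memory_classifier"
  out
}

#' Classify by maximum cosine similarity to a training document
#'
#' Each test document receives the label of the training document with the
#' highest cosine similarity (1-nearest-neighbour in the shared latent
#' space). Ties break to the lowest training index. Zero-norm rows (on
#' either side) have similarity 0 to everything; a zero-norm test document
#' gets the majority training class. Per-class scores are the maximum
#' similarity to any training document of that class, suitable as ROC
#' scores.
#'
#' @param clf a `memory_classifier`.
#' @param testRepr matrix of test representations (same width as training).
#' @return list with `labels` (character) and `scores` (matrix, test docs x
#'   classes).
#' @export
memoryClassify <- function(clf, testRepr) {
  stopifnot(inherits(clf, "memory_classifier"))
  testRepr <- .asDense(testRepr)
  if (ncol(testRepr) != ncol(clf$repr))
    stop("dimension mismatch between test and training representations")
  trNorm <- clf$norms
  teNorm <- sqrt(rowSums(testRepr^2))
  ## cosine similarity matrix, zero-norm rows defined as similarity 0
  S <- testRepr %*% t(clf$repr)
  denom <- outer(teNorm, trNorm)
  S <- ifelse(denom > 0, S / ifelse(denom > 0, denom, 1), 0)
  labSet <- clf$labelSet
  majority <- names(which.max(table(factor(clf$labels, levels = labSet))))
  idx <- apply(S, 1L, which.max)           # ties: which.max takes lowest index
  labels <- clf$labels[idx]
  zero <- teNorm == 0
  labels[zero] <- majority
  scores <- vapply(labSet, function(cl) {
    cols <- clf$labels == cl
    apply(S[, cols, drop = FALSE], 1L, max)
  }, numeric(nrow(S)))
  scores <- matrix(scores, nrow = nrow(S),
                   dimnames = list(NULL, labSet))
  list(labels = labels, scores = scores)
}

## ---- model-based classifier registry --------------------------------------

.classifierRegistry <- new.env(parent = emptyenv())

#' Register a downstream classifier family
#'
#' The model-based route is a contract: any family providing a `train(x, y,
#' hyperparameters, seed)` function returning a model and a `predict(model,
#' x)` function returning `list(labels, scores)` can be plugged in.
#'
#' @param name family name.
#' @param train function(x, y, hyperparameters, seed) -> model.
#' @param predict function(model, x) -> list(labels = character,
#'   scores = matrix docs x classes).
#' @export
registerClassifierFamily <- function(name, train, predict) {
  assign(name, list(train = train, predict = predict),
         envir = .classifierRegistry)
  invisible(name)
}

#' @rdname registerClassifierFamily
#' @export
classifierFamilies <- function() sort(ls(.classifierRegistry))

#' Downstream classifier specification
#'
#' @param family registered family name; default `"svm"` (max-margin
#'   classifier with radial-basis kernel, one-vs-rest scores from class
#'   probabilities).
#' @param hyperparameters named list passed to the family's trainer.
#' @param seed integer seed.
#' @return a `classifier_spec` list.
#' @export
classifierSpec <- function(family = "svm", hyperparameters = list(), seed = 1L) {
  if (!family %in% classifierFamilies())
    stop("unknown classifier family: ", family,
         " (registered: ", paste(classifierFamilies(), collapse = ", "), ")")
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Train / predict with a registered model-based classifier
#'
#' @param features numeric matrix (documents x features): raw DTM, SVD
#'   coordinates, NNMF coordinates, possibly augmented.
#' @param labels character labels, >= 2 distinct classes.
#' @param spec a `classifier_spec`.
#' @return `modelTrain`: a `trained_model`. `modelPredict`: list with
#'   `labels` and per-class `scores`.
#' @export
modelTrain <- function(features, labels, spec = classifierSpec()) {
  features <- .asDense(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("training labels contain a single class")
  if (nrow(features) != length(labels))
    stop("label count must equal feature row count")
  fam <- get(spec$family, envir = .classifierRegistry)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  model <- fam$train(features, labels, spec$hyperparameters, spec$seed)
  structure(list(model = model, family = spec$family, width = ncol(features),
                 labelSet = sort(unique(labels))),
            class = "trained_model")
}

#' @rdname modelTrain
#' @param model a `trained_model` from [modelTrain()].
#' @export
modelPredict <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  features <- .asDense(features)
  if (ncol(features) != model$width)
    stop("feature width ", ncol(features),
         " does not match training width ", model$width)
  fam <- get(model$family, envir = .classifierRegistry)
  fam$predict(model$model, features)
}

## built-in family: RBF-kernel SVM (e1071), probability scores per class
.svmTrain <- function(x, y, hp, seed) {
  args <- list(x = x, y = factor(y), kernel = "radial",
               probability = TRUE, scale = FALSE)
  args[names(hp)] <- hp
  do.call(e1071::svm, args)
}

.svmPredict <- function(model, x) {
  pr <- stats::predict(model, x, probability = TRUE)
  probs <- attr(pr, "probabilities")
  probs <- probs[, sort(colnames(probs)), drop = FALSE]
  list(labels = as.character(pr), scores = probs)
}

## 1-NN through the same contract, for the traditional-classifier slot
.knnTrain <- function(x, y, hp, seed) memoryClassifier(x, y)
.knnPredict <- function(model, x) memoryClassify(model, x)

#' One-hot augmentation with an auxiliary code
#'
#' Appends p columns (one per auxiliary class) to the feature matrix; the
#' row of a document with auxiliary class i has 1 in column k+i and 0 in the
#' other appended columns.
#'
#' @param features numeric matrix (documents x k).
#' @param auxLabels auxiliary code per document.
#' @param labelSet ordered auxiliary class set (must cover `auxLabels`).
#' @return matrix of width k + p; appended columns named `aux:<class>`.
#' @export
augmentWithCode <- function(features, auxLabels, labelSet) {
  features <- .asDense(features)
  auxLabels <- as.character(auxLabels)
  if (!all(auxLabels %in% labelSet))
    stop("auxiliary label(s) outside the declared label set: ",
         paste(setdiff(auxLabels, labelSet), collapse = ", "))
  p <- length(labelSet)
  block <- matrix(0, nrow(features), p,
                  dimnames = list(NULL, paste0("aux:", labelSet)))
  block[cbind(seq_along(auxLabels), match(auxLabels, labelSet))] <- 1
  cbind(features, block)
}

#' Two-stage cross-code learning enhancement
#'
#' Exploits the correlation between the two injury codes (e.g. burns with
#' hot objects): when classifying the target code, the other ("auxiliary")
#' code is appended as one-hot supplementary features. Training uses the
#' gold auxiliary labels; at prediction time the auxiliary labels are
#' themselves predicted by a stage-1 unaugmented classifier
#' (`auxSource = "predicted"`, the deployable default) or taken as gold
#' (`auxSource = "gold"`, the oracle upper bound).
#'
#' @param trainFeatures,testFeatures numeric matrices in the same
#'   representation.
#' @param trainTarget gold target-code labels for training documents.
#' @param trainAux gold auxiliary-code labels for training documents.
#' @param auxLabelSet ordered auxiliary class set.
#' @param spec a `classifier_spec` used for both stages.
#' @param auxSource `"predicted"` or `"gold"`.
#' @param testAux gold auxiliary labels for test documents (required for
#'   `auxSource = "gold"`).
#' @return list with `labels`, `scores` and `auxPredicted` (stage-1 labels,
#'   NULL under gold augmentation).
#' @export
enhancedClassify <- function(trainFeatures, trainTarget, trainAux,
                             auxLabelSet, testFeatures,
                             spec = classifierSpec(),
                             auxSource = c("predicted", "gold"),
                             testAux = NULL) {
  auxSource <- match.arg(auxSource)
  if (identical(as.character(trainTarget), as.character(trainAux)))
    stop("target and auxiliary codes must differ")
  if (auxSource == "predicted") {
    stage1 <- modelTrain(trainFeatures, trainAux, spec)
    auxTest <- modelPredict(stage1, testFeatures)$labels
    auxPred <- auxTest
  } else {
    if (is.null(testAux)) stop("auxSource = 'gold' requires testAux")
    auxTest <- as.character(testAux)
    auxPred <- NULL
  }
  trainAug <- augmentWithCode(trainFeatures, trainAux, auxLabelSet)
  testAug <- augmentWithCode(testFeatures, auxTest, auxLabelSet)
  stage2 <- modelTrain(trainAug, trainTarget, spec)
  out <- modelPredict(stage2, testAug)
  list(labels = out$labels, scores = out$scores, auxPredicted = auxPred)
}

#' 1-nearest-neighbour baseline on raw weighted features
#'
#' The traditional k-NN (k = 1) baseline: [memoryClassify()] applied
#' directly to the weighted document-term rows rather than a latent space.
#'
#' @param trainDtm,testDtm [DocumentTermMatrix-class] objects (or matrices)
#'   over the same vocabulary.
#' @param trainLabels training labels.
#' @return list with `labels` and `scores` as in [memoryClassify()].
#' @export
knnBaseline <- function(trainDtm, trainLabels, testDtm) {
  memoryClassify(memoryClassifier(trainDtm, trainLabels), testDtm)
}
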