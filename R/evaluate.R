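## Medical-domain evaluation battery: per-class one-vs-rest sensitivity /
## specificity / PPV, overall accuracy, chance-corrected kappa, one-vs-rest
## ROC AUC, and leakage-free stratified cross-validation.

#' Build a confusion matrix
#'
#' @param trueLabels,predLabels equal-length label vectors.
#' @param labelSet ordered class set covering both vectors; defaults to the
#'   sorted union of observed labels.
#' @return a [ConfusionMatrix-class] (rows = true class, columns = predicted).
#' @export
confusion <- function(trueLabels, predLabels, labelSet = NULL) {
  trueLabels <- as.character(trueLabels)
  predLabels <- as.character(predLabels)
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  if (is.null(labelSet)) labelSet <- sort(unique(c(trueLabels, predLabels)))
  if (!all(trueLabels %in% labelSet) || !all(predLabels %in% labelSet))
    stop("labels outside the declared label set")
  counts <- as.matrix(table(factor(trueLabels, levels = labelSet),
                            factor(predLabels, levels = labelSet)))
  dimnames(counts) <- list(true = labelSet, predicted = labelSet)
  new("ConfusionMatrix", labels = as.character(labelSet),
      counts = matrix(as.numeric(counts), nrow = length(labelSet),
                      dimnames = dimnames(counts)))
}

#' Per-class one-vs-rest counts
#'
#' @param cm a [ConfusionMatrix-class].
#' @return data.frame with one row per class: TP, FP, TN, FN.
#' @export
ovrCounts <- function(cm) {
  n <- sum(cm@counts)
  tp <- diag(cm@counts)
  fn <- rowSums(cm@counts) - tp
  fp <- colSums(cm@counts) - tp
  tn <- n - tp - fn - fp
  data.frame(class = cm@labels, TP = tp, FP = fp, TN = tn, FN = fn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-class sensitivity, specificity and PPV
#'
#' One-vs-rest reductions of the binary definitions: sensitivity
#' TP/(TP+FN), specificity TN/(FP+TN), PPV TP/(TP+FP). A 0/0 denominator
#' yields `NA` with the corresponding `undefined_*` flag set, never a silent
#' zero.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return data.frame with class, sensitivity, specificity, ppv and
#'   undefined-metric flags.
#' @export
perClassMetrics <- function(cm) {
  oc <- ovrCounts(cm)
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.frame(
    class = oc$class,
    sensitivity = safe(oc$TP, oc$TP + oc$FN),
    specificity = safe(oc$TN, oc$FP + oc$TN),
    ppv = safe(oc$TP, oc$TP + oc$FP),
    undefined_sensitivity = (oc$TP + oc$FN) == 0,
    undefined_specificity = (oc$FP + oc$TN) == 0,
    undefined_ppv = (oc$TP + oc$FP) == 0,
    stringsAsFactors = FALSE
  )
}

#' Overall accuracy
#'
#' Multiclass accuracy trace/n; equals (TP+TN)/(TP+FP+TN+FN) in the binary
#' case.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return scalar in \[0, 1\].
#' @export
overallAccuracy <- function(cm) {
  n <- sum(cm@counts)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(cm@counts)) / n
}

#' Cohen's kappa
#'
#' Chance-corrected agreement K = (I_o - I_e)/(1 - I_e) with observed
#' agreement I_o = trace/n and expected agreement
#' I_e = sum_c row_c * col_c / n^2, the multiclass generalization that
#' reduces exactly to the binary
#' I_e = ((TN+FN)(TN+FP) + (TP+FP)(TP+FN))/n^2 for two classes. When
#' I_e = 1 (both marginals degenerate), K is 1 if agreement is perfect and
#' `NA` (flagged) otherwise.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with `kappa`, `Io`, `Ie`, `undefined`.
#' @export
kappaStatistic <- function(cm) {
  n <- sum(cm@counts)
  if (n == 0) stop("empty confusion matrix")
  Io <- sum(diag(cm@counts)) / n
  Ie <- sum(rowSums(cm@counts) * colSums(cm@counts)) / n^2
  if (1 - Ie < .Machine$double.eps * 4) {
    k <- if (Io == 1) 1 else NA_real_
    return(list(kappa = k, Io = Io, Ie = Ie, undefined = is.na(k)))
  }
  list(kappa = (Io - Ie) / (1 - Ie), Io = Io, Ie = Ie, undefined = FALSE)
}

.aucBinary <- function(scores, positive) {
  ## threshold-sweep trapezoidal area over the one-vs-rest ROC; tied scores
  ## fall in one threshold group, which makes the area equal the rank
  ## (Mann-Whitney) statistic
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  n1 <- sum(positive); n0 <- length(positive) - n1
  grp <- cumsum(!duplicated(s))
  tpGrp <- tapply(as.numeric(y), grp, sum)
  fpGrp <- tapply(as.numeric(!y), grp, sum)
  tpr <- c(0, cumsum(tpGrp) / n1)
  fpr <- c(0, cumsum(fpGrp) / n0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' One-vs-rest ROC AUC
#'
#' For each class, the documents of that class are the positives and the
#' per-class score column is swept over thresholds; the area is computed by
#' the trapezoidal rule, with tied scores grouped (equivalent to the
#' Mann-Whitney rank statistic). Classes with no positive or no negative
#' document are excluded from the macro average and flagged.
#'
#' @param scores matrix (documents x classes) of per-class decision scores;
#'   column names are the class labels.
#' @param trueLabels per-document gold labels.
#' @return list with `perClass` (named numeric, NA where undefined),
#'   `macro` (unweighted mean over defined classes) and `excluded`
#'   (character vector of skipped classes).
#' @export
rocAuc <- function(scores, trueLabels) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("scores must have class column names")
  trueLabels <- as.character(trueLabels)
  if (nrow(scores) != length(trueLabels))
    stop("one score row per document required")
  classes <- colnames(scores)
  per <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    pos <- trueLabels == cl
    if (any(pos) && any(!pos)) per[cl] <- .aucBinary(scores[, cl], pos)
  }
  excluded <- classes[is.na(per)]
  list(perClass = per,
       macro = mean(per[!is.na(per)]),
       excluded = excluded)
}

#' Stratified fold assignment
#'
#' Deterministic under the seed; within each class, documents are shuffled
#' and dealt round-robin, so fold sizes differ by at most one and per-fold
#' class proportions are within one document of the global ones. Classes
#' with fewer members than folds degrade gracefully (their few members land
#' in distinct folds).
#'
#' @param labels per-document class labels.
#' @param folds number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..folds.
#' @export
stratifiedFolds <- function(labels, folds = 10L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2) stop("folds must be >= 2")
  labels <- as.character(labels)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
    offset <- offset + length(idx)   # stagger classes across folds
  }
  fold
}

#' Stratified k-fold cross-validation of a pipeline
#'
#' Runs the configured classification pipeline `folds` times, each time
#' fitting every learned component (vocabulary cutoff, IDF statistics,
#' factorization bases, classifiers) on the training folds only and
#' evaluating on the held-out fold. Deterministic under the seed.
#'
#' @param corpus a [NarrativeCorpus-class].
#' @param config a [pipelineConfig()] describing the pipeline.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling fold assignment and all stage seeds.
#' @param foldIds optional precomputed fold assignment (overrides the
#'   stratified default; used e.g. for leakage probes where fold membership
#'   must not depend on labels).
#' @param returnArtifacts also return each fold's fitted artifacts
#'   (vocabulary, idf, factorization) for reproducibility audits.
#' @return list with `perFold` (data.frame: fold, accuracy, kappa, macroAuc),
#'   `mean` (named numeric means), `confusion` (pooled
#'   [ConfusionMatrix-class]), `report` (pooled metric report), and
#'   optionally `artifacts`.
#' @export
crossValidate <- function(corpus, config, folds = 10L, seed = 1L,
                          foldIds = NULL, returnArtifacts = FALSE) {
  target <- config$target
  y <- codes(corpus, target)
  if (is.null(foldIds)) foldIds <- stratifiedFolds(y, folds, seed)
  folds <- max(foldIds)
  tokens <- preprocessCorpus(corpus, config$preprocess)
  perFold <- vector("list", folds)
  arts <- vector("list", folds)
  allTrue <- character(0); allPred <- character(0)
  scoreRows <- list()
  labelSet <- codeLabels(corpus, target)
  for (f in seq_len(folds)) {
    teIdx <- which(foldIds == f)
    trIdx <- which(foldIds != f)
    fit <- fitPipeline(tokens[trIdx], corpus[trIdx], config,
                       seed = seed + f)
    pred <- predictPipeline(fit, tokens[teIdx])
    truth <- y[teIdx]
    cmF <- confusion(truth, pred$labels, labelSet)
    aucF <- tryCatch(rocAuc(pred$scores, truth)$macro,
                     error = function(e) NA_real_)
    perFold[[f]] <- data.frame(
      fold = f,
      accuracy = overallAccuracy(cmF),
      kappa = kappaStatistic(cmF)$kappa,
      macroAuc = aucF
    )
    allTrue <- c(allTrue, truth)
    allPred <- c(allPred, pred$labels)
    scoreRows[[f]] <- pred$scores
    if (returnArtifacts) arts[[f]] <- fit$artifacts
  }
  perFold <- do.call(rbind, perFold)
  cm <- confusion(allTrue, allPred, labelSet)
  out <- list(
    perFold = perFold,
    mean = c(accuracy = mean(perFold$accuracy),
             kappa = mean(perFold$kappa, na.rm = TRUE),
             macroAuc = mean(perFold$macroAuc, na.rm = TRUE)),
    confusion = cm,
    report = metricReport(cm)
  )
  if (returnArtifacts) out$artifacts <- arts
  out
}

#' Full metric report from a confusion matrix
#'
#' @param cm a [ConfusionMatrix-class].
#' @param scores optional score matrix for AUC (documents x classes).
#' @param trueLabels optional gold labels matching `scores`.
#' @return list with `perClass`, `accuracy`, `kappa` and (when scores are
#'   given) `auc`.
#' @export
metricReport <- function(cm, scores = NULL, trueLabels = NULL) {
  out <- list(
    perClass = perClassMetrics(cm),
    accuracy = overallAccuracy(cm),
    kappa = kappaStatistic(cm)
  )
  if (!is.null(scores) && !is.null(trueLabels))
    out$auc <- rocAuc(scores, trueLabels)
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f   Kappa: %.4f (Io %.4f, Ie %.4f)\n",
              x$accuracy, x$kappa$kappa, x$kappa$Io, x$kappa$Ie))
  if (!is.null(x$auc))
    cat(sprintf("Macro AUC: %.4f\n", x$auc$macro))
  print(x$perClass, digits = 3)
  invisible(x)
}
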