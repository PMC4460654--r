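## Vocabulary pruning by a two-component Gaussian mixture over term
## frequencies, and weighted document-term matrix construction.

#' Corpus term-frequency profile
#'
#' @param tokenLists list of token vectors (one per document), as returned by
#'   [preprocessCorpus()].
#' @return list with `terms` (ordered vocabulary) and `x` (per-term corpus
#'   frequency, positive integers), class `term_frequency_profile`.
#' @export
termFrequencyProfile <- function(tokenLists) {
  tab <- table(unlist(tokenLists, use.names = FALSE))
  if (!length(tab)) stop("termFrequencyProfile: no tokens in corpus")
  terms <- sort(names(tab))
  out <- list(terms = terms, x = as.integer(tab[terms]))
  class(out) <- "term_frequency_profile"
  out
}

#' Fit a two-component Gaussian mixture to term frequencies by EM
#'
#' Separates the vocabulary into an infrequent and a frequent cluster.
#' The E-step computes per-term responsibilities proportional to the two
#' Gaussian densities under equal mixing proportions; the M-step updates
#' each component's mean and standard deviation as responsibility-weighted
#' moments. Iteration stops when the componentwise change in all means and
#' standard deviations falls below `epsilon` (default 1e-6) or at `maxIter`.
#' By default the fit is on ln(frequency), where term-frequency histograms
#' are far closer to Gaussian than raw counts; `logScale = FALSE` fits raw
#' frequencies.
#'
#' Initialization is deterministic (component means at the 25th/75th
#' percentiles, both sds at the pooled standard deviation), so `seed` only
#' matters if random restarts are requested.
#'
#' @param profile a `term_frequency_profile`.
#' @param epsilon convergence tolerance (> 0), default `1e-6`.
#' @param maxIter iteration cap, default 500.
#' @param seed integer seed (reserved for random restarts; the default
#'   deterministic initialization ignores it).
#' @param logScale fit on ln(frequency) (default TRUE).
#' @return a [TermMixtureModel-class].
#' @export
fitFrequencyMixture <- function(profile, epsilon = 1e-6, maxIter = 500L,
                                seed = 1L, logScale = TRUE) {
  stopifnot(inherits(profile, "term_frequency_profile"), epsilon > 0)
  x <- as.numeric(profile$x)
  if (any(x < 1)) stop("term frequencies must be >= 1")
  if (logScale) x <- log(x)
  if (length(unique(x)) < 2)
    stop("degenerate input: all term frequencies identical")

  sdFloor <- 1e-8
  qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  if (qs[1] == qs[2]) qs <- range(x)
  mu <- qs
  sg <- rep(max(stats::sd(x), sdFloor), 2)

  n <- length(x)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  resp <- matrix(0.5, n, 2)
  while (iter < maxIter) {
    iter <- iter + 1L
    ## E-step: equal implicit priors, responsibilities normalized per term
    d1 <- stats::dnorm(x, mu[1], sg[1])
    d2 <- stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    resp <- cbind(d1 / tot, d2 / tot)
    loglik <- c(loglik, sum(log(0.5 * tot)))
    ## M-step: responsibility-weighted mean and standard deviation
    muNew <- mu; sgNew <- sg
    for (j in 1:2) {
      w <- resp[, j]
      sw <- sum(w)
      if (sw == 0) next
      muNew[j] <- sum(w * x) / sw
      sgNew[j] <- max(sqrt(sum(w * (x - muNew[j])^2) / sw), sdFloor)
    }
    delta <- max(abs(c(muNew - mu, sgNew - sg)))
    mu <- muNew; sg <- sgNew
    if (delta < epsilon) { converged <- TRUE; break }
  }

  ord <- order(mu)
  new("TermMixtureModel",
      mean = mu[ord], sd = sg[ord],
      responsibilities = resp[, ord, drop = FALSE],
      logLik = loglik, nIter = iter, converged = converged,
      epsilon = epsilon, logScale = logScale)
}

#' Assign each term to the infrequent or frequent cluster
#'
#' Argmax of the fitted responsibilities; exact ties go to `frequent`.
#'
#' @param model a fitted [TermMixtureModel-class].
#' @param profile the `term_frequency_profile` the model was fitted to.
#' @return character vector (`"infrequent"`/`"frequent"`) named by term.
#' @export
assignTermClusters <- function(model, profile) {
  stopifnot(is(model, "TermMixtureModel"),
            inherits(profile, "term_frequency_profile"))
  if (nrow(model@responsibilities) != length(profile$terms))
    stop("model was fitted to a different profile")
  lab <- ifelse(model@responsibilities[, 1] > model@responsibilities[, 2],
                "infrequent", "frequent")
  stats::setNames(lab, profile$terms)
}

#' Reduce the vocabulary using the mixture clustering
#'
#' Drops every term in the infrequent cluster. Frequent-tail ("top-N")
#' removal is applied only when the caller supplies an explicit curated list
#' of terms to drop: indiscriminate removal of the most frequent terms is
#' known to hurt precision on injury narratives, so the default is none and
#' a warning notes the risk whenever a list is supplied.
#'
#' @param profile a `term_frequency_profile`.
#' @param labels cluster labels from [assignTermClusters()].
#' @param topNRemove optional character vector of curated frequent terms to
#'   drop additionally.
#' @return reduced ordered character vocabulary.
#' @export
reduceVocabulary <- function(profile, labels, topNRemove = NULL) {
  stopifnot(length(labels) == length(profile$terms))
  keep <- profile$terms[labels[profile$terms] == "frequent"]
  if (!is.null(topNRemove) && length(topNRemove)) {
    warning("removing curated top-N terms: frequent terms can carry class signal; ",
            "remove only under domain guidance")
    keep <- setdiff(keep, topNRemove)
  }
  if (!length(keep))
    stop("vocabulary reduction would remove every term")
  keep
}

#' Build a weighted document-term matrix
#'
#' @param tokenLists list of token vectors (one per document); names become
#'   document ids (defaults to `doc1..docm`).
#' @param vocabulary ordered term vocabulary (columns). Tokens outside it are
#'   ignored; documents with no surviving term become zero rows and are kept.
#' @param weighting `"binary"` (presence), `"tf"` (raw within-document count)
#'   or `"tfidf"` (tf x ln(m/df)). For `"tfidf"`, `idf` can be supplied to
#'   reuse training-split document frequencies on test documents; otherwise
#'   it is computed from `tokenLists` itself. Terms appearing in no document
#'   of the fitting split get idf 0.
#' @param idf optional named numeric vector of per-term idf weights.
#' @return a [DocumentTermMatrix-class].
#' @export
buildDtm <- function(tokenLists, vocabulary,
                     weighting = c("binary", "tf", "tfidf"), idf = NULL) {
  weighting <- match.arg(weighting)
  if (!length(vocabulary)) stop("buildDtm: empty vocabulary")
  m <- length(tokenLists)
  ids <- names(tokenLists)
  if (is.null(ids)) ids <- paste0("doc", seq_len(m))
  ii <- integer(0); jj <- integer(0); cnt <- numeric(0)
  for (d in seq_len(m)) {
    toks <- tokenLists[[d]]
    hit <- match(toks, vocabulary)
    hit <- hit[!is.na(hit)]
    if (!length(hit)) next
    tab <- table(hit)
    ii <- c(ii, rep.int(d, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    cnt <- c(cnt, as.numeric(tab))
  }
  D <- sparseMatrix(i = ii, j = jj, x = cnt,
                    dims = c(m, length(vocabulary)))
  if (weighting == "binary") {
    D@x[] <- 1
  } else if (weighting == "tfidf") {
    if (is.null(idf)) {
      df <- Matrix::colSums(D > 0)
      idfv <- ifelse(df > 0, log(m / pmax(df, 1)), 0)
    } else {
      if (is.null(names(idf)) || !all(vocabulary %in% names(idf)))
        stop("supplied idf must be named and cover the vocabulary")
      idfv <- unname(idf[vocabulary])
    }
    D <- D %*% Matrix::Diagonal(x = idfv)
    idf <- stats::setNames(idfv, vocabulary)
  }
  if (is.null(idf)) idf <- numeric(0)
  new("DocumentTermMatrix", D = methods::as(D, "CsparseMatrix"),
      weighting = weighting,
      vocabulary = as.character(vocabulary), docIds = ids, idf = idf)
}

#' Write / read a DocumentTermMatrix
#'
#' The sparse matrix is serialized in Matrix Market coordinate format with
#' two plain-text sidecar files, `<path>.vocab` (one term per line) and
#' `<path>.docs` (one line per document: id and weighting tag on the first
#' line's header comment). Round-trips exactly.
#'
#' @param dtm a [DocumentTermMatrix-class].
#' @param path base path for the `.mtx` file (sidecar names derived from it).
#' @return `writeDtm`: `path` invisibly. `readDtm`: the restored object.
#' @export
writeDtm <- function(dtm, path) {
  stopifnot(is(dtm, "DocumentTermMatrix"))
  if (nrow(dtm@D) == 0) stop("refusing to write an empty (0-document) matrix")
  Matrix::writeMM(methods::as(dtm@D, "generalMatrix"), path)
  writeLines(dtm@vocabulary, paste0(path, ".vocab"))
  writeLines(c(paste0("#weighting=", dtm@weighting), dtm@docIds),
             paste0(path, ".docs"))
  if (length(dtm@idf))
    utils::write.table(
      data.frame(term = names(dtm@idf), idf = unname(dtm@idf)),
      paste0(path, ".idf"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDtm
#' @export
readDtm <- function(path) {
  D <- Matrix::readMM(path)
  if (is(D, "nMatrix")) D <- D * 1   # pattern file (all entries 1)
  D <- methods::as(D, "CsparseMatrix")
  vocab <- readLines(paste0(path, ".vocab"), warn = FALSE)
  docLines <- readLines(paste0(path, ".docs"), warn = FALSE)
  weighting <- sub("^#weighting=", "", docLines[1])
  ids <- docLines[-1]
  if (length(vocab) != ncol(D))
    stop("vocabulary sidecar length does not match matrix columns")
  if (length(ids) != nrow(D))
    stop("doc-id sidecar length does not match matrix rows")
  if (nrow(D) == 0) stop("empty (0-document) matrix")
  idf <- numeric(0)
  idfPath <- paste0(path, ".idf")
  if (file.exists(idfPath)) {
    tb <- utils::read.table(idfPath, header = TRUE, sep = "\t",
                            colClasses = c("character", "numeric"))
    idf <- stats::setNames(tb$idf, tb$term)[vocab]
  }
  new("DocumentTermMatrix", D = D, weighting = weighting,
      vocabulary = vocab, docIds = ids, idf = idf)
}
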