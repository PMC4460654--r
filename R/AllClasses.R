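#' @import methods
#' @importFrom Matrix Matrix sparseMatrix readMM writeMM t rowSums colSums
NULL

#' NarrativeCorpus: a collection of coded injury narratives
#'
#' Holds free-text injury narratives together with their two gold-standard
#' codes: the external cause (event or circumstance producing the injury) and
#' the major injury factor (object or substance involved). Label vocabularies
#' are carried explicitly so that classes absent from a subset (e.g. a
#' cross-validation fold) keep their identity.
#'
#' @slot recordId character vector of unique record identifiers.
#' @slot narrative character vector of free-text narratives (non-empty after
#'   whitespace stripping).
#' @slot externalCause factor of external-cause codes.
#' @slot injuryFactor factor of major-injury-factor codes.
#' @slot externalLabels ordered external-cause label vocabulary.
#' @slot injuryLabels ordered injury-factor label vocabulary.
#' @exportClass NarrativeCorpus
setClass("NarrativeCorpus",
  representation(
    recordId = "character",
    narrative = "character",
    externalCause = "character",
    injuryFactor = "character",
    externalLabels = "character",
    injuryLabels = "character"
  )
)

setValidity("NarrativeCorpus", function(object) {
  n <- length(object@recordId)
  msgs <- character()
  if (length(object@narrative) != n || length(object@externalCause) != n ||
      length(object@injuryFactor) != n)
    msgs <- c(msgs, "record fields must have equal length")
  if (anyDuplicated(object@recordId))
    msgs <- c(msgs, "record ids must be unique")
  if (n > 0 && any(!nzchar(trimws(object@narrative))))
    msgs <- c(msgs, "narratives must be non-empty after whitespace stripping")
  if (n > 0 && !all(object@externalCause %in% object@externalLabels))
    msgs <- c(msgs, "external_cause labels outside declared vocabulary")
  if (n > 0 && !all(object@injuryFactor %in% object@injuryLabels))
    msgs <- c(msgs, "injury_factor labels outside declared vocabulary")
  if (anyDuplicated(object@externalLabels) || anyDuplicated(object@injuryLabels))
    msgs <- c(msgs, "label vocabularies must not contain duplicates")
  if (length(msgs)) msgs else TRUE
})

#' DocumentTermMatrix: weighted sparse docs-by-terms matrix
#'
#' A sparse m-by-n matrix of term weights under a named weighting scheme,
#' with the term vocabulary and document ids as sidecars.
#'
#' @slot D sparse Matrix (docs in rows, terms in columns), entries >= 0.
#' @slot weighting one of "binary", "tf", "tfidf".
#' @slot vocabulary ordered character vector of terms (length = ncol(D)).
#' @slot docIds character vector of document ids (length = nrow(D)).
#' @slot idf per-term inverse document frequencies used for "tfidf"
#'   (empty otherwise); fitted on training documents and reused at test time.
#' @exportClass DocumentTermMatrix
setClass("DocumentTermMatrix",
  representation(
    D = "Matrix",
    weighting = "character",
    vocabulary = "character",
    docIds = "character",
    idf = "numeric"
  )
)

setValidity("DocumentTermMatrix", function(object) {
  msgs <- character()
  if (!object@weighting %in% c("binary", "tf", "tfidf"))
    msgs <- c(msgs, "weighting must be one of binary/tf/tfidf")
  if (ncol(object@D) != length(object@vocabulary))
    msgs <- c(msgs, "vocabulary length must equal ncol(D)")
  if (nrow(object@D) != length(object@docIds))
    msgs <- c(msgs, "docIds length must equal nrow(D)")
  if (length(object@D@x) && min(object@D@x) < 0)
    msgs <- c(msgs, "entries must be non-negative")
  if (object@weighting == "binary" && length(object@D@x) &&
      !all(object@D@x %in% c(0, 1)))
    msgs <- c(msgs, "binary weighting requires entries in {0,1}")
  if (length(msgs)) msgs else TRUE
})

#' TermMixtureModel: two-component Gaussian mixture over term frequencies
#'
#' EM fit of an equal-prior two-Gaussian mixture to (by default
#' log-transformed) corpus term frequencies; component 1 is the infrequent
#' cluster (smaller mean), component 2 the frequent one.
#'
#' @slot mean component means, ordered increasing.
#' @slot sd component standard deviations (floored away from zero).
#' @slot responsibilities n-by-2 matrix of per-term posterior membership
#'   probabilities; rows sum to 1.
#' @slot logLik per-iteration log-likelihood trace.
#' @slot nIter iterations run.
#' @slot converged whether the componentwise parameter-change criterion fell
#'   below epsilon before maxIter.
#' @slot epsilon convergence tolerance.
#' @slot logScale whether the fit was on ln(frequency).
#' @exportClass TermMixtureModel
setClass("TermMixtureModel",
  representation(
    mean = "numeric",
    sd = "numeric",
    responsibilities = "matrix",
    logLik = "numeric",
    nIter = "integer",
    converged = "logical",
    epsilon = "numeric",
    logScale = "logical"
  )
)

setValidity("TermMixtureModel", function(object) {
  msgs <- character()
  if (length(object@mean) != 2 || length(object@sd) != 2)
    msgs <- c(msgs, "exactly two components required")
  if (any(object@sd <= 0))
    msgs <- c(msgs, "component standard deviations must be positive")
  if (object@mean[1] > object@mean[2])
    msgs <- c(msgs, "components must be ordered by mean (infrequent first)")
  if (ncol(object@responsibilities) != 2)
    msgs <- c(msgs, "responsibilities must have two columns")
  rs <- rowSums(object@responsibilities)
  if (length(rs) && max(abs(rs - 1)) > 1e-8)
    msgs <- c(msgs, "responsibilities must sum to 1 per term")
  if (length(msgs)) msgs else TRUE
})

#' SvdFactorization: truncated singular value decomposition
#'
#' Best rank-k approximation D ~ U_k diag(sigma_k) V_k' of a document-term
#' matrix, with the training-side right singular vectors retained for
#' out-of-sample projection of test documents.
#'
#' @slot U m-by-k left singular vectors (documents).
#' @slot sigma k singular values, non-increasing, >= 0.
#' @slot V n-by-k right singular vectors (terms).
#' @slot k retained rank.
#' @exportClass SvdFactorization
setClass("SvdFactorization",
  representation(U = "matrix", sigma = "numeric", V = "matrix", k = "integer")
)

setValidity("SvdFactorization", function(object) {
  msgs <- character()
  k <- object@k
  if (ncol(object@U) != k || ncol(object@V) != k || length(object@sigma) != k)
    msgs <- c(msgs, "U, V, sigma must agree with k")
  if (any(diff(object@sigma) > 1e-12) || any(object@sigma < -1e-12))
    msgs <- c(msgs, "singular values must be non-increasing and non-negative")
  orth <- function(M) max(abs(crossprod(M) - diag(ncol(M))))
  if (orth(object@U) > 1e-8 || orth(object@V) > 1e-8)
    msgs <- c(msgs, "singular vector columns must be orthonormal (tol 1e-8)")
  if (length(msgs)) msgs else TRUE
})

#' NnmfFactorization: non-negative matrix factorization D ~ A H
#'
#' Lee-Seung multiplicative-update factorization of a non-negative
#' document-term matrix into a document representation A (m-by-r) and a term
#' representation H (r-by-n), both elementwise non-negative.
#'
#' @slot A m-by-r non-negative document coordinates in the latent topic space.
#' @slot H r-by-n non-negative term loadings.
#' @slot r latent dimension.
#' @slot loss "frobenius" or "kl".
#' @slot objective per-iteration objective trace (non-increasing).
#' @slot seed integer seed used for the random initialization.
#' @slot converged whether the relative-change stopping rule fired.
#' @exportClass NnmfFactorization
setClass("NnmfFactorization",
  representation(
    A = "matrix", H = "matrix", r = "integer", loss = "character",
    objective = "numeric", seed = "integer", converged = "logical"
  )
)

setValidity("NnmfFactorization", function(object) {
  msgs <- character()
  if (min(object@A) < 0 || min(object@H) < 0)
    msgs <- c(msgs, "A and H must be elementwise non-negative")
  if (ncol(object@A) != object@r || nrow(object@H) != object@r)
    msgs <- c(msgs, "latent dimensions of A and H must equal r")
  if (!object@loss %in% c("frobenius", "kl"))
    msgs <- c(msgs, "loss must be frobenius or kl")
  if (length(object@objective) > 1 &&
      any(diff(object@objective) > 1e-9 * max(1, object@objective[1])))
    msgs <- c(msgs, "objective trace must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' ConfusionMatrix: multiclass confusion counts with one-vs-rest views
#'
#' Counts of (true, predicted) label pairs over an ordered class set, plus
#' the derived per-class one-vs-rest TP/FP/TN/FN views from which the
#' medical-domain metrics (sensitivity, specificity, PPV) are computed.
#'
#' @slot labels ordered class set.
#' @slot counts c-by-c integer matrix; rows = true class, columns = predicted.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
  representation(labels = "character", counts = "matrix")
)

setValidity("ConfusionMatrix", function(object) {
  msgs <- character()
  c1 <- length(object@labels)
  if (nrow(object@counts) != c1 || ncol(object@counts) != c1)
    msgs <- c(msgs, "counts must be square over the label set")
  if (any(object@counts < 0))
    msgs <- c(msgs, "counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn NarrativeCorpus number of records
#' @param x a NarrativeCorpus
#' @export
setMethod("length", "NarrativeCorpus", function(x) length(x@recordId))

setMethod("show", "NarrativeCorpus", function(object) {
  cat(sprintf(
    "NarrativeCorpus with %d records\n  external-cause classes: %d\n  injury-factor classes: %d\n",
    length(object), length(object@externalLabels), length(object@injuryLabels)
  ))
  if (length(object) > 0) {
    ex <- substr(object@narrative[1], 1, 60)
    cat(sprintf("  first narrative: \"%s\"\n", ex))
  }
})

setMethod("show", "DocumentTermMatrix", function(object) {
  cat(sprintf(
    "DocumentTermMatrix: %d documents x %d terms, weighting = %s, %.2f%% nonzero\n",
    nrow(object@D), ncol(object@D), object@weighting,
    100 * length(object@D@x) / max(1, prod(dim(object@D)))
  ))
})

setMethod("show", "TermMixtureModel", function(object) {
  cat(sprintf(
    "TermMixtureModel (EM, equal priors%s)\n  infrequent: mean %.4f sd %.4f\n  frequent:   mean %.4f sd %.4f\n  %d iterations, converged: %s (epsilon %.1e)\n",
    if (object@logScale) ", log scale" else "",
    object@mean[1], object@sd[1], object@mean[2], object@sd[2],
    object@nIter, object@converged, object@epsilon
  ))
})

setMethod("show", "SvdFactorization", function(object) {
  cat(sprintf(
    "SvdFactorization: rank %d, %d documents x %d terms\n  leading singular values: %s\n",
    object@k, nrow(object@U), nrow(object@V),
    paste(signif(utils::head(object@sigma, 5), 4), collapse = ", ")
  ))
})

setMethod("show", "NnmfFactorization", function(object) {
  cat(sprintf(
    "NnmfFactorization: r = %d, %d documents x %d terms, loss = %s\n  final objective %.6g after %d iterations (converged: %s)\n",
    object@r, nrow(object@A), ncol(object@H), object@loss,
    utils::tail(object@objective, 1), length(object@objective), object@converged
  ))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix over %d classes, n = %d\n",
              length(object@labels), sum(object@counts)))
  print(object@counts)
})
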