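## Latent-space factorizations of the document-term matrix: truncated SVD
## with shared-basis test projection, and Lee-Seung NNMF with a fixed-H
## transform for out-of-sample documents.

.asDense <- function(D) {
  if (is(D, "DocumentTermMatrix")) D <- D@D
  as.matrix(D)
}

#' Truncated singular value decomposition
#'
#' Computes the best rank-`k` approximation of the document-term matrix in
#' Frobenius norm. For reproducibility the sign of each right singular
#' vector is fixed so its largest-magnitude entry is positive (the matching
#' left vector is flipped accordingly).
#'
#' @param D a [DocumentTermMatrix-class], Matrix or base matrix.
#' @param k retained rank, `1 <= k <= min(m, n)`.
#' @return an [SvdFactorization-class].
#' @export
svdTruncate <- function(D, k) {
  M <- .asDense(D)
  k <- as.integer(k)
  if (k < 1 || k > min(dim(M)))
    stop("k must satisfy 1 <= k <= min(m, n)")
  s <- svd(M, nu = k, nv = k)
  U <- s$u; V <- s$v
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  new("SvdFactorization", U = U, sigma = s$d[seq_len(k)], V = V, k = k)
}

#' Project documents onto a training SVD basis
#'
#' Test documents share the training-side right singular vectors: the
#' smoothed representation is `D_new V_k V_k'` (which recovers
#' `U_k Sigma_k V_k'` when `D_new` is the training matrix itself, since the
#' columns of `V_k` are orthonormal), and the k-dimensional coordinates are
#' `D_new V_k`.
#'
#' @param Dnew matrix of new documents (columns must match the training
#'   vocabulary), a [DocumentTermMatrix-class] or matrix.
#' @param fact an [SvdFactorization-class] fitted on training documents
#'   (alternatively, pass `V` directly as a matrix).
#' @return list with `coords` (`D_new V_k`, m_new x k) and `smoothed`
#'   (`D_new V_k V_k'`, m_new x n).
#' @export
svdProject <- function(Dnew, fact) {
  M <- .asDense(Dnew)
  V <- if (is(fact, "SvdFactorization")) fact@V else as.matrix(fact)
  if (ncol(M) != nrow(V))
    stop("dimension mismatch: ncol(Dnew) must equal nrow(V_k)")
  coords <- M %*% V
  list(coords = coords, smoothed = coords %*% t(V))
}

.nnmfObjective <- function(M, A, H, loss) {
  R <- A %*% H
  if (loss == "frobenius") {
    sum((M - R)^2)
  } else {
    eps <- 1e-12
    sum(ifelse(M > 0, M * log(M / (R + eps)), 0) - M + R)
  }
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative document-term matrix as `D ~ A H` with
#' `A >= 0` (documents in the latent topic space) and `H >= 0` (terms),
#' using Lee-Seung multiplicative updates for the chosen loss (squared
#' Frobenius norm by default, generalized Kullback-Leibler divergence via
#' `loss = "kl"`). Initial factors are absolute values of seeded Gaussian
#' draws scaled to match the data magnitude, so runs are reproducible given
#' the seed. Iteration stops when the relative objective change drops below
#' `tol` or at `maxIter`.
#'
#' @param D non-negative matrix, Matrix or [DocumentTermMatrix-class].
#' @param r latent dimension, `1 <= r <= min(m, n)`.
#' @param loss `"frobenius"` or `"kl"`.
#' @param seed integer seed for the random initialization.
#' @param maxIter iteration cap (default 500).
#' @param tol relative objective-change stopping tolerance (default 1e-5).
#' @return an [NnmfFactorization-class] with the per-iteration objective trace.
#' @export
nnmfFit <- function(D, r, loss = c("frobenius", "kl"), seed = 1L,
                    maxIter = 500L, tol = 1e-5) {
  loss <- match.arg(loss)
  M <- .asDense(D)
  if (min(M) < 0) stop("NNMF requires a non-negative matrix")
  r <- as.integer(r)
  if (r < 1 || r > min(dim(M)))
    stop("r must satisfy 1 <= r <= min(m, n)")
  m <- nrow(M); n <- ncol(M)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  scale <- sqrt(max(mean(M), 1e-8) / r)
  A <- matrix(abs(stats::rnorm(m * r)) * scale, m, r)
  H <- matrix(abs(stats::rnorm(r * n)) * scale, r, n)
  eps <- 1e-12
  obj <- .nnmfObjective(M, A, H, loss)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    if (loss == "frobenius") {
      H <- H * (crossprod(A, M)) / (crossprod(A) %*% H + eps)
      A <- A * (M %*% t(H)) / (A %*% tcrossprod(H) + eps)
    } else {
      W <- M / (A %*% H + eps)
      H <- H * (crossprod(A, W)) / (colSums(A) + eps)
      W <- M / (A %*% H + eps)
      A <- A * (W %*% t(H)) / matrix(rowSums(H) + eps, m, r, byrow = TRUE)
    }
    objNew <- .nnmfObjective(M, A, H, loss)
    obj <- c(obj, objNew)
    prev <- obj[length(obj) - 1]
    if (abs(prev - objNew) <= tol * max(abs(prev), eps)) {
      converged <- TRUE
      break
    }
  }
  new("NnmfFactorization", A = A, H = H, r = r, loss = loss,
      objective = obj, seed = as.integer(seed), converged = converged)
}

#' Map new documents into a trained NNMF latent space
#'
#' Solves for non-negative coordinates `A_new` minimizing the chosen loss
#' with the term representation fixed at the training `H`, via multiplicative
#' updates on `A` only. This places test documents in the same latent space
#' as the training documents, making cosine similarity between them
#' well-defined.
#'
#' @param Dnew non-negative matrix of new documents (columns = training
#'   vocabulary).
#' @param fact trained [NnmfFactorization-class] (or `H` as a matrix, in
#'   which case `loss` applies).
#' @param maxIter iteration cap (default 200).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param seed integer seed for the initialization of `A_new`.
#' @param loss loss to use when `fact` is a bare matrix.
#' @return matrix `A_new` (m_new x r), elementwise non-negative.
#' @export
nnmfTransform <- function(Dnew, fact, maxIter = 200L, tol = 1e-6, seed = 1L,
                          loss = "frobenius") {
  M <- .asDense(Dnew)
  if (is(fact, "NnmfFactorization")) {
    H <- fact@H; loss <- fact@loss
  } else H <- as.matrix(fact)
  if (ncol(M) != ncol(H))
    stop("dimension mismatch: ncol(Dnew) must equal ncol(H)")
  if (min(M) < 0) stop("NNMF transform requires a non-negative matrix")
  r <- nrow(H); m <- nrow(M)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  A <- matrix(abs(stats::rnorm(m * r)) * sqrt(max(mean(M), 1e-8) / r), m, r)
  eps <- 1e-12
  obj <- .nnmfObjective(M, A, H, loss)
  for (it in seq_len(maxIter)) {
    if (loss == "frobenius") {
      A <- A * (M %*% t(H)) / (A %*% tcrossprod(H) + eps)
    } else {
      W <- M / (A %*% H + eps)
      A <- A * (W %*% t(H)) / matrix(rowSums(H) + eps, m, r, byrow = TRUE)
    }
    objNew <- .nnmfObjective(M, A, H, loss)
    if (abs(obj - objNew) <= tol * max(abs(obj), eps)) { obj <- objNew; break }
    obj <- objNew
  }
  zero <- rowSums(M) == 0
  A[zero, ] <- 0   # zero documents have exact zero representation
  A
}

#' Reconstruction error of a factorization
#'
#' Squared Frobenius distance (or generalized KL divergence, for a KL-fitted
#' NNMF) between `D` and its reconstruction under the factorization.
#'
#' @param fact an [SvdFactorization-class] or [NnmfFactorization-class].
#' @param D the matrix being approximated.
#' @return non-negative scalar.
#' @export
reconstructionError <- function(fact, D) {
  M <- .asDense(D)
  if (is(fact, "SvdFactorization")) {
    R <- fact@U %*% (fact@sigma * t(fact@V))
    if (!all(dim(R) == dim(M))) stop("shape mismatch")
    sum((M - R)^2)
  } else if (is(fact, "NnmfFactorization")) {
    if (nrow(fact@A) != nrow(M) || ncol(fact@H) != ncol(M))
      stop("shape mismatch")
    .nnmfObjective(M, fact@A, fact@H, fact@loss)
  } else stop("unsupported factorization object")
}
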