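## Seeded generator of injury-narrative-like corpora: short documents, two
## correlated code axes with heavy class imbalance, class signature
## vocabularies over a shared background, misspelling corruption and
## abbreviation variants. Ground truth is recorded so preprocessing and
## classification can be scored against the generating process.

#' Generator configuration
#'
#' Defaults emulate the documented structure of emergency-department injury
#' narratives: ~20 external-cause classes with two majors holding 70% of the
#' mass, ~10 injury-factor classes with two majors holding 50%, code-code
#' correlation (burns with hot objects), short documents, misspellings and
#' abbreviation variants.
#'
#' @param nDocs number of documents.
#' @param nExternal number of external-cause classes (default 20).
#' @param nInjury number of injury-factor classes (default 10).
#' @param externalProbs external class marginal; default: two majors at 0.35
#'   each, the rest uniform on the remaining 0.30.
#' @param injuryProbs injury class marginal; default: two majors at 0.25
#'   each, the rest uniform on 0.50.
#' @param gamma code-coupling strength in \[0, 1\]: each document draws its
#'   injury class from the marginal, then its external class from
#'   `gamma * onehot(map(injury)) + (1 - gamma) * externalProbs`, where `map`
#'   sends injury class j to external class ((j - 1) mod nExternal) + 1.
#'   `gamma = 1` makes the external code a deterministic function of the
#'   injury code; `gamma = 0` makes the codes independent.
#' @param signatureSize words per class signature vocabulary (default 6).
#' @param backgroundSize size of the shared background vocabulary (default 40).
#' @param signatureOverlap fraction of each signature drawn from a common
#'   shared pool instead of class-unique words (default 0: disjoint
#'   signatures).
#' @param mixWeights token-source probabilities (external signature, injury
#'   signature, background); default (0.35, 0.35, 0.30).
#' @param meanLength mean document length in tokens (truncated geometric;
#'   default 12, a realistic triage-text scale).
#' @param maxLength maximum document length (default 40).
#' @param misspellingRate per-token probability of a random single-edit
#'   corruption (default 0.05).
#' @param abbreviationRate per-token probability that a canonical
#'   abbreviation is emitted as a variant form (default 0.05).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `generator_config` list.
#' @export
generatorConfig <- function(nDocs = 1000L, nExternal = 20L, nInjury = 10L,
                            externalProbs = NULL, injuryProbs = NULL,
                            gamma = 0.6,
                            signatureSize = 6L, backgroundSize = 40L,
                            signatureOverlap = 0,
                            mixWeights = c(0.35, 0.35, 0.30),
                            meanLength = 12, maxLength = 40L,
                            misspellingRate = 0.05, abbreviationRate = 0.05,
                            seed = 1L) {
  skewed <- function(n, majorMass, nMajor = 2L) {
    p <- rep((1 - majorMass) / (n - nMajor), n)
    p[seq_len(nMajor)] <- majorMass / nMajor
    p
  }
  if (is.null(externalProbs)) externalProbs <- skewed(nExternal, 0.70)
  if (is.null(injuryProbs)) injuryProbs <- skewed(nInjury, 0.50)
  stopifnot(length(externalProbs) == nExternal,
            length(injuryProbs) == nInjury,
            abs(sum(externalProbs) - 1) < 1e-8,
            abs(sum(injuryProbs) - 1) < 1e-8,
            gamma >= 0, gamma <= 1,
            meanLength >= 1,
            signatureOverlap >= 0, signatureOverlap < 1,
            abs(sum(mixWeights) - 1) < 1e-8)
  structure(list(
    nDocs = as.integer(nDocs), nExternal = as.integer(nExternal),
    nInjury = as.integer(nInjury),
    externalProbs = externalProbs, injuryProbs = injuryProbs,
    gamma = gamma, signatureSize = as.integer(signatureSize),
    backgroundSize = as.integer(backgroundSize),
    signatureOverlap = signatureOverlap,
    mixWeights = mixWeights,
    meanLength = meanLength, maxLength = as.integer(maxLength),
    misspellingRate = misspellingRate, abbreviationRate = abbreviationRate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

.singleEdit <- function(word) {
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  ops <- if (n >= 2) c("insert", "delete", "substitute") else c("insert", "substitute")
  op <- sample(ops, 1)
  letter <- sample(letters, 1)
  if (op == "insert") {
    pos <- sample.int(n + 1, 1)
    paste(append(chars, letter, after = pos - 1), collapse = "")
  } else if (op == "delete") {
    pos <- sample.int(n, 1)
    paste(chars[-pos], collapse = "")
  } else {
    pos <- sample.int(n, 1)
    repeat {
      if (letter != chars[pos]) break
      letter <- sample(letters, 1)
    }
    chars[pos] <- letter
    paste(chars, collapse = "")
  }
}

.variantTable <- function() {
  ext <- system.file("extdata", "abbreviations.tsv", package = "narrafact")
  tb <- utils::read.table(ext, sep = "\t",
                          col.names = c("variant", "canonical"),
                          colClasses = "character")
  split(tb$variant, tb$canonical)
}

#' Generate a synthetic injury-narrative corpus
#'
#' Per document: draw the injury class from its marginal, the external class
#' from the coupling row, a truncated-geometric length, then fill tokens from
#' the two class signature vocabularies and the shared background according
#' to `mixWeights`; finally apply single-edit misspelling corruption and
#' abbreviation-variant substitution at the configured rates. Signature and
#' background words come from the packaged injury-domain lexicon so the
#' preprocessing stages (stemming, phrase handling) are exercised on
#' realistic vocabulary.
#'
#' @param config a [generatorConfig()].
#' @return list with `corpus` (a [NarrativeCorpus-class]) and `truth`
#'   (a `generator_truth` list: per-document codes, corruption records,
#'   signature assignments, the clean dictionary, and the config).
#' @export
generateCorpus <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  lex <- readLines(system.file("extdata", "injury_lexicon.txt",
                               package = "narrafact"), warn = FALSE)
  lex <- unique(tolower(trimws(lex)))
  lex <- lex[nzchar(lex)]
  nShared <- round(config$signatureOverlap * config$signatureSize)
  nUnique <- config$signatureSize - nShared
  nClasses <- config$nExternal + config$nInjury
  need <- nClasses * nUnique + max(nShared, 1) * 2 + config$backgroundSize
  if (length(lex) < need)
    stop("lexicon too small for the requested signature distinctness: need ",
         need, " words, have ", length(lex))

  pool <- sample(lex)                      # seeded permutation of the lexicon
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  sharedPool <- if (nShared > 0) take(max(2 * nShared, nShared)) else character(0)
  extLabels <- sprintf("ext%02d", seq_len(config$nExternal))
  injLabels <- sprintf("inj%02d", seq_len(config$nInjury))
  mkSig <- function() {
    sig <- take(nUnique)
    if (nShared > 0) sig <- c(sig, sample(sharedPool, nShared))
    sig
  }
  extSigs <- stats::setNames(lapply(extLabels, function(x) mkSig()), extLabels)
  injSigs <- stats::setNames(lapply(injLabels, function(x) mkSig()), injLabels)
  background <- take(config$backgroundSize)

  variants <- .variantTable()
  canonWithVariants <- names(variants)

  extMap <- ((seq_len(config$nInjury) - 1L) %% config$nExternal) + 1L
  injIdx <- sample.int(config$nInjury, config$nDocs, replace = TRUE,
                       prob = config$injuryProbs)
  extIdx <- integer(config$nDocs)
  for (d in seq_len(config$nDocs)) {
    row <- (1 - config$gamma) * config$externalProbs
    row[extMap[injIdx[d]]] <- row[extMap[injIdx[d]]] + config$gamma
    extIdx[d] <- sample.int(config$nExternal, 1, prob = row)
  }

  lens <- pmin(1L + stats::rgeom(config$nDocs, 1 / config$meanLength),
               config$maxLength)
  corrDoc <- integer(0); corrOrig <- character(0); corrForm <- character(0)
  narr <- character(config$nDocs)
  for (d in seq_len(config$nDocs)) {
    src <- sample.int(3L, lens[d], replace = TRUE, prob = config$mixWeights)
    toks <- character(lens[d])
    for (t in seq_len(lens[d])) {
      toks[t] <- switch(src[t],
        sample(extSigs[[extIdx[d]]], 1),
        sample(injSigs[[injIdx[d]]], 1),
        sample(background, 1))
    }
    ## abbreviation variants, then misspellings (a token gets at most one)
    for (t in seq_len(lens[d])) {
      if (toks[t] %in% canonWithVariants &&
          stats::runif(1) < config$abbreviationRate) {
        toks[t] <- sample(variants[[toks[t]]], 1)
      } else if (stats::runif(1) < config$misspellingRate) {
        orig <- toks[t]
        toks[t] <- .singleEdit(orig)
        corrDoc <- c(corrDoc, d); corrOrig <- c(corrOrig, orig)
        corrForm <- c(corrForm, toks[t])
      }
    }
    narr[d] <- paste(toks, collapse = " ")
  }

  corpus <- narrativeCorpus(
    sprintf("d%05d", seq_len(config$nDocs)), narr,
    extLabels[extIdx], injLabels[injIdx],
    externalLabels = extLabels, injuryLabels = injLabels
  )
  truth <- structure(list(
    externalCodes = extLabels[extIdx],
    injuryCodes = injLabels[injIdx],
    corruptions = data.frame(doc = corrDoc, original = corrOrig,
                             corrupted = corrForm, stringsAsFactors = FALSE),
    externalSignatures = extSigs,
    injurySignatures = injSigs,
    background = background,
    dictionary = unique(c(unlist(extSigs), unlist(injSigs), background,
                          canonWithVariants)),
    config = config
  ), class = "generator_truth")
  list(corpus = corpus, truth = truth)
}

#' Summarize the ground truth of a generated corpus
#'
#' @param truth a `generator_truth` from [generateCorpus()].
#' @return list with `nCorruptions`, `signatureOverlap` (mean pairwise
#'   Jaccard similarity between class signatures, per axis),
#'   `empiricalCoupling` (P(external | injury) matrix), and
#'   `codeMutualInformation` (plug-in estimate in nats).
#' @export
describeTruth <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  jacc <- function(sigs) {
    k <- length(sigs)
    if (k < 2) return(0)
    tot <- 0; cnt <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      tot <- tot + length(intersect(sigs[[i]], sigs[[j]])) /
        length(union(sigs[[i]], sigs[[j]]))
      cnt <- cnt + 1
    }
    tot / cnt
  }
  joint <- table(truth$injuryCodes, truth$externalCodes)
  pj <- joint / sum(joint)
  pi_ <- rowSums(pj); pe <- colSums(pj)
  mi <- 0
  for (i in seq_along(pi_)) for (j in seq_along(pe)) {
    if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (pi_[i] * pe[j]))
  }
  coupling <- sweep(joint, 1, pmax(rowSums(joint), 1), "/")
  list(
    nCorruptions = nrow(truth$corruptions),
    signatureOverlap = c(
      external = jacc(truth$externalSignatures),
      injury = jacc(truth$injurySignatures)
    ),
    empiricalCoupling = coupling,
    codeMutualInformation = as.numeric(mi)
  )
}
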