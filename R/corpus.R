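#' Construct a NarrativeCorpus
#'
#' @param recordId character vector of unique ids.
#' @param narrative character vector of free-text narratives.
#' @param externalCause character vector of external-cause codes.
#' @param injuryFactor character vector of major-injury-factor codes.
#' @param externalLabels optional explicit external label vocabulary; defaults
#'   to the sorted unique labels occurring in `externalCause`. Extra declared
#'   labels beyond those occurring are allowed.
#' @param injuryLabels optional explicit injury label vocabulary.
#' @return a [NarrativeCorpus-class] object.
#' @export
narrativeCorpus <- function(recordId, narrative, externalCause, injuryFactor,
                            externalLabels = NULL, injuryLabels = NULL) {
  recordId <- as.character(recordId)
  narrative <- as.character(narrative)
  externalCause <- as.character(externalCause)
  injuryFactor <- as.character(injuryFactor)
  if (is.null(externalLabels)) externalLabels <- sort(unique(externalCause))
  if (is.null(injuryLabels)) injuryLabels <- sort(unique(injuryFactor))
  new("NarrativeCorpus",
      recordId = recordId, narrative = narrative,
      externalCause = externalCause, injuryFactor = injuryFactor,
      externalLabels = as.character(externalLabels),
      injuryLabels = as.character(injuryLabels))
}

#' Accessors for NarrativeCorpus
#'
#' @param x a [NarrativeCorpus-class].
#' @return `narratives()` the narrative texts; `recordIds()` the ids;
#'   `codeLabels()` the label vocabulary of one code axis; `codes()` the
#'   per-record labels of one axis.
#' @param axis which code axis, `"external_cause"` or `"injury_factor"`.
#' @export
narratives <- function(x) x@narrative

#' @rdname narratives
#' @export
recordIds <- function(x) x@recordId

#' @rdname narratives
#' @export
codes <- function(x, axis = c("external_cause", "injury_factor")) {
  axis <- match.arg(axis)
  if (axis == "external_cause") x@externalCause else x@injuryFactor
}

#' @rdname narratives
#' @export
codeLabels <- function(x, axis = c("external_cause", "injury_factor")) {
  axis <- match.arg(axis)
  if (axis == "external_cause") x@externalLabels else x@injuryLabels
}

#' Subset a corpus by record index
#'
#' Label vocabularies are preserved, so folds keep the full class set.
#'
#' @param x a NarrativeCorpus.
#' @param i integer or logical index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "NarrativeCorpus", function(x, i, j, ..., drop = FALSE) {
  new("NarrativeCorpus",
      recordId = x@recordId[i], narrative = x@narrative[i],
      externalCause = x@externalCause[i], injuryFactor = x@injuryFactor[i],
      externalLabels = x@externalLabels, injuryLabels = x@injuryLabels)
})

CORPUS_COLUMNS <- c("record_id", "narrative", "external_cause", "injury_factor")

#' Read a narrative corpus from a delimited file
#'
#' Expects a header row naming the columns `record_id`, `narrative`,
#' `external_cause`, `injury_factor` (order free; extra columns ignored).
#' Records with an empty narrative or an empty value for either code are
#' dropped, mirroring routine surveillance-data cleaning; the number dropped
#' is reported via a message.
#'
#' @param path file path.
#' @param dialect `"csv"` (comma, quoted) or `"tsv"`.
#' @return a [NarrativeCorpus-class].
#' @export
readCorpus <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read corpus: no such file: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", comment.char = "",
                          fileEncoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing))
    stop("corpus file is missing required column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, CORPUS_COLUMNS]
  keep <- nzchar(trimws(df$narrative)) &
    nzchar(trimws(df$external_cause)) &
    nzchar(trimws(df$injury_factor))
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("readCorpus: dropped %d record(s) with empty narrative or code", dropped))
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df$record_id))
    stop("duplicate record_id values in corpus file")
  narrativeCorpus(df$record_id, df$narrative, df$external_cause, df$injury_factor)
}

#' Write a narrative corpus to a delimited file
#'
#' Inverse of [readCorpus()]: `readCorpus(writeCorpus(x, p), dialect)` returns
#' a corpus identical to `x` up to label-vocabulary ordering. Fields are
#' quoted, so delimiter characters inside narratives round-trip safely.
#'
#' @param corpus a valid [NarrativeCorpus-class].
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validObject(corpus)
  df <- data.frame(
    record_id = corpus@recordId,
    narrative = corpus@narrative,
    external_cause = corpus@externalCause,
    injury_factor = corpus@injuryFactor,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = if (dialect == "csv") "," else "\t",
                     qmethod = "double", row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Summary statistics of a corpus
#'
#' Narrative length is measured in whitespace tokens. Per-class proportions
#' are reported for both code axes and sum to 1 on each.
#'
#' @param corpus a non-empty [NarrativeCorpus-class].
#' @return list with `nDocs`, `avgLength`, `maxLength`, `minLength`,
#'   `externalCounts`, `externalProportions`, `injuryCounts`,
#'   `injuryProportions`.
#' @export
corpusStats <- function(corpus) {
  if (length(corpus) == 0) stop("corpusStats: empty corpus")
  lens <- lengths(strsplit(trimws(corpus@narrative), "\\s+"))
  extTab <- table(factor(corpus@externalCause, levels = corpus@externalLabels))
  injTab <- table(factor(corpus@injuryFactor, levels = corpus@injuryLabels))
  list(
    nDocs = length(corpus),
    avgLength = mean(lens), maxLength = max(lens), minLength = min(lens),
    externalCounts = extTab,
    externalProportions = extTab / length(corpus),
    injuryCounts = injTab,
    injuryProportions = injTab / length(corpus)
  )
}
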