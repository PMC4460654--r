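## Narrative-text cleaning chain. Order matters: punctuation must go before
## stop-word removal and stemming, otherwise tokens glued to punctuation
## ("(from") escape the stop list; phrase protection must precede stop-word
## removal so that class-bearing phrases ("fall off") survive it.

#' Preprocessing configuration
#'
#' Bundles the resources and switches of the narrative cleaning chain.
#' All stages are individually switchable; the stage order is fixed
#' (lowercase, punctuation removal, tokenization, abbreviation
#' canonicalization, phrase protection, spelling correction, stop-word
#' removal, Porter stemming).
#'
#' @param dictionary character vector of known words for spelling correction.
#' @param abbreviationMap named character vector: names are variant forms,
#'   values the canonical single-token form.
#' @param phraseList character vector of multi-word expressions (>= 2
#'   whitespace-separated words each) to collapse into single underscore-joined
#'   tokens, exempting them from stop-word removal.
#' @param stopwordList character vector of stop words.
#' @param maxEditDistance non-negative integer bound on the Levenshtein
#'   distance accepted by the spelling corrector (default 2).
#' @param stages named logical vector switching stages on/off; names among
#'   `punctuation`, `abbreviations`, `phrases`, `spelling`, `stopwords`,
#'   `stemming`.
#' @return a `preprocess_config` list.
#' @export
preprocessConfig <- function(dictionary = character(),
                             abbreviationMap = character(),
                             phraseList = character(),
                             stopwordList = character(),
                             maxEditDistance = 2L,
                             stages = c(punctuation = TRUE, abbreviations = TRUE,
                                        phrases = TRUE, spelling = TRUE,
                                        stopwords = TRUE, stemming = TRUE)) {
  if (length(phraseList) && any(lengths(strsplit(phraseList, "\\s+")) < 2))
    stop("phraseList entries must contain at least two words")
  if (length(abbreviationMap) && any(grepl("\\s", abbreviationMap)))
    stop("abbreviationMap values must be single tokens")
  if (maxEditDistance < 0) stop("maxEditDistance must be non-negative")
  full <- c(punctuation = TRUE, abbreviations = TRUE, phrases = TRUE,
            spelling = TRUE, stopwords = TRUE, stemming = TRUE)
  full[names(stages)] <- stages
  ## stop words that are components of protected phrases stay on the list;
  ## protection itself shields the joined token, not the loose word
  cfg <- list(
    dictionary = unique(tolower(dictionary)),
    abbreviationMap = abbreviationMap,
    phraseList = tolower(phraseList),
    stopwordList = unique(tolower(stopwordList)),
    maxEditDistance = as.integer(maxEditDistance),
    stages = full,
    .soundexIndex = NULL
  )
  if (length(cfg$dictionary))
    cfg$.soundexIndex <- split(cfg$dictionary, soundexKey(cfg$dictionary))
  class(cfg) <- "preprocess_config"
  cfg
}

#' Default preprocessing configuration
#'
#' Loads the stop-word list, abbreviation map, phrase list and injury-domain
#' dictionary shipped with the package.
#'
#' @param ... overrides passed on to [preprocessConfig()].
#' @export
defaultPreprocessConfig <- function(...) {
  ext <- function(f) system.file("extdata", f, package = "narrafact")
  stop_words <- readLines(ext("stopwords_en.txt"), warn = FALSE)
  lex <- readLines(ext("injury_lexicon.txt"), warn = FALSE)
  abb <- utils::read.table(ext("abbreviations.tsv"), sep = "\t",
                           col.names = c("variant", "canonical"),
                           colClasses = "character")
  phrases <- readLines(ext("phrases.txt"), warn = FALSE)
  args <- list(
    dictionary = lex,
    abbreviationMap = stats::setNames(abb$canonical, abb$variant),
    phraseList = phrases,
    stopwordList = stop_words
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(preprocessConfig, args)
}

#' Replace punctuation by spaces
#'
#' Every punctuation character becomes a single space, so token boundaries
#' are preserved and words glued to brackets or commas are freed before the
#' stop-word and stemming stages see them.
#'
#' @param text character vector.
#' @return character vector with punctuation replaced and whitespace squeezed.
#' @export
removePunctuation <- function(text) {
  out <- gsub("[[:punct:]]", " ", text)
  trimws(gsub("\\s+", " ", out))
}

#' Canonicalize abbreviation variants
#'
#' @param tokens character vector of tokens.
#' @param abbreviationMap named character vector (variant -> canonical form).
#' @return tokens with every variant replaced by its canonical form.
#' @export
normalizeAbbreviations <- function(tokens, abbreviationMap) {
  if (!length(abbreviationMap) || !length(tokens)) return(tokens)
  hit <- match(tokens, names(abbreviationMap))
  tokens[!is.na(hit)] <- unname(abbreviationMap[hit[!is.na(hit)]])
  tokens
}

#' Collapse listed phrases into single tokens
#'
#' Scans left to right; at each position the longest listed phrase starting
#' there is collapsed into one underscore-joined token (leftmost match wins on
#' overlaps). Joined tokens are exempt from stop-word removal.
#'
#' @param tokens character vector of tokens.
#' @param phraseList character vector of multi-word phrases.
#' @return token vector with phrases collapsed.
#' @export
protectPhrases <- function(tokens, phraseList) {
  if (!length(phraseList) || length(tokens) < 2) return(tokens)
  parts <- strsplit(phraseList, "\\s+")
  byFirst <- split(parts, vapply(parts, `[`, "", 1L))
  out <- character(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    cands <- byFirst[[tokens[i]]]
    matched <- 0L
    if (!is.null(cands)) {
      for (p in cands[order(-lengths(cands))]) {  # longest first
        L <- length(p)
        if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == p)) {
          matched <- L
          out <- c(out, paste(p, collapse = "_"))
          break
        }
      }
    }
    if (matched == 0L) {
      out <- c(out, tokens[i])
      i <- i + 1L
    } else {
      i <- i + matched
    }
  }
  out
}

## American Soundex code; vectorized. Non-alphabetic tokens key to "".
soundexKey <- function(words) {
  vapply(words, function(w) {
    w <- tolower(w)
    letters_ <- strsplit(w, "")[[1]]
    letters_ <- letters_[letters_ %in% letters]
    if (!length(letters_)) return("")
    code <- c(b = "1", f = "1", p = "1", v = "1",
              c = "2", g = "2", j = "2", k = "2", q = "2", s = "2",
              x = "2", z = "2",
              d = "3", t = "3", l = "4", m = "5", n = "5", r = "6")
    digs <- code[letters_]
    digs[is.na(digs)] <- ifelse(letters_[is.na(digs)] %in% c("h", "w"), "-", "0")
    ## collapse runs of the same digit, treating h/w as transparent
    keep <- character(0)
    prev <- digs[1]
    for (j in seq_along(digs)[-1]) {
      d <- digs[j]
      if (d == "-") next           # h/w: transparent, previous code persists
      if (d != prev) keep <- c(keep, d)
      prev <- d
    }
    keep <- keep[keep != "0"]
    paste0(toupper(letters_[1]), substr(paste(c(keep, "000"), collapse = ""), 1, 3))
  }, "", USE.NAMES = FALSE)
}

#' Soundalike spelling correction
#'
#' Tokens found in the dictionary are returned unchanged. For an unknown
#' token, candidates sharing its Soundex phonetic key are ranked by
#' Levenshtein distance; the closest within `maxEditDistance` wins. If no
#' soundalike qualifies, the globally closest dictionary word within the
#' bound is used. Ties break to the lexicographically smallest candidate;
#' with no candidate within the bound the token is returned unchanged.
#' Tokens containing digits and underscore-joined phrase tokens are never
#' corrected.
#'
#' @param tokens character vector of (lowercase) tokens.
#' @param dictionary character vector of known words, or a
#'   `preprocess_config` (its dictionary and cached phonetic index are used).
#' @param maxEditDistance non-negative integer edit-distance bound.
#' @return corrected token vector.
#' @export
correctSpelling <- function(tokens, dictionary, maxEditDistance = 2L) {
  known <- character(0)
  if (inherits(dictionary, "preprocess_config")) {
    cfg <- dictionary
    dict <- cfg$dictionary
    index <- cfg$.soundexIndex
    maxEditDistance <- cfg$maxEditDistance
    known <- cfg$stopwordList   # stop words are not misspellings; they are
  } else {                      # removed by the next stage anyway
    dict <- unique(tolower(dictionary))
    index <- split(dict, soundexKey(dict))
  }
  if (!length(dict)) stop("correctSpelling: dictionary is empty")
  unknown <- !(tokens %in% dict) & !(tokens %in% known) & !grepl("[0-9_]", tokens)
  if (!any(unknown)) return(tokens)
  fix <- function(tok) {
    cands <- index[[soundexKey(tok)]]
    pick <- function(cs) {
      if (is.null(cs) || !length(cs)) return(NULL)
      d <- utils::adist(tok, cs)[1, ]
      dmin <- min(d)
      if (dmin > maxEditDistance) return(NULL)
      sort(cs[d == dmin])[1]
    }
    best <- pick(cands)
    if (is.null(best)) best <- pick(dict)
    if (is.null(best)) tok else best
  }
  tokens[unknown] <- vapply(unique(tokens[unknown]), fix, "")[tokens[unknown]]
  tokens
}

#' Remove stop words
#'
#' Underscore-joined phrase tokens are kept even when a component word is a
#' stop word: that is the point of phrase protection.
#'
#' @param tokens character vector of tokens.
#' @param stopwordList character vector of stop words.
#' @return filtered token vector.
#' @export
removeStopwords <- function(tokens, stopwordList) {
  if (!length(stopwordList)) return(tokens)
  tokens[!(tokens %in% stopwordList) | grepl("_", tokens)]
}

## ---- Porter stemmer (original 1980 algorithm) -----------------------------
## Implemented in full because no installed package provides it. Operates on
## single lowercase words.

.pt_isCons <- function(chs) {
  # consonant flags for a character vector of single letters
  n <- length(chs)
  vowel <- chs %in% c("a", "e", "i", "o", "u")
  cons <- !vowel
  for (i in seq_len(n)) {
    if (chs[i] == "y") cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
  }
  cons
}

.pt_m <- function(stem) {
  chs <- strsplit(stem, "")[[1]]
  if (!length(chs)) return(0L)
  cons <- .pt_isCons(chs)
  r <- rle(cons)$values          # alternating TRUE/FALSE runs
  if (r[1]) r <- r[-1]           # drop leading consonant block
  as.integer(length(r) %/% 2)    # count complete VC pairs
}

.pt_hasVowel <- function(stem) {
  chs <- strsplit(stem, "")[[1]]
  length(chs) > 0 && any(!.pt_isCons(chs))
}

.pt_doubleCons <- function(stem) {
  n <- nchar(stem)
  if (n < 2) return(FALSE)
  a <- substr(stem, n - 1, n - 1); b <- substr(stem, n, n)
  a == b && .pt_isCons(strsplit(stem, "")[[1]])[n]
}

.pt_cvc <- function(stem) {
  # ends consonant-vowel-consonant, final consonant not w, x or y
  n <- nchar(stem)
  if (n < 3) return(FALSE)
  chs <- strsplit(stem, "")[[1]]
  cons <- .pt_isCons(chs)
  cons[n] && !cons[n - 1] && cons[n - 2] && !(chs[n] %in% c("w", "x", "y"))
}

.pt_ends <- function(word, suffix) {
  nc <- nchar(word); ns <- nchar(suffix)
  nc > ns && substr(word, nc - ns + 1, nc) == suffix
}

.pt_rule <- function(word, rules, cond) {
  # rules: named char vector suffix -> replacement; longest matching suffix is
  # the only one tried (Porter's longest-match-wins)
  sfx <- names(rules)[order(-nchar(names(rules)))]
  for (s in sfx) {
    if (.pt_ends(word, s)) {
      stem <- substr(word, 1, nchar(word) - nchar(s))
      if (cond(stem)) return(paste0(stem, rules[[s]]))
      return(word)
    }
  }
  word
}

porterStemWord <- function(word) {
  if (nchar(word) <= 2) return(word)
  w <- word

  ## Step 1a
  if (.pt_ends(w, "sses")) w <- substr(w, 1, nchar(w) - 2)
  else if (.pt_ends(w, "ies")) w <- substr(w, 1, nchar(w) - 2)
  else if (.pt_ends(w, "ss")) w <- w
  else if (.pt_ends(w, "s")) w <- substr(w, 1, nchar(w) - 1)

  ## Step 1b
  if (.pt_ends(w, "eed")) {
    stem <- substr(w, 1, nchar(w) - 3)
    if (.pt_m(stem) > 0) w <- substr(w, 1, nchar(w) - 1)
  } else {
    hit <- FALSE
    if (.pt_ends(w, "ed")) {
      stem <- substr(w, 1, nchar(w) - 2)
      if (.pt_hasVowel(stem)) { w <- stem; hit <- TRUE }
    } else if (.pt_ends(w, "ing")) {
      stem <- substr(w, 1, nchar(w) - 3)
      if (.pt_hasVowel(stem)) { w <- stem; hit <- TRUE }
    }
    if (hit) {
      if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.pt_doubleCons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- substr(w, 1, nchar(w) - 1)
      } else if (.pt_m(w) == 1 && .pt_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  ## Step 1c
  if (.pt_ends(w, "y") && .pt_hasVowel(substr(w, 1, nchar(w) - 1)))
    w <- paste0(substr(w, 1, nchar(w) - 1), "i")

  ## Step 2 (condition m(stem) > 0)
  w <- .pt_rule(w, c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(s) .pt_m(s) > 0)

  ## Step 3 (m(stem) > 0)
  w <- .pt_rule(w, c(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""
  ), function(s) .pt_m(s) > 0)

  ## Step 4 (m(stem) > 1; "ion" additionally needs stem ending s or t)
  sfx4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
            "ion", "ism", "ate", "iti", "ous", "ive", "ize", "al", "er",
            "ic", "ou")
  for (s in sfx4[order(-nchar(sfx4))]) {
    if (.pt_ends(w, s)) {
      stem <- substr(w, 1, nchar(w) - nchar(s))
      ok <- .pt_m(stem) > 1 &&
        (s != "ion" || substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
      if (ok) w <- stem
      break
    }
  }

  ## Step 5a
  if (.pt_ends(w, "e")) {
    stem <- substr(w, 1, nchar(w) - 1)
    m <- .pt_m(stem)
    if (m > 1 || (m == 1 && !.pt_cvc(stem))) w <- stem
  }

  ## Step 5b
  if (.pt_m(w) > 1 && .pt_doubleCons(w) &&
      substr(w, nchar(w), nchar(w)) == "l")
    w <- substr(w, 1, nchar(w) - 1)

  w
}

#' Porter-stem a token vector
#'
#' Underscore-joined phrase tokens are stemmed per component and re-joined.
#' Tokens containing digits are left untouched.
#'
#' @param tokens character vector of lowercase tokens.
#' @return stemmed tokens.
#' @export
stemTokens <- function(tokens) {
  if (!length(tokens)) return(tokens)
  stem1 <- function(tok) {
    if (grepl("[0-9]", tok)) return(tok)
    if (grepl("_", tok)) {
      paste(vapply(strsplit(tok, "_")[[1]], porterStemWord, ""), collapse = "_")
    } else porterStemWord(tok)
  }
  vapply(tokens, stem1, "", USE.NAMES = FALSE)
}

#' Run the full cleaning chain on one narrative
#'
#' Applies, in order: lowercasing, punctuation removal, whitespace
#' tokenization, abbreviation canonicalization, phrase protection, spelling
#' correction, stop-word removal, Porter stemming. Stages can be switched
#' off individually via the config.
#'
#' @param text a single narrative string.
#' @param config a `preprocess_config` from [preprocessConfig()].
#' @return character vector of processed tokens (possibly empty).
#' @export
preprocessDocument <- function(text, config) {
  stopifnot(inherits(config, "preprocess_config"))
  st <- config$stages
  txt <- tolower(text)
  if (st[["punctuation"]]) txt <- removePunctuation(txt)
  toks <- strsplit(trimws(txt), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  if (st[["abbreviations"]]) toks <- normalizeAbbreviations(toks, config$abbreviationMap)
  if (st[["phrases"]]) toks <- protectPhrases(toks, config$phraseList)
  if (st[["spelling"]] && length(config$dictionary))
    toks <- correctSpelling(toks, config)
  if (st[["stopwords"]]) toks <- removeStopwords(toks, config$stopwordList)
  if (st[["stemming"]]) toks <- stemTokens(toks)
  toks
}

#' Preprocess every narrative in a corpus
#'
#' @param corpus a [NarrativeCorpus-class].
#' @param config a `preprocess_config`.
#' @return named list of token vectors, one per record (names = record ids).
#' @export
preprocessCorpus <- function(corpus, config = defaultPreprocessConfig()) {
  out <- lapply(corpus@narrative, preprocessDocument, config = config)
  names(out) <- corpus@recordId
  out
}
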