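test_that("punctuation is replaced by spaces before later stages see the text", {
  expect_equal(removePunctuation("fall (from the high chair)"),
               "fall from the high chair")
  expect_equal(removePunctuation(""), "")
  expect_equal(removePunctuation("a,b.c"), "a b c")
})

test_that("abbreviation variants collapse to one canonical form", {
  map <- c(kmph = "kph")
  expect_equal(normalizeAbbreviations(c("60", "kmph"), map), c("60", "kph"))
  expect_equal(normalizeAbbreviations(c("60", "kmph"), character()),
               c("60", "kmph"))
  expect_equal(normalizeAbbreviations("kph", map), "kph")
})

test_that("phrase protection joins listed phrases, leftmost-longest first", {
  expect_equal(protectPhrases(c("fall", "off", "ladder"), "fall off"),
               c("fall_off", "ladder"))
  expect_equal(protectPhrases(c("a", "b", "c"), c("a b", "b c")),
               c("a_b", "c"))
  expect_equal(protectPhrases(c("x", "y"), "fall off"), c("x", "y"))
  # every input token ends up in exactly one output token
  toks <- c("he", "fell", "off", "the", "fall", "off", "zone")
  out <- protectPhrases(toks, c("fell off", "fall off"))
  expect_equal(unlist(strsplit(out, "_")), toks)
  expect_lte(length(out), length(toks))
})

test_that("soundalike correction picks the minimum-edit-distance soundalike", {
  dict <- c("laceration", "location", "vacation")
  # oracle: exhaustive edit distance over the 3-word dictionary
  d <- utils::adist("lacration", dict)[1, ]
  expect_equal(dict[which.min(d)], "laceration")
  expect_equal(correctSpelling("lacration", dict), "laceration")
  expect_equal(correctSpelling("laceration", dict), "laceration")
  expect_equal(correctSpelling("xqzt", dict, maxEditDistance = 2), "xqzt")
})

test_that("spelling correction is idempotent and ties break lexicographically", {
  dict <- c("bat", "cat")   # equidistant from "rat"; no soundex key shared
  expect_equal(correctSpelling("rat", dict, 1), "bat")
  g <- generateCorpus(generatorConfig(nDocs = 100, misspellingRate = 0.08,
                                      seed = 5))
  cfg <- preprocessConfig(dictionary = g$truth$dictionary)
  bad <- unique(g$truth$corruptions$corrupted)
  once <- correctSpelling(bad, cfg)
  expect_equal(correctSpelling(once, cfg), once)
})

test_that("stop words are removed but protected phrase tokens survive", {
  expect_equal(removeStopwords(c("fall", "from", "chair"), "from"),
               c("fall", "chair"))
  expect_equal(removeStopwords("fall_off", "off"), "fall_off")
  expect_equal(removeStopwords(c("a", "b"), character()), c("a", "b"))
})

test_that("the Porter stemmer reproduces the reference algorithm's outputs", {
  words <- c("falling", "running", "chair", "caresses", "ponies", "ties",
             "caress", "cats", "feed", "agreed", "plastered", "bled",
             "motoring", "sing", "hopping", "sized", "filing", "happy",
             "sky", "relational", "conditional", "rational", "valenci",
             "hesitanci", "conflated", "troubled")
  stems <- c("fall", "run", "chair", "caress", "poni", "ti",
             "caress", "cat", "feed", "agre", "plaster", "bled",
             "motor", "sing", "hop", "size", "file", "happi",
             "sky", "relat", "condit", "ration", "valenc",
             "hesit", "conflat", "troubl")
  expect_equal(stemTokens(words), stems)
  # phrase tokens are stemmed per component; numerals pass through
  expect_equal(stemTokens(c("fall_off", "falling_off", "60")),
               c("fall_off", "fall_off", "60"))
})

test_that("the full chain runs in the documented order", {
  cfg <- preprocessConfig(dictionary = c("fall", "high", "chair"),
                          stopwordList = c("from", "the"))
  expect_equal(preprocessDocument("Fall (from the high chair)", cfg),
               c("fall", "high", "chair"))
  # punctuation removal must precede stop-word removal: "(from" would
  # otherwise escape the stop list
  cfgNoPunct <- preprocessConfig(dictionary = character(),
                                 stopwordList = c("from", "the"),
                                 stages = c(punctuation = FALSE,
                                            spelling = FALSE,
                                            stemming = FALSE))
  expect_true("(from" %in%
    preprocessDocument("Fall (from the high chair)", cfgNoPunct))

  off <- preprocessConfig(stages = c(punctuation = FALSE, abbreviations = FALSE,
                                     phrases = FALSE, spelling = FALSE,
                                     stopwords = FALSE, stemming = FALSE))
  expect_equal(preprocessDocument("Fell OFF the Ladder", off),
               c("fell", "off", "the", "ladder"))
  expect_equal(preprocessDocument("?!...", preprocessConfig()), character(0))
})

test_that("misspelled generator tokens are recovered through the pipeline", {
  g <- generateCorpus(generatorConfig(nDocs = 300, misspellingRate = 0.05,
                                      seed = 9))
  cfg <- defaultPreprocessConfig(dictionary = g$truth$dictionary,
                                 stages = c(stemming = FALSE))
  corr <- g$truth$corruptions
  recovered <- correctSpelling(corr$corrupted, cfg) == corr$original
  expect_gte(mean(recovered), 0.95)
})

test_that("config validation rejects malformed resources", {
  expect_error(preprocessConfig(phraseList = "single"), "two words")
  expect_error(preprocessConfig(abbreviationMap = c(kmph = "k p h")),
               "single tokens")
  expect_error(preprocessConfig(maxEditDistance = -1), "non-negative")
})
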