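test_that("records with empty narrative or codes are dropped at read time", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,narrative,external_cause,injury_factor",
    'a,"fell off ladder",fall,structure',
    'b,"",fall,structure',
    'c,"burnt hand",fire,appliance'
  ), path)
  expect_message(cp <- readCorpus(path), "dropped 1")
  expect_equal(length(cp), 2L)
  expect_equal(recordIds(cp), c("a", "c"))

  writeLines(c(
    "record_id,narrative,external_cause,injury_factor",
    'a,"fell off ladder",,structure'
  ), path)
  expect_message(cp2 <- readCorpus(path))
  expect_equal(length(cp2), 0L)
})

test_that("a single complete row yields singleton label vocabularies", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,narrative,external_cause,injury_factor",
    'a,"fell off ladder",fall,structure'
  ), path)
  cp <- readCorpus(path)
  expect_equal(length(cp), 1L)
  expect_length(codeLabels(cp, "external_cause"), 1L)
  expect_length(codeLabels(cp, "injury_factor"), 1L)
})

test_that("schema violations and duplicate ids are errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("record_id,narrative,external_cause",
               'a,"fell",fall'), path)
  expect_error(readCorpus(path), "injury_factor")
  writeLines(c(
    "record_id,narrative,external_cause,injury_factor",
    'a,"fell",fall,structure',
    'a,"burnt",fire,appliance'
  ), path)
  expect_error(readCorpus(path), "duplicate")
  expect_error(readCorpus(file.path(tempdir(), "no-such-file.csv")),
               "no such file")
})

test_that("write/read round-trips, including embedded delimiters and quotes", {
  cp <- narrativeCorpus(
    c("r1", "r2"),
    c('fell, then hit "hard" surface', "burnt\thand on stove"),
    c("fall", "fire"), c("structure", "appliance"))
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    writeCorpus(cp, path, dialect)
    back <- readCorpus(path, dialect)
    expect_equal(narratives(back), narratives(cp))
    expect_equal(recordIds(back), recordIds(cp))
    expect_equal(codes(back, "external_cause"), codes(cp, "external_cause"))
    expect_equal(codes(back, "injury_factor"), codes(cp, "injury_factor"))
  }
})

test_that("invalid corpora cannot be constructed or written", {
  expect_error(narrativeCorpus("a", "  ", "fall", "structure"), "non-empty")
  expect_error(narrativeCorpus(c("a", "a"), c("x", "y"),
                               c("fall", "fall"), c("s", "s")), "unique")
  cp <- tinyCorpus()
  cp@injuryFactor[2] <- ""   # corrupt a slot behind the constructor's back
  expect_error(writeCorpus(cp, tempfile()), "vocabulary|non-empty")
})

test_that("corpus statistics use whitespace-token lengths and proportions sum to 1", {
  cp <- narrativeCorpus(
    c("a", "b"), c("one two three", "one two three four five"),
    c("fall", "fall"), c("s", "t"))
  st <- corpusStats(cp)
  expect_equal(st$avgLength, 4)
  expect_equal(st$maxLength, 5)
  expect_equal(st$minLength, 3)
  expect_equal(sum(st$externalProportions), 1)
  expect_equal(sum(st$injuryProportions), 1)

  cp10 <- narrativeCorpus(
    sprintf("d%d", 1:10), rep("some narrative text", 10),
    c(rep("A", 7), rep("B", 3)), rep("s", 10))
  expect_equal(unname(corpusStats(cp10)$externalProportions["A"]), 0.7)
  expect_error(corpusStats(tinyCorpus()[0]), "empty")
})

test_that("generated major-class share concentrates near the 0.70 target", {
  # independence regime isolates the external multinomial
  g <- generateCorpus(generatorConfig(nDocs = 2000, gamma = 0, seed = 42))
  share <- sum(sort(corpusStats(g$corpus)$externalProportions,
                    decreasing = TRUE)[1:2])
  expect_lt(abs(share - 0.70), 0.05)
})
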