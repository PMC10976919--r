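test_that("read_corpus parses JSONL and txt_dir and enforces the schema", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"report_id":"r1","text":"Chest: mass.","gold_t":"T1a","gold_n":"N0"}',
    '{"report_id":"r2","text":"Chest: nothing.","modality":"PETCT"}'
  ), tmp)
  corp <- read_corpus(tmp, "jsonl")
  expect_length(corp, 2L)
  expect_equal(corp[[1]]$report_id, "r1")
  expect_equal(corp[[1]]$gold_t, "T1a")
  expect_equal(corp[[2]]$modality_hint, "PETCT")

  dir <- withr::local_tempdir()
  writeLines("Chest: a mass.", file.path(dir, "a.txt"))
  writeLines("Chest: a node.", file.path(dir, "b.txt"))
  corp2 <- read_corpus(dir, "txt_dir")
  expect_equal(vapply(corp2, function(r) r$report_id, character(1)),
               c("a", "b"))

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"report_id":"r1"}', bad)
  expect_error(read_corpus(bad, "jsonl"), "line 1")
  writeLines(c('{"report_id":"x","text":"t."}',
               '{"report_id":"x","text":"t."}'), bad)
  expect_error(read_corpus(bad, "jsonl"), "duplicate")
})

test_that("write_corpus round-trips through read_corpus", {
  corp <- generate_corpus(generator_spec(n_reports = 5L, seed = 3L))
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, tmp)
  back <- read_corpus(tmp, "jsonl")
  expect_equal(vapply(back, `[[`, character(1), "text"),
               vapply(corp, `[[`, character(1), "text"))
  expect_equal(vapply(back, `[[`, character(1), "gold_t"),
               vapply(corp, `[[`, character(1), "gold_t"))
})

test_that("sectionize recognizes subheadings and degrades to unsectioned", {
  lex <- test_lexicon()
  r <- list(report_id = "s1", text = "Clinical details: cough.\nImpression: mass.")
  sec <- sectionize(r, lex)
  expect_equal(sec$sections$label, c("clinical_details", "impression"))

  r2 <- list(report_id = "s2", text = "There is a mass. No nodes.")
  sec2 <- sectionize(r2, lex)
  expect_equal(sec2$sections$label, "unsectioned")
  expect_equal(sec2$sections$start, 0L)
  expect_equal(sec2$sections$end, nchar(r2$text))

  r3 <- list(report_id = "s3", text = "Impression: single heading only.")
  sec3 <- sectionize(r3, lex)
  expect_equal(nrow(sec3$sections), 1L)
  expect_equal(sec3$sections$label, "impression")
  expect_equal(c(sec3$sections$start, sec3$sections$end),
               c(0L, nchar(r3$text)))
})

test_that("section spans are ordered, non-overlapping and cover the text", {
  lex <- test_lexicon()
  headings <- c("Clinical details:", "Technique:", "Chest:", "Abdomen:",
                "Impression:", "Skeleton:")
  fillers <- c("There is a mass.", "No nodes seen.", "normal.", "text",
               "12 mm nodule\nacross lines.")
  set.seed(421)
  for (i in 1:1000) {
    n <- sample(1:6, 1)
    parts <- vapply(seq_len(n), function(j) {
      h <- if (stats::runif(1) < 0.7) sample(headings, 1) else ""
      paste0(h, " ", sample(fillers, 1))
    }, character(1))
    txt <- paste(parts, collapse = "\n")
    if (!nzchar(trimws(txt))) next
    sec <- sectionize(list(report_id = "f", text = txt), lex)$sections
    expect_gte(nrow(sec), 1L)
    expect_true(all(diff(sec$start) > 0) || nrow(sec) == 1L)
    if (nrow(sec) > 1L) {
      expect_true(all(sec$end[-nrow(sec)] <= sec$start[-1L]))
    }
    expect_equal(sec$end[nrow(sec)], nchar(txt))
    # idempotence: re-running yields identical spans
    sec2 <- sectionize(list(report_id = "f", text = txt), lex)$sections
    expect_identical(sec, sec2)
  }
})

test_that("detect_modality uses PET cues, body-part count and hint precedence", {
  lex <- test_lexicon()
  pet <- list(report_id = "m1",
              text = "Technique: Whole-body 18F-FDG PET-CT.\nChest: clear.")
  expect_equal(sectionize(pet, lex)$modality, "PETCT")

  ct <- list(report_id = "m2",
             text = "Technique: Contrast-enhanced CT.\nChest: clear.")
  expect_equal(sectionize(ct, lex)$modality, "CT")

  multi <- list(report_id = "m3",
                text = "Chest: clear.\nAbdomen: clear.\nSkeleton: clear.")
  expect_equal(sectionize(multi, lex)$modality, "PETCT")

  hinted <- list(report_id = "m4", modality_hint = "PETCT",
                 text = "Chest: clear.")
  expect_equal(sectionize(hinted, lex)$modality, "PETCT")
})
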