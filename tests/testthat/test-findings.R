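test_that("extract_tumor links sizes, honors blacklist and certainty policy", {
  ann <- annotate_text("There is a spiculated mass measuring 25 mm.")
  tum <- extract_tumor(ann$mentions, ann$measurements, ann$sentences)
  expect_true(tum$present)
  expect_equal(tum$size_mm, 25)

  # blacklisted adrenal size elsewhere in the report is ignored
  ann2 <- annotate_text(
    "There is a mass in the right upper lobe measuring 30 mm.",
    "The adrenal gland is enlarged, measuring 45 mm.")
  tum2 <- extract_tumor(ann2$mentions, ann2$measurements, ann2$sentences)
  expect_equal(tum2$size_mm, 30)
  expect_equal(tum2$side, "right")
  expect_equal(tum2$lobes, "RUL")

  # uncertain-only tumor is not present
  ann3 <- annotate_text("Possible mass in the left lower lobe.")
  tum3 <- extract_tumor(ann3$mentions, ann3$measurements, ann3$sentences)
  expect_false(tum3$present)
  expect_true(any(grepl("uncertainty", tum3$notes)))
})

test_that("tumor size can come from an adjacent unattached measurement", {
  ann <- annotate_text("There is a spiculated mass in the right lower lobe.",
                       "It measures 42 mm.")
  tum <- extract_tumor(ann$mentions, ann$measurements, ann$sentences)
  expect_equal(tum$size_mm, 42)
  # ... but a node-owned measurement next door is not stolen
  ann2 <- annotate_text("There is a spiculated mass in the right lower lobe.",
                        "An enlarged lymph node at station 4R measures 12 mm.")
  tum2 <- extract_tumor(ann2$mentions, ann2$measurements, ann2$sentences)
  expect_true(is.na(tum2$size_mm))
})

test_that("invasion features and nodule cues feed T overruling", {
  ann <- annotate_text(
    "The mass invades the mediastinum.",
    "A satellite nodule is present in the same lobe.",
    "There is a separate tumour nodule in another lobe of the same lung.")
  tum <- extract_tumor(ann$mentions, ann$measurements, ann$sentences)
  expect_equal(tum$invasion_features, "T4")
  expect_true(tum$satellite_same_lobe)
  expect_true(tum$separate_nodule_other_lobe)
})

extract_nodes_text <- function(txt) {
  ann <- annotate_text(txt)
  extract_nodes(ann$mentions, ann$measurements, ann$sentences)
}

test_that("extract_nodes builds per-sentence findings with station/side/size", {
  ann <- annotate_text("There is an enlarged lymph node at station 4R, measuring 12 mm.")
  nd <- extract_nodes(ann$mentions, ann$measurements, ann$sentences)
  expect_equal(nrow(nd), 1L)
  expect_equal(nd$station, 4L)
  expect_equal(nd$side, "right")
  expect_equal(nd$size_mm, 12)
  expect_true(nd$described_pathologic)

  # short axis is used for multidimensional node sizes
  ann2 <- annotate_text("An enlarged subcarinal node of 15 x 9 mm.")
  nd2 <- extract_nodes(ann2$mentions, ann2$measurements, ann2$sentences)
  expect_equal(nd2$size_mm, 9)
  expect_equal(nd2$station, 7L)

  expect_equal(nrow(extract_nodes_text("No enlarged mediastinal nodes.")), 0L)
  expect_equal(nrow(extract_nodes_text("A pathologic node in the mesentery.")), 0L)
})

test_that("match_avidity is gated on modality and reads negated cues", {
  ann <- annotate_text("An FDG-avid lymph node at station 7.")
  nd <- extract_nodes(ann$mentions, ann$measurements, ann$sentences)
  tum <- extract_tumor(ann$mentions, ann$measurements, ann$sentences)
  av <- match_avidity(ann$mentions, tum, nd, "PETCT")
  expect_true(av$nodes$avid)

  ann2 <- annotate_text("An enlarged lymph node without FDG uptake.")
  nd2 <- extract_nodes(ann2$mentions, ann2$measurements, ann2$sentences)
  av2 <- match_avidity(ann2$mentions, tum, nd2, "PETCT")
  expect_false(av2$nodes$avid)

  # CT reports never carry avidity, whatever the prose says
  av3 <- match_avidity(ann$mentions, tum, nd, "CT")
  expect_true(is.na(av3$nodes$avid))
})

test_that("larger tumor-linked measurements never decrease the size", {
  lex <- test_lexicon()
  base <- "There is a mass measuring 20 mm."
  ann <- annotate_text(base, lexicon = lex)
  s0 <- extract_tumor(ann$mentions, ann$measurements, ann$sentences)$size_mm
  for (extra in c(25, 40, 80)) {
    ann2 <- annotate_text(base,
                          sprintf("A further mass measuring %d mm.", extra),
                          lexicon = lex)
    s <- extract_tumor(ann2$mentions, ann2$measurements, ann2$sentences)$size_mm
    expect_gte(s, s0)
    s0 <- s
  }
})

test_that("fully negated node corpora yield zero node findings", {
  sents <- c("No enlarged lymph nodes at station 4R.",
             "No mediastinal or hilar lymphadenopathy.",
             "There are no FDG-avid lymph nodes.")
  ann <- do.call(annotate_text, as.list(sents))
  expect_equal(nrow(extract_nodes(ann$mentions, ann$measurements,
                                  ann$sentences)), 0L)
})
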