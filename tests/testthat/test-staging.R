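test_that("map_t applies size buckets with inclusive boundaries", {
  rules <- test_rules()
  cases <- list(
    list(5, "T1a"), list(10, "T1a"), list(11, "T1b"), list(20, "T1b"),
    list(30, "T1c"), list(31, "T2a"), list(40, "T2a"), list(50, "T2b"),
    list(51, "T3"), list(70, "T3"), list(71, "T4"), list(95, "T4")
  )
  for (cs in cases) {
    expect_equal(map_t(make_tumor(size_mm = cs[[1]]), rules), cs[[2]],
                 label = paste(cs[[1]], "mm"))
  }
  expect_equal(map_t(make_tumor(present = FALSE), rules), "T0")
})

test_that("map_t feature overruling lifts but never lowers the stage", {
  rules <- test_rules()
  expect_equal(map_t(make_tumor(size_mm = 20, satellite_same_lobe = TRUE),
                     rules), "T3")
  expect_equal(map_t(make_tumor(size_mm = 15,
                                separate_nodule_other_lobe = TRUE),
                     rules), "T4")
  expect_equal(map_t(make_tumor(size_mm = 80, invasion_features = "T2"),
                     rules), "T4")
  # generic T2: feature without size
  expect_equal(map_t(make_tumor(invasion_features = "T2"), rules), "T2")
  # with a size, a T2 feature yields at least T2a
  expect_equal(map_t(make_tumor(size_mm = 15, invasion_features = "T2"),
                     rules), "T2a")
})

test_that("map_t agrees with the hand-coded decision-table oracle", {
  rules <- test_rules()
  sizes <- c(NA, seq(5, 90, by = 5))
  for (size in sizes) {
    for (t2f in c(FALSE, TRUE)) for (t3f in c(FALSE, TRUE)) {
      for (sat in c(FALSE, TRUE)) for (multi in c(FALSE, TRUE)) {
        feats <- c(if (t2f) "T2", if (t3f) "T3")
        got <- map_t(make_tumor(size_mm = if (is.na(size)) NA_real_ else size,
                                invasion_features = feats,
                                satellite_same_lobe = sat,
                                separate_nodule_other_lobe = multi), rules)
        want <- oracle_map_t(size, t2f, t3f, FALSE, sat, multi)
        expect_equal(got, want,
                     label = paste("size", size, "t2", t2f, "t3", t3f,
                                   "sat", sat, "multi", multi))
      }
    }
  }
})

test_that("decide_node_pathologic implements PET overruling of the CT rule", {
  rules <- test_rules()
  # enlarged but non-avid -> non-pathological
  expect_false(decide_node_pathologic(
    make_node(size_mm = 14, described_pathologic = TRUE, avid = FALSE),
    "PETCT", rules))
  # small but avid -> pathological
  expect_true(decide_node_pathologic(
    make_node(size_mm = 7, avid = TRUE), "PETCT", rules))
  # CT size rule with the 10 mm short-axis cutoff
  expect_true(decide_node_pathologic(make_node(size_mm = 12), "CT", rules))
  expect_true(decide_node_pathologic(make_node(size_mm = 10), "CT", rules))
  expect_false(decide_node_pathologic(make_node(size_mm = 9), "CT", rules))
  expect_true(decide_node_pathologic(
    make_node(described_pathologic = TRUE), "CT", rules))
  # unstated avidity on PET-CT falls back to the CT rule
  expect_true(decide_node_pathologic(
    make_node(size_mm = 12), "PETCT", rules))
})

test_that("map_n maps stations by laterality and degrades conservatively", {
  rules <- test_rules()
  n_of <- function(node, tumor_side = "right", modality = "CT") {
    map_n(node, tumor_side, modality, rules)
  }
  expect_equal(n_of(make_node(4L, "right", described_pathologic = TRUE)), "N2")
  expect_equal(n_of(make_node(10L, "left", described_pathologic = TRUE)), "N3")
  expect_equal(n_of(make_node(10L, "right", described_pathologic = TRUE)), "N1")
  expect_equal(n_of(make_node(1L, "left", described_pathologic = TRUE)), "N3")
  expect_equal(n_of(make_node(7L, "left", described_pathologic = TRUE)), "N2")
  # no pathologic nodes
  expect_equal(n_of(make_node(4L, "right")), "N0")
  # unknown tumor side: stations 2-9 conservatively N2
  expect_equal(n_of(make_node(4L, "left", described_pathologic = TRUE),
                    tumor_side = "unknown"), "N2")
  # relation wording wins when no absolute side is known
  expect_equal(n_of(make_node(10L, relation = "contralateral",
                              described_pathologic = TRUE)), "N3")
  # station-less mediastinal wording degrades to N2
  expect_equal(n_of(make_node(region = "mediastinal",
                              described_pathologic = TRUE)), "N2")
  # max over several nodes
  nodes <- rbind(make_node(11L, "right", described_pathologic = TRUE),
                 make_node(4L, "right", described_pathologic = TRUE))
  expect_equal(n_of(nodes), "N2")
})

test_that("map_n agrees with the hand-coded station oracle", {
  rules <- test_rules()
  for (st in 1:14) {
    for (ns in c("left", "right", "midline")) {
      for (ts in c("left", "right", "unknown")) {
        for (path in c(FALSE, TRUE)) {
          got <- map_n(make_node(st, ns, described_pathologic = path),
                       ts, "CT", rules)
          expect_equal(got, oracle_map_n(st, ns, ts, path),
                       label = paste("station", st, "node", ns, "tumor", ts,
                                     "path", path))
        }
      }
    }
  }
})

test_that("adding a pathologic node never lowers N", {
  rules <- test_rules()
  set.seed(31)
  for (i in 1:50) {
    base <- make_node(sample(1:14, 1), sample(c("left", "right"), 1),
                      described_pathologic = TRUE)
    extra <- make_node(sample(1:14, 1), sample(c("left", "right"), 1),
                       described_pathologic = TRUE)
    n1 <- map_n(base, "right", "CT", rules)
    n2 <- map_n(rbind(base, extra), "right", "CT", rules)
    expect_gte(match(n2, n_labels), match(n1, n_labels))
  }
})

test_that("stage_report composes the pipeline end to end", {
  lex <- test_lexicon()
  rules <- test_rules()
  rep <- list(report_id = "e2e", text = paste(
    "Technique: Contrast-enhanced CT of the chest.",
    "Chest: There is a spiculated mass in the right upper lobe measuring 28 mm.",
    "There is an enlarged lymph node at station 4R, measuring 14 mm.",
    "Impression: Primary lung carcinoma.", sep = "\n"))
  res <- stage_report(rep, lex, rules)
  expect_equal(res$t, "T1c")
  expect_equal(res$n, "N2")
  expect_gt(length(res$trace), 0L)

  # all findings negated -> T0/N0
  rep2 <- list(report_id = "neg", text =
    "Chest: No mass. No enlarged lymph nodes.")
  res2 <- stage_report(rep2, lex, rules)
  expect_equal(c(res2$t, res2$n), c("T0", "N0"))

  # PET overruling both ways: enlarged contralateral node without uptake is
  # ignored, small avid ipsilateral station 11 node counts -> N1
  rep3 <- list(report_id = "pet", text = paste(
    "Technique: Whole-body 18F-FDG PET-CT.",
    "Chest: There is a spiculated mass in the right upper lobe measuring 30 mm.",
    "There is an enlarged lymph node at station 4L, measuring 15 mm, without FDG uptake.",
    "A 7 mm FDG-avid lymph node is seen at station 11R.", sep = "\n"))
  res3 <- stage_report(rep3, lex, rules)
  expect_equal(res3$n, "N1")
  expect_true(any(grepl("overruling", res3$trace)))

  expect_error(stage_report(list(report_id = "x", text = "  "), lex, rules),
               "empty text")
})

test_that("stage_report is deterministic", {
  lex <- test_lexicon()
  rules <- test_rules()
  rep <- generate_report("T2b", "N3", "PETCT", seed = 77)
  r1 <- stage_report(rep, lex, rules)
  r2 <- stage_report(rep, lex, rules)
  expect_identical(r1, r2)
})
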