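#' T and N stage label sets
#'
#' T labels are totally ordered `T0 < T1a < T1b < T1c < T2 < T2a < T2b < T3
#' < T4`; the generic `T2` is used only when a T2 feature exists without any
#' tumor size. N labels are `N0 < N1 < N2 < N3`.
#'
#' @name stage_labels
NULL

#' @rdname stage_labels
#' @export
t_labels <- c("T0", "T1a", "T1b", "T1c", "T2", "T2a", "T2b", "T3", "T4")

#' @rdname stage_labels
#' @export
n_labels <- c("N0", "N1", "N2", "N3")

t_rank <- function(t) match(t, t_labels) - 1L
n_rank <- function(n) match(n, n_labels) - 1L

#' Load TNM staging rules
#'
#' Reads the versioned rules configuration: tumor-size thresholds,
#' feature-to-T map, the 10 mm short-axis node size cutoff, and the
#' station-by-laterality N map. The numeric content follows the 8th TNM
#' edition; a revised edition can be dropped in as a different YAML file.
#'
#' @param path Rules YAML; `NULL` (default) loads the built-in TNM-8 rules.
#' @return A list of class `tn_rules`.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tnm8_rules.yaml", package = "lungtnm")
  }
  if (!file.exists(path)) stop("rules file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  thr <- data.frame(
    max_mm = vapply(raw$t_size_thresholds_mm,
                    function(x) as.numeric(x$max_mm %||% Inf), numeric(1)),
    stage = vapply(raw$t_size_thresholds_mm,
                   function(x) as.character(x$stage), character(1)),
    stringsAsFactors = FALSE
  )
  if (is.unsorted(thr$max_mm, strictly = TRUE)) {
    stop("t_size_thresholds_mm must be strictly increasing", call. = FALSE)
  }
  rules <- structure(list(
    version = as.character(raw$version %||% "unversioned"),
    t_size_thresholds_mm = thr,
    feature_to_t = raw$feature_to_t,
    node_size_cutoff_mm = as.numeric(raw$node_size_cutoff_mm),
    station_to_n = raw$station_to_n
  ), class = "tn_rules")
  for (rel in c("ipsilateral", "contralateral")) {
    missing <- setdiff(as.character(1:14), names(rules$station_to_n[[rel]]))
    if (length(missing) > 0L) {
      stop("station_to_n$", rel, " leaves stations unmapped: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  rules
}

size_stage <- function(size_mm, rules) {
  thr <- rules$t_size_thresholds_mm
  thr$stage[which(size_mm <= thr$max_mm)[1L]]
}

#' Map a tumor finding to a T stage
#'
#' The size stage is the smallest threshold bucket holding the long-axis
#' size, boundaries inclusive (30 mm is T1c). Feature-based overruling then
#' takes the maximum of the size stage and the stage implied by invasion
#' features, a same-lobe satellite nodule (T3) or a separate nodule in
#' another ipsilateral lobe (T4). A T2 feature without any size yields the
#' generic label `T2`; with a known size it lifts the stage to at least T2a.
#' No certain tumor yields `T0`.
#'
#' @param tumor A `tn_tumor` finding.
#' @param rules A `tn_rules` object.
#' @return A single T label (see [t_labels]).
#' @export
map_t <- function(tumor, rules = load_rules()) {
  if (!isTRUE(tumor$present)) return("T0")
  stages <- character(0)
  if (!is.null(tumor$size_mm) && !is.na(tumor$size_mm)) {
    stages <- size_stage(tumor$size_mm, rules)
  }
  feats <- as.character(tumor$invasion_features %||% character(0))
  if (isTRUE(tumor$satellite_same_lobe)) feats <- c(feats, "satellite_same_lobe")
  if (isTRUE(tumor$separate_nodule_other_lobe)) {
    feats <- c(feats, "separate_nodule_other_lobe")
  }
  for (f in feats) {
    fs <- rules$feature_to_t[[f]]
    if (is.null(fs)) next
    if (identical(fs, "T2") && length(stages) > 0L) fs <- "T2a"
    stages <- c(stages, fs)
  }
  if (length(stages) == 0L) return("T0")
  t_labels[max(t_rank(stages)) + 1L]
}

#' Decide whether a lymph node is pathologic
#'
#' On PET-CT the metabolic information overrules the anatomical criterion:
#' an enlarged node without FDG uptake is non-pathological, and a
#' non-enlarged node with FDG uptake is pathological. When avidity is
#' unstated — and always on pure CT — the CT rule applies: pathologic iff
#' affirmed enlarged/pathologic wording or short axis at or above the size
#' cutoff (10 mm).
#'
#' @param node One row of a `tn_nodes` data.frame (or an equivalent list
#'   with `avid`, `described_pathologic`, `size_mm`).
#' @param modality `"CT"` or `"PETCT"`.
#' @param rules A `tn_rules`.
#' @return `TRUE` or `FALSE`.
#' @export
decide_node_pathologic <- function(node, modality, rules = load_rules()) {
  if (identical(modality, "PETCT") && !is.na(node$avid)) {
    return(isTRUE(node$avid))
  }
  isTRUE(node$described_pathologic) ||
    (!is.na(node$size_mm) && node$size_mm >= rules$node_size_cutoff_mm)
}

#' Map node findings to an N stage
#'
#' Each pathologic node contributes an N value from the station-by-laterality
#' map: station 1 (supraclavicular/scalene) is N3 on either side; station 7
#' (subcarinal) is N2 on either side; ipsilateral stations 2-9 are N2 and
#' 10-14 are N1; contralateral stations are N3. The final N is the maximum
#' over pathologic nodes; no pathologic node yields N0. When laterality
#' cannot be resolved (unknown tumor side, or a midline/unsided node) the
#' ipsilateral — conservative — mapping is used and a trace warning emitted;
#' a pathologic node with mediastinal wording but no station maps to N2 with
#' a warning.
#'
#' @param nodes A `tn_nodes` data.frame with `avid` set per modality.
#' @param tumor_side `"left"`, `"right"` or `"unknown"`.
#' @param modality `"CT"` or `"PETCT"`.
#' @param rules A `tn_rules`.
#' @param trace Optional environment collecting trace strings.
#' @return A single N label (see [n_labels]).
#' @export
map_n <- function(nodes, tumor_side = "unknown", modality = "CT",
                  rules = load_rules(), trace = NULL) {
  note <- function(msg) {
    if (!is.null(trace)) trace$lines <- c(trace$lines, msg)
  }
  best <- 0L
  for (i in seq_len(nrow(nodes))) {
    node <- nodes[i, ]
    path <- decide_node_pathologic(node, modality, rules)
    if (identical(modality, "PETCT") && !is.na(node$avid)) {
      ct_verdict <- isTRUE(node$described_pathologic) ||
        (!is.na(node$size_mm) && node$size_mm >= rules$node_size_cutoff_mm)
      if (ct_verdict != path) {
        note(paste0("[overruling] PET avidity (", node$avid,
                    ") overruled CT size/wording verdict for node in sentence ",
                    node$source_sentence))
      }
    }
    if (!path) next
    nv <- node_n_value(node, tumor_side, rules, note)
    if (is.na(nv)) next
    best <- max(best, n_rank(nv))
  }
  n_labels[best + 1L]
}

node_n_value <- function(node, tumor_side, rules, note) {
  station <- node$station
  if (is.na(station)) {
    if (identical(node$region, "mediastinal")) {
      note(paste0("[node] pathologic mediastinal node without station in ",
                  "sentence ", node$source_sentence, "; assuming N2"))
      return("N2")
    }
    note(paste0("[node] pathologic node without station or region in ",
                "sentence ", node$source_sentence, "; ignored"))
    return(NA_character_)
  }
  relation <- node$relation
  if (is.na(relation)) {
    side <- node$side
    if (identical(side, "midline")) {
      relation <- "midline"
    } else if (side %in% c("left", "right") &&
               tumor_side %in% c("left", "right")) {
      relation <- if (side == tumor_side) "ipsilateral" else "contralateral"
    } else {
      relation <- "unknown"
    }
  }
  key <- as.character(station)
  if (relation %in% c("ipsilateral", "contralateral")) {
    return(rules$station_to_n[[relation]][[key]])
  }
  # midline or unresolved laterality: conservative (ipsilateral) mapping
  if (relation == "unknown") {
    note(paste0("[node] laterality unresolved for station ", station,
                " node; conservative ipsilateral mapping"))
  }
  rules$station_to_n[["ipsilateral"]][[key]]
}

#' Stage one free-text report
#'
#' Runs the full pipeline: sectionize, detect modality, clean/split/measure,
#' match concepts and assign assertions, aggregate tumor and node findings,
#' match PET avidity, and map to the final T and N stage. Every decision —
#' including PET-over-CT overrulings, blacklist ties, uncertain pathology
#' exclusions and degraded-input fallbacks — is recorded in the trace.
#'
#' @param report A `tn_report` (or list with `report_id`, `text`, optional
#'   `modality_hint`).
#' @param lexicon A `tn_lexicon`.
#' @param rules A `tn_rules`.
#' @return An object of class `tn_result`: `report_id`, `t`, `n`,
#'   `modality`, `trace` (character vector), and the underlying `tumor` and
#'   `nodes` findings.
#' @examples
#' rep <- list(report_id = "ex1",
#'             text = "Chest: There is a spiculated mass in the right upper lobe measuring 25 mm.\nNo pathologically enlarged lymph nodes.\nImpression: Primary lung carcinoma.")
#' res <- stage_report(rep)
#' c(res$t, res$n)
#' @export
stage_report <- function(report, lexicon = load_lexicon(),
                         rules = load_rules()) {
  if (!nzchar(trimws(report$text %||% ""))) {
    stop("report '", report$report_id %||% "?", "' has empty text",
         call. = FALSE)
  }
  tr <- new.env(parent = emptyenv())
  tr$lines <- character(0)

  sectioned <- sectionize(report, lexicon)
  if (nrow(sectioned$sections) == 1L &&
      sectioned$sections$label[1L] == "unsectioned") {
    tr$lines <- c(tr$lines,
                  "[sectionizer] no subheadings matched; whole text unsectioned")
  } else {
    tr$lines <- c(tr$lines, paste0("[sectionizer] ", nrow(sectioned$sections),
                                   " sections: ",
                                   paste(sectioned$sections$label,
                                         collapse = ", ")))
  }
  modality <- sectioned$modality
  tr$lines <- c(tr$lines, paste0("[modality] ", modality,
                                 if (!is.na(report$modality_hint %||% NA))
                                   " (from hint)" else ""))

  ann <- annotate_report(sectioned, lexicon)
  n_unc <- sum(ann$mentions$assertion == "uncertain")
  n_neg <- sum(ann$mentions$assertion == "negated")
  tr$lines <- c(tr$lines, paste0("[context] ", nrow(ann$mentions),
                                 " mentions (", n_neg, " negated, ", n_unc,
                                 " uncertain)"))
  if (any(ann$measurements$blacklisted)) {
    tr$lines <- c(tr$lines, paste0("[measurement] ",
                                   sum(ann$measurements$blacklisted),
                                   " measurement(s) blacklisted"))
  }

  tumor <- extract_tumor(ann$mentions, ann$measurements, ann$sentences)
  tr$lines <- c(tr$lines, tumor$notes)
  nodes <- extract_nodes(ann$mentions, ann$measurements, ann$sentences)

  tum_aff <- ann$mentions[ann$mentions$category == "tumor" &
                            ann$mentions$assertion == "affirmed", ,
                          drop = FALSE]
  av <- match_avidity(ann$mentions, tumor, nodes, modality,
                      tumor_sentences = unique(tum_aff$sentence_index))
  tumor <- av$tumor; nodes <- av$nodes

  t_stage <- map_t(tumor, rules)
  if (!tumor$present) {
    tr$lines <- c(tr$lines, "[tumor] no certain tumor found; T0")
  } else {
    tr$lines <- c(tr$lines, paste0(
      "[tumor] present, size ", tumor$size_mm, " mm, side ", tumor$side,
      if (length(tumor$invasion_features))
        paste0(", invasion ", paste(tumor$invasion_features, collapse = "/"))
      else "",
      if (tumor$satellite_same_lobe) ", satellite nodule same lobe" else "",
      if (tumor$separate_nodule_other_lobe)
        ", separate nodule other lobe" else "",
      " -> ", t_stage))
  }

  n_stage <- map_n(nodes, tumor$side, modality, rules, trace = tr)
  tr$lines <- c(tr$lines, paste0("[node] ", nrow(nodes), " node finding(s) -> ",
                                 n_stage))

  structure(list(
    report_id = report$report_id, t = t_stage, n = n_stage,
    modality = modality, trace = tr$lines, tumor = tumor, nodes = nodes
  ), class = "tn_result")
}

#' Stage every report of a corpus
#'
#' @param corpus A `tn_corpus` (list of reports).
#' @inheritParams stage_report
#' @return A list of `tn_result`, one per report, order preserved.
#' @export
stage_corpus <- function(corpus, lexicon = load_lexicon(),
                         rules = load_rules()) {
  lapply(corpus, stage_report, lexicon = lexicon, rules = rules)
}

#' @export
print.tn_result <- function(x, ...) {
  cat("<tn_result>", x$report_id, paste0(x$t, x$n),
      paste0("(", x$modality, ")"), "\n")
  invisible(x)
}

#' Serialize staging results to JSON-lines
#'
#' @param results List of `tn_result`.
#' @param path Output file.
#' @param trace Include the trace array per report.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, trace = FALSE) {
  lines <- vapply(results, function(r) {
    rec <- list(report_id = r$report_id, t = r$t, n = r$n,
                modality = r$modality)
    if (trace) rec$trace <- r$trace
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
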