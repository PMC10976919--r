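# Sections in which tumor/node evidence is collected.  Other body-part
# sections of a whole-body PET-CT (abdomen, neck, skeleton) contribute only
# blacklist context: searching them caused tumor/node mismatches.
searched_sections <- function(labels) {
  labels %in% c("body_part:chest", "impression", "unsectioned")
}

#' Aggregate mentions and measurements into a tumor finding
#'
#' The tumor is considered present only when at least one *affirmed* tumor
#' mention occurs in a chest or impression section (uncertainty phrasing such
#' as "possible mass" does not count: pathology is only included when stated
#' as certain). Tumor size is the largest long-axis, non-blacklisted
#' measurement attached to a tumor mention — attachment is nearest-concept
#' within the sentence, falling back to unattached measurements in an
#' adjacent sentence of the same section. Invasion features, same-lobe
#' satellite nodules and separate nodules in another lobe are collected for
#' feature-based T overruling.
#'
#' @param mentions Mentions with final assertions ([assign_modifiers()]).
#' @param measurements Measurements with blacklist flags
#'   ([apply_blacklist()]).
#' @param sentences Sentence table ([split_sentences()]).
#' @return A list of class `tn_tumor`: `present`, `size_mm`, `side`,
#'   `lobes`, `invasion_features`, `satellite_same_lobe`,
#'   `separate_nodule_other_lobe`, `avid`, `notes`.
#' @export
extract_tumor <- function(mentions, measurements, sentences) {
  notes <- character(0)
  in_scope <- sentences$index[searched_sections(sentences$section_label)]
  m <- mentions[mentions$sentence_index %in% in_scope, , drop = FALSE]

  tum <- m[m$category == "tumor", , drop = FALSE]
  tum_aff <- tum[tum$assertion == "affirmed", , drop = FALSE]
  present <- nrow(tum_aff) > 0L
  if (!present && any(tum$assertion == "uncertain")) {
    notes <- c(notes, "[context] tumor mentioned only with uncertainty; excluded")
  }

  tumor_sent <- unique(tum_aff$sentence_index)
  size_mm <- NA_real_
  if (present) {
    att <- attach_measurements(measurements, m, sentences, tumor_sent)
    tum_meas <- att[att$attached %in% "tumor" & !att$blacklisted, , drop = FALSE]
    if (nrow(tum_meas) > 0L) {
      size_mm <- max(tum_meas$long_mm)
      if (any(tum_meas$blacklist_tie)) {
        notes <- c(notes, "[measurement] blacklist distance tie; measurement kept")
      }
    } else {
      notes <- c(notes, "[measurement] no size linked to tumor")
    }
  }

  side <- "unknown"; lobes <- character(0)
  if (present) {
    loc <- m[m$sentence_index %in% tumor_sent &
               m$category %in% c("laterality", "lobe") &
               !is.na(m$side), , drop = FALSE]
    if (nrow(loc) > 0L) {
      # nearest to a tumor mention in the same sentence
      d <- vapply(seq_len(nrow(loc)), function(k) {
        ts <- tum_aff[tum_aff$sentence_index == loc$sentence_index[k], ,
                      drop = FALSE]
        min(span_gap(loc$start[k], loc$end[k], ts$start, ts$end))
      }, numeric(1))
      side <- loc$side[which.min(d)]
    }
    lobes <- unique(stats::na.omit(m$lobe[m$sentence_index %in% tumor_sent]))
  }

  inv <- m[m$category == "invasion_target" & m$assertion == "affirmed", ,
           drop = FALSE]
  sat <- any(m$category == "satellite_nodule" & m$assertion == "affirmed")
  sep <- any(m$category == "multilobe_cue" & m$assertion == "affirmed")

  structure(list(
    present = present, size_mm = size_mm, side = side, lobes = lobes,
    invasion_features = unique(stats::na.omit(inv$t_feature_class)),
    satellite_same_lobe = sat, separate_nodule_other_lobe = sep,
    avid = NA, notes = notes
  ), class = "tn_tumor")
}

# Attach non-blacklisted measurements to "tumor" or "node": nearest affirmed
# tumor/lymph-node mention within the same sentence; a measurement whose
# sentence has neither attaches to the tumor when an adjacent sentence of the
# same section holds an affirmed tumor mention.
attach_measurements <- function(measurements, mentions, sentences, tumor_sent) {
  if (nrow(measurements) == 0L) return(measurements)
  aff <- mentions[mentions$assertion == "affirmed" &
                    mentions$category %in% c("tumor", "lymph_node"), ,
                  drop = FALSE]
  for (j in seq_len(nrow(measurements))) {
    if (measurements$blacklisted[j]) next
    si <- measurements$sentence_index[j]
    same <- aff[aff$sentence_index == si, , drop = FALSE]
    if (nrow(same) > 0L) {
      d <- span_gap(measurements$start[j], measurements$end[j],
                    same$start, same$end)
      measurements$attached[j] <- ifelse(
        same$category[which.min(d)] == "tumor", "tumor", "node")
      next
    }
    sec <- sentences$section_label[sentences$index == si]
    neigh <- sentences$index[abs(sentences$index - si) == 1L &
                               sentences$section_label == sec]
    if (length(neigh) > 0L && any(neigh %in% tumor_sent)) {
      measurements$attached[j] <- "tumor"
    }
  }
  measurements
}

#' Aggregate mentions into lymph-node findings
#'
#' One `NodeFinding` per chest/impression sentence holding at least one
#' *affirmed* lymph-node mention; negated node sentences yield no finding.
#' Station and side come from station and laterality mentions in the same
#' sentence (a parsed `station 4R` supplies both); node size is the nearest
#' non-blacklisted measurement, short axis for multi-dimensional forms
#' (radiological convention for nodes). Sentences naming a non-thoracic
#' nodal region (mesentery, axilla, ...) are excluded.
#'
#' @inheritParams extract_tumor
#' @return A data.frame of class `tn_nodes`, one row per finding: `station`,
#'   `side`, `relation` (ipsilateral/contralateral wording), `size_mm`,
#'   `described_pathologic`, `avid`, `region`, `source_sentence`.
#' @export
extract_nodes <- function(mentions, measurements, sentences) {
  in_scope <- sentences$index[searched_sections(sentences$section_label)]
  m <- mentions[mentions$sentence_index %in% in_scope, , drop = FALSE]
  rows <- list()
  for (si in unique(m$sentence_index)) {
    sm <- m[m$sentence_index == si, , drop = FALSE]
    nodes <- sm[sm$category == "lymph_node" & sm$assertion == "affirmed", ,
                drop = FALSE]
    if (nrow(nodes) == 0L) next
    if (any(sm$category == "blacklist_anatomy" & sm$nodal_exclude)) next

    anchor_s <- nodes$start[1L]; anchor_e <- nodes$end[1L]
    st <- sm[sm$category == "station" & !is.na(sm$station_number), ,
             drop = FALSE]
    station <- NA_integer_; st_side <- NA_character_
    if (nrow(st) > 0L) {
      d <- span_gap(anchor_s, anchor_e, st$start, st$end)
      k <- which.min(d)
      station <- st$station_number[k]
      st_side <- st$side[k]
    }
    region <- if (any(sm$category == "station" & !is.na(sm$region))) {
      sm$region[sm$category == "station" & !is.na(sm$region)][1L]
    } else NA_character_

    side <- st_side
    if (is.na(side)) {
      lat <- sm[sm$category == "laterality" & !is.na(sm$side), , drop = FALSE]
      if (nrow(lat) > 0L) {
        d <- span_gap(anchor_s, anchor_e, lat$start, lat$end)
        side <- lat$side[which.min(d)]
      }
    }
    relation <- NA_character_
    rel <- sm[sm$category == "laterality" & !is.na(sm$relation), , drop = FALSE]
    if (nrow(rel) > 0L) relation <- rel$relation[1L]

    size_mm <- NA_real_
    mm <- measurements[measurements$sentence_index == si &
                         !measurements$blacklisted, , drop = FALSE]
    if (nrow(mm) > 0L) {
      d <- span_gap(anchor_s, anchor_e, mm$start, mm$end)
      size_mm <- mm$short_mm[which.min(d)]
    }

    rows[[length(rows) + 1L]] <- data.frame(
      station = station,
      side = ifelse(is.na(side), "unknown", side),
      relation = relation,
      size_mm = size_mm,
      described_pathologic = any(nodes$pathologic),
      avid = NA,
      region = region,
      source_sentence = si,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0L) {
    data.frame(station = integer(0), side = character(0),
               relation = character(0), size_mm = numeric(0),
               described_pathologic = logical(0), avid = logical(0),
               region = character(0), source_sentence = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  class(out) <- c("tn_nodes", class(out))
  out
}

#' Set FDG avidity on tumor and node findings
#'
#' On a PET-CT report each finding's `avid` field is read from avidity
#' mentions in the finding's own sentence: an affirmed positive cue
#' ("FDG-avid", "increased uptake") sets `TRUE`; an explicit negative cue
#' ("without FDG uptake", "non-avid") or a negated positive cue sets `FALSE`;
#' no avidity mention leaves `NA` (unstated). On a pure CT report avidity is
#' always unstated, whatever stray PET vocabulary occurs.
#'
#' @param mentions Mentions with final assertions.
#' @param tumor A `tn_tumor`.
#' @param nodes A `tn_nodes` data.frame.
#' @param modality `"CT"` or `"PETCT"`.
#' @param tumor_sentences Sentence indices holding affirmed tumor mentions
#'   (used to locate the tumor's avidity statement).
#' @return `list(tumor = ..., nodes = ...)` with `avid` fields set.
#' @export
match_avidity <- function(mentions, tumor, nodes, modality,
                          tumor_sentences = integer(0)) {
  if (!identical(modality, "PETCT")) {
    tumor$avid <- NA
    if (nrow(nodes) > 0L) nodes$avid <- NA
    return(list(tumor = tumor, nodes = nodes))
  }
  sentence_avidity <- function(si) {
    sm <- mentions[mentions$sentence_index == si, , drop = FALSE]
    neg <- any(sm$category == "avidity_neg") ||
      any(sm$category == "avidity_pos" & sm$assertion == "negated")
    pos <- any(sm$category == "avidity_pos" & sm$assertion == "affirmed")
    if (neg) FALSE else if (pos) TRUE else NA
  }
  if (nrow(nodes) > 0L) {
    nodes$avid <- vapply(nodes$source_sentence, sentence_avidity, logical(1))
  }
  if (isTRUE(tumor$present) && length(tumor_sentences) > 0L) {
    av <- vapply(tumor_sentences, sentence_avidity, logical(1))
    tumor$avid <- if (any(!av, na.rm = TRUE)) FALSE
                  else if (any(av, na.rm = TRUE)) TRUE else NA
  }
  list(tumor = tumor, nodes = nodes)
}

#' @export
print.tn_tumor <- function(x, ...) {
  cat("<tn_tumor> present:", x$present,
      " size_mm:", x$size_mm, " side:", x$side, "\n")
  if (length(x$invasion_features)) {
    cat("  invasion:", paste(x$invasion_features, collapse = ", "), "\n")
  }
  if (x$satellite_same_lobe) cat("  satellite nodule same lobe\n")
  if (x$separate_nodule_other_lobe) cat("  separate nodule other lobe\n")
  invisible(x)
}

#' Serialize findings to JSON (for `--trace` output)
#'
#' @param tumor A `tn_tumor`.
#' @param nodes A `tn_nodes`.
#' @return A JSON string.
#' @export
findings_to_json <- function(tumor, nodes) {
  jsonlite::toJSON(list(tumor = unclass(tumor),
                        nodes = as.data.frame(unclass(nodes))),
                   auto_unbox = TRUE, dataframe = "rows", na = "null")
}
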