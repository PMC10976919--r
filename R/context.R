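#' Find lexicon concept mentions in sentences
#'
#' Matches every non-structural concept category (tumor, lymph node, station,
#' invasion target, satellite/multilobe cues, avidity, laterality, lobe,
#' blacklist anatomy) against each sentence, case-insensitively and
#' leftmost-longest; overlapping matches of the same category resolve to the
#' longer match. Station mentions written as `station 4R` have their number
#' and side parsed from the matched text. Every mention starts `affirmed`;
#' [assign_modifiers()] revises that.
#'
#' @param sentences Sentence table from [split_sentences()] (or a one-row
#'   subset).
#' @param lexicon A `tn_lexicon`.
#' @return A data.frame of mentions: `sentence_index`, `concept_id`,
#'   `category`, `start`, `end` (0-based half-open, report-global), `text`,
#'   `assertion`, plus inherited attribute columns `station_number`, `side`,
#'   `relation`, `t_feature_class`, `lobe`, `pathologic`, `nodal_exclude`,
#'   `region`.
#' @export
find_mentions <- function(sentences, lexicon = load_lexicon()) {
  concepts <- lex_concepts(lexicon, c(
    "tumor", "lymph_node", "station", "invasion_target", "satellite_nodule",
    "multilobe_cue", "avidity_pos", "avidity_neg", "laterality", "lobe",
    "blacklist_anatomy"
  ))
  cand <- list()
  for (co in concepts) {
    m <- locate_many(sentences$text, co$patterns)
    if (nrow(m) == 0L) next
    at <- co$attributes
    soff <- sentences$start[m$item]
    txt <- substring(sentences$text[m$item], m$start + 1L, m$end)
    df <- data.frame(
      sentence_index = sentences$index[m$item], concept_id = co$id,
      category = co$category,
      start = soff + m$start, end = soff + m$end, text = txt,
      assertion = "affirmed",
      station_number = as.integer(at$station_number %||% NA_integer_),
      side = as.character(at$side %||% NA_character_),
      relation = as.character(at$relation %||% NA_character_),
      t_feature_class = as.character(at$t_feature_class %||% NA_character_),
      lobe = as.character(at$lobe %||% NA_character_),
      pathologic = isTRUE(at$pathologic),
      nodal_exclude = isTRUE(at$nodal_exclude),
      region = as.character(at$region %||% NA_character_),
      stringsAsFactors = FALSE
    )
    if (isTRUE(at$parse)) {
      num <- stringi::stri_match_first_regex(df$text, "(1[0-4]|[1-9])")[, 2L]
      df$station_number <- as.integer(num)
      tail_side <- stringi::stri_match_first_regex(df$text, "([RL])\\s*$",
        opts_regex = re_opts())[, 2L]
      df$side <- ifelse(is.na(tail_side), NA_character_,
                        ifelse(toupper(tail_side) == "R", "right", "left"))
    }
    cand[[length(cand) + 1L]] <- df
  }
  if (length(cand) == 0L) {
    return(empty_mentions())
  }
  all_m <- do.call(rbind, cand)
  pieces <- lapply(split(all_m, all_m$sentence_index),
                   resolve_category_overlaps)
  out <- do.call(rbind, pieces)
  out <- out[order(out$sentence_index, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_mentions <- function() {
  data.frame(
    sentence_index = integer(0), concept_id = character(0),
    category = character(0), start = integer(0), end = integer(0),
    text = character(0), assertion = character(0),
    station_number = integer(0), side = character(0), relation = character(0),
    t_feature_class = character(0), lobe = character(0),
    pathologic = logical(0), nodal_exclude = logical(0), region = character(0),
    stringsAsFactors = FALSE
  )
}

# within each category keep the longer (then leftmost) of overlapping matches
resolve_category_overlaps <- function(m) {
  keep <- logical(nrow(m))
  for (cat in unique(m$category)) {
    idx <- which(m$category == cat)
    idx <- idx[order(-(m$end[idx] - m$start[idx]), m$start[idx])]
    taken <- matrix(numeric(0), ncol = 2)
    for (j in idx) {
      s <- m$start[j]; e <- m$end[j]
      if (nrow(taken) == 0L || !any(taken[, 1] < e & s < taken[, 2])) {
        keep[j] <- TRUE
        taken <- rbind(taken, c(s, e))
      }
    }
  }
  m[keep, , drop = FALSE]
}

#' Assign assertion status to mentions (ConText-style)
#'
#' Implements trigger-scope semantics within a sentence: each non-pseudo
#' negation or uncertainty trigger opens a scope running from the trigger to
#' the sentence boundary in its direction, truncated at the first termination
#' trigger (e.g. "but", "however") or the next non-pseudo trigger. Mentions
#' inside a negation scope become `negated`; mentions inside an uncertainty
#' scope that are not negated become `uncertain` (negation takes precedence).
#' Pseudo triggers ("cannot be excluded") are matched first and suppress any
#' overlapping substring trigger. Scopes never cross sentence boundaries.
#'
#' @param sentences Sentence table (supplies text and offsets).
#' @param mentions Mentions from [find_mentions()].
#' @param lexicon A `tn_lexicon`.
#' @return `mentions` with the `assertion` column finalized.
#' @export
assign_modifiers <- function(sentences, mentions, lexicon = load_lexicon()) {
  if (nrow(mentions) == 0L) return(mentions)
  all_trig <- locate_modifiers(sentences, lexicon)
  for (i in seq_len(nrow(sentences))) {
    sidx <- sentences$index[i]
    sel <- which(mentions$sentence_index == sidx)
    if (length(sel) == 0L) next
    soff <- sentences$start[i]
    slen <- nchar(sentences$text[i])

    trig <- all_trig[all_trig$item == i, , drop = FALSE]
    if (nrow(trig) == 0L) next
    pseudo <- trig[trig$class == "pseudo", , drop = FALSE]
    act <- trig[trig$class != "pseudo", , drop = FALSE]
    if (nrow(pseudo) > 0L && nrow(act) > 0L) {
      covered <- vapply(seq_len(nrow(act)), function(k) {
        any(pseudo$start < act$end[k] & act$start[k] < pseudo$end)
      }, logical(1))
      act <- act[!covered, , drop = FALSE]
    }
    if (nrow(act) == 0L) next
    term <- act[act$class == "termination", , drop = FALSE]
    scoped <- act[act$class %in% c("negation", "uncertainty"), , drop = FALSE]
    if (nrow(scoped) == 0L) next

    ms <- mentions$start[sel] - soff
    me <- mentions$end[sel] - soff
    negated <- logical(length(sel))
    uncertain <- logical(length(sel))
    for (k in seq_len(nrow(scoped))) {
      dir <- scoped$direction[k]
      dirs <- if (dir == "bidirectional") c("forward", "backward") else dir
      for (d in dirs) {
        if (d == "forward") {
          lo <- scoped$end[k]
          stops <- c(term$start[term$start >= lo],
                     act$start[act$start >= lo & act$start != scoped$start[k]])
          hi <- if (length(stops) > 0L) min(stops) else slen
        } else {
          hi <- scoped$start[k]
          stops <- c(term$end[term$end <= hi],
                     act$end[act$end <= hi & act$start != scoped$start[k]])
          lo <- if (length(stops) > 0L) max(stops) else 0L
        }
        if (hi <= lo) next
        inside <- ms < hi & me > lo
        if (scoped$class[k] == "negation") negated <- negated | inside
        else uncertain <- uncertain | inside
      }
    }
    mentions$assertion[sel][uncertain] <- "uncertain"
    mentions$assertion[sel][negated] <- "negated"   # precedence: negation wins
  }
  mentions
}

# locate all modifier trigger matches in all sentences (local 0-based spans;
# `item` is the row number in `sentences`)
locate_modifiers <- function(sentences, lexicon) {
  rows <- list()
  for (mo in lexicon$modifiers) {
    m <- locate_many(sentences$text, mo$patterns)
    if (nrow(m) == 0L) next
    m$class <- mo$modifier_class
    m$direction <- mo$direction
    rows[[length(rows) + 1L]] <- m
  }
  if (length(rows) == 0L) {
    return(data.frame(item = integer(0), start = integer(0),
                      end = integer(0), class = character(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Sentence-split, measure and annotate a sectioned report
#'
#' Convenience wrapper running [split_sentences()], [extract_measurements()]
#' per sentence, [apply_blacklist()], [find_mentions()] and
#' [assign_modifiers()] in one call.
#'
#' @param sectioned A `tn_sectioned` report.
#' @param lexicon A `tn_lexicon`.
#' @return A list with `sentences`, `measurements`, `mentions`.
#' @export
annotate_report <- function(sectioned, lexicon = load_lexicon()) {
  sentences <- split_sentences(sectioned, lexicon)
  measurements <- measure_sentences(sentences)
  measurements <- apply_blacklist(measurements, sentences, lexicon)
  mentions <- find_mentions(sentences, lexicon)
  mentions <- assign_modifiers(sentences, mentions, lexicon)
  list(sentences = sentences, measurements = measurements, mentions = mentions)
}
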