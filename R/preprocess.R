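#' Normalize report text without changing its length
#'
#' Applies only 1:1 character substitutions so that every downstream span
#' stays valid against the original text: unicode spaces become ASCII spaces,
#' unicode dashes become `-`, and a decimal comma between two digits becomes a
#' decimal point (`"3,2 cm"` -> `"3.2 cm"`). Idempotent.
#'
#' @param text A character vector.
#' @return The normalized text, same lengths.
#' @export
clean_text <- function(text) {
  out <- stringi::stri_replace_all_regex(text, "[\\u00a0\\u2000-\\u200a\\u202f\\u205f]", " ")
  out <- stringi::stri_replace_all_regex(out, "[\\u2010-\\u2015\\u2212]", "-")
  out <- gsub("(?<=[0-9]),(?=[0-9])", ".", out, perl = TRUE)
  out
}

#' Split a sectioned report into sentences
#'
#' Rule-based splitting on sentence-final punctuation and line breaks, with
#' protection of decimal numbers (`"3.2 cm"`), single-letter initials and the
#' lexicon's abbreviation list (`"St. 4R"` stays one sentence). Deterministic;
#' sentence spans are 0-based half-open intervals into the raw report text.
#'
#' @param sectioned A `tn_sectioned` report.
#' @param lexicon A `tn_lexicon` (supplies the protected-abbreviation list).
#' @return A data.frame with columns `index`, `section_label`, `start`,
#'   `end`, `text` (cleaned text of the sentence).
#' @export
split_sentences <- function(sectioned, lexicon = load_lexicon()) {
  text <- clean_text(sectioned$text)
  abbrevs <- lexicon$abbreviations
  rows <- list()
  idx <- 0L
  sec <- sectioned$sections
  for (i in seq_len(nrow(sec))) {
    body_start <- sec$body_start[i]
    body_end <- sec$end[i]
    if (body_end <= body_start) next
    seg <- substring(text, body_start + 1L, body_end)
    for (sp in split_segment(seg, abbrevs)) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        index = idx,
        section_label = sec$label[i],
        start = body_start + sp[1L],
        end = body_start + sp[2L],
        text = substring(seg, sp[1L] + 1L, sp[2L]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (idx == 0L) {
    return(data.frame(index = integer(0), section_label = character(0),
                      start = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Split one text segment; returns list of local 0-based half-open spans.
split_segment <- function(seg, abbrevs) {
  n <- nchar(seg)
  m <- stringi::stri_locate_all_regex(seg, "[.!?]|\\n+")[[1]]
  breaks <- integer(0)
  if (!(nrow(m) == 0L || is.na(m[1L, 1L]))) {
    for (k in seq_len(nrow(m))) {
      s <- m[k, 1L]; e <- m[k, 2L]
      ch <- substring(seg, s, s)
      if (ch == ".") {
        before <- if (s > 1L) substring(seg, s - 1L, s - 1L) else ""
        after <- if (e < n) substring(seg, e + 1L, e + 1L) else ""
        if (grepl("[0-9]", before) && grepl("[0-9]", after)) next
        tok <- stringi::stri_extract_last_regex(substring(seg, 1L, s - 1L),
                                                "[A-Za-z]+$")
        if (!is.na(tok)) {
          if (tolower(tok) %in% abbrevs) next
          # a lone letter is an initial ("J. Smith") unless it trails a
          # digit, as in the laterality suffix of "station 5L."
          pre <- s - nchar(tok) - 1L
          pre_ch <- if (pre >= 1L) substring(seg, pre, pre) else ""
          if (nchar(tok) == 1L && !grepl("[0-9]", pre_ch)) next
        }
      }
      breaks <- c(breaks, e)  # sentence ends after the punctuation run
    }
  }
  bounds <- unique(c(0L, breaks, n))
  spans <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    s <- bounds[k]; e <- bounds[k + 1L]
    piece <- substring(seg, s + 1L, e)
    lead <- nchar(piece) - nchar(sub("^\\s+", "", piece))
    trail <- nchar(piece) - nchar(sub("\\s+$", "", piece))
    s2 <- s + lead; e2 <- e - trail
    if (e2 > s2) spans[[length(spans) + 1L]] <- c(s2, e2)
  }
  spans
}

meas_pattern_range <- "([0-9]+(?:\\.[0-9]+)?)\\s*(?:-|to )\\s*([0-9]+(?:\\.[0-9]+)?)\\s*(mm|cm)\\b"
meas_pattern_multi <- "([0-9]+(?:\\.[0-9]+)?)\\s*x\\s*([0-9]+(?:\\.[0-9]+)?)(?:\\s*x\\s*([0-9]+(?:\\.[0-9]+)?))?\\s*(mm|cm)\\b"
meas_pattern_single <- "([0-9]+(?:\\.[0-9]+)?)\\s*(mm|cm)\\b"

#' Extract size measurements from a sentence
#'
#' Recognizes single lengths (`"12 mm"`, `"3.2 cm"`), two- and
#' three-dimensional forms (`"32 x 21 mm"`) and ranges (`"1-2 cm"`, which
#' take the upper bound). Centimeters are converted to millimeters; numbers
#' without a length unit are ignored. The internal unit is integer-friendly
#' millimeters because TNM thresholds are centimeter multiples.
#'
#' @param text Cleaned sentence text (a single string).
#' @param sentence_index Index recorded on the output rows.
#' @param offset Global 0-based offset of the sentence start (so output spans
#'   refer to the report, not the sentence).
#' @return A data.frame with one row per measurement: `sentence_index`,
#'   `start`, `end`, `text`, `d1`, `d2`, `d3` (mm, NA when absent),
#'   `long_mm`, `short_mm`, `blacklisted`, `blacklist_tie`, `attached`.
#' @export
extract_measurements <- function(text, sentence_index = 1L, offset = 0L) {
  empty <- data.frame(
    sentence_index = integer(0), start = integer(0), end = integer(0),
    text = character(0), d1 = numeric(0), d2 = numeric(0), d3 = numeric(0),
    long_mm = numeric(0), short_mm = numeric(0), blacklisted = logical(0),
    blacklist_tie = logical(0), attached = character(0),
    stringsAsFactors = FALSE
  )
  harvest <- function(pattern, dims_from) {
    loc <- stringi::stri_locate_all_regex(text, pattern, opts_regex = re_opts())[[1]]
    if (nrow(loc) == 0L || is.na(loc[1L, 1L])) return(NULL)
    grp <- stringi::stri_match_all_regex(text, pattern, opts_regex = re_opts())[[1]]
    out <- vector("list", nrow(loc))
    for (k in seq_len(nrow(loc))) {
      g <- grp[k, ]
      unit <- tolower(g[length(g)])
      dims <- suppressWarnings(as.numeric(g[dims_from]))
      dims <- dims[!is.na(dims)]
      if (unit == "cm") dims <- dims * 10
      dims <- dims[dims > 0 & dims < 1000]
      if (length(dims) == 0L) next
      out[[k]] <- data.frame(
        sentence_index = sentence_index,
        start = offset + loc[k, 1L] - 1L, end = offset + loc[k, 2L],
        text = substring(text, loc[k, 1L], loc[k, 2L]),
        d1 = dims[1L], d2 = if (length(dims) >= 2L) dims[2L] else NA_real_,
        d3 = if (length(dims) >= 3L) dims[3L] else NA_real_,
        long_mm = max(dims), short_mm = min(dims),
        blacklisted = FALSE, blacklist_tie = FALSE,
        attached = NA_character_, stringsAsFactors = FALSE
      )
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) NULL else do.call(rbind, out)
  }
  # priority: range > multi-dimension > single; later matches may not overlap
  # an earlier (more specific) one
  found <- empty
  for (spec in list(list(meas_pattern_range, 3L),     # upper bound of range
                    list(meas_pattern_multi, 2:4),
                    list(meas_pattern_single, 2L))) {
    cand <- harvest(spec[[1]], spec[[2]])
    if (is.null(cand)) next
    if (nrow(found) > 0L) {
      ok <- vapply(seq_len(nrow(cand)), function(k) {
        !any(found$start < cand$end[k] & cand$start[k] < found$end)
      }, logical(1))
      cand <- cand[ok, , drop = FALSE]
    }
    found <- rbind(found, cand)
  }
  found <- found[order(found$start), , drop = FALSE]
  rownames(found) <- NULL
  found
}

# Run extract_measurements over every sentence of a report.
measure_sentences <- function(sentences) {
  if (nrow(sentences) == 0L) return(extract_measurements(""))
  out <- lapply(seq_len(nrow(sentences)), function(i) {
    extract_measurements(sentences$text[i], sentences$index[i],
                         sentences$start[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag measurements belonging to blacklisted anatomy
#'
#' A measurement is blacklisted when a blacklist-anatomy concept (adrenal
#' gland, kidney, cyst, fluid collection, ...) occurs in the same sentence
#' and no tumor or lymph-node concept sits nearer (in characters) to the
#' measurement. An exact distance tie keeps the measurement but marks
#' `blacklist_tie` so the staging trace can surface it: a missed tumor size
#' is the costlier error.
#'
#' @param measurements Output of [extract_measurements()] (any number of
#'   sentences).
#' @param sentences The sentence table from [split_sentences()].
#' @param lexicon A `tn_lexicon`.
#' @return `measurements` with `blacklisted` and `blacklist_tie` filled in.
#' @export
apply_blacklist <- function(measurements, sentences, lexicon = load_lexicon()) {
  if (nrow(measurements) == 0L) return(measurements)
  bl_concepts <- lex_concepts(lexicon, "blacklist_anatomy")
  keep_concepts <- lex_concepts(lexicon, c("tumor", "lymph_node"))
  bl_pats <- unlist(lapply(bl_concepts, function(co) co$patterns))
  keep_pats <- unlist(lapply(keep_concepts, function(co) co$patterns))
  for (si in unique(measurements$sentence_index)) {
    row <- sentences[sentences$index == si, , drop = FALSE]
    if (nrow(row) == 0L) next
    bl <- locate_patterns(row$text, bl_pats)
    if (nrow(bl) == 0L) next
    kp <- locate_patterns(row$text, keep_pats)
    sel <- which(measurements$sentence_index == si)
    for (j in sel) {
      ms <- measurements$start[j] - row$start
      me <- measurements$end[j] - row$start
      d_bl <- min(span_gap(ms, me, bl$start, bl$end))
      d_kp <- if (nrow(kp) == 0L) Inf else min(span_gap(ms, me, kp$start, kp$end))
      if (d_bl < d_kp) {
        measurements$blacklisted[j] <- TRUE
      } else if (is.finite(d_kp) && d_bl == d_kp) {
        measurements$blacklist_tie[j] <- TRUE
      }
    }
  }
  measurements
}

# character gap between span (s,e) and spans (ss,ee); 0 when overlapping
span_gap <- function(s, e, ss, ee) {
  pmax(0L, pmax(ss - e, s - ee))
}
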