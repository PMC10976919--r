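#' Read a report corpus
#'
#' Reads free-text radiology reports from either a directory of UTF-8 `.txt`
#' files (one report per file, `report_id` taken from the file name) or a
#' JSON-lines file with fields `report_id`, `text` and optional `modality`,
#' `gold_t`, `gold_n`.
#'
#' @param path Directory (for `format = "txt_dir"`) or JSONL file.
#' @param format `"txt_dir"` or `"jsonl"`.
#' @return A list of class `tn_corpus`; each element is a list with
#'   `report_id`, `text`, `modality_hint` (`"CT"`, `"PETCT"` or `NA`) and,
#'   when supplied, `gold_t`/`gold_n`.
#' @export
read_corpus <- function(path, format = c("jsonl", "txt_dir")) {
  format <- match.arg(format)
  if (format == "txt_dir") {
    if (!dir.exists(path)) stop("directory not found: ", path, call. = FALSE)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) stop("no .txt files in ", path, call. = FALSE)
    reports <- lapply(files, function(f) {
      new_report(report_id = sub("\\.txt$", "", basename(f)),
                 text = paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                              collapse = "\n"))
    })
  } else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    reports <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) NULL)
      if (is.null(rec) || !is.list(rec)) {
        stop("malformed JSON on line ", i, call. = FALSE)
      }
      if (is.null(rec$report_id) || is.null(rec$text)) {
        stop("line ", i, ": required keys report_id/text missing",
             call. = FALSE)
      }
      reports[[i]] <- new_report(
        report_id     = as.character(rec$report_id),
        text          = as.character(rec$text),
        modality_hint = rec$modality,
        gold_t        = rec$gold_t,
        gold_n        = rec$gold_n
      )
    }
  }
  ids <- vapply(reports, function(r) r$report_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate report_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  structure(reports, class = "tn_corpus")
}

new_report <- function(report_id, text, modality_hint = NULL,
                       gold_t = NULL, gold_n = NULL) {
  if (!nzchar(trimws(report_id))) stop("empty report_id", call. = FALSE)
  if (!nzchar(trimws(text))) {
    stop("report '", report_id, "' has empty text", call. = FALSE)
  }
  hint <- if (is.null(modality_hint) || is.na(modality_hint)) NA_character_
          else match.arg(toupper(modality_hint), c("CT", "PETCT"))
  r <- list(report_id = report_id, text = text, modality_hint = hint)
  if (!is.null(gold_t) && !is.na(gold_t)) r$gold_t <- as.character(gold_t)
  if (!is.null(gold_n) && !is.na(gold_n)) r$gold_n <- as.character(gold_n)
  class(r) <- "tn_report"
  r
}

#' Write a corpus to JSON-lines
#'
#' @param corpus A `tn_corpus` (list of reports).
#' @param path Output JSONL file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(r) {
    rec <- list(report_id = r$report_id, text = r$text)
    if (!is.na(r$modality_hint %||% NA)) rec$modality <- r$modality_hint
    if (!is.null(r$gold_t)) rec$gold_t <- r$gold_t
    if (!is.null(r$gold_n)) rec$gold_n <- r$gold_n
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Split a report into labeled sections
#'
#' Section headings are recognized by the lexicon's `section_header` patterns,
#' case-insensitively, anchored at line starts; the colon after a heading is
#' optional when the heading stands alone on its line. Each heading opens a
#' section running to the next heading or the end of the text. Text before
#' the first heading — or the whole report when no heading matches — becomes
#' a single `unsectioned` section, so a report without recognizable
#' subheadings is a valid degenerate case, not an error.
#'
#' @param report A `tn_report` (or any list with `report_id`, `text`).
#' @param lexicon A `tn_lexicon`.
#' @return An object of class `tn_sectioned`: list with `report_id`, `text`,
#'   `modality` and a data.frame `sections` with columns `label`,
#'   `heading_text`, `start`, `end`, `body_start` (0-based half-open spans
#'   into the raw text; `body_start` skips the heading itself).
#' @export
sectionize <- function(report, lexicon = load_lexicon()) {
  text <- report$text
  headers <- lex_concepts(lexicon, "section_header")
  hits <- list()
  for (co in headers) {
    anchored <- paste0("(?m)^[ \\t]*(?:", paste(co$patterns, collapse = "|"),
                       ")[ \\t]*(?::|$)")
    m <- locate_patterns(text, anchored)
    if (nrow(m) > 0L) {
      m$label <- co$attributes$section %||% "unsectioned"
      hits[[length(hits) + 1L]] <- m
    }
  }
  if (length(hits) > 0L) {
    h <- do.call(rbind, hits)
    # a heading position can only open one section: keep the longest match
    h <- h[order(h$start, -(h$end - h$start)), , drop = FALSE]
    h <- h[!duplicated(h$start), , drop = FALSE]
  } else {
    h <- data.frame(start = integer(0), end = integer(0),
                    text = character(0), label = character(0),
                    stringsAsFactors = FALSE)
  }

  n <- nrow(h)
  if (n == 0L) {
    sections <- data.frame(
      label = "unsectioned", heading_text = "",
      start = 0L, end = nchar(text), body_start = 0L,
      stringsAsFactors = FALSE
    )
  } else {
    starts <- h$start
    ends <- c(h$start[-1L], nchar(text))
    sections <- data.frame(
      label = h$label, heading_text = trimws(h$text),
      start = starts, end = ends, body_start = h$end,
      stringsAsFactors = FALSE
    )
    if (starts[1L] > 0L) {
      pre <- data.frame(label = "unsectioned", heading_text = "",
                        start = 0L, end = starts[1L], body_start = 0L,
                        stringsAsFactors = FALSE)
      sections <- rbind(pre, sections)
    }
  }
  rownames(sections) <- NULL
  out <- list(report_id = report$report_id, text = text,
              modality_hint = report$modality_hint %||% NA_character_,
              sections = sections)
  class(out) <- "tn_sectioned"
  out$modality <- detect_modality(out, lexicon)
  out
}

#' Detect report modality (CT vs PET-CT)
#'
#' A report is classified PETCT when a PET cue (FDG, tracer, whole-body, ...)
#' matches inside the modality-description section, or when the report has two
#' or more non-chest body-part sections (a PET-CT is a whole-body
#' examination). An explicit `modality_hint` on the report overrides the cues;
#' otherwise the default is CT.
#'
#' @param sectioned A `tn_sectioned` report.
#' @param lexicon A `tn_lexicon`.
#' @return `"CT"` or `"PETCT"`.
#' @export
detect_modality <- function(sectioned, lexicon = load_lexicon()) {
  hint <- sectioned$modality_hint %||% NA_character_
  if (!is.na(hint)) return(hint)
  cues <- lex_concepts(lexicon, "modality_cue")
  pet_patterns <- unlist(lapply(cues, function(co) {
    if (identical(co$attributes$modality %||% "PETCT", "PETCT")) co$patterns
  }))
  sec <- sectioned$sections
  mod_rows <- which(sec$label == "modality_description")
  for (i in mod_rows) {
    seg <- substring(sectioned$text, sec$body_start[i] + 1L, sec$end[i])
    if (any_pattern(seg, pet_patterns)) return("PETCT")
  }
  body <- sec$label[startsWith(sec$label, "body_part:")]
  if (sum(body != "body_part:chest") >= 2L) return("PETCT")
  "CT"
}

#' @export
print.tn_sectioned <- function(x, ...) {
  cat("<tn_sectioned>", x$report_id, "modality:", x$modality, "\n")
  print(x$sections[, c("label", "start", "end")])
  invisible(x)
}

#' Serialize a sectioned report to JSON
#'
#' @param sectioned A `tn_sectioned` report.
#' @return A JSON string with report id, modality and section spans.
#' @export
sectioned_to_json <- function(sectioned) {
  jsonlite::toJSON(
    list(report_id = sectioned$report_id, modality = sectioned$modality,
         sections = sectioned$sections),
    auto_unbox = TRUE, dataframe = "rows"
  )
}
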