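#' Load a staging lexicon
#'
#' Reads the YAML vocabulary that drives every matching step of the pipeline:
#' concept patterns (tumor, lymph node, nodal stations, laterality, lobes,
#' invasion targets, FDG avidity cues, the anatomical measurement blacklist,
#' section headers, modality cues) and ConText-style modifier triggers
#' (negation, uncertainty, pseudo, termination).
#'
#' @param path Path to a lexicon YAML file. When `NULL` (default) the
#'   built-in English lexicon shipped with the package is loaded.
#' @return A validated object of class `tn_lexicon`: a list with elements
#'   `version`, `abbreviations`, `concepts` and `modifiers`.
#' @examples
#' lex <- load_lexicon()
#' lex$version
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lexicon_en.yaml", package = "lungtnm")
  }
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  lex <- structure(
    list(
      version       = as.character(raw$version %||% "unversioned"),
      abbreviations = tolower(as.character(unlist(raw$abbreviations))),
      concepts      = lapply(raw$concepts, normalize_concept),
      modifiers     = lapply(raw$modifiers, normalize_modifier)
    ),
    class = "tn_lexicon"
  )
  viol <- validate_lexicon(lex)
  bad <- viol$severity == "error"
  if (any(bad)) {
    stop("invalid lexicon:\n  ",
         paste(viol$message[bad], collapse = "\n  "), call. = FALSE)
  }
  lex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_concept <- function(x) {
  list(
    id         = as.character(x$id %||% NA_character_),
    category   = as.character(x$category %||% NA_character_),
    patterns   = as.character(unlist(x$patterns)),
    attributes = x$attributes %||% list()
  )
}

normalize_modifier <- function(x) {
  list(
    id             = as.character(x$id %||% NA_character_),
    modifier_class = as.character(x$modifier_class %||% NA_character_),
    direction      = as.character(x$direction %||% "forward"),
    patterns       = as.character(unlist(x$patterns))
  )
}

concept_categories <- c(
  "tumor", "lymph_node", "station", "invasion_target", "satellite_nodule",
  "multilobe_cue", "avidity_pos", "avidity_neg", "laterality", "lobe",
  "blacklist_anatomy", "section_header", "modality_cue"
)
modifier_classes <- c("negation", "uncertainty", "pseudo", "termination")

regex_compiles <- function(pattern) {
  ok <- TRUE
  tryCatch(
    stringi::stri_detect_regex("probe", pattern,
                               opts_regex = stringi::stri_opts_regex(case_insensitive = TRUE)),
    error = function(e) ok <<- FALSE
  )
  ok
}

#' Validate a lexicon
#'
#' Checks concept-id uniqueness, regex compilability, required categories
#' (at least one tumor, lymph node, negation and uncertainty entry), attribute
#' ranges (station numbers 1-14, invasion T feature classes) and nodal-station
#' coverage of stations 1-14. Violations are returned as data, not raised.
#'
#' @param lexicon A `tn_lexicon` or a structurally similar list.
#' @return A data.frame with columns `severity` (`"error"` or `"warning"`),
#'   `entry` and `message`; zero rows means the lexicon is fully valid.
#' @examples
#' nrow(validate_lexicon(load_lexicon())) == 0
#' @export
validate_lexicon <- function(lexicon) {
  out <- list()
  note <- function(severity, entry, message) {
    out[[length(out) + 1L]] <<- data.frame(
      severity = severity, entry = entry, message = message,
      stringsAsFactors = FALSE
    )
  }

  ids <- vapply(lexicon$concepts, function(x) x$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) note("error", d, paste0("duplicate concept_id '", d, "'"))

  for (co in lexicon$concepts) {
    if (is.na(co$category) || !co$category %in% concept_categories) {
      note("error", co$id, paste0("concept '", co$id, "' has unknown category '",
                                  co$category, "'"))
    }
    if (length(co$patterns) == 0L) {
      note("error", co$id, paste0("concept '", co$id, "' has no patterns"))
    }
    for (p in co$patterns) {
      if (!regex_compiles(p)) {
        note("error", co$id, paste0("concept '", co$id,
                                    "' pattern does not compile: ", p))
      }
    }
    sn <- co$attributes$station_number
    if (!is.null(sn) && (!is.numeric(sn) || sn < 1 || sn > 14)) {
      note("error", co$id, paste0("concept '", co$id, "' station_number ", sn,
                                  " outside 1..14"))
    }
    tf <- co$attributes$t_feature_class
    if (!is.null(tf) && !tf %in% c("T2", "T3", "T4")) {
      note("error", co$id, paste0("concept '", co$id, "' t_feature_class '", tf,
                                  "' not in T2/T3/T4"))
    }
    if (identical(co$category, "invasion_target") && is.null(tf)) {
      note("error", co$id, paste0("invasion_target '", co$id,
                                  "' lacks a t_feature_class"))
    }
  }

  for (mo in lexicon$modifiers) {
    if (is.na(mo$modifier_class) || !mo$modifier_class %in% modifier_classes) {
      note("error", mo$id, paste0("modifier '", mo$id, "' has unknown class '",
                                  mo$modifier_class, "'"))
    }
    if (!mo$direction %in% c("forward", "backward", "bidirectional")) {
      note("error", mo$id, paste0("modifier '", mo$id, "' has unknown direction '",
                                  mo$direction, "'"))
    }
    for (p in mo$patterns) {
      if (!regex_compiles(p)) {
        note("error", mo$id, paste0("modifier '", mo$id,
                                    "' pattern does not compile: ", p))
      }
    }
  }

  cats <- vapply(lexicon$concepts, function(x) x$category, character(1))
  if (!any(cats == "tumor"))      note("error", NA, "no tumor concept defined")
  if (!any(cats == "lymph_node")) note("error", NA, "no lymph_node concept defined")
  mcls <- vapply(lexicon$modifiers, function(x) x$modifier_class, character(1))
  if (!any(mcls == "negation"))    note("error", NA, "no negation modifier defined")
  if (!any(mcls == "uncertainty")) note("error", NA, "no uncertainty modifier defined")

  # station coverage 1..14 (via fixed attributes or a parsed numbered pattern)
  fixed <- unlist(lapply(lexicon$concepts, function(x) {
    if (identical(x$category, "station")) x$attributes$station_number else NULL
  }))
  has_parser <- any(vapply(lexicon$concepts, function(x) {
    identical(x$category, "station") && isTRUE(x$attributes$parse)
  }, logical(1)))
  if (!has_parser) {
    for (s in setdiff(1:14, fixed)) {
      note("warning", NA, paste0("station ", s, " unmapped"))
    }
  }

  if (length(out) == 0L) {
    return(data.frame(severity = character(0), entry = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a lexicon back to YAML
#'
#' Round-trips with [load_lexicon()]: `load_lexicon(save_lexicon(lex, f))`
#' reproduces `lex`.
#'
#' @param lexicon A `tn_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_lexicon <- function(lexicon, path) {
  strip_na_id <- function(x) {
    x <- x[!vapply(x, function(v) length(v) == 1L && is.na(v), logical(1))]
    x[vapply(x, length, integer(1)) > 0L | names(x) == "attributes"]
  }
  raw <- list(
    version       = lexicon$version,
    abbreviations = as.list(lexicon$abbreviations),
    concepts      = lapply(lexicon$concepts, strip_na_id),
    modifiers     = lapply(lexicon$modifiers, strip_na_id)
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.tn_lexicon <- function(x, ...) {
  cats <- table(vapply(x$concepts, function(co) co$category, character(1)))
  cat("<tn_lexicon> version", x$version, "\n")
  cat(" ", length(x$concepts), "concepts:",
      paste(names(cats), as.integer(cats), sep = "=", collapse = ", "), "\n")
  cat(" ", length(x$modifiers), "modifier entries\n")
  invisible(x)
}

# internal: all concepts of one or more categories
lex_concepts <- function(lexicon, categories) {
  Filter(function(co) co$category %in% categories, lexicon$concepts)
}
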