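# Synthetic labeled CT / PET-CT report generator.  The generator decides the
# structured findings first, verifies with the staging rules that they map to
# the requested gold (T, N), and only then renders text — so gold labels are
# guaranteed by construction and the pipeline can be tested by round-trip.

adversarial_knobs <- c("negation", "uncertainty", "blacklist_trap",
                       "missing_subheadings", "multidim_size",
                       "implicit_satellite", "avidity_conflict")

#' Build a generator specification
#'
#' Defaults state the emulated world: the stage distribution follows the
#' shape of the training cohort the method was developed on (heavier T4,
#' sparse T1/N1 cells), about 60% of reports are PET-CT, and the adversarial
#' rates default to 0.2 for negation, uncertainty and blacklist traps and 0.1
#' for missing subheadings (multi-dimension sizes, implicit satellite/other
#' lobe nodules and PET/CT avidity conflicts at 0.2 each).
#'
#' @param n_reports Number of reports to generate.
#' @param petct_frac Fraction of PET-CT reports (binomial, seeded).
#' @param stage_distribution Data.frame with columns `t`, `n`, `weight`;
#'   non-negative weights, not all zero.
#' @param adversarial_rates Named numeric vector of probabilities over
#'   `r paste(adversarial_knobs, collapse = ", ")`.
#' @param seed Integer RNG seed; every source of randomness flows from it.
#' @return A list of class `tn_genspec`.
#' @export
generator_spec <- function(n_reports = 100L, petct_frac = 0.6,
                           stage_distribution = default_stage_distribution(),
                           adversarial_rates = default_adversarial_rates(),
                           seed = 1L) {
  rates <- default_adversarial_rates()
  rates[names(adversarial_rates)] <- adversarial_rates
  if (any(rates < 0 | rates > 1)) stop("adversarial rates must be in [0,1]")
  if (any(stage_distribution$weight < 0) ||
      all(stage_distribution$weight == 0)) {
    stop("stage_distribution weights must be non-negative, not all zero")
  }
  structure(list(
    n_reports = as.integer(n_reports), petct_frac = petct_frac,
    stage_distribution = stage_distribution,
    adversarial_rates = rates, seed = as.integer(seed)
  ), class = "tn_genspec")
}

#' @rdname generator_spec
#' @export
default_adversarial_rates <- function() {
  c(negation = 0.2, uncertainty = 0.2, blacklist_trap = 0.2,
    missing_subheadings = 0.1, multidim_size = 0.2,
    implicit_satellite = 0.2, avidity_conflict = 0.2)
}

#' @rdname generator_spec
#' @export
default_stage_distribution <- function() {
  # training-cohort shape of the emulated setting (n = 63)
  cells <- list(
    c("T1a", "N0", 1), c("T1b", "N0", 4), c("T1b", "N2", 1),
    c("T1c", "N0", 3), c("T1c", "N1", 1), c("T1c", "N2", 1), c("T1c", "N3", 1),
    c("T2", "N3", 2),
    c("T2a", "N0", 4), c("T2a", "N2", 3), c("T2a", "N3", 3),
    c("T2b", "N0", 2), c("T2b", "N2", 1), c("T2b", "N3", 2),
    c("T3", "N0", 5), c("T3", "N1", 1), c("T3", "N2", 4), c("T3", "N3", 3),
    c("T4", "N0", 11), c("T4", "N1", 2), c("T4", "N2", 4), c("T4", "N3", 4)
  )
  data.frame(
    t = vapply(cells, `[`, character(1), 1L),
    n = vapply(cells, `[`, character(1), 2L),
    weight = as.numeric(vapply(cells, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

t_size_range <- function(t) {
  switch(t,
    T1a = c(6L, 10L), T1b = c(11L, 20L), T1c = c(21L, 30L),
    T2a = c(31L, 40L), T2b = c(41L, 50L), T3 = c(51L, 70L),
    T4 = c(71L, 95L),
    stop("no size range for ", t, call. = FALSE)
  )
}

rint <- function(lo, hi) if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
pick <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

lobe_phrases <- list(
  right = c("right upper lobe", "right middle lobe", "right lower lobe"),
  left  = c("left upper lobe", "left lower lobe")
)

#' Generate one labeled synthetic report
#'
#' Renders a report whose findings stage exactly to `(t, n)` under the
#' default rules. Adversarial flags inject distractors that must *not*
#' change the gold label: a negated contralateral node sentence, uncertainty
#' phrasing on an incidental node, a blacklisted adrenal measurement, missing
#' subheadings, multi-dimensional sizes, implicit satellite / other-lobe
#' nodule mentions for T3/T4, and an enlarged-but-non-avid conflicting node
#' on PET-CT. The generator self-checks by staging its internal finding
#' specification before rendering.
#'
#' @param t Gold T label (`T1a` ... `T4`; `T0` is not generated).
#' @param n Gold N label.
#' @param modality `"CT"` or `"PETCT"`.
#' @param flags Character vector of adversarial knobs to switch on.
#' @param report_id Report identifier.
#' @param seed Optional integer; when given, seeds the RNG locally so the
#'   same call is byte-identical.
#' @param rules Staging rules used for the self-check.
#' @return A `tn_report` with `gold_t`, `gold_n`.
#' @export
generate_report <- function(t, n, modality = c("CT", "PETCT"),
                            flags = character(0), report_id = "SYN-0001",
                            seed = NULL, rules = load_rules()) {
  modality <- match.arg(modality)
  if (!t %in% t_labels[-1L]) stop("gold T must be one of ",
                                  paste(t_labels[-1L], collapse = ", "))
  if (!n %in% n_labels) stop("gold N must be one of ",
                             paste(n_labels, collapse = ", "))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  flags <- intersect(flags, adversarial_knobs)
  petct <- modality == "PETCT"

  tumor_side <- pick(c("right", "left"))
  side_letter <- toupper(substr(tumor_side, 1L, 1L))
  contra_side <- if (tumor_side == "right") "left" else "right"
  contra_letter <- toupper(substr(contra_side, 1L, 1L))
  lobe <- pick(lobe_phrases[[tumor_side]])

  # ---- tumor finding spec + sentences --------------------------------------
  tumor_spec <- list(present = TRUE, size_mm = NA_real_, side = tumor_side,
                     invasion_features = character(0),
                     satellite_same_lobe = FALSE,
                     separate_nodule_other_lobe = FALSE)
  chest <- character(0)
  size_phrase <- function(size) {
    if ("multidim_size" %in% flags) {
      short <- max(5L, round(size * 0.6))
      paste0(size, " x ", short, " mm")
    } else {
      paste0(size, " mm")
    }
  }
  if (t == "T2") {
    # generic T2: feature without size
    tumor_spec$invasion_features <- "T2"
    chest <- c(chest, paste0("There is a central mass in the ", lobe,
                             " with invasion of the main bronchus."))
  } else if (t == "T3" && "implicit_satellite" %in% flags) {
    size <- rint(21L, 30L)
    tumor_spec$size_mm <- size
    tumor_spec$satellite_same_lobe <- TRUE
    chest <- c(chest,
               paste0("There is a spiculated mass in the ", lobe,
                      " measuring ", size_phrase(size), "."),
               "A satellite nodule is present in the same lobe.")
  } else if (t == "T4" && "implicit_satellite" %in% flags) {
    size <- rint(21L, 40L)
    tumor_spec$size_mm <- size
    tumor_spec$separate_nodule_other_lobe <- TRUE
    chest <- c(chest,
               paste0("There is a spiculated mass in the ", lobe,
                      " measuring ", size_phrase(size), "."),
               "There is a separate tumour nodule in another lobe of the same lung.")
  } else {
    rng <- t_size_range(t)
    size <- rint(rng[1L], rng[2L])
    tumor_spec$size_mm <- size
    chest <- c(chest, paste0("There is a spiculated mass in the ", lobe,
                             " measuring ", size_phrase(size), "."))
  }
  got_t <- map_t(tumor_spec, rules)
  if (!identical(got_t, t)) {
    stop("generator self-check failed: tumor spec stages to ", got_t,
         " not ", t, call. = FALSE)
  }

  # ---- node finding specs + sentences --------------------------------------
  node_spec <- list()
  add_node <- function(station, side, relation, size, pathologic_word, avid) {
    node_spec[[length(node_spec) + 1L]] <<- data.frame(
      station = station, side = side, relation = relation, size_mm = size,
      described_pathologic = pathologic_word, avid = avid,
      region = NA_character_, source_sentence = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  node_sentence <- function(station, letter, target_side) {
    size <- rint(11L, 25L)
    if (petct && stats::runif(1) < 0.5) {
      # PET-specific upgrade: small, non-enlarged but avid node
      size <- rint(5L, 9L)
      add_node(station, target_side, NA_character_, size, FALSE, TRUE)
      paste0("A ", size, " mm FDG-avid lymph node is seen at station ",
             station, letter, ".")
    } else {
      add_node(station, target_side, NA_character_, size, TRUE,
               if (petct) TRUE else NA)
      paste0("There is an enlarged lymph node at station ", station, letter,
             ", measuring ", size, " mm",
             if (petct) " with increased FDG uptake" else "", ".")
    }
  }
  impression_node <- ""
  if (n == "N0") {
    chest <- c(chest, "No pathologically enlarged mediastinal or hilar lymph nodes.")
    impression_node <- " No thoracic lymphadenopathy."
  } else if (n == "N1") {
    st <- pick(c(10L, 11L, 12L))
    chest <- c(chest, node_sentence(st, side_letter, tumor_side))
    impression_node <- " Ipsilateral hilar lymphadenopathy."
  } else if (n == "N2") {
    st <- pick(c(2L, 4L, 5L, 7L, 8L))
    chest <- c(chest, node_sentence(st, side_letter, tumor_side))
    if (stats::runif(1) < 0.4) {   # realistic N1 companion; max() keeps N2
      chest <- c(chest, node_sentence(pick(c(10L, 11L)), side_letter,
                                      tumor_side))
    }
    impression_node <- " Ipsilateral mediastinal lymphadenopathy."
  } else {
    if (stats::runif(1) < 0.5) {
      size <- rint(11L, 22L)
      add_node(1L, "unknown", NA_character_, size, TRUE,
               if (petct) TRUE else NA)
      chest <- c(chest, paste0(
        "There is an enlarged supraclavicular lymph node measuring ", size,
        " mm", if (petct) " with intense FDG uptake" else "", "."))
      impression_node <- " Supraclavicular lymphadenopathy."
    } else {
      st <- pick(c(2L, 4L, 10L))
      chest <- c(chest, node_sentence(st, contra_letter, contra_side))
      impression_node <- " Contralateral mediastinal lymphadenopathy."
    }
  }

  # ---- adversarial distractors (gold-neutral) ------------------------------
  if ("avidity_conflict" %in% flags && petct) {
    size <- rint(12L, 18L)
    add_node(4L, contra_side, NA_character_, size, TRUE, FALSE)
    chest <- c(chest, paste0(
      "There is an enlarged lymph node at station 4", contra_letter,
      ", measuring ", size, " mm, without FDG uptake."))
  }
  if ("negation" %in% flags) {
    chest <- c(chest, "No enlarged lymph nodes at the contralateral hilum.")
  }
  if ("uncertainty" %in% flags) {
    chest <- c(chest, "Suspicion of subcarinal lymphadenopathy.")
  }
  trap <- NULL
  if ("blacklist_trap" %in% flags) {
    trap_size <- max(40L, round((tumor_spec$size_mm %||% 30) + 13))
    if (is.na(trap_size)) trap_size <- 45L
    trap <- paste0("The right adrenal gland is enlarged, measuring ",
                   trap_size, " mm.")
  }

  # ---- self-check N --------------------------------------------------------
  nodes_df <- if (length(node_spec) == 0L) {
    data.frame(station = integer(0), side = character(0),
               relation = character(0), size_mm = numeric(0),
               described_pathologic = logical(0), avid = logical(0),
               region = character(0), source_sentence = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, node_spec)
  }
  if (!petct && nrow(nodes_df) > 0L) nodes_df$avid <- NA
  got_n <- map_n(nodes_df, tumor_side, modality, rules)
  if (!identical(got_n, n)) {
    stop("generator self-check failed: node spec stages to ", got_n,
         " not ", n, call. = FALSE)
  }

  # ---- render --------------------------------------------------------------
  technique <- if (petct) {
    "Whole-body 18F-FDG PET-CT from the skull base to the mid-thighs."
  } else {
    "Contrast-enhanced CT of the chest."
  }
  abdomen <- if (petct) {
    paste0("The liver and spleen are unremarkable.",
           if (!is.null(trap)) paste0(" ", trap) else
             " Both adrenal glands are normal.")
  } else {
    NULL
  }
  if (!petct && !is.null(trap)) chest <- c(chest, trap)
  impression <- paste0(
    "Primary lung carcinoma in the ", lobe, ".", impression_node)

  if ("missing_subheadings" %in% flags) {
    text <- paste(c("Staging of known pulmonary malignancy.",
                    technique, chest,
                    if (!is.null(abdomen)) abdomen,
                    if (petct) "No suspicious osseous lesions.",
                    impression),
                  collapse = "\n")
  } else {
    text <- paste(c(
      "Clinical details: Staging of known pulmonary malignancy.",
      paste0("Technique: ", technique),
      paste0("Chest: ", paste(chest, collapse = " ")),
      if (!is.null(abdomen)) paste0("Abdomen: ", abdomen),
      if (petct) "Skeleton: No suspicious osseous lesions.",
      paste0("Impression: ", impression)
    ), collapse = "\n")
  }

  new_report(report_id = report_id, text = text, gold_t = t, gold_n = n)
}

#' Generate a labeled synthetic corpus
#'
#' Samples `(T, N)` cells from the spec's stage distribution, modality from
#' the PET-CT fraction and adversarial flags from their rates, all under the
#' spec's seed, then calls [generate_report()] per report. Deterministic:
#' the same spec yields a byte-identical corpus.
#'
#' @param spec A `tn_genspec` from [generator_spec()].
#' @param rules Staging rules for the generator self-check.
#' @return A `tn_corpus` of labeled reports (JSONL-serializable with
#'   [write_corpus()]).
#' @export
generate_corpus <- function(spec, rules = load_rules()) {
  stopifnot(inherits(spec, "tn_genspec"))
  set.seed(spec$seed)
  dist <- spec$stage_distribution
  cells <- sample.int(nrow(dist), spec$n_reports, replace = TRUE,
                      prob = dist$weight)
  reports <- vector("list", spec$n_reports)
  for (i in seq_len(spec$n_reports)) {
    modality <- if (stats::runif(1) < spec$petct_frac) "PETCT" else "CT"
    rates <- spec$adversarial_rates
    flags <- names(rates)[stats::runif(length(rates)) < rates]
    reports[[i]] <- generate_report(
      t = dist$t[cells[i]], n = dist$n[cells[i]], modality = modality,
      flags = flags, report_id = sprintf("SYN-%04d", i), rules = rules
    )
  }
  structure(reports, class = "tn_corpus")
}
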