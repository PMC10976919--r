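# Shared regex matching helpers.  All spans in this package are 0-based
# half-open character intervals into the original report text.

re_opts <- function() stringi::stri_opts_regex(case_insensitive = TRUE)

# Locate all case-insensitive matches of a set of patterns in one string.
# Returns a data.frame(start, end, text) with 0-based half-open spans,
# overlaps across patterns resolved to the longer (then leftmost) match.
locate_patterns <- function(text, patterns) {
  hits <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    m <- stringi::stri_locate_all_regex(text, patterns[[i]],
                                        opts_regex = re_opts())[[1]]
    if (nrow(m) == 0L || is.na(m[1L, 1L])) next
    hits[[i]] <- data.frame(start = m[, 1L] - 1L, end = m[, 2L],
                            stringsAsFactors = FALSE)
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  df <- df[order(-(df$end - df$start), df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    overlaps <- nrow(taken) > 0L && any(taken[, 1] < e & s < taken[, 2])
    if (!overlaps) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(s, e))
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  df$text <- substring(text, df$start + 1L, df$end)
  rownames(df) <- NULL
  df
}

# Vectorized variant: locate all matches of `patterns` in each element of
# `texts`.  Returns data.frame(item, start, end) with 0-based half-open local
# spans; overlaps within one item resolved to the longer (then leftmost)
# match.  Used on the hot path (every concept against every sentence).
locate_many <- function(texts, patterns) {
  n <- length(texts)
  items <- integer(0); starts <- integer(0); ends <- integer(0)
  for (p in patterns) {
    loc <- stringi::stri_locate_all_regex(texts, p, opts_regex = re_opts(),
                                          omit_no_match = TRUE)
    cnt <- vapply(loc, nrow, integer(1))
    if (sum(cnt) == 0L) next
    m <- do.call(rbind, loc)
    items <- c(items, rep.int(seq_len(n), cnt))
    starts <- c(starts, m[, 1L] - 1L)
    ends <- c(ends, m[, 2L])
  }
  if (length(items) == 0L) {
    return(data.frame(item = integer(0), start = integer(0),
                      end = integer(0)))
  }
  df <- data.frame(item = items, start = starts, end = ends)
  df <- df[order(df$item, -(df$end - df$start), df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  for (it in unique(df$item)) {
    idx <- which(df$item == it)
    taken_s <- numeric(0); taken_e <- numeric(0)
    for (j in idx) {
      s <- df$start[j]; e <- df$end[j]
      if (!any(taken_s < e & s < taken_e)) {
        keep[j] <- TRUE
        taken_s <- c(taken_s, s); taken_e <- c(taken_e, e)
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$item, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# TRUE if any pattern matches anywhere in text.
any_pattern <- function(text, patterns) {
  for (p in patterns) {
    if (isTRUE(stringi::stri_detect_regex(text, p, opts_regex = re_opts()))) {
      return(TRUE)
    }
  }
  FALSE
}
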