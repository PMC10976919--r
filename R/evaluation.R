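#' Score predictions against gold labels
#'
#' Computes separate T-stage, N-stage and combined TN accuracies (TN correct
#' iff both axes are correct), support-weighted one-vs-rest precision, recall
#' and F1 over the joint TN labels, and confusion matrices for T, N and TN.
#' Weights are gold supports, so weighted recall equals TN accuracy; labels
#' that occur only in predictions get zero weight.
#'
#' @param predictions List of `tn_result` (from [stage_report()] /
#'   [stage_corpus()]), or a data.frame with `report_id`, `t`, `n`.
#' @param gold A labeled `tn_corpus` (reports carrying `gold_t`, `gold_n`),
#'   or a data.frame with `report_id`, `gold_t`, `gold_n`.
#' @return An object of class `tn_metrics`.
#' @export
evaluate <- function(predictions, gold) {
  pred <- as_label_frame(predictions, c("t", "n"))
  gd <- as_label_frame(gold, c("gold_t", "gold_n"))
  missing_p <- setdiff(gd$report_id, pred$report_id)
  missing_g <- setdiff(pred$report_id, gd$report_id)
  if (length(missing_p) || length(missing_g)) {
    stop("report_id mismatch; missing from predictions: ",
         paste(missing_p, collapse = ", "), "; missing from gold: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  df <- merge(pred, gd, by = "report_id", sort = TRUE)
  nrep <- nrow(df)

  acc_t <- mean(df$t == df$gold_t)
  acc_n <- mean(df$n == df$gold_n)
  acc_tn <- mean(df$t == df$gold_t & df$n == df$gold_n)

  joint_pred <- paste0(df$t, df$n)
  joint_gold <- paste0(df$gold_t, df$gold_n)
  w <- weighted_prf(joint_pred, joint_gold)

  conf <- function(pred, gold, levels) {
    table(gold = factor(gold, levels = levels),
          predicted = factor(pred, levels = levels))
  }
  joint_levels <- sort(unique(c(joint_pred, joint_gold)))

  structure(list(
    n_reports = nrep,
    accuracy_t = acc_t, accuracy_n = acc_n, accuracy_tn = acc_tn,
    weighted_precision = w$precision, weighted_recall = w$recall,
    weighted_f1 = w$f1,
    confusion_t = conf(df$t, df$gold_t, t_labels),
    confusion_n = conf(df$n, df$gold_n, n_labels),
    confusion_tn = conf(joint_pred, joint_gold, joint_levels),
    per_report = df
  ), class = "tn_metrics")
}

# support-weighted one-vs-rest P/R/F1 over the labels observed in gold
weighted_prf <- function(pred, gold) {
  classes <- unique(gold)
  n <- length(gold)
  p <- r <- f <- s <- numeric(length(classes))
  for (i in seq_along(classes)) {
    c <- classes[i]
    tp <- sum(pred == c & gold == c)
    np <- sum(pred == c)
    ng <- sum(gold == c)
    p[i] <- if (np > 0) tp / np else 0
    r[i] <- tp / ng
    f[i] <- if (p[i] + r[i] > 0) 2 * p[i] * r[i] / (p[i] + r[i]) else 0
    s[i] <- ng / n
  }
  list(precision = sum(s * p), recall = sum(s * r), f1 = sum(s * f))
}

as_label_frame <- function(x, cols) {
  if (is.data.frame(x)) {
    stopifnot(all(c("report_id", cols) %in% names(x)))
    return(x[, c("report_id", cols)])
  }
  rows <- lapply(x, function(r) {
    vals <- lapply(cols, function(cl) {
      v <- r[[cl]] %||% r[[sub("^gold_", "", cl)]]
      if (is.null(v)) stop("missing label field '", cl, "' for report ",
                           r$report_id, call. = FALSE)
      v
    })
    names(vals) <- cols
    data.frame(report_id = r$report_id, vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.tn_metrics <- function(x, ...) {
  cat("TN staging accuracy (n =", x$n_reports, ")\n")
  cat(sprintf("  Accuracy T stage   %.2f\n", x$accuracy_t))
  cat(sprintf("  Accuracy N stage   %.2f\n", x$accuracy_n))
  cat(sprintf("  Accuracy TN stage  %.2f\n", x$accuracy_tn))
  cat(sprintf("  Weighted precision %.2f  recall %.2f  F1 %.2f\n",
              x$weighted_precision, x$weighted_recall, x$weighted_f1))
  invisible(x)
}

#' Serialize metrics to JSON
#'
#' @param metrics A `tn_metrics`.
#' @return JSON string (confusion matrices as row lists).
#' @export
metrics_to_json <- function(metrics) {
  jsonlite::toJSON(list(
    n_reports = metrics$n_reports,
    accuracy_t = metrics$accuracy_t, accuracy_n = metrics$accuracy_n,
    accuracy_tn = metrics$accuracy_tn,
    weighted_precision = metrics$weighted_precision,
    weighted_recall = metrics$weighted_recall,
    weighted_f1 = metrics$weighted_f1,
    confusion_t = as.data.frame.matrix(unclass(metrics$confusion_t)),
    confusion_n = as.data.frame.matrix(unclass(metrics$confusion_n)),
    confusion_tn = as.data.frame.matrix(unclass(metrics$confusion_tn))
  ), auto_unbox = TRUE, dataframe = "rows")
}

#' Write a confusion matrix to CSV
#'
#' @param confusion One of the confusion tables from [evaluate()].
#' @param path Output CSV (rows = gold, columns = predicted).
#' @return `path`, invisibly.
#' @export
confusion_to_csv <- function(confusion, path) {
  utils::write.csv(as.data.frame.matrix(unclass(confusion)), path)
  invisible(path)
}

#' Categorized error report
#'
#' One record per report whose prediction misses the gold label on T, N or
#' both, auto-tagged by inspecting the staging trace: an unsectioned
#' fallback suggests a sectionizer error, a blacklist distance tie or a
#' missing tumor size a measurement/reporter problem, uncertainty exclusions
#' and PET-over-CT overrulings a context problem, station-less nodes a
#' concept problem. Auto-categorization is best-effort; `unclassified` is an
#' honest bucket.
#'
#' @param predictions List of `tn_result` (traces are read from these).
#' @param gold Labeled gold corpus.
#' @return A data.frame with columns `report_id`, `axis` (`T`, `N`,
#'   `both`), `predicted`, `gold`, `auto_category`, `trace_excerpt`; zero
#'   rows when everything is correct.
#' @export
error_report <- function(predictions, gold) {
  metrics <- evaluate(predictions, gold)
  df <- metrics$per_report
  traces <- stats::setNames(lapply(predictions, function(r) r$trace %||%
                                     character(0)),
                            vapply(predictions, function(r) r$report_id,
                                   character(1)))
  bad <- df[df$t != df$gold_t | df$n != df$gold_n, , drop = FALSE]
  if (nrow(bad) == 0L) {
    return(data.frame(report_id = character(0), axis = character(0),
                      predicted = character(0), gold = character(0),
                      auto_category = character(0),
                      trace_excerpt = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(bad)), function(i) {
    b <- bad[i, ]
    axis <- if (b$t != b$gold_t && b$n != b$gold_n) "both"
            else if (b$t != b$gold_t) "T" else "N"
    tr <- traces[[b$report_id]] %||% character(0)
    cat_ <- categorize_trace(tr)
    data.frame(
      report_id = b$report_id, axis = axis,
      predicted = paste0(b$t, b$n), gold = paste0(b$gold_t, b$gold_n),
      auto_category = cat_$category,
      trace_excerpt = cat_$excerpt,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

categorize_trace <- function(tr) {
  pickline <- function(pat) {
    hit <- grep(pat, tr, value = TRUE)
    if (length(hit) > 0L) hit[1L] else ""
  }
  if (any(grepl("no subheadings matched", tr))) {
    return(list(category = "sectionizer",
                excerpt = pickline("no subheadings matched")))
  }
  if (any(grepl("\\[overruling\\]", tr)) ||
      any(grepl("only with uncertainty", tr))) {
    return(list(category = "context",
                excerpt = pickline("\\[overruling\\]|only with uncertainty")))
  }
  if (any(grepl("blacklist distance tie", tr))) {
    return(list(category = "measurement",
                excerpt = pickline("blacklist distance tie")))
  }
  if (any(grepl("no size linked to tumor|no certain tumor", tr))) {
    return(list(category = "reporter_input",
                excerpt = pickline("no size linked to tumor|no certain tumor")))
  }
  if (any(grepl("without station", tr))) {
    return(list(category = "concept", excerpt = pickline("without station")))
  }
  list(category = "unclassified",
       excerpt = if (length(tr) > 0L) tr[length(tr)] else "")
}
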