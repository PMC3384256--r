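# Score rows and reports.  A row holds the raw counts for one category
# (gold count, answer count, and the number of gold/answer items matched)
# together with recall, precision and F-score derived from them.

#' Harmonic mean of recall and precision
#'
#' @param recall,precision percentages in `[0, 100]`.
#' @param decimals decimal places of the reported value (2 for the usual
#'   event tables, 1 for compact coreference tables); ties round away
#'   from zero.
#' @return F-score percentage.
#' @examples
#' compute_fscore(22.2, 73.3, decimals = 1)    # 34.1
#' compute_fscore(48.62, 58.96)                # 53.29
#' @export
compute_fscore <- function(recall, precision, decimals = 2) {
  f <- ifelse(recall + precision == 0, 0,
              2 * recall * precision / (recall + precision))
  round_half_up(f, decimals)
}

score_row <- function(category, gold, answer, recall_matched,
                      precision_matched, decimals = 2) {
  stopifnot(recall_matched >= 0, recall_matched <= gold,
            precision_matched >= 0, precision_matched <= answer)
  recall <- if (gold > 0) 100 * recall_matched / gold else 0
  precision <- if (answer > 0) 100 * precision_matched / answer else 0
  data.frame(category = category, gold = gold, answer = answer,
             recall_matched = recall_matched,
             precision_matched = precision_matched,
             recall = round_half_up(recall, decimals),
             precision = round_half_up(precision, decimals),
             fscore = compute_fscore(recall, precision, decimals),
             stringsAsFactors = FALSE)
}

new_score_report <- function(rows, mode = NULL, decimals = 2, level = NULL) {
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  # distinguishes per-type rows from aggregate (group) rows whose labels
  # may coincide with a type name, e.g. Regulation
  rep$level <- if (is.null(level)) "group" else level
  rep <- rep[, c("category", "level", setdiff(names(rep),
                                              c("category", "level")))]
  attr(rep, "mode") <- mode
  attr(rep, "decimals") <- decimals
  class(rep) <- c("score_report", "data.frame")
  rep
}

#' @export
print.score_report <- function(x, ...) {
  mode <- attr(x, "mode")
  if (!is.null(mode)) cat("# ", mode, "\n", sep = "")
  d <- attr(x, "decimals") %||% 2
  df <- data.frame(
    category = x$category, level = x$level, gold = x$gold, answer = x$answer,
    `R/P/F` = paste(fmt_num(x$recall, d), fmt_num(x$precision, d),
                    fmt_num(x$fscore, d), sep = "/"),
    check.names = FALSE, stringsAsFactors = FALSE)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Format a score report as TSV lines
#'
#' One line per category with the raw counts and the combined
#' `RR.RR/PP.PP/FF.FF` triple.
#'
#' @param report a `score_report`.
#' @param decimals decimal places for the triple; defaults to the
#'   report's own setting.
#' @return character vector of tab-separated lines (with header).
#' @export
format_report <- function(report, decimals = NULL) {
  d <- decimals %||% attr(report, "decimals") %||% 2
  c(paste("category", "level", "gold", "answer", "recall_matched",
          "precision_matched", "R/P/F", sep = "\t"),
    paste(report$category, report$level, report$gold, report$answer,
          report$recall_matched, report$precision_matched,
          paste(fmt_num(report$recall, d), fmt_num(report$precision, d),
                fmt_num(report$fscore, d), sep = "/"),
          sep = "\t"))
}

#' Write a score report to a file
#'
#' @param report a `score_report`.
#' @param path output file path, or `""` for standard output.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    writeLines(format_report(report), if (nzchar(path)) path else stdout())
  } else {
    out <- as.data.frame(report)
    txt <- jsonlite::toJSON(out, dataframe = "rows", digits = NA,
                            pretty = TRUE)
    if (nzchar(path)) writeLines(txt, path) else writeLines(txt)
  }
  invisible(path)
}
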