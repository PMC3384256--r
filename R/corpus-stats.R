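# Descriptive statistics over a standoff corpus: annotation counts,
# densities (proteins per word, events per word, events per protein) and
# the average coordination ratio (events per distinct trigger -- a
# trigger shared by several events signals coordinated mentions).

#' Percentage ratio with fixed rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero.  The
#' word counts underlying published density figures depend on the
#' original tokenizer, so this helper also serves to recompute densities
#' from externally supplied counts.
#'
#' @param numerator,denominator non-negative counts.
#' @param decimals decimal places.
#' @return percentage, or `NA` when the denominator is zero.
#' @examples
#' ratio_percent(14969, 267229)   # 5.60
#' ratio_percent(13603, 14969)    # 90.87
#' @export
ratio_percent <- function(numerator, denominator, decimals = 2) {
  if (denominator == 0) return(NA_real_)
  round_half_up(100 * numerator / denominator, decimals)
}

#' Average coordination ratio
#'
#' Events per distinct event trigger; a ratio above 1 means triggers are
#' shared by several (coordinated) events.
#'
#' @param events event count.
#' @param triggers count of distinct trigger text-bounds referenced by at
#'   least one event.
#' @return ratio rounded to 2 decimals; `NA` when both counts are zero.
#' @examples
#' coordination_ratio(13603, 11057)   # 1.23
#' @export
coordination_ratio <- function(events, triggers) {
  if (triggers == 0) {
    if (events > 0) {
      stop("events present but no triggers counted: integrity violation",
           call. = FALSE)
    }
    return(NA_real_)
  }
  round_half_up(events / triggers, 2)
}

count_words <- function(text) {
  if (is.null(text) || !nzchar(text)) return(0L)
  length(regmatches(text, gregexpr("[^[:space:]]+", text))[[1]])
}

#' Profile a standoff corpus
#'
#' Computes counts (words, proteins, distinct event triggers, events per
#' type, coreference relations), the densities P/W, E/W and E/P as
#' percentages, and the average coordination ratio E/T.  Words are
#' whitespace-delimited tokens of the raw text.
#'
#' @param corpus a `standoff_document` or a named list of them.
#' @param section optional section label; only documents carrying that
#'   label are profiled.
#' @return an object of class `corpus_profile`.
#' @export
profile_corpus <- function(corpus, section = NULL) {
  corpus <- as_corpus(corpus)
  if (!is.null(section)) {
    labels <- vapply(corpus, function(d) d$section_label, character(1))
    corpus <- corpus[!is.na(labels) & labels == section]
  }
  words <- sum(vapply(corpus, function(d) count_words(d$text), integer(1)))
  proteins <- sum(vapply(corpus, function(d) {
    sum(vapply(d$text_bounds, function(tb) tb$type == "Protein", logical(1)))
  }, numeric(1)))
  triggers <- sum(vapply(corpus, function(d) {
    length(unique(vapply(d$events, `[[`, character(1), "trigger")))
  }, numeric(1)))
  per_type <- stats::setNames(rep(0, length(EVENT_TYPES)), EVENT_TYPES)
  for (d in corpus) {
    for (e in d$events) {
      if (e$type %in% EVENT_TYPES) {
        per_type[e$type] <- per_type[e$type] + 1
      }
    }
  }
  events <- sum(vapply(corpus, function(d) length(d$events), numeric(1)))
  corefs <- sum(vapply(corpus, function(d) length(d$coref_relations),
                       numeric(1)))
  structure(
    list(section = section %||% "All",
         words = words, proteins = proteins, triggers = triggers,
         events = events, events_by_type = per_type, coreferences = corefs,
         density_p_w = ratio_percent(proteins, words),
         density_e_w = ratio_percent(events, words),
         density_e_p = ratio_percent(events, proteins),
         coordination_e_t = coordination_ratio(events, triggers)),
    class = "corpus_profile")
}

#' @export
print.corpus_profile <- function(x, ...) {
  cat("<corpus_profile> section: ", x$section, "\n", sep = "")
  cat("  words ", x$words, "  proteins ", x$proteins,
      "  triggers ", x$triggers, "  events ", x$events,
      "  coreferences ", x$coreferences, "\n", sep = "")
  cat("  density P/W ", fmt_num(x$density_p_w, 2), "%",
      "  E/W ", fmt_num(x$density_e_w, 2), "%",
      "  E/P ", fmt_num(x$density_e_p, 2), "%",
      "  coord E/T ", fmt_num(x$coordination_e_t, 2), "\n", sep = "")
  invisible(x)
}

#' Serialize a corpus profile
#'
#' @param profile a `corpus_profile`.
#' @param path output path, or `""` for standard output.
#' @param format `"tsv"` or `"json"`.
#' @return the path, invisibly.
#' @export
write_profile <- function(profile, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    txt <- jsonlite::toJSON(unclass(profile), auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
    if (nzchar(path)) writeLines(txt, path) else writeLines(txt)
  } else {
    flat <- c(section = profile$section, words = profile$words,
              proteins = profile$proteins, triggers = profile$triggers,
              events = profile$events, profile$events_by_type,
              coreferences = profile$coreferences,
              `density_P/W` = profile$density_p_w,
              `density_E/W` = profile$density_e_w,
              `density_E/P` = profile$density_e_p,
              `coordination_E/T` = profile$coordination_e_t)
    lines <- paste(names(flat), unname(flat), sep = "\t")
    writeLines(lines, if (nzchar(path)) path else stdout())
  }
  invisible(path)
}
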