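# Scoring of predicted event annotation against gold annotation.
#
# Matched counting is existence-based and computed independently for the
# two directions: a gold item is recall-matched when at least one
# predicted item matches it, and a predicted item is precision-matched
# when at least one gold item matches it.  Group rows (Simple Event,
# Binding, Regulation, All) aggregate raw counts over their member types
# (micro-average), so every row satisfies the same recall/precision/F
# formulas as the per-type rows.

check_same_documents <- function(gold, pred) {
  missing_pred <- setdiff(names(gold), names(pred))
  missing_gold <- setdiff(names(pred), names(gold))
  if (length(missing_pred) > 0 || length(missing_gold) > 0) {
    stop("gold and predicted corpora cover different documents",
         if (length(missing_pred) > 0)
           paste0("; missing from predictions: ",
                  paste(missing_pred, collapse = ", ")),
         if (length(missing_gold) > 0)
           paste0("; missing from gold: ",
                  paste(missing_gold, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

strip_secondary <- function(doc) {
  doc$events <- lapply(doc$events, function(e) {
    e$args <- e$args[!e$args$role %in% SECONDARY_ROLES, , drop = FALSE]
    rownames(e$args) <- NULL
    e
  })
  doc
}

mode_label <- function(config, extra = NULL) {
  paste0(c(extra,
           paste0("span=", config$span_mode),
           paste0("recursive=", config$recursive_mode),
           if (config$decomposition) "decomposition",
           config$task_level),
         collapse = ", ")
}

# Existence-based matched flags for one document pair.  Returns per-unit
# logical vectors for the gold and predicted scoring populations.
match_event_units <- function(gold_doc, pred_doc, config) {
  if (config$task_level == "task1") {
    gold_doc <- strip_secondary(gold_doc)
    pred_doc <- strip_secondary(pred_doc)
  }
  if (config$decomposition) {
    g <- decomposed_view(gold_doc)
    p <- decomposed_view(pred_doc)
    gold_doc <- g$doc
    pred_doc <- p$doc
    gold_ids <- g$unit_ids
    pred_ids <- p$unit_ids
  } else {
    gold_ids <- names(gold_doc$events)
    pred_ids <- names(pred_doc$events)
  }
  m <- event_matcher(gold_doc, pred_doc, config)
  gtype <- vapply(gold_doc$events[gold_ids], `[[`, character(1), "type")
  ptype <- vapply(pred_doc$events[pred_ids], `[[`, character(1), "type")
  gold_matched <- rep(FALSE, length(gold_ids))
  pred_matched <- rep(FALSE, length(pred_ids))
  for (i in seq_along(gold_ids)) {
    cand <- which(ptype == gtype[i])
    for (j in cand) {
      if (m$event(pred_ids[j], gold_ids[i])) {
        gold_matched[i] <- TRUE
        pred_matched[j] <- TRUE
      }
    }
  }
  list(gold_type = unname(gtype), pred_type = unname(ptype),
       gold_matched = gold_matched, pred_matched = pred_matched)
}

#' Score predicted events against gold events
#'
#' Computes recall, precision and F-score per event type, per group
#' (Simple Event, Binding, Regulation, All), under the evaluation mode in
#' `config`.  See [match_config()] for the mode switches; the default is
#' approximate span plus approximate recursive matching at task level 1.
#'
#' @param gold,pred gold and predicted corpora (a `standoff_document` or
#'   a named list of them); they must cover the same document ids.
#' @param config a [match_config()].
#' @param decimals decimal places for reported percentages.
#' @param by_section if `TRUE` and documents carry section labels, a list
#'   of reports is returned: one per section plus `"All"`.
#' @return a `score_report` (or a named list of them with `by_section`).
#' @export
score_events <- function(gold, pred, config = match_config(), decimals = 2,
                         by_section = FALSE) {
  gold <- as_corpus(gold)
  pred <- as_corpus(pred)
  check_same_documents(gold, pred)
  if (by_section) {
    labels <- vapply(gold, function(d) d$section_label, character(1))
    out <- list(All = score_events(gold, pred, config, decimals))
    for (lab in unique(labels[!is.na(labels)])) {
      sel <- names(gold)[!is.na(labels) & labels == lab]
      out[[lab]] <- score_events(gold[sel], pred[sel], config, decimals)
    }
    return(out)
  }
  tallies <- lapply(names(gold), function(id) {
    match_event_units(gold[[id]], pred[[id]], config)
  })
  count_for <- function(types) {
    gold_n <- sum(vapply(tallies, function(t) sum(t$gold_type %in% types), numeric(1)))
    ans_n <- sum(vapply(tallies, function(t) sum(t$pred_type %in% types), numeric(1)))
    rm_n <- sum(vapply(tallies, function(t)
      sum(t$gold_matched[t$gold_type %in% types]), numeric(1)))
    pm_n <- sum(vapply(tallies, function(t)
      sum(t$pred_matched[t$pred_type %in% types]), numeric(1)))
    c(gold_n, ans_n, rm_n, pm_n)
  }
  rows <- lapply(EVENT_TYPES, function(tp) {
    k <- count_for(tp)
    score_row(tp, k[1], k[2], k[3], k[4], decimals)
  })
  rows <- c(rows, lapply(names(EVENT_GROUPS), function(gname) {
    k <- count_for(EVENT_GROUPS[[gname]])
    score_row(gname, k[1], k[2], k[3], k[4], decimals)
  }))
  new_score_report(rows, mode = mode_label(config, "event scoring"),
                   decimals = decimals,
                   level = rep(c("type", "group"),
                               c(length(EVENT_TYPES), length(EVENT_GROUPS))))
}

#' Score core event extraction (Task 1)
#'
#' Task 1 targets typed events with their primary arguments; secondary
#' arguments are stripped from both gold and predicted events before
#' matching regardless of the `task_level` in `config`.
#'
#' @inheritParams score_events
#' @return a `score_report`.
#' @export
score_task1 <- function(gold, pred, config = match_config(), decimals = 2,
                        by_section = FALSE) {
  config$task_level <- "task1"
  score_events(gold, pred, config, decimals, by_section)
}

secondary_units <- function(doc) {
  rows <- list()
  for (ev in doc$events) {
    sec <- ev$args[ev$args$role %in% SECONDARY_ROLES, , drop = FALSE]
    if (nrow(sec) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        event = ev$id, ev_type = ev$type, role = sec$role,
        target = sec$target, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(event = character(0), ev_type = character(0),
                      role = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

task2_category <- function(role, ev_type) {
  ifelse(role %in% c("Site", "CSite"), "Sites", "Locations")
}

#' Score secondary argument extraction (Task 2)
#'
#' The scoring unit is one secondary argument (Site/CSite or
#' AtLoc/ToLoc).  A gold secondary argument is recall-matched when a
#' predicted event matching its host event under Task 1 criteria carries
#' a secondary argument with the same role and a matching entity;
#' precision is the mirror image over predicted secondary arguments.
#' Site rows are additionally broken down by host event type
#' (Phosphorylation, Binding, Regulation family).
#'
#' @inheritParams score_events
#' @return a `score_report` with rows Sites, Locations, All and the
#'   per-host-type Site breakdown.
#' @export
score_task2 <- function(gold, pred, config = match_config(), decimals = 2) {
  gold <- as_corpus(gold)
  pred <- as_corpus(pred)
  check_same_documents(gold, pred)
  host_cfg <- config
  host_cfg$task_level <- "task1"
  host_cfg$decomposition <- FALSE

  units <- list()
  for (id in names(gold)) {
    gdoc <- gold[[id]]
    pdoc <- pred[[id]]
    m <- event_matcher(strip_secondary(gdoc), strip_secondary(pdoc), host_cfg)
    text <- gdoc$text %||% pdoc$text
    gu <- secondary_units(gdoc)
    pu <- secondary_units(pdoc)
    # does `host_args` (in `host_doc`) carry a secondary argument whose
    # role equals `role` and whose entity matches `other_tb`?  The span
    # relaxation is always anchored on the gold entity.
    arg_hit <- function(host_args, host_doc, role, other_tb, gold_side_is_host) {
      sec <- host_args[host_args$role == role, , drop = FALSE]
      for (tgt in sec$target) {
        cand <- host_doc$text_bounds[[tgt]]
        if (!is.null(cand) && !is.null(other_tb)) {
          ok <- if (gold_side_is_host) {
            text_bound_match(other_tb, cand, config$span_mode, text)
          } else {
            text_bound_match(cand, other_tb, config$span_mode, text)
          }
          if (ok) return(TRUE)
        }
      }
      FALSE
    }
    gu$matched <- vapply(seq_len(nrow(gu)), function(i) {
      gtb <- gdoc$text_bounds[[gu$target[i]]]
      for (pid in names(pdoc$events)) {
        if (m$event(pid, gu$event[i]) &&
            arg_hit(pdoc$events[[pid]]$args, pdoc, gu$role[i], gtb, FALSE)) {
          return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    pu$matched <- vapply(seq_len(nrow(pu)), function(i) {
      ptb <- pdoc$text_bounds[[pu$target[i]]]
      for (gid in names(gdoc$events)) {
        if (m$event(pu$event[i], gid) &&
            arg_hit(gdoc$events[[gid]]$args, gdoc, pu$role[i], ptb, TRUE)) {
          return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    units[[id]] <- list(gold = gu, pred = pu)
  }

  gall <- do.call(rbind, lapply(units, `[[`, "gold"))
  pall <- do.call(rbind, lapply(units, `[[`, "pred"))
  row_for <- function(label, gsel, psel) {
    score_row(label, sum(gsel), sum(psel),
              sum(gall$matched[gsel]), sum(pall$matched[psel]), decimals)
  }
  gsite <- gall$role %in% c("Site", "CSite")
  psite <- pall$role %in% c("Site", "CSite")
  rows <- list(
    row_for("Sites", gsite, psite),
    row_for("Locations", !gsite, !psite),
    row_for("All", rep(TRUE, nrow(gall)), rep(TRUE, nrow(pall))),
    row_for("Sites/Phosphorylation",
            gsite & gall$ev_type == "Phosphorylation",
            psite & pall$ev_type == "Phosphorylation"),
    row_for("Sites/Binding",
            gsite & gall$ev_type == "Binding",
            psite & pall$ev_type == "Binding"),
    row_for("Sites/Regulation",
            gsite & gall$ev_type %in% REGULATION_TYPES,
            psite & pall$ev_type %in% REGULATION_TYPES))
  new_score_report(rows, mode = mode_label(config, "secondary arguments"),
                   decimals = decimals)
}

#' Score negation/speculation detection (Task 3)
#'
#' The scoring unit is one modification.  A gold modification is
#' recall-matched when a predicted modification of the same type attaches
#' to an event matching the gold modification's event under Task 1
#' criteria; precision is the mirror image.
#'
#' @inheritParams score_events
#' @return a `score_report` with rows Negation, Speculation, All.
#' @export
score_task3 <- function(gold, pred, config = match_config(), decimals = 2) {
  gold <- as_corpus(gold)
  pred <- as_corpus(pred)
  check_same_documents(gold, pred)
  cfg <- config
  cfg$task_level <- "task1"
  cfg$decomposition <- FALSE

  gtype <- character(0); gmatched <- logical(0)
  ptype <- character(0); pmatched <- logical(0)
  for (id in names(gold)) {
    gdoc <- gold[[id]]
    pdoc <- pred[[id]]
    m <- event_matcher(gdoc, pdoc, cfg)
    for (gm in gdoc$modifications) {
      hit <- any(vapply(pdoc$modifications, function(pm) {
        pm$type == gm$type && m$event(pm$event, gm$event)
      }, logical(1)))
      gtype <- c(gtype, gm$type)
      gmatched <- c(gmatched, hit)
    }
    for (pm in pdoc$modifications) {
      hit <- any(vapply(gdoc$modifications, function(gm) {
        pm$type == gm$type && m$event(pm$event, gm$event)
      }, logical(1)))
      ptype <- c(ptype, pm$type)
      pmatched <- c(pmatched, hit)
    }
  }
  row_for <- function(label, types) {
    gs <- gtype %in% types
    ps <- ptype %in% types
    score_row(label, sum(gs), sum(ps), sum(gmatched[gs]), sum(pmatched[ps]),
              decimals)
  }
  rows <- list(row_for("Negation", "Negation"),
               row_for("Speculation", "Speculation"),
               row_for("All", c("Negation", "Speculation")))
  new_score_report(rows, mode = mode_label(config, "modifications"),
                   decimals = decimals)
}
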