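# The equality and relaxation calculus for event matching.
#
# Event equality holds when (1) the event types are the same, (2) the
# triggers are equal as text entities, and (3) the argument multisets are
# fully matched: a perfect one-to-one correspondence pairing arguments of
# equal role and equal target, where a text-bound target matches by text
# entity equality (same type, same span) and an event target matches by
# event equality applied recursively.  Relaxations:
#
#   * approximate span: a predicted span matches a gold span when it is
#     entirely contained in the gold span extended by one word to each side;
#   * approximate recursive: an event in *argument position* is matched by
#     a relaxed criterion -- same type, matching trigger, and matching
#     Theme arguments only (recursively); its non-Theme arguments are
#     ignored.  The top-level event's own argument set must still fully
#     match;
#   * decomposition: every multi-argument event is split into
#     single-argument events sharing the trigger and type, and the
#     resulting units are scored as separate events.

#' Evaluation mode configuration
#'
#' Bundles the switches that define an evaluation mode.  The default is
#' the headline reporting mode: approximate span matching combined with
#' approximate recursive matching at task level 1.
#'
#' @param span_mode `"approximate"` (one-word extension of gold spans) or
#'   `"strict"` (exact offsets).
#' @param recursive_mode `"approximate"` (events in argument position are
#'   compared on type, trigger and Theme arguments only) or `"strict"`.
#' @param decomposition if `TRUE`, both gold and predicted events are
#'   decomposed into single-argument units before scoring.
#' @param task_level `"task1"` strips secondary arguments (Site, CSite,
#'   AtLoc, ToLoc) from both sides before matching; `"task2"` retains
#'   them.
#' @return an object of class `match_config`.
#' @export
match_config <- function(span_mode = c("approximate", "strict"),
                         recursive_mode = c("approximate", "strict"),
                         decomposition = FALSE,
                         task_level = c("task1", "task2")) {
  structure(
    list(span_mode = match.arg(span_mode),
         recursive_mode = match.arg(recursive_mode),
         decomposition = isTRUE(decomposition),
         task_level = match.arg(task_level)),
    class = "match_config")
}

#' @export
print.match_config <- function(x, ...) {
  cat("<match_config> span=", x$span_mode, ", recursive=", x$recursive_mode,
      ", decomposition=", x$decomposition, ", level=", x$task_level, "\n",
      sep = "")
  invisible(x)
}

# word = maximal run of characters that are neither whitespace nor
# punctuation; returns 0-based end-exclusive offsets
word_spans <- function(text) {
  m <- gregexpr("[^[:space:][:punct:]]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(beg = integer(0), end = integer(0)))
  }
  beg <- as.integer(m) - 1L
  data.frame(beg = beg, end = beg + attr(m, "match.length"))
}

#' Extend a gold span by one word on each side
#'
#' Computes the word-extended span used by approximate span matching: the
#' gold span extended leftward to the start of the preceding word and
#' rightward to the end of the following word.  At a document edge, where
#' no adjacent word exists, the corresponding boundary stays at the gold
#' boundary.
#'
#' @param gold_span list with `beg` and `end` (0-based, end-exclusive).
#' @param text the document text.
#' @return list with `beg`, `end` (the extended boundaries) and `source`
#'   (the gold span).
#' @examples
#' extend_span(list(beg = 4, end = 7), "the p65 subunit")  # covers all 15 chars
#' @export
extend_span <- function(gold_span, text) {
  ws <- word_spans(text)
  beg <- gold_span$beg
  end <- gold_span$end
  left <- which(ws$end <= beg)
  ebeg <- if (length(left) > 0) ws$beg[max(left)] else beg
  right <- which(ws$beg >= end)
  eend <- if (length(right) > 0) ws$end[min(right)] else end
  list(beg = ebeg, end = eend, source = list(beg = beg, end = end))
}

#' Compare two spans under a matching mode
#'
#' Strict mode requires exact offset equality; approximate mode requires
#' the predicted span to be entirely contained within the gold span
#' extended by one word to each side (see [extend_span()]).
#'
#' @param pred,gold lists with `beg` and `end` components (a text-bound
#'   annotation qualifies).
#' @param mode `"strict"` or `"approximate"`.
#' @param text document text; required for approximate mode.
#' @return logical.
#' @export
span_match <- function(pred, gold, mode = c("strict", "approximate"),
                       text = NULL) {
  mode <- match.arg(mode)
  if (pred$beg == gold$beg && pred$end == gold$end) return(TRUE)
  if (mode == "strict") return(FALSE)
  if (is.null(text)) {
    stop("approximate span matching needs the document text", call. = FALSE)
  }
  ext <- extend_span(gold, text)
  pred$beg >= ext$beg && pred$end <= ext$end
}

#' Text entity equality
#'
#' Two text entities are equal when their types are the same and their
#' spans match under the given mode.  Event triggers are text entities,
#' so the same criterion applies to them.
#'
#' @param pred,gold text-bound annotations.
#' @inheritParams span_match
#' @return logical.
#' @export
text_bound_match <- function(pred, gold, mode = c("strict", "approximate"),
                             text = NULL) {
  pred$type == gold$type && span_match(pred, gold, match.arg(mode), text)
}

# Kuhn's augmenting-path search for a perfect matching in the bipartite
# compatibility graph (rows = predicted arguments, columns = gold
# arguments).  Argument sets are small (<= a handful of slots) so the
# O(V*E) bound is immaterial; the point is correctness without the
# exponential blow-up of permutation search, which is kept as a test
# oracle only.
has_perfect_matching <- function(compat) {
  n <- nrow(compat)
  if (n != ncol(compat)) return(FALSE)
  if (n == 0) return(TRUE)
  match_of <- rep(0L, n)  # gold column -> pred row
  augment <- function(u, seen) {
    for (v in seq_len(n)) {
      if (compat[u, v] && !seen[v]) {
        seen[v] <- TRUE
        if (match_of[v] == 0L) {
          match_of[v] <<- u
          return(TRUE)
        }
        prev <- match_of[v]
        match_of[v] <<- u
        if (augment(prev, seen)) return(TRUE)
        match_of[v] <<- prev
      }
    }
    FALSE
  }
  for (u in seq_len(n)) {
    if (!augment(u, rep(FALSE, n))) return(FALSE)
  }
  TRUE
}

# Builds a memoized matcher over a (gold document, predicted document)
# pair sharing the same underlying text.  All user-facing matching
# functions and the scorers delegate here.
event_matcher <- function(gold_doc, pred_doc, config) {
  text <- gold_doc$text %||% pred_doc$text
  memo <- new.env(parent = emptyenv())
  relax_children <- config$recursive_mode == "approximate"

  tb_match_ids <- function(pid, gid) {
    p <- pred_doc$text_bounds[[pid]]
    g <- gold_doc$text_bounds[[gid]]
    !is.null(p) && !is.null(g) &&
      text_bound_match(p, g, config$span_mode, text)
  }

  filter_level <- function(args) {
    if (config$task_level == "task1") {
      args[!args$role %in% SECONDARY_ROLES, , drop = FALSE]
    } else {
      args
    }
  }

  target_match <- function(ptgt, gtgt) {
    p_ev <- pred_doc$events[[ptgt]]
    g_ev <- gold_doc$events[[gtgt]]
    if (!is.null(p_ev) && !is.null(g_ev)) {
      ev_match(ptgt, gtgt, relaxed = relax_children)
    } else if (is.null(p_ev) && is.null(g_ev)) {
      tb_match_ids(ptgt, gtgt)
    } else {
      FALSE
    }
  }

  args_match <- function(pargs, gargs, theme_only = FALSE) {
    if (theme_only) {
      pargs <- pargs[pargs$role == "Theme", , drop = FALSE]
      gargs <- gargs[gargs$role == "Theme", , drop = FALSE]
    }
    n <- nrow(gargs)
    if (nrow(pargs) != n) return(FALSE)
    if (n == 0) return(TRUE)
    compat <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (pargs$role[i] == gargs$role[j]) {
          compat[i, j] <- target_match(pargs$target[i], gargs$target[j])
        }
      }
    }
    has_perfect_matching(compat)
  }

  ev_match <- function(pid, gid, relaxed = FALSE) {
    key <- paste0(pid, "\r", gid, "\r", relaxed)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    p <- pred_doc$events[[pid]]
    g <- gold_doc$events[[gid]]
    res <- FALSE
    if (!is.null(p) && !is.null(g) && p$type == g$type &&
        tb_match_ids(p$trigger, g$trigger)) {
      res <- args_match(filter_level(p$args), filter_level(g$args),
                        theme_only = relaxed)
    }
    memo[[key]] <- res
    res
  }

  list(event = function(pid, gid) ev_match(pid, gid, relaxed = FALSE),
       tb = tb_match_ids,
       args = args_match)
}

#' Full matching of two argument multisets
#'
#' True iff a perfect one-to-one correspondence exists pairing arguments
#' with equal role and equal target (text entity equality for text-bound
#' targets; event equality, possibly relaxed, for event targets), found
#' as a maximum matching of the bipartite compatibility graph.
#'
#' @param pred_doc,gold_doc documents providing target resolution for the
#'   two argument sets.
#' @param pred_args,gold_args argument data frames with columns `role`
#'   and `target`.
#' @param config a [match_config()].
#' @return logical.
#' @export
arguments_match <- function(pred_doc, gold_doc, pred_args, gold_args,
                            config = match_config()) {
  m <- event_matcher(gold_doc, pred_doc, config)
  m$args(pred_args, gold_args)
}

#' Event equality under an evaluation mode
#'
#' @param pred_doc,gold_doc documents holding the two events (they share
#'   the same underlying text).
#' @param pred_id,gold_id event identifiers.
#' @param config a [match_config()].
#' @return logical.
#' @examples
#' lines <- c("T1\tProtein 15 18\tp65", "T2\tLocalization 19 32\ttranslocation",
#'            "E1\tLocalization:T2 Theme:T1")
#' doc <- parse_document(NULL, lines)
#' event_match(doc, doc, "E1", "E1")
#' @export
event_match <- function(pred_doc, gold_doc, pred_id, gold_id,
                        config = match_config()) {
  m <- event_matcher(gold_doc, pred_doc, config)
  m$event(pred_id, gold_id)
}

#' Decompose events into single-argument units
#'
#' Each event with two or more arguments yields one single-argument event
#' per argument, sharing the original trigger and type; events with zero
#' or one argument are preserved unchanged (so the operation is
#' idempotent).  Argument targets are left intact: a unit may still
#' reference an original multi-argument event, and such references are
#' resolved against the original event when units are matched.
#'
#' @param events a `standoff_document` or a named list of event frames.
#' @return named list of event frames; unit identifiers are
#'   `<original id>*<argument index>`.
#' @export
decompose_events <- function(events) {
  if (inherits(events, "standoff_document")) events <- events$events
  out <- list()
  for (e in events) {
    k <- nrow(e$args)
    if (k <= 1) {
      out[[e$id]] <- e
    } else {
      for (i in seq_len(k)) {
        u <- e
        u$id <- paste0(e$id, "*", i)
        u$args <- e$args[i, , drop = FALSE]
        rownames(u$args) <- NULL
        out[[u$id]] <- u
      }
    }
  }
  out
}

# Replaces a document's events by their decomposition units while keeping
# the original multi-argument frames available for nested-argument
# resolution.  Returns the modified document plus the ids of the units
# that constitute the scoring population.
decomposed_view <- function(doc) {
  units <- decompose_events(doc$events)
  keep <- setdiff(names(doc$events), names(units))
  doc$events <- c(units, doc$events[keep])
  list(doc = doc, unit_ids = names(units))
}
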