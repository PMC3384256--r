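# Coreference scoring.
#
# Two modes.  The *surface* mode scores anaphora -> antecedent links as
# annotated, regardless of protein content, with partial markable
# matching: a response expression is correct when it covers the gold
# expression's minimal (head) boundary and is included in its maximal
# boundary.  The *protein* mode -- the primary evaluation perspective --
# scores (anaphora, protein) pairs obtained by tracing each chain of
# surface links until an antecedent embedding a protein name is found;
# intermediate antecedents and links that reach no protein are ignored.

min_span_of <- function(tb) {
  if (is.na(tb$min_beg)) list(beg = tb$beg, end = tb$end)
  else list(beg = tb$min_beg, end = tb$min_end)
}

#' Partial markable matching
#'
#' A response markable matches a gold markable when its span covers the
#' gold minimal boundary (the head; defaults to the full span when no
#' minimal span is annotated) and is included in the gold maximal
#' boundary (the full span of the expression annotation).
#'
#' @param response,gold text-bound annotations.
#' @return logical.
#' @export
markable_match <- function(response, gold) {
  gm <- min_span_of(gold)
  response$beg <= gm$beg && response$end >= gm$end &&
    response$beg >= gold$beg && response$end <= gold$end
}

surface_links <- function(doc) {
  data.frame(
    id = vapply(doc$coref_relations, `[[`, character(1), "id"),
    anaphora = vapply(doc$coref_relations, `[[`, character(1), "anaphora"),
    antecedent = vapply(doc$coref_relations, `[[`, character(1), "antecedent"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Score surface coreference links
#'
#' A response link is correct when its two argument expressions match
#' those of a gold link under [markable_match()]; recall is over gold
#' links and precision over response links.
#'
#' @param gold,response gold and response corpora (a `standoff_document`
#'   or a named list of them).
#' @param decimals decimal places for reported percentages.
#' @return a one-row `score_report`.
#' @export
score_surface <- function(gold, response, decimals = 1) {
  gold <- as_corpus(gold)
  response <- as_corpus(response)
  check_same_documents(gold, response)
  gold_n <- ans_n <- rm_n <- pm_n <- 0
  for (id in names(gold)) {
    gdoc <- gold[[id]]
    rdoc <- response[[id]]
    gl <- surface_links(gdoc)
    rl <- surface_links(rdoc)
    gold_n <- gold_n + nrow(gl)
    ans_n <- ans_n + nrow(rl)
    if (nrow(gl) == 0 || nrow(rl) == 0) next
    link_ok <- function(ri, gi) {
      markable_match(rdoc$text_bounds[[rl$anaphora[ri]]],
                     gdoc$text_bounds[[gl$anaphora[gi]]]) &&
        markable_match(rdoc$text_bounds[[rl$antecedent[ri]]],
                       gdoc$text_bounds[[gl$antecedent[gi]]])
    }
    hits <- outer(seq_len(nrow(rl)), seq_len(nrow(gl)),
                  Vectorize(link_ok))
    rm_n <- rm_n + sum(apply(hits, 2, any))
    pm_n <- pm_n + sum(apply(hits, 1, any))
  }
  new_score_report(list(score_row("Surface", gold_n, ans_n, rm_n, pm_n,
                                  decimals)),
                   mode = "surface coreference", decimals = decimals)
}

#' Derive protein coreference links by chain tracing
#'
#' For each anaphoric expression the chain of surface links is traced
#' until an antecedent embedding a protein name is found; one link is
#' emitted per protein embedded in that (direct or indirect) antecedent.
#' Anaphors whose chains reach no protein-embedding antecedent yield no
#' links.  The bracketed protein list of a relation line is trusted when
#' present; when absent the embedded proteins are recomputed as the
#' annotated Protein text-bounds whose spans fall inside the antecedent
#' span.  Cycles in the antecedent graph terminate the trace with a
#' warning.
#'
#' @param doc a `standoff_document`.
#' @return data frame with columns `anaphora` and `protein`.
#' @export
build_protein_links <- function(doc) {
  rels <- doc$coref_relations
  empty <- data.frame(anaphora = character(0), protein = character(0),
                      stringsAsFactors = FALSE)
  if (length(rels) == 0) return(empty)
  anas <- vapply(rels, `[[`, character(1), "anaphora")
  by_ana <- split(unname(rels), anas)
  prot_ids <- names(doc$text_bounds)[vapply(doc$text_bounds, function(tb) {
    tb$type == "Protein"
  }, logical(1))]
  embedded <- function(rel) {
    if (length(rel$proteins) > 0) return(rel$proteins)
    ant <- doc$text_bounds[[rel$antecedent]]
    prot_ids[vapply(prot_ids, function(p) {
      tb <- doc$text_bounds[[p]]
      tb$beg >= ant$beg && tb$end <= ant$end
    }, logical(1))]
  }
  cycle_seen <- FALSE
  rows <- list()
  for (a in names(by_ana)) {
    visited <- character(0)
    found <- character(0)
    walk <- function(id) {
      if (id %in% visited) {
        cycle_seen <<- TRUE
        return(invisible())
      }
      visited <<- c(visited, id)
      for (rel in by_ana[[id]] %||% list()) {
        ps <- embedded(rel)
        if (length(ps) > 0) {
          found <<- union(found, ps)
        } else if (!is.null(by_ana[[rel$antecedent]])) {
          walk(rel$antecedent)
        }
      }
      invisible()
    }
    walk(a)
    if (length(found) > 0) {
      rows[[a]] <- data.frame(anaphora = a, protein = sort(found),
                              stringsAsFactors = FALSE)
    }
  }
  if (cycle_seen) {
    warning("cycle in the antecedent chain of document ", doc$doc_id,
            "; affected anaphors resolve to no protein beyond the cycle",
            call. = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score protein coreference links (primary mode)
#'
#' Protein links are generated from both the gold and the response
#' surface links by [build_protein_links()].  A response link is correct
#' when its anaphor matches a gold link's anaphor under
#' [markable_match()] and the two reference the same protein annotation
#' (the given protein set is shared by both sides).
#'
#' @inheritParams score_surface
#' @return a one-row `score_report`.
#' @export
score_protein <- function(gold, response, decimals = 1) {
  gold <- as_corpus(gold)
  response <- as_corpus(response)
  check_same_documents(gold, response)
  gold_n <- ans_n <- rm_n <- pm_n <- 0
  for (id in names(gold)) {
    gdoc <- gold[[id]]
    rdoc <- response[[id]]
    gl <- build_protein_links(gdoc)
    rl <- build_protein_links(rdoc)
    gold_n <- gold_n + nrow(gl)
    ans_n <- ans_n + nrow(rl)
    if (nrow(gl) == 0 || nrow(rl) == 0) next
    link_ok <- function(ri, gi) {
      rl$protein[ri] == gl$protein[gi] &&
        markable_match(rdoc$text_bounds[[rl$anaphora[ri]]],
                       gdoc$text_bounds[[gl$anaphora[gi]]])
    }
    hits <- outer(seq_len(nrow(rl)), seq_len(nrow(gl)), Vectorize(link_ok))
    rm_n <- rm_n + sum(apply(hits, 2, any))
    pm_n <- pm_n + sum(apply(hits, 1, any))
  }
  new_score_report(list(score_row("Protein", gold_n, ans_n, rm_n, pm_n,
                                  decimals)),
                   mode = "protein coreference", decimals = decimals)
}

span_overlap <- function(a, b) {
  max(0L, min(a$end, b$end) - max(a$beg, b$beg))
}

#' Protein coreference scores broken down by anaphora type
#'
#' Anaphora-type labels (relative pronoun, pronoun, definite noun phrase,
#' ...) are consumed from an external table, never inferred.  Each
#' response link is attributed to the gold anaphor it matches under
#' [markable_match()] (largest span overlap on ties of matching, earliest
#' offset on remaining ties); response links matching no gold anaphor
#' count only toward All precision.
#'
#' @inheritParams score_surface
#' @param labels data frame with columns `doc_id`, `id` (anaphor
#'   text-bound id) and `label`, or `NULL` (only the All row is then
#'   produced).
#' @return a `score_report` with one row per label plus All.
#' @export
score_by_anaphora_type <- function(gold, response, labels = NULL,
                                   decimals = 1) {
  gold <- as_corpus(gold)
  response <- as_corpus(response)
  check_same_documents(gold, response)
  per_doc <- list()
  for (id in names(gold)) {
    gdoc <- gold[[id]]
    rdoc <- response[[id]]
    gl <- build_protein_links(gdoc)
    rl <- build_protein_links(rdoc)
    lab_of <- function(ana) {
      if (is.null(labels)) return(NA_character_)
      hit <- labels$label[labels$doc_id == id & labels$id == ana]
      if (length(hit) > 0) hit[1] else NA_character_
    }
    gl$label <- vapply(gl$anaphora, lab_of, character(1))
    gl$matched <- FALSE
    rl$gold_ana <- NA_character_
    rl$correct <- FALSE
    if (nrow(rl) > 0 && nrow(gl) > 0) {
      gold_anas <- unique(gl$anaphora)
      for (ri in seq_len(nrow(rl))) {
        rtb <- rdoc$text_bounds[[rl$anaphora[ri]]]
        cand <- gold_anas[vapply(gold_anas, function(ga) {
          markable_match(rtb, gdoc$text_bounds[[ga]])
        }, logical(1))]
        if (length(cand) > 0) {
          ov <- vapply(cand, function(ga) {
            span_overlap(rtb, gdoc$text_bounds[[ga]])
          }, numeric(1))
          beg <- vapply(cand, function(ga) gdoc$text_bounds[[ga]]$beg,
                        numeric(1))
          best <- cand[order(-ov, beg)][1]
          rl$gold_ana[ri] <- best
          hit <- gl$anaphora == best & gl$protein == rl$protein[ri]
          if (any(hit)) {
            rl$correct[ri] <- TRUE
            gl$matched[hit] <- TRUE
          }
        }
      }
    }
    per_doc[[id]] <- list(gl = gl, rl = rl,
                          rlab = vapply(rl$gold_ana, lab_of, character(1)))
  }
  gall <- do.call(rbind, lapply(per_doc, `[[`, "gl"))
  rall <- do.call(rbind, lapply(per_doc, `[[`, "rl"))
  rlab <- unlist(lapply(per_doc, `[[`, "rlab"), use.names = FALSE)
  rows <- list()
  if (!is.null(labels)) {
    for (lab in unique(stats::na.omit(gall$label))) {
      gsel <- !is.na(gall$label) & gall$label == lab
      psel <- !is.na(rlab) & rlab == lab
      rows[[length(rows) + 1]] <- score_row(
        lab, sum(gsel), sum(psel),
        sum(gall$matched[gsel]), sum(rall$correct[psel]), decimals)
    }
  }
  rows[[length(rows) + 1]] <- score_row(
    "All", nrow(gall), nrow(rall), sum(gall$matched), sum(rall$correct),
    decimals)
  new_score_report(rows, mode = "protein coreference by anaphora type",
                   decimals = decimals)
}
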