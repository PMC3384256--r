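# Shared fixtures built in code.

# The event annotation example: a negated localization of p65 to a
# cellular compartment, with the trigger and secondary-argument entity
# annotated alongside the protein.
figure1_text <- "the failure of p65 translocation to the nuclei."
figure1_lines <- c(
  "T1 Protein 15 18 p65",
  "T2 Localization 19 32 translocation",
  "T3 Entity 40 46 nuclei",
  "E1 Localization:T2 Theme:T1 ToLoc:T3",
  "M1 Negation E1")
figure1_doc <- function() parse_document(figure1_text, figure1_lines)

# The coreference annotation example: protein mentions, anaphoric
# expressions with minimal spans, and the anaphora -> antecedent
# relations, including a chain through an intermediate antecedent
# (T33 -> T32 -> T31).  Offsets as printed; the document text itself is
# not reproduced, so text consistency checks are skipped.
coref_protein_lines <- c(
  "T4 Protein 275 278 p65",
  "T5 Protein 294 297 p50",
  "T6 Protein 367 372 v-rel",
  "T7 Protein 406 409 p65",
  "T8 Protein 597 600 p50",
  "T9 Protein 843 848 MAD-3",
  "T10 Protein 879 882 p65")
coref_markable_lines <- c(
  "T27 Exp 179 222 the N. . 215 222 complex",
  "T28 Exp 264 297 NF-ka. .",
  "T29 Exp 307 312 which",
  "T30 Exp 459 471 this . . 464 471 complex",
  "T31 Exp 868 882 NF-ka. .",
  "T32 Exp 1022 1047 this . . 1027 1047 tra. .")
coref_relation_lines <- c(
  "R1 Coref Ana:T29 Ant:T28 [T5, T4]",
  "R2 Coref Ana:T30 Ant:T27",
  "R3 Coref Ana:T32 Ant:T31 [T10]")
# the chain-tracing variant adds a second-order anaphor T33 -> T32
coref_chain_lines <- c(
  "T33 Exp 1100 1110 this one",
  "R4 Coref Ana:T33 Ant:T32")

coref_doc <- function(with_chain = FALSE) {
  parse_document(NULL, c(coref_protein_lines, coref_markable_lines,
                         if (with_chain) coref_chain_lines[1],
                         coref_relation_lines,
                         if (with_chain) coref_chain_lines[2]),
                 doc_id = "CO")
}

# Incremental token/offset builder for hand-made documents; tokens are
# joined by single spaces.
tok_builder <- function() {
  env <- new.env()
  env$tokens <- character(0)
  env$len <- 0L
  env$emit <- function(tok) {
    beg <- if (length(env$tokens) == 0) 0L else env$len + 1L
    env$tokens <- c(env$tokens, tok)
    env$len <- beg + nchar(tok)
    c(beg, beg + nchar(tok))
  }
  env$text <- function() paste(env$tokens, collapse = " ")
  env
}

span_line <- function(id, type, span, text) {
  paste0(id, "\t", type, " ", span[1], " ", span[2], "\t", text)
}

# One document of n unary gene-expression statements at mutually distant
# positions ("the GENEi expression .").
make_simple_doc <- function(n, doc_id = "S1") {
  b <- tok_builder()
  lines <- character(0)
  for (i in seq_len(n)) {
    b$emit("the")
    pn <- sprintf("GENE%02d", i)
    ps <- b$emit(pn)
    ts <- b$emit("expression")
    b$emit(".")
    lines <- c(lines,
               span_line(paste0("TP", i), "Protein", ps, pn),
               span_line(paste0("TT", i), "Gene_expression", ts, "expression"),
               paste0("E", i, "\tGene_expression:TT", i, " Theme:TP", i))
  }
  parse_document(b$text(), lines, doc_id = doc_id)
}

# Exhaustive permutation oracle for full argument matching: tries every
# pairing of predicted against gold arguments and accepts when some
# permutation pairs equal roles with matching targets.
perm_oracle <- function(pred_doc, gold_doc, pargs, gargs, config) {
  n <- nrow(gargs)
  if (nrow(pargs) != n) return(FALSE)
  if (n == 0) return(TRUE)
  text <- gold_doc$text
  pair_ok <- function(i, j) {
    if (pargs$role[i] != gargs$role[j]) return(FALSE)
    pt <- pred_doc$text_bounds[[pargs$target[i]]]
    gt <- gold_doc$text_bounds[[gargs$target[j]]]
    if (!is.null(pt) && !is.null(gt)) {
      return(text_bound_match(pt, gt, config$span_mode, text))
    }
    if (is.null(pt) && is.null(gt)) {
      return(event_match(pred_doc, gold_doc, pargs$target[i],
                         gargs$target[j], config))
    }
    FALSE
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(seq_len(n))) {
    if (all(vapply(seq_len(n), function(i) pair_ok(i, p[i]), logical(1)))) {
      return(TRUE)
    }
  }
  FALSE
}

# decomposition view mirroring the scorer's unit population: units plus
# the original multi-argument frames for nested-reference resolution
decompose_doc <- function(doc) {
  units <- decompose_events(doc)
  keep <- setdiff(names(doc$events), names(units))
  doc$events <- c(units, doc$events[keep])
  list(doc = doc, unit_ids = names(units))
}

all_match_configs <- function() {
  grid <- expand.grid(span = c("strict", "approximate"),
                      rec = c("strict", "approximate"),
                      dec = c(FALSE, TRUE),
                      task = c("task1", "task2"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    match_config(grid$span[i], grid$rec[i], grid$dec[i], grid$task[i])
  })
}
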