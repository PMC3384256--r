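# Synthetic standoff corpora with known-by-construction scores.
#
# The generator writes schema-valid gold corpora over a small vocabulary
# of gene-symbol-like tokens and trigger nominalizations, with every
# annotation span indexing a real substring of the synthetic text.
# Sentences are laid out so that any two annotated spans from different
# statements are separated by at least two words: the one-word extension
# of approximate span matching then never bridges two distinct
# annotations, which makes the effect of every injected error exactly
# computable.  perturb_corpus() applies a controlled error budget to a
# generated corpus and returns, alongside the perturbed predictions, the
# closed-form expected counts per evaluation mode implied by the applied
# operations.

PROTEIN_NAMES <- c("p65", "p50", "STAT1", "IkBa", "TRAF2", "IL2Ra",
                   "c-Jun", "c-Fos", "RelA", "c-Myc", "TNFa", "CD28re")
TRIGGER_WORDS <- list(
  Gene_expression = c("expression", "production", "synthesis"),
  Transcription = c("transcription", "mRNA"),
  Protein_catabolism = c("degradation", "proteolysis"),
  Phosphorylation = c("phosphorylation", "hyperphosphorylation"),
  Localization = c("translocation", "secretion", "release"),
  Binding = c("binding", "interaction", "association"),
  Regulation = c("regulation", "modulation", "effect"),
  Positive_regulation = c("activation", "induction", "upregulation"),
  Negative_regulation = c("inhibition", "suppression", "downregulation"))
ENTITY_WORDS <- c("nucleus", "cytoplasm", "promoter", "membrane",
                  "Tyr701", "Ser32", "enhancer")

#' Parameters of the synthetic corpus generator
#'
#' Defaults describe a small abstract-like corpus: the type mix follows
#' the frequencies typical of molecular-biology event corpora (gene
#' expression and positive regulation dominant, protein catabolism rare),
#' regulation events nest other events a little under half of the time,
#' and chains of one to three anaphors point back at antecedent noun
#' phrases that usually embed protein names.
#'
#' @param seed integer seed; identical seed and parameters reproduce the
#'   corpus byte for byte.
#' @param n_docs number of documents.
#' @param events_per_doc inclusive integer range for events per document.
#' @param type_mix named probability distribution over the nine event
#'   types; must sum to 1.
#' @param nesting_prob probability that a Regulation-family Theme targets
#'   a previously generated event rather than a protein.
#' @param secondary_arg_prob probability that an event which permits a
#'   secondary argument carries one.
#' @param negation_prob,speculation_prob per-event modification rates.
#' @param coref_links_per_doc inclusive range for coreference chains per
#'   document.
#' @param protein_antecedent_prob probability that a chain's antecedent
#'   noun phrase embeds protein mentions.
#' @param chain_length inclusive range for anaphors per chain.
#' @return an object of class `fixture_params`.
#' @export
fixture_params <- function(seed = 1L,
                           n_docs = 4L,
                           events_per_doc = c(8L, 12L),
                           type_mix = c(Gene_expression = 0.20,
                                        Transcription = 0.06,
                                        Protein_catabolism = 0.02,
                                        Phosphorylation = 0.05,
                                        Localization = 0.05,
                                        Binding = 0.14,
                                        Regulation = 0.12,
                                        Positive_regulation = 0.24,
                                        Negative_regulation = 0.12),
                           nesting_prob = 0.4,
                           secondary_arg_prob = 0.25,
                           negation_prob = 0.08,
                           speculation_prob = 0.05,
                           coref_links_per_doc = c(2L, 4L),
                           protein_antecedent_prob = 0.6,
                           chain_length = c(1L, 3L)) {
  if (!setequal(names(type_mix), EVENT_TYPES)) {
    stop("type_mix must name exactly the nine event types", call. = FALSE)
  }
  if (abs(sum(type_mix) - 1) > 1e-8) {
    stop("type_mix must sum to 1", call. = FALSE)
  }
  probs <- c(nesting_prob, secondary_arg_prob, negation_prob,
             speculation_prob, protein_antecedent_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  check_range <- function(r, what, min_lo = 0L) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < min_lo) {
      stop(what, " must be an increasing pair of non-negative integers",
           call. = FALSE)
    }
  }
  check_range(events_per_doc, "events_per_doc", 1L)
  check_range(coref_links_per_doc, "coref_links_per_doc")
  check_range(chain_length, "chain_length", 1L)
  if (n_docs < 1) stop("n_docs must be positive", call. = FALSE)
  if (nesting_prob > 0 && events_per_doc[1] < 2) {
    stop("nesting requires at least two events per document", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_docs = as.integer(n_docs),
         events_per_doc = as.integer(events_per_doc), type_mix = type_mix,
         nesting_prob = nesting_prob, secondary_arg_prob = secondary_arg_prob,
         negation_prob = negation_prob, speculation_prob = speculation_prob,
         coref_links_per_doc = as.integer(coref_links_per_doc),
         protein_antecedent_prob = protein_antecedent_prob,
         chain_length = as.integer(chain_length)),
    class = "fixture_params")
}

# draw one integer from an inclusive range (robust to lo == hi, where
# base sample() would treat the scalar as 1:n)
sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1)
}

generate_doc <- function(doc_id, params, section_label = NA_character_) {
  tokens <- character(0)
  cursor <- 0L
  emit <- function(tok) {
    beg <- if (length(tokens) == 0) 0L else cursor + 1L
    end <- beg + nchar(tok)
    tokens[[length(tokens) + 1]] <<- tok
    cursor <<- end
    c(beg, end)
  }
  tbs <- list(); evs <- list(); mods <- list(); rels <- list()
  counters <- c(t = 0L, e = 0L, m = 0L, r = 0L)
  next_id <- function(kind) {
    counters[kind] <<- counters[kind] + 1L
    paste0(toupper(kind), counters[kind])
  }
  add_tb <- function(type, span, min_span = NULL) {
    id <- next_id("t")
    tbs[[id]] <<- new_text_bound(
      id, type, span[1], span[2],
      min_beg = if (is.null(min_span)) NA_integer_ else min_span[1],
      min_end = if (is.null(min_span)) NA_integer_ else min_span[2])
    id
  }
  new_protein <- function() {
    add_tb("Protein", emit(sample(PROTEIN_NAMES, 1)))
  }
  new_trigger <- function(type) {
    add_tb(type, emit(sample(TRIGGER_WORDS[[type]], 1)))
  }
  new_entity <- function() {
    add_tb("Entity", emit(sample(ENTITY_WORDS, 1)))
  }
  add_event <- function(type, trigger, roles, targets) {
    id <- next_id("e")
    evs[[id]] <<- new_event(id, type, trigger, event_args(roles, targets))
    id
  }

  # opening filler guarantees at least two words to the left of every
  # annotated span (needed by beyond-one-word span perturbations)
  for (tok in c("In", "these", "experiments", "cells", "were",
                "analysed", ".")) emit(tok)

  n_events <- sample_range(params$events_per_doc)
  types <- sample(names(params$type_mix), n_events, replace = TRUE,
                  prob = params$type_mix)
  referenced <- character(0)   # events already serving as arguments
  reg_pc <- character(0)       # regulation events with protein Theme + Cause
  for (type in types) {
    emit("the")
    if (type %in% SIMPLE_TYPES) {
      p <- new_protein()
      tr <- new_trigger(type)
      roles <- "Theme"; targets <- p
      if (stats::runif(1) < params$secondary_arg_prob &&
          type %in% c("Phosphorylation", "Localization")) {
        if (type == "Phosphorylation") {
          emit("at")
          roles <- c(roles, "Site")
        } else {
          emit("to")
          roles <- c(roles, "ToLoc")
        }
        targets <- c(targets, new_entity())
      }
      add_event(type, tr, roles, targets)
    } else if (type == "Binding") {
      tr <- new_trigger(type)
      emit("of")
      p1 <- new_protein()
      emit("and")
      p2 <- new_protein()
      roles <- c("Theme", "Theme"); targets <- c(p1, p2)
      if (stats::runif(1) < params$secondary_arg_prob) {
        emit("at")
        roles <- c(roles, "Site")
        targets <- c(targets, new_entity())
      }
      add_event(type, tr, roles, targets)
    } else {
      tr <- new_trigger(type)
      emit("of")
      nested_theme <- length(evs) > 0 && stats::runif(1) < params$nesting_prob
      if (nested_theme) {
        emit("it")
        # regulation chains usually target other regulatory statements;
        # prefer an event not yet serving as an argument elsewhere
        good <- setdiff(intersect(reg_pc, names(evs)), referenced)
        theme <- if (length(good) > 0 && stats::runif(1) < 0.6) {
          sample(good, 1)
        } else {
          sample(names(evs), 1)
        }
        referenced <- c(referenced, theme)
      } else {
        theme <- new_protein()
      }
      roles <- "Theme"; targets <- theme
      has_protein_cause <- FALSE
      if (stats::runif(1) < 0.5) {
        emit("by")
        if (length(evs) > 1 && stats::runif(1) < params$nesting_prob / 2) {
          emit("this")
          cause <- sample(setdiff(names(evs), targets), 1)
          referenced <- c(referenced, cause)
        } else {
          cause <- new_protein()
          has_protein_cause <- TRUE
        }
        roles <- c(roles, "Cause"); targets <- c(targets, cause)
      }
      if (stats::runif(1) < params$secondary_arg_prob) {
        emit("at")
        roles <- c(roles, if (stats::runif(1) < 0.5) "Site" else "CSite")
        targets <- c(targets, new_entity())
      }
      eid <- add_event(type, tr, roles, targets)
      if (!nested_theme && has_protein_cause) reg_pc <- c(reg_pc, eid)
    }
    emit(".")
  }

  for (eid in names(evs)) {
    if (stats::runif(1) < params$negation_prob) {
      id <- next_id("m")
      mods[[id]] <- list(id = id, type = "Negation", event = eid)
    }
    if (stats::runif(1) < params$speculation_prob) {
      id <- next_id("m")
      mods[[id]] <- list(id = id, type = "Speculation", event = eid)
    }
  }

  # coreference chains: an antecedent noun phrase followed by a chain of
  # anaphoric sentences, each linking back to the previous expression
  chains <- list()
  labels <- data.frame(doc_id = character(0), id = character(0),
                       label = character(0), stringsAsFactors = FALSE)
  n_chains <- if (params$coref_links_per_doc[2] == 0) 0 else {
    sample_range(params$coref_links_per_doc)
  }
  for (ci in seq_len(n_chains)) {
    with_protein <- stats::runif(1) < params$protein_antecedent_prob
    np_beg <- emit("the")[1]
    prots <- character(0)
    if (with_protein) {
      prots <- new_protein()
      if (stats::runif(1) < 0.5) {
        emit("and")
        prots <- c(prots, new_protein())
      }
      head_span <- emit("complex")
    } else {
      emit("signaling")
      head_span <- emit("pathway")
    }
    base <- add_tb("Exp", c(np_beg, head_span[2]), head_span)
    for (tok in c("was", "observed", ".")) emit(tok)
    len <- sample_range(params$chain_length)
    prev <- base
    anaphors <- character(0)
    rel_ids <- character(0)
    for (j in seq_len(len)) {
      label <- sample(c("Relative pronoun", "Pronoun", "Definite NP"), 1,
                      prob = c(0.5, 0.33, 0.17))
      if (label == "Relative pronoun") {
        ana <- add_tb("Exp", emit("which"))
      } else if (label == "Pronoun") {
        ana <- add_tb("Exp", emit("it"))
      } else {
        d_beg <- emit("this")[1]
        h <- emit("complex")
        ana <- add_tb("Exp", c(d_beg, h[2]), h)
      }
      for (tok in c("was", "required", ".")) emit(tok)
      rid <- next_id("r")
      rels[[rid]] <- list(id = rid, anaphora = ana, antecedent = prev,
                          proteins = if (j == 1) prots else character(0))
      labels <- rbind(labels, data.frame(doc_id = doc_id, id = ana,
                                         label = label,
                                         stringsAsFactors = FALSE))
      anaphors <- c(anaphors, ana)
      rel_ids <- c(rel_ids, rid)
      prev <- ana
    }
    chains[[ci]] <- list(base = base, proteins = prots, anaphors = anaphors,
                         relations = rel_ids, tail_anaphor = prev,
                         tail_relation = rel_ids[len],
                         protein_free = !with_protein)
  }

  text <- paste(unlist(tokens), collapse = " ")
  for (id in names(tbs)) {
    tbs[[id]]$text <- substring(text, tbs[[id]]$beg + 1L, tbs[[id]]$end)
    if (!is.na(tbs[[id]]$min_beg)) {
      tbs[[id]]$min_text <- substring(text, tbs[[id]]$min_beg + 1L,
                                      tbs[[id]]$min_end)
    }
  }
  doc <- structure(
    list(doc_id = doc_id, text = text, text_bounds = tbs, events = evs,
         modifications = mods, coref_relations = rels,
         section_label = section_label),
    class = "standoff_document")
  validate_document(doc)
  list(doc = doc, chains = chains, labels = labels)
}

#' Generate a gold synthetic corpus
#'
#' Produces a deterministic, schema-valid standoff corpus under the given
#' parameters.  The result carries the generation metadata used by
#' [perturb_corpus()] as attributes: `params`, `anaphora_types` (a label
#' table consumable by [score_by_anaphora_type()]) and `chains` (the
#' coreference chain structure per document).
#'
#' @param params a [fixture_params()] object.
#' @param section_labels optional character vector of section labels,
#'   recycled over documents.
#' @return a named list of `standoff_document` objects (class
#'   `standoff_corpus`).
#' @export
generate_gold <- function(params = fixture_params(), section_labels = NULL) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  docs <- list()
  chains <- list()
  labels <- list()
  for (d in seq_len(params$n_docs)) {
    id <- sprintf("D%03d", d)
    lab <- if (is.null(section_labels)) NA_character_ else {
      section_labels[[(d - 1L) %% length(section_labels) + 1L]]
    }
    built <- generate_doc(id, params, lab)
    docs[[id]] <- built$doc
    chains[[id]] <- built$chains
    labels[[d]] <- built$labels
  }
  structure(docs, class = c("standoff_corpus", "list"),
            params = params,
            chains = chains,
            anaphora_types = do.call(rbind, labels))
}

#' Controlled error budget for corpus perturbation
#'
#' Each field counts how many times the corresponding error operation is
#' injected into the predicted copy of a gold corpus.  Every operation
#' has an exactly computable effect on the scores of every evaluation
#' mode; [perturb_corpus()] returns that bookkeeping as the expected
#' score table.
#'
#' @param drop_events gold events removed from the predictions.
#' @param spurious_events fabricated predicted events (an existing
#'   trigger paired with a distant protein it never governs).
#' @param span_shift_within_word predicted trigger spans grown by one
#'   adjacent word: breaks strict but not approximate span matching.
#' @param span_shift_beyond_word predicted trigger spans grown by two
#'   adjacent words: breaks both span modes.
#' @param type_swaps predicted event (and trigger) retyped: breaks every
#'   mode.
#' @param theme_drops one Theme removed from a multi-Theme Binding.
#' @param nested_arg_perturbs the Cause of an event sitting in argument
#'   position retargeted to a distant protein: breaks strict recursive
#'   matching of the parent but not approximate recursive matching.
#' @param mod_drops predicted modifications removed.
#' @param wrong_antecedents a chain-tail coreference link redirected to a
#'   protein-free expression.
#' @param dropped_links chain-tail coreference links removed.
#' @return an object of class `error_budget`.
#' @export
error_budget <- function(drop_events = 0, spurious_events = 0,
                         span_shift_within_word = 0,
                         span_shift_beyond_word = 0, type_swaps = 0,
                         theme_drops = 0, nested_arg_perturbs = 0,
                         mod_drops = 0, wrong_antecedents = 0,
                         dropped_links = 0) {
  b <- list(drop_events = drop_events, spurious_events = spurious_events,
            span_shift_within_word = span_shift_within_word,
            span_shift_beyond_word = span_shift_beyond_word,
            type_swaps = type_swaps, theme_drops = theme_drops,
            nested_arg_perturbs = nested_arg_perturbs, mod_drops = mod_drops,
            wrong_antecedents = wrong_antecedents,
            dropped_links = dropped_links)
  if (any(unlist(b) < 0)) stop("budget counts must be non-negative",
                               call. = FALSE)
  structure(lapply(b, as.integer), class = "error_budget")
}

# argument-unit count of an event at a task level (the decomposition unit
# count: zero-argument events still count as one unit)
unit_count <- function(ev, task_level) {
  args <- ev$args
  if (task_level == "task1") {
    args <- args[!args$role %in% SECONDARY_ROLES, , drop = FALSE]
  }
  max(1L, nrow(args))
}

referenced_event_ids <- function(doc) {
  out <- character(0)
  for (ev in doc$events) {
    out <- c(out, intersect(ev$args$target, names(doc$events)))
  }
  out
}

# proteins whose span cannot be confused with `tb` under approximate span
# matching in either direction
distant_proteins <- function(doc, tb, exclude = character(0)) {
  cands <- names(doc$text_bounds)[vapply(doc$text_bounds, function(x) {
    x$type == "Protein"
  }, logical(1))]
  cands <- setdiff(cands, exclude)
  cands[vapply(cands, function(p) {
    ptb <- doc$text_bounds[[p]]
    !span_match(ptb, tb, "approximate", doc$text) &&
      !span_match(tb, ptb, "approximate", doc$text)
  }, logical(1))]
}

#' Perturb a generated corpus with a controlled error budget
#'
#' Applies the requested error operations to a predicted copy of `gold`
#' (which must come from [generate_gold()], whose chain metadata the
#' coreference operations need) and returns both the predictions and the
#' expected score counts per evaluation mode, derived purely from the
#' bookkeeping of the applied operations.  Operations target disjoint
#' annotations, so their effects are additive; an infeasible budget (more
#' operations than eligible targets) is an error.
#'
#' @param gold a corpus from [generate_gold()].
#' @param budget an [error_budget()].
#' @param seed seed for target selection.
#' @return list with components `pred` (the perturbed corpus) and
#'   `expected` (data frames `events`, `modifications`, `surface`,
#'   `protein` of expected gold/answer/matched counts).
#' @export
perturb_corpus <- function(gold, budget = error_budget(), seed = 1L) {
  stopifnot(inherits(gold, "standoff_corpus"))
  chains <- attr(gold, "chains")
  set.seed(seed)
  pred <- lapply(gold, identity)

  # ---- candidate bookkeeping -------------------------------------------
  all_events <- list()   # (doc, id) pairs keyed "doc\rid"
  for (id in names(gold)) {
    refd <- referenced_event_ids(gold[[id]])
    ref_n <- table(refd)
    modded <- vapply(gold[[id]]$modifications, `[[`, character(1), "event")
    for (eid in names(gold[[id]]$events)) {
      ev <- gold[[id]]$events[[eid]]
      all_events[[paste0(id, "\r", eid)]] <- list(
        doc = id, id = eid, type = ev$type,
        referenced = eid %in% refd,
        ref_once = !is.na(ref_n[eid]) && ref_n[eid] == 1,
        modded = eid %in% modded,
        n_theme = sum(ev$args$role == "Theme"),
        protein_theme = all(vapply(
          ev$args$target[ev$args$role == "Theme"],
          function(t) t %in% names(gold[[id]]$text_bounds), logical(1))),
        protein_cause = {
          cz <- ev$args$target[ev$args$role == "Cause"]
          length(cz) == 1 && cz %in% names(gold[[id]]$text_bounds)
        })
    }
  }
  used <- character(0)
  free <- function(keys) setdiff(keys, used)
  pick <- function(cands, k, what) {
    cands <- free(cands)
    if (length(cands) < k) {
      stop("infeasible budget: ", what, " needs ", k,
           " eligible targets but only ", length(cands), " remain",
           call. = FALSE)
    }
    if (k == 0) return(character(0))
    chosen <- cands[sample.int(length(cands), k)]
    used <<- c(used, chosen)
    chosen
  }
  info <- function(key) all_events[[key]]
  keys_where <- function(f) names(all_events)[vapply(all_events, f, logical(1))]

  plain <- keys_where(function(x) !x$referenced && !x$modded)
  # spurious events are cloned from any event with protein Themes: the
  # clone keeps the trigger but takes a single distant Theme, so it can
  # match neither the template nor any other gold event in any mode
  spurious_templates <- keys_where(function(x) {
    x$n_theme >= 1 && x$protein_theme
  })

  # nested pairs: an argument event G (referenced exactly once, protein
  # Theme and protein Cause) under an unreferenced, unmodified parent R
  nested_pairs <- list()
  for (key in keys_where(function(x) {
    x$referenced && x$ref_once && !x$modded && x$n_theme == 1 &&
      x$protein_theme && x$protein_cause
  })) {
    g <- info(key)
    doc <- gold[[g$doc]]
    parents <- names(doc$events)[vapply(doc$events, function(ev) {
      g$id %in% ev$args$target
    }, logical(1))]
    pkey <- paste0(g$doc, "\r", parents[1])
    p <- info(pkey)
    if (!is.null(p) && !p$referenced && !p$modded) {
      nested_pairs[[key]] <- pkey
    }
  }

  chain_tails <- list()      # key -> (doc, chain index)
  redirectable <- character(0)
  for (id in names(gold)) {
    cs <- chains[[id]]
    free_bases <- vapply(cs, function(c) c$protein_free, logical(1))
    for (ci in seq_along(cs)) {
      key <- paste0(id, "\r", cs[[ci]]$tail_relation)
      chain_tails[[key]] <- list(doc = id, chain = ci)
      # redirect needs a protein-free base from a *different* chain
      if (sum(free_bases[-ci]) > 0) redirectable <- c(redirectable, key)
    }
  }

  # ---- select disjoint targets -----------------------------------------
  nest_keys <- pick(names(nested_pairs), budget$nested_arg_perturbs,
                    "nested_arg_perturbs")
  used <- c(used, unlist(nested_pairs[nest_keys]))  # parents blocked too
  theme_keys <- pick(keys_where(function(x) {
    !x$referenced && !x$modded && x$type == "Binding" && x$n_theme >= 2
  }), budget$theme_drops, "theme_drops")
  swap_keys <- pick(plain, budget$type_swaps, "type_swaps")
  beyond_keys <- pick(plain, budget$span_shift_beyond_word,
                      "span_shift_beyond_word")
  within_keys <- pick(plain, budget$span_shift_within_word,
                      "span_shift_within_word")
  spur_keys <- pick(spurious_templates, budget$spurious_events,
                    "spurious_events")
  drop_keys <- pick(plain, budget$drop_events, "drop_events")
  mod_keys <- local({
    cands <- character(0)
    for (id in names(gold)) {
      for (mid in names(gold[[id]]$modifications)) {
        ekey <- paste0(id, "\r", gold[[id]]$modifications[[mid]]$event)
        if (!ekey %in% used) cands <- c(cands, paste0(id, "\r", mid))
      }
    }
    pick(cands, budget$mod_drops, "mod_drops")
  })
  wrong_keys <- pick(redirectable, budget$wrong_antecedents,
                     "wrong_antecedents")
  drop_link_keys <- pick(names(chain_tails), budget$dropped_links,
                         "dropped_links")

  # ---- apply operations to the predicted copy --------------------------
  split_key <- function(key) strsplit(key, "\r", fixed = TRUE)[[1]]

  word_before <- function(text, beg, n = 1) {
    ws <- word_spans(text)
    left <- which(ws$end <= beg)
    if (length(left) < n) {
      stop("no word available to the left of offset ", beg, call. = FALSE)
    }
    ws$beg[left[length(left) - n + 1]]
  }

  for (key in drop_keys) {
    k <- split_key(key)
    pred[[k[1]]]$events[[k[2]]] <- NULL
  }
  for (key in spur_keys) {
    k <- split_key(key)
    doc <- pred[[k[1]]]
    ev <- gold[[k[1]]]$events[[k[2]]]
    themes <- ev$args$target[ev$args$role == "Theme"]
    far <- NULL
    for (t in themes) {
      cand <- distant_proteins(gold[[k[1]]],
                               gold[[k[1]]]$text_bounds[[t]],
                               exclude = themes)
      far <- if (is.null(far)) cand else intersect(far, cand)
    }
    if (length(far) == 0) stop("no distant protein for a spurious event",
                               call. = FALSE)
    q <- far[sample.int(length(far), 1)]
    nid <- paste0(k[2], "S")
    doc$events[[nid]] <- new_event(nid, ev$type, ev$trigger,
                                   event_args("Theme", q))
    pred[[k[1]]] <- doc
  }
  shift_trigger <- function(key, n_words) {
    k <- split_key(key)
    doc <- pred[[k[1]]]
    tr <- doc$events[[k[2]]]$trigger
    tb <- doc$text_bounds[[tr]]
    tb$beg <- word_before(doc$text, tb$beg, n_words)
    tb$text <- substring(doc$text, tb$beg + 1L, tb$end)
    doc$text_bounds[[tr]] <- tb
    pred[[k[1]]] <<- doc
  }
  for (key in within_keys) shift_trigger(key, 1)
  for (key in beyond_keys) shift_trigger(key, 2)
  for (key in swap_keys) {
    k <- split_key(key)
    doc <- pred[[k[1]]]
    ev <- doc$events[[k[2]]]
    new_type <- sample(setdiff(EVENT_TYPES, ev$type), 1)
    doc$events[[k[2]]]$type <- new_type
    doc$text_bounds[[ev$trigger]]$type <- new_type
    pred[[k[1]]] <- doc
  }
  for (key in theme_keys) {
    k <- split_key(key)
    doc <- pred[[k[1]]]
    args <- doc$events[[k[2]]]$args
    theme_rows <- which(args$role == "Theme")
    drop_row <- theme_rows[sample.int(length(theme_rows), 1)]
    doc$events[[k[2]]]$args <- args[-drop_row, , drop = FALSE]
    pred[[k[1]]] <- doc
  }
  for (key in nest_keys) {
    k <- split_key(key)
    doc <- pred[[k[1]]]
    args <- doc$events[[k[2]]]$args
    crow <- which(args$role == "Cause")
    c_tb <- gold[[k[1]]]$text_bounds[[args$target[crow]]]
    far <- distant_proteins(gold[[k[1]]], c_tb, exclude = args$target[crow])
    if (length(far) == 0) stop("no distant protein for a Cause retarget",
                               call. = FALSE)
    doc$events[[k[2]]]$args$target[crow] <- far[sample.int(length(far), 1)]
    pred[[k[1]]] <- doc
  }
  for (key in mod_keys) {
    k <- split_key(key)
    pred[[k[1]]]$modifications[[k[2]]] <- NULL
  }
  for (key in wrong_keys) {
    tl <- chain_tails[[key]]
    doc <- pred[[tl$doc]]
    rel_id <- split_key(key)[2]
    cs <- chains[[tl$doc]]
    free_bases <- which(vapply(cs, function(c) c$protein_free, logical(1)))
    free_bases <- setdiff(free_bases, tl$chain)
    target <- cs[[free_bases[sample.int(length(free_bases), 1)]]]$base
    doc$coref_relations[[rel_id]]$antecedent <- target
    doc$coref_relations[[rel_id]]$proteins <- character(0)
    pred[[tl$doc]] <- doc
  }
  for (key in drop_link_keys) {
    tl <- chain_tails[[key]]
    rel_id <- split_key(key)[2]
    pred[[tl$doc]]$coref_relations[[rel_id]] <- NULL
  }
  removed_protein_links <- 0L
  for (key in c(wrong_keys, drop_link_keys)) {
    tl <- chain_tails[[key]]
    removed_protein_links <- removed_protein_links +
      length(chains[[tl$doc]][[tl$chain]]$proteins)
  }

  # ---- expected score table --------------------------------------------
  combos <- expand.grid(task_level = c("task1", "task2"),
                        span_mode = c("strict", "approximate"),
                        recursive_mode = c("strict", "approximate"),
                        decomposition = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  n_events <- sum(vapply(gold, function(d) length(d$events), numeric(1)))
  totals <- function(task) {
    sum(vapply(gold, function(d) {
      sum(vapply(d$events, unit_count, integer(1), task_level = task))
    }, numeric(1)))
  }
  u_total <- c(task1 = totals("task1"), task2 = totals("task2"))
  weight <- function(key, combo) {
    if (!combo$decomposition) return(1L)
    k <- split_key(key)
    unit_count(gold[[k[1]]]$events[[k[2]]], combo$task_level)
  }
  ev_expected <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    combo <- combos[i, ]
    base <- if (combo$decomposition) u_total[[combo$task_level]] else n_events
    gold_n <- base
    ans_n <- base
    rm_n <- base
    pm_n <- base
    for (key in drop_keys) {
      w <- weight(key, combo)
      ans_n <- ans_n - w; rm_n <- rm_n - w; pm_n <- pm_n - w
    }
    ans_n <- ans_n + length(spur_keys)
    if (combo$span_mode == "strict") {
      for (key in within_keys) {
        w <- weight(key, combo)
        rm_n <- rm_n - w; pm_n <- pm_n - w
      }
    }
    for (key in c(beyond_keys, swap_keys)) {
      w <- weight(key, combo)
      rm_n <- rm_n - w; pm_n <- pm_n - w
    }
    for (key in theme_keys) {
      if (combo$decomposition) {
        # the dropped Theme unit disappears from the answer side entirely;
        # the remaining units all still match
        ans_n <- ans_n - 1L; rm_n <- rm_n - 1L; pm_n <- pm_n - 1L
      } else {
        rm_n <- rm_n - 1L; pm_n <- pm_n - 1L
      }
    }
    d_nest <- if (combo$recursive_mode == "strict") 2L else 1L
    rm_n <- rm_n - d_nest * length(nest_keys)
    pm_n <- pm_n - d_nest * length(nest_keys)
    data.frame(combo, gold = gold_n, answer = ans_n, recall_matched = rm_n,
               precision_matched = pm_n, stringsAsFactors = FALSE)
  }))
  rownames(ev_expected) <- NULL

  n_mods <- sum(vapply(gold, function(d) length(d$modifications), numeric(1)))
  mods_expected <- data.frame(
    gold = n_mods, answer = n_mods - length(mod_keys),
    recall_matched = n_mods - length(mod_keys),
    precision_matched = n_mods - length(mod_keys))

  n_links <- sum(vapply(gold, function(d) length(d$coref_relations),
                        numeric(1)))
  surface_expected <- data.frame(
    gold = n_links,
    answer = n_links - length(drop_link_keys),
    recall_matched = n_links - length(drop_link_keys) - length(wrong_keys),
    precision_matched = n_links - length(drop_link_keys) - length(wrong_keys))

  n_plinks <- 0L
  for (id in names(gold)) {
    for (ch in chains[[id]]) {
      n_plinks <- n_plinks + length(ch$proteins) * length(ch$anaphors)
    }
  }
  protein_expected <- data.frame(
    gold = n_plinks,
    answer = n_plinks - removed_protein_links,
    recall_matched = n_plinks - removed_protein_links,
    precision_matched = n_plinks - removed_protein_links)

  list(pred = structure(pred, class = c("standoff_corpus", "list")),
       expected = list(events = ev_expected,
                       modifications = mods_expected,
                       surface = surface_expected,
                       protein = protein_expected))
}
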