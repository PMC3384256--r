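# Standoff annotation input/output.
#
# Annotations live in files separate from the document text and reference
# it by character offsets.  Offsets are 0-based and end-exclusive: the span
# (275, 278) covers the 276th through 278th characters of the text.  Four
# record kinds are supported:
#
#   T<id>  text-bound annotation: a typed character span (a protein, an
#          event trigger, a generic Entity, or a coreference markable
#          "Exp", the latter optionally carrying a minimal/head span)
#   E<id>  event: a type, a trigger text-bound, and role-labelled
#          arguments that may reference text-bounds or other events
#   M<id>  event modification: Negation or Speculation over an event
#   R<id>  coreference relation: anaphora -> antecedent, optionally with
#          the protein mentions embedded in the antecedent

new_text_bound <- function(id, type, beg, end, text = NA_character_,
                           min_beg = NA_integer_, min_end = NA_integer_,
                           min_text = NA_character_) {
  list(id = id, type = type, beg = as.integer(beg), end = as.integer(end),
       text = text, min_beg = as.integer(min_beg),
       min_end = as.integer(min_end), min_text = min_text)
}

new_event <- function(id, type, trigger, args = empty_args()) {
  list(id = id, type = type, trigger = trigger, args = args)
}

empty_args <- function() {
  data.frame(role = character(0), target = character(0),
             stringsAsFactors = FALSE)
}

event_args <- function(roles, targets) {
  data.frame(role = normalize_role(roles), target = targets,
             stringsAsFactors = FALSE)
}

#' Normalize numbered argument roles
#'
#' Multi-argument events may carry numbered roles (`Theme2`, `Site3`, ...)
#' to keep argument slots distinct in the flat file format.  Numbering has
#' no order semantics for evaluation, so roles are normalized to their base
#' name and argument collections are treated as multisets.
#'
#' @param role character vector of role labels.
#' @return character vector of base role labels.
#' @export
normalize_role <- function(role) {
  sub("^([A-Za-z]+)[0-9]+$", "\\1", role)
}

as_offset <- function(x, line) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v) || v < 0) {
    stop("malformed offset '", x, "' in line: ", line, call. = FALSE)
  }
  v
}

parse_tb_line <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) >= 2) {
    id <- fields[1]
    meta <- strsplit(trimws(fields[2]), " +")[[1]]
    if (length(meta) < 3) {
      stop("malformed text-bound line: ", line, call. = FALSE)
    }
    type <- meta[1]
    beg <- as_offset(meta[2], line)
    end <- as_offset(meta[3], line)
    txt <- if (length(fields) >= 3 && nzchar(fields[3])) fields[3] else NA_character_
    min_beg <- min_end <- NA_integer_
    min_text <- NA_character_
    if (length(fields) >= 4 && grepl("^[0-9]+ [0-9]+$", fields[4])) {
      mm <- strsplit(fields[4], " ", fixed = TRUE)[[1]]
      min_beg <- as_offset(mm[1], line)
      min_end <- as_offset(mm[2], line)
      if (length(fields) >= 5 && nzchar(fields[5])) min_text <- fields[5]
    }
    return(new_text_bound(id, type, beg, end, txt, min_beg, min_end, min_text))
  }
  # single-line space-delimited dialect: "T4 Protein 275 278 p65" or, for
  # coreference markables, a two-offset-pair form carrying the full span,
  # its text, the minimal (head) span and the head text:
  # "T27 Exp 179 222 the NF-kappa B transcription factor complex 215 222 complex"
  toks <- strsplit(trimws(line), " +")[[1]]
  if (length(toks) < 4) stop("malformed text-bound line: ", line, call. = FALSE)
  id <- toks[1]
  type <- toks[2]
  beg <- as_offset(toks[3], line)
  end <- as_offset(toks[4], line)
  rest <- if (length(toks) > 4) paste(toks[-(1:4)], collapse = " ") else ""
  txt <- if (nzchar(rest)) rest else NA_character_
  min_beg <- min_end <- NA_integer_
  min_text <- NA_character_
  m <- regexec("^(.*[^ ]) ([0-9]+) ([0-9]+) ([^ ].*)$", rest)[[1]]
  if (m[1] != -1L) {
    parts <- regmatches(rest, list(m))[[1]]
    mb <- as.integer(parts[3])
    me <- as.integer(parts[4])
    # accept the two-pair reading only when it forms a span nested in the
    # full span; otherwise the trailing digits belong to the surface text
    if (!is.na(mb) && !is.na(me) && mb < me && mb >= beg && me <= end) {
      txt <- parts[2]
      min_beg <- mb
      min_end <- me
      min_text <- parts[5]
    }
  }
  new_text_bound(id, type, beg, end, txt, min_beg, min_end, min_text)
}

parse_event_line <- function(line) {
  toks <- strsplit(trimws(gsub("\t", " ", line, fixed = TRUE)), " +")[[1]]
  if (length(toks) < 2) stop("malformed event line: ", line, call. = FALSE)
  id <- toks[1]
  tt <- strsplit(toks[2], ":", fixed = TRUE)[[1]]
  if (length(tt) != 2) {
    stop("malformed event type:trigger field in line: ", line, call. = FALSE)
  }
  roles <- character(0)
  targets <- character(0)
  for (tok in toks[-(1:2)]) {
    rt <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(rt) != 2) {
      stop("malformed argument '", tok, "' in line: ", line, call. = FALSE)
    }
    roles <- c(roles, rt[1])
    targets <- c(targets, rt[2])
  }
  new_event(id, tt[1], tt[2], event_args(roles, targets))
}

parse_mod_line <- function(line) {
  toks <- strsplit(trimws(gsub("\t", " ", line, fixed = TRUE)), " +")[[1]]
  if (length(toks) != 3) stop("malformed modification line: ", line, call. = FALSE)
  if (!toks[2] %in% c("Negation", "Speculation")) {
    stop("unknown modification type in line: ", line, call. = FALSE)
  }
  list(id = toks[1], type = toks[2], event = toks[3])
}

parse_rel_line <- function(line) {
  norm <- trimws(gsub("\t", " ", line, fixed = TRUE))
  m <- regexec(
    "^([^ ]+) +Coref +Ana:([^ ]+) +Ant:([^ ]+)( +\\[([^]]*)\\])? *$", norm)[[1]]
  if (m[1] == -1L) stop("malformed coreference relation line: ", line, call. = FALSE)
  parts <- regmatches(norm, list(m))[[1]]
  proteins <- character(0)
  if (length(parts) >= 6 && nzchar(parts[6])) {
    proteins <- trimws(strsplit(parts[6], ",", fixed = TRUE)[[1]])
    proteins <- proteins[nzchar(proteins)]
  }
  list(id = parts[2], anaphora = parts[3], antecedent = parts[4],
       proteins = proteins)
}

#' Parse a standoff-annotated document
#'
#' Reads tab- or space-delimited standoff records (`T`/`E`/`M`/`R` lines)
#' into a validated document object.  Coreference markable lines may carry
#' either a single span or the two-offset-pair form (full span, surface
#' text, minimal span, head text); when no minimal span is given it
#' defaults to the full span at match time.
#'
#' @param text the document text, or `NULL` when only the annotation
#'   structure is available (offset-vs-text consistency checks are then
#'   skipped).
#' @param annotation_lines character vector of standoff records.
#' @param doc_id document identifier.
#' @param section_label optional section tag for the document
#'   (e.g. `"TIAB"`, `"Intro"`, `"R/D/C"`, `"Methods"`, `"Caption"`).
#' @return an object of class `standoff_document` with components
#'   `doc_id`, `text`, `text_bounds`, `events`, `modifications`,
#'   `coref_relations`, `section_label`.
#' @seealso [serialize_document()], [read_corpus()]
#' @examples
#' doc <- parse_document(
#'   text = NULL,
#'   annotation_lines = c(
#'     "T1\tProtein 15 18\tp65",
#'     "T2\tLocalization 19 32\ttranslocation",
#'     "E1\tLocalization:T2 Theme:T1"))
#' names(doc$events)
#' @export
parse_document <- function(text = NULL, annotation_lines = character(),
                           doc_id = "doc", section_label = NA_character_) {
  tbs <- list()
  evs <- list()
  mods <- list()
  rels <- list()
  seen <- character(0)
  for (raw in annotation_lines) {
    line <- sub("[\r\n]+$", "", raw)
    if (!nzchar(trimws(line))) next
    id <- sub("^([^ \t]+).*$", "\\1", line)
    if (id %in% seen) {
      stop("duplicate annotation identifier '", id, "' in line: ", line,
           call. = FALSE)
    }
    seen <- c(seen, id)
    kind <- substr(id, 1, 1)
    if (kind == "T") {
      tbs[[id]] <- parse_tb_line(line)
    } else if (kind == "E") {
      evs[[id]] <- parse_event_line(line)
    } else if (kind == "M") {
      mods[[id]] <- parse_mod_line(line)
    } else if (kind == "R") {
      rels[[id]] <- parse_rel_line(line)
    } else {
      stop("unknown annotation line kind: ", line, call. = FALSE)
    }
  }
  doc <- structure(
    list(doc_id = doc_id, text = text, text_bounds = tbs, events = evs,
         modifications = mods, coref_relations = rels,
         section_label = section_label),
    class = "standoff_document")
  validate_document(doc)
  doc
}

validate_document <- function(doc) {
  n <- if (!is.null(doc$text)) nchar(doc$text) else NA_integer_
  for (tb in doc$text_bounds) {
    if (tb$beg < 0 || tb$beg >= tb$end) {
      stop("invalid span [", tb$beg, ",", tb$end, ") for ", tb$id, call. = FALSE)
    }
    if (!is.na(n) && tb$end > n) {
      stop("span of ", tb$id, " exceeds document length ", n, call. = FALSE)
    }
    if (!is.na(n) && !is.na(tb$text)) {
      got <- substring(doc$text, tb$beg + 1L, tb$end)
      if (got != tb$text) {
        stop("span/text mismatch for ", tb$id, ": annotation says '",
             tb$text, "' but document has '", got, "'", call. = FALSE)
      }
    }
    if (!is.na(tb$min_beg)) {
      if (tb$min_beg < tb$beg || tb$min_end > tb$end || tb$min_beg >= tb$min_end) {
        stop("minimal span of ", tb$id, " not contained in its span", call. = FALSE)
      }
      if (!is.na(n) && !is.na(tb$min_text)) {
        got <- substring(doc$text, tb$min_beg + 1L, tb$min_end)
        if (got != tb$min_text) {
          stop("minimal span/text mismatch for ", tb$id, call. = FALSE)
        }
      }
    }
  }
  tb_ids <- names(doc$text_bounds)
  ev_ids <- names(doc$events)
  for (ev in doc$events) {
    if (!ev$trigger %in% tb_ids) {
      stop("dangling trigger reference ", ev$trigger, " in event ", ev$id,
           call. = FALSE)
    }
    if (doc$text_bounds[[ev$trigger]]$type != ev$type) {
      stop("trigger ", ev$trigger, " of event ", ev$id,
           " is typed ", doc$text_bounds[[ev$trigger]]$type,
           " but the event is typed ", ev$type, call. = FALSE)
    }
    for (tgt in ev$args$target) {
      if (!tgt %in% tb_ids && !tgt %in% ev_ids) {
        stop("dangling argument reference ", tgt, " in event ", ev$id,
             call. = FALSE)
      }
    }
  }
  check_event_acyclicity(doc)
  for (mod in doc$modifications) {
    if (!mod$event %in% ev_ids) {
      stop("dangling event reference ", mod$event, " in modification ",
           mod$id, call. = FALSE)
    }
  }
  for (rel in doc$coref_relations) {
    if (rel$anaphora == rel$antecedent) {
      stop("relation ", rel$id, " links an expression to itself", call. = FALSE)
    }
    for (ref in c(rel$anaphora, rel$antecedent, rel$proteins)) {
      if (!ref %in% tb_ids) {
        stop("dangling reference ", ref, " in relation ", rel$id, call. = FALSE)
      }
    }
    ant <- doc$text_bounds[[rel$antecedent]]
    for (p in rel$proteins) {
      ptb <- doc$text_bounds[[p]]
      if (ptb$beg < ant$beg || ptb$end > ant$end) {
        stop("protein ", p, " listed in relation ", rel$id,
             " lies outside the antecedent span", call. = FALSE)
      }
    }
  }
  invisible(doc)
}

check_event_acyclicity <- function(doc) {
  ev_ids <- names(doc$events)
  state <- stats::setNames(rep(0L, length(ev_ids)), ev_ids)  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) {
      stop("cyclic event reference involving ", id, call. = FALSE)
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (tgt in doc$events[[id]]$args$target) {
      if (tgt %in% ev_ids) visit(tgt)
    }
    state[[id]] <<- 2L
    invisible()
  }
  for (id in ev_ids) visit(id)
  invisible(doc)
}

#' Serialize a document to standoff records
#'
#' Emits tab-delimited standoff lines; [parse_document()] applied to the
#' result reproduces the document (round-trip identity up to line order).
#'
#' @param doc a `standoff_document`.
#' @return character vector of annotation lines.
#' @export
serialize_document <- function(doc) {
  lines <- character(0)
  for (tb in doc$text_bounds) {
    l <- paste0(tb$id, "\t", tb$type, " ", tb$beg, " ", tb$end)
    if (!is.na(tb$min_beg)) {
      l <- paste0(l, "\t", if (is.na(tb$text)) "" else tb$text,
                  "\t", tb$min_beg, " ", tb$min_end)
      if (!is.na(tb$min_text)) l <- paste0(l, "\t", tb$min_text)
    } else if (!is.na(tb$text)) {
      l <- paste0(l, "\t", tb$text)
    }
    lines <- c(lines, l)
  }
  for (ev in doc$events) {
    l <- paste0(ev$id, "\t", ev$type, ":", ev$trigger)
    if (nrow(ev$args) > 0) {
      l <- paste(l, paste(paste0(ev$args$role, ":", ev$args$target),
                          collapse = " "))
    }
    lines <- c(lines, l)
  }
  for (mod in doc$modifications) {
    lines <- c(lines, paste0(mod$id, "\t", mod$type, " ", mod$event))
  }
  for (rel in doc$coref_relations) {
    l <- paste0(rel$id, "\tCoref Ana:", rel$anaphora, " Ant:", rel$antecedent)
    if (length(rel$proteins) > 0) {
      l <- paste0(l, " [", paste(rel$proteins, collapse = ", "), "]")
    }
    lines <- c(lines, l)
  }
  lines
}

#' Check events against the event-type schema
#'
#' Verifies the role constraints of the nine-type event typology: simple
#' types (Gene_expression, Transcription, Protein_catabolism,
#' Phosphorylation, Localization) take exactly one protein Theme; Binding
#' takes one or more protein Themes; the Regulation family takes at most
#' one Theme and one Cause, each a protein or an event.  Secondary roles
#' are checked against the types that permit them (Site for
#' Phosphorylation/Binding/Regulation family, CSite for the Regulation
#' family, AtLoc/ToLoc for Localization).
#'
#' Schema conformance is deliberately not enforced at parse time: system
#' predictions may be structurally valid yet schema-violating (for
#' instance a Binding with a dropped Theme) and must still be scorable.
#'
#' @param doc a `standoff_document`.
#' @return character vector of violation messages (empty when conformant).
#' @export
validate_event_schema <- function(doc) {
  bad <- character(0)
  note <- function(...) bad <<- c(bad, paste0(...))
  allowed_secondary <- list(
    Gene_expression = character(0), Transcription = character(0),
    Protein_catabolism = character(0), Phosphorylation = "Site",
    Localization = c("AtLoc", "ToLoc"), Binding = "Site",
    Regulation = c("Site", "CSite"), Positive_regulation = c("Site", "CSite"),
    Negative_regulation = c("Site", "CSite"))
  for (ev in doc$events) {
    if (!ev$type %in% EVENT_TYPES) {
      note(ev$id, ": unknown event type ", ev$type)
      next
    }
    args <- ev$args
    themes <- args[args$role == "Theme", , drop = FALSE]
    causes <- args[args$role == "Cause", , drop = FALSE]
    second <- args[args$role %in% SECONDARY_ROLES, , drop = FALSE]
    other <- args[!args$role %in% c(PRIMARY_ROLES, SECONDARY_ROLES), , drop = FALSE]
    if (nrow(other) > 0) {
      note(ev$id, ": roles not in the typology: ",
           paste(unique(other$role), collapse = ", "))
    }
    is_protein <- function(tgt) {
      tb <- doc$text_bounds[[tgt]]
      !is.null(tb) && tb$type == "Protein"
    }
    is_event <- function(tgt) tgt %in% names(doc$events)
    if (ev$type %in% SIMPLE_TYPES) {
      if (nrow(themes) != 1) note(ev$id, ": simple event needs exactly one Theme")
      if (nrow(causes) > 0) note(ev$id, ": simple event takes no Cause")
      if (nrow(themes) >= 1 && !all(vapply(themes$target, is_protein, logical(1)))) {
        note(ev$id, ": Theme of a simple event must be a Protein")
      }
    } else if (ev$type == "Binding") {
      if (nrow(themes) < 1) note(ev$id, ": Binding needs at least one Theme")
      if (nrow(causes) > 0) note(ev$id, ": Binding takes no Cause")
      if (!all(vapply(themes$target, is_protein, logical(1)))) {
        note(ev$id, ": Binding Themes must be Proteins")
      }
    } else {
      if (nrow(themes) > 1) note(ev$id, ": at most one Theme allowed")
      if (nrow(causes) > 1) note(ev$id, ": at most one Cause allowed")
      for (tgt in c(themes$target, causes$target)) {
        if (!is_protein(tgt) && !is_event(tgt)) {
          note(ev$id, ": primary argument ", tgt,
               " is neither a Protein nor an event")
        }
      }
    }
    bad_sec <- setdiff(unique(second$role), allowed_secondary[[ev$type]])
    if (length(bad_sec) > 0) {
      note(ev$id, ": secondary roles not permitted for ", ev$type, ": ",
           paste(bad_sec, collapse = ", "))
    }
  }
  bad
}

#' @export
print.standoff_document <- function(x, ...) {
  cat("<standoff_document> ", x$doc_id,
      if (!is.na(x$section_label)) paste0(" [", x$section_label, "]") else "",
      "\n", sep = "")
  cat("  text:        ",
      if (is.null(x$text)) "(absent)" else paste0(nchar(x$text), " chars"),
      "\n", sep = "")
  cat("  text-bounds: ", length(x$text_bounds),
      "  events: ", length(x$events),
      "  modifications: ", length(x$modifications),
      "  coref relations: ", length(x$coref_relations), "\n", sep = "")
  invisible(x)
}

as_corpus <- function(x) {
  if (inherits(x, "standoff_document")) {
    x <- stats::setNames(list(x), x$doc_id)
  }
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "standoff_document"))) {
    stop("expected a standoff_document or a list of them", call. = FALSE)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- vapply(x, function(d) d$doc_id, character(1))
  }
  x
}

#' Read a standoff corpus from a directory
#'
#' Pairs every `<id>.txt` file with its annotation files: `<id>.a1`
#' (given annotations, conventionally the proteins) and `<id>.a2`
#' (target annotations: triggers, entities, events, modifications and
#' coreference relations).  Either annotation file may be absent.
#'
#' @param dir directory containing the corpus.
#' @param section_labels optional named character vector mapping document
#'   ids to section labels.
#' @return named list of `standoff_document` objects.
#' @export
read_corpus <- function(dir, section_labels = NULL) {
  txts <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(txts) == 0) stop("no .txt files found in ", dir, call. = FALSE)
  docs <- list()
  for (txt in sort(txts)) {
    id <- sub("\\.txt$", "", basename(txt))
    text <- paste(readLines(txt, warn = FALSE), collapse = "\n")
    ann <- character(0)
    for (ext in c(".a1", ".a2")) {
      f <- file.path(dir, paste0(id, ext))
      if (file.exists(f)) ann <- c(ann, readLines(f, warn = FALSE))
    }
    lab <- if (!is.null(section_labels) && id %in% names(section_labels)) {
      section_labels[[id]]
    } else NA_character_
    docs[[id]] <- parse_document(text, ann, doc_id = id, section_label = lab)
  }
  docs
}

#' Write a standoff corpus to a directory
#'
#' Inverse of [read_corpus()]: writes `<id>.txt`, `<id>.a1` (Protein
#' text-bounds) and `<id>.a2` (all remaining annotations) per document.
#'
#' @param corpus a `standoff_document` or list of them.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  corpus <- as_corpus(corpus)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    writeLines(doc$text %||% "", file.path(dir, paste0(doc$doc_id, ".txt")))
    lines <- serialize_document(doc)
    is_a1 <- vapply(lines, function(l) {
      id <- sub("^([^\t ]+).*$", "\\1", l)
      startsWith(id, "T") && !is.null(doc$text_bounds[[id]]) &&
        doc$text_bounds[[id]]$type == "Protein"
    }, logical(1))
    writeLines(lines[is_a1], file.path(dir, paste0(doc$doc_id, ".a1")))
    writeLines(lines[!is_a1], file.path(dir, paste0(doc$doc_id, ".a2")))
  }
  invisible(dir)
}
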