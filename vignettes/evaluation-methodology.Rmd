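---
title: "Scoring event extraction and protein coreference from standoff annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring event extraction and protein coreference from standoff annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standoffeval)
```

## The evaluation problem

Fine-grained biomedical information extraction systems predict *events*:
typed n-ary relations such as "p65 is translocated to the nucleus" or
"IkBa inhibits the expression of p50", anchored to the text by a trigger
expression and role-labelled arguments.  Nine event types are scored.
Five *simple* types (Gene_expression, Transcription, Protein_catabolism,
Phosphorylation, Localization) take a single protein Theme; Binding takes
one or more protein Themes; and the three Regulation-family types take a
Theme and optionally a Cause, either of which may itself be an event, so
predictions form recursive structures.  Site, CSite, AtLoc and ToLoc are
*secondary* arguments that further specify an event.

Annotation lives in standoff records that reference the text by 0-based,
end-exclusive character offsets:

```{r}
doc <- parse_document(
  text = "the failure of p65 translocation to the nuclei.",
  annotation_lines = c(
    "T1 Protein 15 18 p65",
    "T2 Localization 19 32 translocation",
    "T3 Entity 40 46 nuclei",
    "E1 Localization:T2 Theme:T1 ToLoc:T3",
    "M1 Negation E1"))
doc
```

Deciding whether a predicted event "equals" a gold event is the core of
the evaluation, and there is no single right answer: exact span equality
punishes harmless boundary disagreements, and full recursive equality
makes a deeply nested prediction fail for a defect in a remote corner of
its argument structure.  The package therefore implements a family of
equality criteria that are composed into evaluation modes.

## The matching calculus

Two events match when their types are equal, their triggers match as
text entities (same type, same span), and a *perfect one-to-one
correspondence* pairs their arguments with equal roles and equal targets.
Text-bound targets are compared by text-entity equality; event targets
are compared by the same event criterion, recursively.  The
correspondence is found as a maximum matching of the bipartite
compatibility graph between the two argument multisets (Kuhn's
augmenting-path search); the test suite checks this search against an
exhaustive permutation oracle for argument sets of up to six slots.

Three relaxations can be switched on via `match_config()`:

* **Approximate span matching.**  A predicted span matches a gold span
  when it is entirely contained in the gold span extended by one word to
  the left and one to the right (`extend_span()`).  "Word" here is a
  maximal run of characters that are neither whitespace nor punctuation;
  the extension snaps to the nearest enclosing word boundaries and stays
  at the gold boundary where no adjacent word exists.  The original
  evaluations do not publish their tokenizer, so this definition is a
  documented choice of this package; spans in real corpora almost always
  start and end on word boundaries, where any reasonable tokenizer
  agrees.  The relaxation applies to all text entities — triggers,
  protein arguments and secondary-argument entities alike.
* **Approximate recursive matching.**  An event appearing in *argument
  position* is matched by a relaxed criterion: same type, matching
  trigger, and matching Theme arguments only, applied recursively; its
  non-Theme arguments are ignored.  The top-level event's own argument
  set must still fully match.  In mixed configurations the trigger of a
  referred event follows the span mode in force, since triggers are text
  entities like any other.
* **Event decomposition.**  Every event with two or more arguments is
  split into single-argument events sharing the trigger and type, on
  both the gold and the predicted side, and the resulting units are
  scored as separate events.  A unit may still reference an original
  multi-argument event as its argument; that reference is resolved
  against the original frame, so decomposition changes the scoring
  population, not the meaning of nested references.  Decomposition
  composes freely with the other modes.

Task levels select the arguments in scope: level 1 (core extraction)
strips secondary arguments from both sides before matching, level 2
retains them.  `score_task2()` scores each gold secondary argument as its
own unit, crediting it when a predicted event matching the host under
task-1 criteria carries an equal secondary argument; `score_task3()`
scores Negation/Speculation modifications the same way.

Counting is existence-based and directional: a gold item is
recall-matched when at least one predicted item matches it, a predicted
item is precision-matched when at least one gold item matches it, and
group rows (Simple Event, Binding, Regulation, All) micro-average the
raw counts, so every row obeys `recall = 100 * matched / gold` exactly.
Duplicate identical predictions therefore inflate the answer count but
never recall.  A category with no answers reports precision 0; empty
categories are zero-filled rather than omitted.  F-scores are harmonic
means, reported at two decimals (one decimal for the compact coreference
tables) with ties rounded away from zero — `round_half_up()` reproduces
the published figures, which banker's rounding would not.

## Coreference scoring

Coreference is annotated as anaphora → antecedent relations between
expressions (markables), each with a maximal span and a minimal (head)
span.  The *surface* mode scores those links directly; a response
expression is accepted when it covers the gold head and stays inside the
gold maximal span.  The *protein* mode — the primary perspective,
because it measures what the links contribute to protein-level
extraction — traces each chain of links until an antecedent embedding a
protein name is found and emits one (anaphora, protein) link per
embedded protein:

```{r}
doc <- parse_document(NULL, c(
  "T4 Protein 275 278 p65", "T5 Protein 294 297 p50",
  "T10 Protein 879 882 p65",
  "T28 Exp 264 297 ante", "T29 Exp 307 312 which",
  "T31 Exp 868 882 ante", "T32 Exp 1022 1047 this",
  "T33 Exp 1100 1110 that",
  "R1 Coref Ana:T29 Ant:T28 [T5, T4]",
  "R3 Coref Ana:T32 Ant:T31 [T10]",
  "R4 Coref Ana:T33 Ant:T32"))
build_protein_links(doc)
```

T33 reaches T10 through the intermediate antecedent T32.  Tracing is
depth-first with a visited set, so cyclic annotation terminates (with a
warning) instead of looping; the trace stops at the *first*
protein-embedding antecedent — proteins further down the chain are not
accumulated.  The bracketed protein list on a relation line is trusted
when present and recomputed from span containment when absent.  When one
response anaphor matches several gold anaphors under the partial
criterion, it is paired with the gold anaphor of largest span overlap
(earliest offset on ties); the annotation scheme gives no disambiguation
rule, so this is a documented package choice.  Anaphora-type breakdowns
(`score_by_anaphora_type()`) consume labels from an external table and
never infer them linguistically.

## The synthetic corpus generator

`generate_gold()` builds deterministic, schema-valid corpora from a
small vocabulary of gene-symbol-like tokens and trigger nominalizations.
Defaults describe a small abstract-like collection: four documents of
8–12 events; a type mix dominated by gene expression (20%) and positive
regulation (24%) with protein catabolism rare (2%), mirroring the
frequencies typical of molecular-biology event corpora; regulation
Themes nesting other events with probability 0.4; secondary arguments on
25% of eligible events; negation and speculation rates of 8% and 5%; and
two to four coreference chains per document, one to three anaphors long,
whose antecedent noun phrase embeds protein mentions 60% of the time.

The layout is engineered for exactness, not linguistic realism: any two
annotated spans from different statements are separated by at least two
words, so the one-word extension of approximate span matching can never
bridge distinct annotations.  That makes every injected error's effect
computable in closed form.  `perturb_corpus()` applies an
`error_budget()` to a predicted copy — dropped and spurious events, span
shifts within and beyond one word, type swaps, Theme drops on multi-Theme
Bindings, Cause retargets on nested events (the operation that separates
strict from approximate recursive matching while remaining visible at
both task levels, which a Site perturbation would not be, since task 1
strips Sites before matching), dropped modifications, and redirected or
dropped chain-tail coreference links — and returns the expected
gold/answer/matched counts for all sixteen combinations of task level,
span mode, recursive mode and decomposition, derived purely from
bookkeeping.  Operations target disjoint annotations so effects are
additive; a budget without enough eligible targets is refused rather
than approximated.

```{r}
gold <- generate_gold(fixture_params(seed = 42))
pb <- perturb_corpus(gold, error_budget(drop_events = 2,
                                        span_shift_within_word = 1),
                     seed = 1)
rep <- score_task1(gold, pb$pred, match_config("strict", "strict"))
rep[rep$category == "All", ]
```

Passing these fixture tests shows that the scorers implement the
matching calculus exactly as specified.  It does not show robustness to
phenomena the generator omits: real trigger spans that cross
tokenization quirks, discontinuous mentions, equivalence annotations, or
prediction errors correlated across events.  Scores on real system
output depend on those phenomena too.

## Numerical and degenerate-input choices

* Offsets are validated at parse time (0 ≤ beg < end ≤ document length,
  text agreement when the text is available); duplicate identifiers,
  dangling references and cyclic event structures are hard errors naming
  the offending line.  Typology conformance is deliberately *not*
  enforced at parse time — system predictions may be schema-violating
  yet must be scorable — and is available separately as
  `validate_event_schema()`.
* Markable lines are accepted in both the single-span and the
  two-offset-pair dialect (full span, text, minimal span, head text);
  the two-pair reading is taken only when the trailing offsets form a
  span nested in the full span, and the minimal span defaults to the
  full span when absent.  The original column layout of such lines
  cannot be pinned down from truncated printed examples, so the parser
  is permissive by design; the serializer always emits the unambiguous
  tab-delimited form.
* Scoring a category with zero gold items reports recall 0; zero
  answers report precision 0; F is 0 when recall and precision are both
  0.  Ratio helpers return `NA` on a zero denominator, and an event
  count with no triggers is an integrity error rather than a ratio.
* Word counts in corpus profiles are whitespace-delimited tokens of the
  raw text.  Published density figures depend on the original
  tokenizer, which is not recoverable, so `ratio_percent()` also accepts
  externally supplied counts.

## Problem sizes used in the test suite

The shipped tests exercise corpora of 2–6 documents (roughly 20–90
events, up to ~25 coreference links), chosen so the full sixteen-mode
recovery suite, the thousand-pair monotonicity sweep and the
permutation-oracle comparison all complete in well under a minute while
still covering every operation and mode combination.  Scores are count
ratios, so they are exact at any corpus size; nothing in the evaluators
is asymptotic.

## Known limitations

* No cluster-based coreference metrics (MUC, B³, CEAF): the scorers
  evaluate links, not entity partitions.
* No partial credit between individual events beyond what decomposition
  provides; matching is boolean per pair.
* Section-wise reporting requires documents to carry section labels; no
  section inference is attempted on raw full text.
* The generator makes no attempt at linguistic realism (see above), and
  equivalence/alias annotations are out of scope throughout.
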