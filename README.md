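# standoffeval

Scoring tools for fine-grained biomedical information extraction:
event extraction and protein coreference evaluated against gold standoff
annotation.

Systems in this field predict *bio-molecular events* — typed n-ary
relations such as "p65 is translocated to the nucleus", anchored to text
by a trigger expression and role-labelled arguments — and *coreference
links* that connect anaphoric expressions ("this transcription factor")
back to the protein mentions they stand for.  Comparing such structured
predictions to gold annotation is not a single equality test: span
boundaries, recursive event arguments and multi-argument events each
need their own notion of "close enough".  `standoffeval` is for tool
developers and shared-task organizers who need those comparisons to be
exact, reproducible and auditable.

## What it implements

* **Standoff I/O** — parsing, validation and serialization of the
  standoff dialect: text-bound records (`T`), events (`E`),
  negation/speculation modifications (`M`) and coreference relations
  (`R`), with 0-based end-exclusive character offsets and referential
  integrity checks.
* **The event-matching calculus.**  Two events are equal when their
  types are equal, their triggers are equal as text entities, and a
  perfect one-to-one correspondence pairs their arguments with equal
  roles and equal targets (recursively for event-valued arguments).
  Relaxations, combinable via `match_config()`:
  * *approximate span*: a predicted span `(beg1, end1)` matches a gold
    span when `beg1 >= ebeg2` and `end1 <= eend2`, where
    `(ebeg2, eend2)` is the gold span extended by one word to each side;
  * *approximate recursive*: an event in argument position matches on
    type, trigger and Theme arguments only;
  * *event decomposition*: every k-argument event becomes k
    single-argument events before scoring, awarding partial credit.
* **Task scoring** — core events (Task 1, secondary arguments stripped),
  secondary arguments (Task 2, per-argument units with host-event
  matching), and negation/speculation (Task 3), each reported as
  recall/precision/F per event type, per group (Simple Event, Binding,
  Regulation, All) and optionally per section.
* **Coreference scoring** — surface mode (links as annotated, with
  min/max-boundary partial markable matching) and the primary protein
  mode, which traces chains of links to direct or indirect
  protein-embedding antecedents and scores the derived
  (anaphora, protein) links.
* **Corpus statistics** — annotation counts, the densities P/W, E/W,
  E/P and the events-per-trigger coordination ratio.
* **A synthetic fixture generator** — seeded, schema-valid corpora plus
  controlled error injection (`perturb_corpus()`) that returns the
  closed-form expected scores for every evaluation mode, so the
  evaluators themselves are testable against known answers.

## Worked example

```r
library(standoffeval)

gold <- generate_gold(fixture_params(seed = 42))     # 4 docs, 42 events
pb   <- perturb_corpus(gold, error_budget(drop_events = 2,
                                          span_shift_within_word = 1),
                       seed = 1)

rep <- score_task1(gold, pb$pred, match_config("strict", "strict"))
rep[rep$level == "group", ]
#> # event scoring, span=strict, recursive=strict, task1
#>      category level gold answer                R/P/F
#>  Simple Event group   16     15    87.50/93.33/90.32
#>       Binding group    6      5   83.33/100.00/90.91
#>    Regulation group   20     20 100.00/100.00/100.00
#>           All group   42     40    92.86/97.50/95.12
```

Three of the 42 gold events go unrewarded under strict matching: the two
that were dropped from the predictions and the one whose trigger span
was widened by a word.  Answer count is 40 (42 minus the two drops), so
precision is 39/40 = 97.50.  Under the default mode — approximate span
plus approximate recursive matching — the widened trigger is forgiven
and only the drops remain:

```r
rep <- score_task1(gold, pb$pred)
rep[rep$category == "All", ]
#> # event scoring, span=approximate, recursive=approximate, task1
#>  category level gold answer              R/P/F
#>       All group   42     40 95.24/100.00/97.56
```

Coreference, primary (protein) mode — chains of anaphora→antecedent
links are traced to the protein mentions they resolve to, and the
derived links are scored:

```r
score_protein(gold, gold)
#> # protein coreference
#>  category level gold answer             R/P/F
#>   Protein group   23     23 100.0/100.0/100.0
```

## Command line

A thin wrapper around the same functions is installed at
`inst/cli/standoffeval.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/standoffeval.R", package="standoffeval"))')" \
  evaluate-events --gold gold_dir/ --pred pred_dir/ --task 1 --mode approx-recursive
```

Subcommands: `evaluate-events`, `evaluate-coref`, `stats`,
`gen-fixtures`; reports as TSV or JSON.  Corpus directories pair
`<id>.txt` with `<id>.a1` (given protein annotations) and `<id>.a2`
(events, modifications, coreference).

## Further reading

The methods vignette (`vignettes/evaluation-methodology.Rmd`) documents
the matching calculus and its relaxations, the chain-tracing rules, the
generator's design and what its fixtures do and do not demonstrate, and
the package's numerical conventions.
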