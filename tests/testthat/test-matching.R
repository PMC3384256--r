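test_that("span extension moves to adjacent word boundaries and clamps at edges", {
  text <- "the p65 subunit"
  ext <- extend_span(list(beg = 4, end = 7), text)
  expect_equal(c(ext$beg, ext$end), c(0L, 15L))
  # span at document start: no word to the left
  ext <- extend_span(list(beg = 0, end = 3), text)
  expect_equal(ext$beg, 0L)
  expect_equal(ext$end, 7L)
  # extension property over arbitrary spans
  set.seed(1)
  long <- paste(sample(c("alpha", "beta-2", "x", "gene", ",", "the"),
                       40, replace = TRUE), collapse = " ")
  for (i in 1:50) {
    beg <- sample.int(nchar(long) - 1, 1) - 1
    end <- beg + sample.int(nchar(long) - beg, 1)
    ext <- extend_span(list(beg = beg, end = end), long)
    expect_lte(ext$beg, beg)
    expect_gte(ext$end, end)
  }
})

test_that("span matching is exact in strict mode and one-word-bounded in approximate mode", {
  text <- "aa the p65 subunit bb"
  gold <- list(beg = 7, end = 10)  # "p65"
  expect_true(span_match(list(beg = 7, end = 10), gold, "strict"))
  expect_false(span_match(list(beg = 3, end = 10), gold, "strict"))
  # one flanking word on each side is tolerated
  expect_true(span_match(list(beg = 3, end = 18), gold, "approximate", text))
  # two words beyond the gold span on one side is not
  expect_false(span_match(list(beg = 0, end = 10), gold, "approximate", text))
  # strict match implies approximate match
  set.seed(2)
  for (i in 1:20) {
    b <- sample(0:15, 1); e <- b + sample.int(nchar(text) - b, 1)
    s <- list(beg = b, end = e)
    if (span_match(s, gold, "strict")) {
      expect_true(span_match(s, gold, "approximate", text))
    }
  }
})

test_that("text entity equality requires the type and tolerates spans only per mode", {
  text <- "aa the p65 subunit bb"
  gold <- list(id = "T1", type = "Protein", beg = 7, end = 10)
  same <- gold
  expect_true(text_bound_match(same, gold, "strict", text))
  wrong_type <- gold; wrong_type$type <- "Entity"
  expect_false(text_bound_match(wrong_type, gold, "strict", text))
  expect_false(text_bound_match(wrong_type, gold, "approximate", text))
  shifted <- gold; shifted$beg <- 3   # includes the preceding word
  expect_false(text_bound_match(shifted, gold, "strict", text))
  expect_true(text_bound_match(shifted, gold, "approximate", text))
})

test_that("argument matching is order-free, cardinality-strict and role-consistent", {
  doc <- parse_document(NULL, c(
    "T1 Protein 10 13 AAA",
    "T2 Protein 20 23 BBB",
    "T3 Binding 30 37 binding",
    "T4 Positive_regulation 40 49 induction",
    "E1 Binding:T3 Theme:T1 Theme:T2"))
  cfg <- match_config("strict", "strict")
  args2 <- function(roles, targets) {
    data.frame(role = roles, target = targets, stringsAsFactors = FALSE)
  }
  # Binding themes {A,B} vs {B,A}: a perfect pairing exists either way
  expect_true(arguments_match(doc, doc,
                              args2(c("Theme", "Theme"), c("T1", "T2")),
                              args2(c("Theme", "Theme"), c("T2", "T1")), cfg))
  # cardinality mismatch
  expect_false(arguments_match(doc, doc,
                               args2("Theme", "T1"),
                               args2(c("Theme", "Theme"), c("T1", "T2")), cfg))
  # role-crossed targets admit no role-consistent pairing
  expect_false(arguments_match(doc, doc,
                               args2(c("Theme", "Cause"), c("T2", "T1")),
                               args2(c("Theme", "Cause"), c("T1", "T2")), cfg))
})

test_that("argument matching agrees with exhaustive permutation search up to size 6", {
  # proteins on a grid, some adjacent so approximate span matching links
  # distinct annotations and the compatibility graph is non-trivial
  b <- tok_builder()
  lines <- character(0)
  n_prot <- 8
  for (i in seq_len(n_prot)) {
    pn <- sprintf("PR%02d", i)
    ps <- b$emit(pn)
    lines <- c(lines, span_line(paste0("T", i), "Protein", ps, pn))
    if (i %% 2 == 0) b$emit("spacer") ; b$emit(".")
  }
  doc <- parse_document(b$text(), lines)
  ids <- paste0("T", seq_len(n_prot))
  set.seed(42)
  n_checked <- 0
  for (case in 1:150) {
    n <- sample(0:6, 1)
    m <- if (runif(1) < 0.8) n else sample(0:6, 1)
    roles <- c("Theme", "Cause", "Site")
    gargs <- data.frame(role = sample(roles, n, replace = TRUE),
                        target = sample(ids, n, replace = TRUE),
                        stringsAsFactors = FALSE)
    pargs <- data.frame(role = sample(roles, m, replace = TRUE),
                        target = sample(ids, m, replace = TRUE),
                        stringsAsFactors = FALSE)
    if (runif(1) < 0.5 && n > 0 && m > 0) {
      # bias toward near-permutations so TRUE cases occur
      k <- min(n, m)
      pargs$role[1:k] <- gargs$role[sample(k)]
      pargs$target[1:k] <- gargs$target[sample(k)]
    }
    cfg <- match_config(sample(c("strict", "approximate"), 1), "strict")
    got <- arguments_match(doc, doc, pargs, gargs, cfg)
    want <- perm_oracle(doc, doc, pargs, gargs, cfg)
    expect_identical(got, want)
    n_checked <- n_checked + want
  }
  expect_gt(n_checked, 10)  # the oracle exercised both outcomes
})

test_that("task level controls whether secondary arguments count toward equality", {
  gold <- figure1_doc()
  pred <- parse_document(figure1_text, c(
    "T1 Protein 15 18 p65",
    "T2 Localization 19 32 translocation",
    "E1 Localization:T2 Theme:T1"))
  expect_true(event_match(pred, gold, "E1", "E1",
                          match_config("strict", "strict", task_level = "task1")))
  expect_false(event_match(pred, gold, "E1", "E1",
                           match_config("strict", "strict", task_level = "task2")))
  # the full representation matches at either level
  expect_true(event_match(gold, gold, "E1", "E1",
                          match_config("strict", "strict", task_level = "task2")))
})

test_that("approximate recursive matching forgives non-Theme differences in referred events", {
  b <- tok_builder()
  b$emit("Cells"); b$emit("show")
  p1 <- b$emit("STAT1")
  t1 <- b$emit("phosphorylation")
  b$emit("at")
  s1 <- b$emit("Tyr701")
  b$emit("and"); b$emit("also"); b$emit("strong")
  t2 <- b$emit("induction")
  b$emit("plus"); b$emit("another"); b$emit("site")
  s2 <- b$emit("Ser727")
  b$emit(".")
  mk <- function(site) {
    parse_document(b$text(), c(
      span_line("TP", "Protein", p1, "STAT1"),
      span_line("TT", "Phosphorylation", t1, "phosphorylation"),
      span_line("TS1", "Entity", s1, "Tyr701"),
      span_line("TS2", "Entity", s2, "Ser727"),
      span_line("TR", "Positive_regulation", t2, "induction"),
      paste0("E1\tPhosphorylation:TT Theme:TP Site:", site),
      "E2\tPositive_regulation:TR Theme:E1"))
  }
  gold <- mk("TS1")
  pred <- mk("TS2")  # the referred event differs only in its Site
  cfg <- function(rec) match_config("strict", rec, task_level = "task2")
  expect_false(event_match(pred, gold, "E2", "E2", cfg("strict")))
  expect_true(event_match(pred, gold, "E2", "E2", cfg("approximate")))
  # the referred event itself, scored at top level, must still fully match
  expect_false(event_match(pred, gold, "E1", "E1", cfg("approximate")))
  # at task level 1 the Site difference is stripped before matching
  expect_true(event_match(pred, gold, "E2", "E2",
                          match_config("strict", "strict", task_level = "task1")))
})

test_that("event matching is reflexive and symmetric in strict mode", {
  gold <- generate_gold(fixture_params(seed = 5, n_docs = 2))
  cfg <- match_config("strict", "strict")
  for (doc in gold) {
    ids <- names(doc$events)
    for (e in ids) {
      expect_true(event_match(doc, doc, e, e, cfg))
    }
    pick <- utils::head(ids, 6)
    for (a in pick) for (b in pick) {
      expect_identical(event_match(doc, doc, a, b, cfg),
                       event_match(doc, doc, b, a, cfg))
    }
  }
})

test_that("relaxation is monotone: a strict event match survives every relaxed mode", {
  gold <- generate_gold(fixture_params(seed = 8, n_docs = 2))
  pb <- perturb_corpus(gold, error_budget(span_shift_within_word = 2,
                                          nested_arg_perturbs = 1,
                                          type_swaps = 1), seed = 9)
  strict <- match_config("strict", "strict")
  relaxed <- list(match_config("approximate", "strict"),
                  match_config("strict", "approximate"),
                  match_config("approximate", "approximate"))
  for (id in names(gold)) {
    gids <- names(gold[[id]]$events)
    pids <- names(pb$pred[[id]]$events)
    for (g in gids) for (p in pids) {
      if (event_match(pb$pred[[id]], gold[[id]], p, g, strict)) {
        for (cfg in relaxed) {
          expect_true(event_match(pb$pred[[id]], gold[[id]], p, g, cfg))
        }
      }
    }
  }
})

test_that("decomposition yields one unit per argument and is idempotent", {
  doc <- parse_document(NULL, c(
    "T1 Protein 10 13 AAA",
    "T2 Protein 20 23 BBB",
    "T3 Binding 30 37 binding",
    "E1 Binding:T3 Theme:T1 Theme:T2"))
  units <- decompose_events(doc)
  expect_length(units, 2)
  expect_true(all(vapply(units, function(u) nrow(u$args) == 1, logical(1))))
  expect_true(all(vapply(units, function(u) u$trigger == "T3", logical(1))))
  expect_setequal(vapply(units, function(u) u$args$target, character(1)),
                  c("T1", "T2"))
  # single-argument events pass through unchanged; re-decomposition is identity
  expect_identical(decompose_events(units), units)
  single <- parse_document(NULL, c(
    "T1 Protein 10 13 AAA", "T2 Gene_expression 16 26 expression",
    "E1 Gene_expression:T2 Theme:T1"))
  expect_identical(decompose_events(single), single$events)
  # unit count over a generated corpus equals sum of max(1, arity)
  gold <- generate_gold(fixture_params(seed = 6, n_docs = 2))
  for (d in gold) {
    want <- sum(vapply(d$events, function(e) max(1L, nrow(e$args)), integer(1)))
    expect_length(decompose_events(d), want)
  }
})
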