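test_that("F-score arithmetic reproduces the published reporting conventions", {
  expect_equal(compute_fscore(22.2, 73.3, decimals = 1), 34.1)
  expect_equal(compute_fscore(48.62, 58.96), 53.29)
  expect_equal(compute_fscore(0, 0), 0)
  expect_equal(compute_fscore(100, 100), 100)
  # harmonic mean never exceeds the arithmetic mean
  set.seed(3)
  r <- runif(50, 0, 100); p <- runif(50, 0, 100)
  expect_true(all(compute_fscore(r, p) <= (r + p) / 2 + 1e-9))
})

test_that("scoring gold against itself yields perfect rows in every mode", {
  gold <- generate_gold(fixture_params(seed = 21, n_docs = 2))
  for (cfg in all_match_configs()) {
    rep <- score_events(gold, gold, cfg)
    present <- rep[rep$gold > 0, ]
    expect_true(all(present$recall == 100))
    expect_true(all(present$precision == 100))
    expect_true(all(present$fscore == 100))
    expect_true(all(rep[rep$gold == 0, ]$answer == 0))
  }
  t2 <- score_task2(gold, gold)
  expect_true(all(t2[t2$gold > 0, ]$fscore == 100))
  t3 <- score_task3(gold, gold)
  expect_true(all(t3[t3$gold > 0, ]$fscore == 100))
})

test_that("dropped and spurious events produce the constructed recall and precision", {
  params <- fixture_params(seed = 31, n_docs = 1, events_per_doc = c(10, 10),
                           nesting_prob = 0, secondary_arg_prob = 0,
                           negation_prob = 0, speculation_prob = 0,
                           coref_links_per_doc = c(0, 0))
  gold <- generate_gold(params)
  expect_equal(sum(vapply(gold, function(d) length(d$events), numeric(1))), 10)
  pb <- perturb_corpus(gold, error_budget(drop_events = 2,
                                          spurious_events = 1), seed = 4)
  for (cfg in all_match_configs()[c(1, 4, 8)]) {
    cfg$decomposition <- FALSE
    rep <- score_events(gold, pb$pred, cfg)
    all_row <- rep[rep$category == "All", ]
    expect_equal(all_row$gold, 10)
    expect_equal(all_row$answer, 9)
    expect_equal(all_row$recall, 80)
    expect_equal(all_row$precision, round_half_up(100 * 8 / 9, 2))
    expect_equal(round_half_up(all_row$precision, 1), 88.9)
  }
})

test_that("group rows aggregate raw counts of their member types", {
  gold <- generate_gold(fixture_params(seed = 13, n_docs = 2))
  pb <- perturb_corpus(gold, error_budget(drop_events = 2, type_swaps = 1),
                       seed = 2)
  rep <- score_events(gold, pb$pred)
  grp <- function(cat) rep[rep$category == cat & rep$level == "group", ]
  typ <- function(cats) rep[rep$category %in% cats & rep$level == "type", ]
  simple <- c("Gene_expression", "Transcription", "Protein_catabolism",
              "Phosphorylation", "Localization")
  reg <- c("Regulation", "Positive_regulation", "Negative_regulation")
  for (col in c("gold", "answer", "recall_matched", "precision_matched")) {
    expect_equal(grp("Simple Event")[[col]], sum(typ(simple)[[col]]))
    expect_equal(grp("Regulation")[[col]], sum(typ(reg)[[col]]))
    expect_equal(grp("All")[[col]],
                 sum(typ(c(simple, "Binding", reg))[[col]]))
  }
})

test_that("secondary argument scoring counts per-argument units with host matching", {
  # four phosphorylation events each with a Site; the response misses one
  # Site and puts another on the wrong entity
  b <- tok_builder()
  lines <- character(0)
  for (i in 1:4) {
    b$emit("the")
    ps <- b$emit(sprintf("KIN%02d", i))
    ts <- b$emit("phosphorylation")
    b$emit("at")
    ss <- b$emit(sprintf("Tyr%02d", i))
    b$emit(".")
    lines <- c(lines,
               span_line(paste0("TP", i), "Protein", ps, sprintf("KIN%02d", i)),
               span_line(paste0("TT", i), "Phosphorylation", ts, "phosphorylation"),
               span_line(paste0("TS", i), "Entity", ss, sprintf("Tyr%02d", i)),
               paste0("E", i, "\tPhosphorylation:TT", i,
                      " Theme:TP", i, " Site:TS", i))
  }
  gold <- parse_document(b$text(), lines, doc_id = "D")
  pred <- gold
  pred$events[["E3"]]$args$target[2] <- "TS1"     # wrong, distant entity
  pred$events[["E4"]]$args <- pred$events[["E4"]]$args[1, , drop = FALSE]
  rep <- score_task2(gold, pred)
  sites <- rep[rep$category == "Sites", ]
  expect_equal(sites$gold, 4)
  expect_equal(sites$answer, 3)
  expect_equal(sites$recall, 50)
  expect_equal(sites$precision, round_half_up(100 * 2 / 3, 2))
  phos <- rep[rep$category == "Sites/Phosphorylation", ]
  expect_equal(phos$recall_matched, 2)
  all_row <- rep[rep$category == "All", ]
  expect_equal(all_row$gold, 4)
  # the full localization example: ToLoc entity recovered
  f1 <- figure1_doc()
  rep <- score_task2(f1, f1)
  loc <- rep[rep$category == "Locations", ]
  expect_equal(c(loc$gold, loc$recall_matched), c(1, 1))
  expect_equal(loc$fscore, 100)
})

test_that("modification scoring requires a matching host event and the same type", {
  f1 <- figure1_doc()
  no_mod <- f1
  no_mod$modifications <- list()
  rep <- score_task3(f1, no_mod)
  neg <- rep[rep$category == "Negation", ]
  expect_equal(c(neg$gold, neg$answer, neg$recall_matched), c(1, 0, 0))
  expect_equal(c(neg$recall, neg$precision, neg$fscore), c(0, 0, 0))

  # five negated events; three found, one prediction on an unmatched event
  gold <- make_simple_doc(6)
  for (i in 1:5) {
    gold$modifications[[paste0("M", i)]] <-
      list(id = paste0("M", i), type = "Negation", event = paste0("E", i))
  }
  pred <- gold
  pred$modifications[c("M4", "M5")] <- NULL
  spur <- pred$events[["E6"]]
  spur$id <- "E9"
  spur$args$target <- "TP1"   # a distant protein the trigger never governs
  pred$events[["E9"]] <- spur
  pred$modifications[["M9"]] <- list(id = "M9", type = "Negation",
                                     event = "E9")
  rep <- score_task3(gold, pred)
  neg <- rep[rep$category == "Negation", ]
  expect_equal(c(neg$gold, neg$answer), c(5, 4))
  expect_equal(neg$recall, 60)
  expect_equal(neg$precision, 75)
})

test_that("relaxed modes never score below strict modes on the same input", {
  gold <- generate_gold(fixture_params(seed = 17, n_docs = 3))
  pb <- perturb_corpus(gold, error_budget(drop_events = 1,
                                          span_shift_within_word = 2,
                                          span_shift_beyond_word = 1,
                                          nested_arg_perturbs = 1,
                                          type_swaps = 1), seed = 18)
  strict <- score_events(gold, pb$pred, match_config("strict", "strict"))
  strict_all <- strict[strict$category == "All", ]
  for (cfg in list(match_config("approximate", "strict"),
                   match_config("strict", "approximate"),
                   match_config("approximate", "approximate"))) {
    rel <- score_events(gold, pb$pred, cfg)
    rel_all <- rel[rel$category == "All", ]
    expect_gte(rel_all$recall, strict_all$recall)
    expect_gte(rel_all$precision, strict_all$precision)
  }
})

test_that("a recall-matched event has all of its decomposed units recall-matched", {
  gold <- generate_gold(fixture_params(seed = 23, n_docs = 2))
  pb <- perturb_corpus(gold, error_budget(drop_events = 1, theme_drops = 1,
                                          span_shift_within_word = 1),
                       seed = 24)
  cfg <- match_config("approximate", "approximate")
  for (id in names(gold)) {
    gdoc <- gold[[id]]
    pdoc <- pb$pred[[id]]
    gdec <- decompose_doc(gdoc)
    pdec <- decompose_doc(pdoc)
    for (gid in names(gdoc$events)) {
      whole <- any(vapply(names(pdoc$events), function(pid) {
        event_match(pdoc, gdoc, pid, gid, cfg)
      }, logical(1)))
      if (!whole) next
      gunits <- names(decompose_events(gdoc$events[gid]))
      for (gu in gunits) {
        expect_true(any(vapply(pdec$unit_ids, function(pu) {
          event_match(pdec$doc, gdec$doc, pu, gu, cfg)
        }, logical(1))))
      }
    }
  }
})

test_that("document coverage mismatches are reported with the missing ids", {
  gold <- generate_gold(fixture_params(seed = 2, n_docs = 2))
  expect_error(score_task1(gold, gold[1]), "D002")
})

test_that("section labels split the report when requested", {
  gold <- generate_gold(fixture_params(seed = 19, n_docs = 4),
                        section_labels = c("TIAB", "Methods"))
  reps <- score_events(gold, gold, by_section = TRUE)
  expect_setequal(names(reps), c("All", "TIAB", "Methods"))
  tiab <- reps$TIAB[reps$TIAB$category == "All", ]
  meth <- reps$Methods[reps$Methods$category == "All", ]
  tot <- reps$All[reps$All$category == "All", ]
  expect_equal(tiab$gold + meth$gold, tot$gold)
  expect_equal(tiab$fscore, 100)
})

test_that("reports format as count columns plus an R/P/F triple", {
  gold <- make_simple_doc(3)
  pred <- gold
  pred$events[["E3"]] <- NULL
  rep <- score_task1(gold, pred)
  lines <- format_report(rep)
  all_line <- grep("^All\t", lines, value = TRUE)
  expect_match(all_line, "66\\.67/100\\.00/80\\.00$")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tmp, format = "json")
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$recall[back$category == "All"], 66.67)
})
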