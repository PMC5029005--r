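triggers <- load_trigger_lexicon()

test_that("each worked example fires exactly its rule family", {
  fx <- table1_fixtures()
  res <- classify_fixtures(fx, triggers)
  t1 <- startsWith(res$template_id, "table1")
  expect_equal(sum(t1), 12L)
  expect_true(all(res$predicted[t1] == "POS"))
  expect_equal(res$rule_id[t1],
               sub("table1_(.*?)(_fig3)?$", "\\1", res$template_id[t1]))
})

test_that("the passive verbal rule reports the verb and its preposition as triggers", {
  fx <- fixture_by_id(table1_fixtures(), "table1_V2_fig3")
  h <- unit_heads(fx)
  m <- match_verbal(fx$graph, h$plant, h$chem, triggers)
  expect_equal(m$rule_id, "V2")
  expect_equal(fx$graph$tokens$text[m$trigger_tokens], c("obtained", "from"))
  # deleting the trigger word from the passive set silences the rule
  tr2 <- trigger_lexicon(triggers$active, setdiff(triggers$passive, "obtained"),
                         triggers$intransitive, triggers$gerund)
  expect_null(match_verbal(fx$graph, h$plant, h$chem, tr2))
})

test_that("prepositions attached outside both entity phrases do not fire", {
  # "The fenamiphos treatment outperformed all controls in tobacco yield":
  # the preposition hangs on the verb, not inside either entity NP
  g <- dep_graph(
    c("The", "fenamiphos", "treatment", "outperformed", "all", "controls",
      "in", "tobacco", "yield", "."),
    c(3L, 3L, 4L, 0L, 6L, 4L, 4L, 9L, 7L, 4L),
    c("det", "nn", "nsubj", "root", "det", "dobj", "prep", "nn", "pobj",
      "punct"))
  plant <- which(g$tokens$text == "tobacco")
  chem <- which(g$tokens$text == "fenamiphos")
  expect_null(match_prepositional(g, plant, chem))
})

test_that("the gerund 'consisting' requires its object through 'of'", {
  fx <- fixture_by_id(table1_fixtures(), "table1_R2")
  h <- unit_heads(fx)
  expect_equal(match_relative(fx$graph, h$plant, h$chem, triggers)$rule_id, "R2")
  # "powder consisting parthenolide" (no "of") must not fire
  g <- dep_graph(c("Feverfew", "powder", "consisting", "parthenolide", "."),
                 c(2L, 0L, 2L, 3L, 2L),
                 c("nn", "root", "partmod", "dobj", "punct"))
  expect_null(match_relative(g, 1L, 4L, triggers))
  # ... while "consisting of parthenolide" does
  g2 <- dep_graph(c("Feverfew", "powder", "consisting", "of", "parthenolide", "."),
                  c(2L, 0L, 2L, 3L, 4L, 2L),
                  c("nn", "root", "partmod", "prep", "pobj", "punct"))
  expect_equal(match_relative(g2, 1L, 5L, triggers)$rule_id, "R2")
})

test_that("apposition matches respect the token-distance bound", {
  k <- 12L  # filler tokens between the two phrases
  g <- dep_graph(
    c("soybean", "oil", ",", rep("indeed", k), "a", "source", "of", "acids", "."),
    c(2L, 0L, 2L, rep(2L, k), 5L + k, 2L, 5L + k, 6L + k, 2L),
    c("nn", "root", "punct", rep("punct", k), "det", "appos", "prep", "pobj",
      "punct"))
  plant <- 2L
  chem <- 7L + k  # "acids"
  expect_null(match_apposition(g, plant, chem, max_dist = 10L))
  m <- match_apposition(g, plant, chem, max_dist = 20L)
  expect_equal(m$rule_id, "A1")
  # direction: chemical-first apposition reports A2
  fx <- fixture_by_id(table1_fixtures(), "table1_A2")
  h <- unit_heads(fx)
  expect_equal(match_apposition(fx$graph, h$plant, h$chem)$rule_id, "A2")
})

test_that("copula matches require both entities around the predicate", {
  fx <- fixture_by_id(table1_fixtures(), "table1_C1")
  h <- unit_heads(fx)
  m <- match_copula(fx$graph, h$plant, h$chem)
  expect_equal(m$rule_id, "C1")
  expect_equal(fx$graph$tokens$text[m$trigger_tokens], "is")
  c2 <- fixture_by_id(table1_fixtures(), "table1_C2")
  h2 <- unit_heads(c2)
  m2 <- match_copula(c2$graph, h2$plant, h2$chem)
  expect_equal(m2$rule_id, "C2")
  expect_equal(c2$graph$tokens$text[m2$trigger_tokens], "were")
  # neither entity inside the predicate subtree -> no match
  g <- dep_graph(c("That", "is", "interesting", "for", "ginger", "and",
                   "calcium", "."),
                 c(3L, 3L, 0L, 3L, 4L, 5L, 5L, 3L),
                 c("nsubj", "cop", "root", "prep", "pobj", "cc", "conj",
                   "punct"))
  # plant and chemical both in the predicate, none in the subject
  expect_null(match_copula(g, 5L, 7L))
})

test_that("compound-noun matches require plant-then-chemical with one space", {
  fx <- fixture_by_id(table1_fixtures(), "table1_CN1")
  expect_equal(match_compound(fx$graph, fx$unit$plant, fx$unit$chemical)$rule_id,
               "CN1")
  # "Aloe emodin": emodin is read as an ingredient of aloe
  m <- match_compound("Aloe emodin",
                      entity_mention("PLANT", 0L, 4L, "Aloe"),
                      entity_mention("CHEMICAL", 5L, 11L, "emodin"))
  expect_equal(m$rule_id, "CN1")
  expect_length(m$trigger_tokens, 0L)
  # chemical before plant does not fire
  expect_null(match_compound("saponins panax",
                             entity_mention("PLANT", 9L, 14L, "panax"),
                             entity_mention("CHEMICAL", 0L, 8L, "saponins")))
})

test_that("classification is pure and reports the first firing family", {
  fx <- fixture_by_id(table1_fixtures(), "table1_V2_fig3")
  r1 <- classify_unit(fx$graph, fx$unit, triggers)
  r2 <- classify_unit(fx$graph, fx$unit, triggers)
  expect_identical(r1, r2)
  expect_equal(r1$label, "POS")
  expect_equal(r1$matches[[1L]]$rule_id, "V2")
  # mention/parse misalignment is an error
  other <- fixture_by_id(table1_fixtures(), "table1_P1")
  expect_error(classify_unit(other$graph, fx$unit, triggers), "align")
})

test_that("documented error fixtures reproduce the model's failure modes", {
  fx <- table1_fixtures()
  res <- classify_fixtures(fx, triggers)
  err <- res[startsWith(res$template_id, "error_"), ]
  expect_equal(nrow(err), 4L)
  # the two semantic false positives fire the prepositional rule
  fp <- err[err$gold == "NEG", ]
  expect_equal(fp$predicted, c("POS", "POS"))
  expect_equal(fp$rule_id, c("P2", "P2"))
  # the two structural false negatives stay NEG
  fn <- err[err$gold == "POS", ]
  expect_equal(fn$predicted, c("NEG", "NEG"))
})

test_that("removing trigger words never flips a NEG prediction to POS", {
  fx <- generate_units(60, 0.6, 0, seed = 13)
  full <- classify_fixtures(fx, triggers)$predicted
  withr::with_seed(21, {
    for (rep in 1:5) {
      tr2 <- trigger_lexicon(
        setdiff(triggers$active, sample(triggers$active, 10L)),
        setdiff(triggers$passive, sample(triggers$passive, 5L)),
        triggers$intransitive,
        setdiff(triggers$gerund, sample(triggers$gerund, 4L)))
      reduced <- classify_fixtures(fx, tr2)$predicted
      expect_true(all(!(full == "NEG" & reduced == "POS")))
    }
  })
})

test_that("with empty triggers and structural families disabled everything is NEG", {
  fx <- c(table1_fixtures(), generate_units(40, 0.7, 0.1, seed = 19))
  empty <- trigger_lexicon()
  lexical_only <- c("verbal", "relative")
  res <- classify_fixtures(fx, empty, families = lexical_only)
  expect_true(all(res$predicted == "NEG"))
})
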