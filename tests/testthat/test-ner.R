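plant_fixture_lex <- function() {
  load_name_lexicon(plantchem_extdata("plants_fixture.tsv"), "PLANT")
}
chem_fixture_lex <- function() {
  load_name_lexicon(plantchem_extdata("chemicals_fixture.tsv"), "CHEMICAL")
}

test_that("dictionary matching finds the worked-example mentions", {
  s <- "Pomegranate derived from the tree Punica granatum contains anthocyanins"
  plants <- match_mentions(s, plant_fixture_lex())
  expect_equal(vapply(plants, `[[`, character(1), "text"),
               c("Pomegranate", "Punica granatum"))
  chems <- match_mentions(s, chem_fixture_lex())
  expect_equal(vapply(chems, `[[`, character(1), "text"), "anthocyanins")
  expect_equal(chems[[1L]]$ids, "MeSH:D000872")
  expect_length(match_mentions("", plant_fixture_lex()), 0L)
})

test_that("the longest term starting at a position wins", {
  lex <- name_lexicon(c("Panax", "Panax notoginseng"), "PLANT")
  got <- match_mentions("Panax notoginseng saponins", lex)
  expect_length(got, 1L)
  expect_equal(got[[1L]]$text, "Panax notoginseng")
})

test_that("matches are token-boundary anchored, with hyphens as boundaries", {
  lex <- name_lexicon(c("cinnamon", "corn"), "PLANT")
  got <- match_mentions("a cinnamon-rat model of popcorn and corner cases", lex)
  # "cinnamon" before a hyphen matches; "corn" inside "popcorn"/"corner"
  # does not
  expect_equal(vapply(got, `[[`, character(1), "text"), "cinnamon")
  expect_equal(got[[1L]]$start, 2L)
})

test_that("matching is case-insensitive and reports the sentence surface form", {
  lex <- name_lexicon("panax notoginseng", "PLANT")
  got <- match_mentions("PANAX Notoginseng extract", lex)
  expect_equal(got[[1L]]$text, "PANAX Notoginseng")
})

test_that("matcher equals the brute-force longest-match oracle on small instances", {
  lex <- name_lexicon(c("aa", "aa bb", "bb", "bb cc dd", "cc"), "PLANT")
  vocab <- c("aa", "bb", "cc", "dd", "ee")
  seps <- c(" ", "-", ", ", " x ")
  withr::with_seed(42, {
    for (rep in 1:150) {
      k <- sample(1:6, 1L)
      toks <- sample(vocab, k, replace = TRUE)
      sep <- sample(seps, max(0L, k - 1L), replace = TRUE)
      text <- paste0(toks, c(sep, ""), collapse = "")
      got <- mention_spans(match_mentions(text, lex))
      want <- brute_match_spans(text, lex)
      expect_equal(got, want, info = text)
    }
  })
})

test_that("mention recognition is deterministic", {
  s <- "Saponins from the flowers of Panax notoginseng"
  a <- match_mentions(s, plant_fixture_lex())
  b <- match_mentions(s, plant_fixture_lex())
  expect_identical(a, b)
})

test_that("annotate_abstract populates the nitrogen / masson pine sentence", {
  text <- "Effects of nitrogen on masson pine (Pinus massoniana) seedlings."
  doc <- abstract_doc("24283344", text, split_sentences(text))
  doc <- annotate_abstract(doc, plant_fixture_lex(), chem_fixture_lex())
  s <- doc$sentences[[1L]]
  expect_equal(vapply(sentence_mentions(s, "PLANT"), `[[`, character(1), "text"),
               c("masson pine", "Pinus massoniana"))
  expect_equal(vapply(sentence_mentions(s, "CHEMICAL"), `[[`, character(1), "text"),
               "nitrogen")
  # no lexicon terms -> no mentions
  empty_doc <- abstract_doc("1", "Nothing relevant here.",
                            split_sentences("Nothing relevant here."))
  empty_doc <- annotate_abstract(empty_doc, plant_fixture_lex(), chem_fixture_lex())
  expect_length(empty_doc$sentences[[1L]]$mentions, 0L)
})

test_that("cross-class overlaps keep the longer span, ties going to the plant", {
  plex <- name_lexicon(c("soybean oil", "ginger"), "PLANT")
  clex <- name_lexicon(c("oil", "ginger"), "CHEMICAL")
  text <- "Compared soybean oil with ginger extract."
  doc <- annotate_abstract(abstract_doc("2", text, split_sentences(text)),
                           plex, clex)
  ms <- doc$sentences[[1L]]$mentions
  got <- vapply(ms, function(m) paste(m$entity_class, m$text), character(1))
  expect_setequal(got, c("PLANT soybean oil", "PLANT ginger"))
})

test_that("annotation recovers exactly the mentions planted by the generator", {
  plex <- name_lexicon(vapply(plantchem:::PLANT_POOL, identity, character(1)), "PLANT")
  clex <- name_lexicon(vapply(plantchem:::CHEM_POOL, identity, character(1)), "CHEMICAL")
  fx <- generate_units(200, 0.5, 0.1, seed = 99)
  for (f in fx) {
    s <- f$unit$sentence$text
    plants <- mention_spans(match_mentions(s, plex))
    chems <- mention_spans(match_mentions(s, clex))
    expect_equal(plants, mention_spans(list(f$unit$plant)), info = s)
    expect_equal(chems, mention_spans(list(f$unit$chemical)), info = s)
  }
})
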