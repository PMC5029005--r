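test_that("abbreviations and initials do not split sentences", {
  one <- split_sentences("Dr. A. Smith studied ginger extracts.")
  expect_length(one, 1L)
  two <- split_sentences("Ginger was studied, e.g. in teas. Corn was not.")
  expect_length(two, 2L)
  expect_equal(two[[2L]]$text, "Corn was not.")
})

test_that("sentence records carry correct document offsets", {
  text <- "First sentence about ginger. Second sentence about corn!"
  got <- split_sentences(text)
  expect_length(got, 2L)
  expect_equal(got[[1L]]$doc_offset, 0L)
  expect_equal(got[[2L]]$doc_offset, 29L)
  for (s in got) {
    expect_equal(plantchem:::substr0(text, s$doc_offset,
                                     s$doc_offset + nchar(s$text)), s$text)
  }
})

test_that("splitter recovers the boundaries of concatenated generated sentences", {
  fx <- generate_units(60, 0.5, 0, seed = 17)
  texts <- vapply(fx, function(f) f$unit$sentence$text, character(1))
  withr::with_seed(4, {
    for (rep in 1:20) {
      pick <- sample(texts, sample(2:5, 1L))
      abstract <- paste(pick, collapse = " ")
      got <- split_sentences(abstract)
      expect_equal(vapply(got, `[[`, character(1), "text"), pick)
    }
  })
})

test_that("splitter output covers all non-whitespace text with disjoint spans", {
  text <- "  Leading space. Then FB1 was found. Trailing!  "
  got <- split_sentences(text)
  covered <- rep(FALSE, nchar(text))
  last_end <- -1L
  for (s in got) {
    expect_gt(s$doc_offset, last_end)
    last_end <- s$doc_offset + nchar(s$text)
    covered[(s$doc_offset + 1L):last_end] <- TRUE
  }
  chars <- strsplit(text, "")[[1L]]
  expect_true(all(covered[grepl("[^[:space:]]", chars)]))
})

test_that("co-occurrence filter equals the brute-force predicate", {
  mk <- function(n_plant, n_chem) {
    # lay out single-letter mentions p/c separated by spaces
    toks <- c(rep("p", n_plant), rep("c", n_chem))
    if (length(toks) == 0L) return(sentence_record(0L, "empty"))
    text <- paste(toks, collapse = " ")
    mentions <- lapply(seq_along(toks), function(i) {
      entity_mention(if (toks[[i]] == "p") "PLANT" else "CHEMICAL",
                     2L * (i - 1L), 2L * i - 1L, toks[[i]])
    })
    sentence_record(0L, text, mentions)
  }
  withr::with_seed(8, {
    sentences <- replicate(40, mk(sample(0:3, 1L), sample(0:3, 1L)),
                           simplify = FALSE)
  })
  kept <- find_cooccurrence(sentences)
  want <- Filter(function(s) {
    length(sentence_mentions(s, "PLANT")) >= 1L &&
      length(sentence_mentions(s, "CHEMICAL")) >= 1L
  }, sentences)
  expect_identical(kept, want)
  # a plant-only sentence is excluded
  expect_length(find_cooccurrence(list(mk(2L, 0L))), 0L)
  # 2 plants + 1 chemical is included
  expect_length(find_cooccurrence(list(mk(2L, 1L))), 1L)
})

test_that("unit expansion is the Cartesian product of plant and chemical mentions", {
  mk <- function(n_plant, n_chem) {
    toks <- c(rep("p", n_plant), rep("c", n_chem))
    text <- paste(toks, collapse = " ")
    mentions <- lapply(seq_along(toks), function(i) {
      entity_mention(if (toks[[i]] == "p") "PLANT" else "CHEMICAL",
                     2L * (i - 1L), 2L * i - 1L, toks[[i]])
    })
    sentence_record(0L, text, mentions)
  }
  for (np in 1:3) {
    for (nc in 1:3) {
      units <- expand_units(mk(np, nc))
      expect_length(units, np * nc)
    }
  }
  # ordering: plant span first, then chemical span
  units <- expand_units(mk(2L, 2L))
  starts <- t(vapply(units, function(u) c(u$plant$start, u$chemical$start),
                     integer(2)))
  expect_true(!is.unsorted(starts[, 1L]))
})

test_that("the full candidate pipeline is deterministic end to end", {
  plex <- load_name_lexicon(plantchem_extdata("plants_fixture.tsv"), "PLANT")
  clex <- load_name_lexicon(plantchem_extdata("chemicals_fixture.tsv"), "CHEMICAL")
  abstracts <- c(
    "24283344" = "Effects of nitrogen on masson pine (Pinus massoniana) seedlings. No other entities here.",
    "15493960" = "Pomegranate contains anthocyanins. Ginger was also assessed.")
  u1 <- candidate_units(abstracts, plex, clex)
  u2 <- candidate_units(abstracts, plex, clex)
  expect_identical(u1, u2)
  expect_length(u1, 3L)  # 2 pairs from the first abstract, 1 from the second
  expect_true(all(vapply(u1, `[[`, character(1), "label") == "UNLABELED"))
})

test_that("unit sampling is seeded and reproducible", {
  fx <- generate_units(30, 0.5, 0, seed = 2)
  units <- lapply(fx, `[[`, "unit")
  a <- sample_units(units, 10, seed = 123)
  b <- sample_units(units, 10, seed = 123)
  expect_identical(a, b)
  expect_length(a, 10L)
})
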