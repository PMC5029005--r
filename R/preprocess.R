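# Sentence splitting, co-occurrence filtering and expansion of sentences
# into candidate (plant, chemical) corpus units.

DEFAULT_ABBREVIATIONS <- c(
  "e.g", "i.e", "etc", "al", "vs", "ca", "cf", "approx", "fig", "figs",
  "sp", "spp", "subsp", "var", "no", "dr", "mr", "mrs", "st", "mg", "kg"
)

#' Split an abstract into sentences
#'
#' The default rule-based splitter breaks after `.`, `!` or `?` followed by
#' whitespace and an uppercase letter or digit, unless the terminator ends a
#' guarded abbreviation (e.g. "Fig.", "et al.") or a single capital-letter
#' initial ("A."). Sentence spans are ordered, disjoint and cover all
#' non-whitespace text. A different splitter can be supplied as a function
#' from abstract text to integer break positions.
#'
#' @param abstract_text Abstract string.
#' @param abbreviations Lowercased abbreviation guard list (final period
#'   excluded).
#' @param splitter Optional replacement: function taking the text and
#'   returning 0-based character positions at which new sentences start.
#' @return List of [sentence_record()] objects (without mentions).
#' @export
split_sentences <- function(abstract_text,
                            abbreviations = DEFAULT_ABBREVIATIONS,
                            splitter = NULL) {
  text <- as.character(abstract_text)
  if (!nzchar(trimws(text))) return(list())
  starts <- if (is.null(splitter)) {
    default_sentence_starts(text, abbreviations)
  } else {
    sort(unique(as.integer(splitter(text))))
  }
  n <- nchar(text)
  bounds <- c(starts, n)
  out <- list()
  for (i in seq_along(starts)) {
    lo <- bounds[[i]]; hi <- bounds[[i + 1L]]
    raw <- substr0(text, lo, hi)
    lead <- nchar(raw) - nchar(sub("^[[:space:]]+", "", raw))
    trail <- nchar(raw) - nchar(sub("[[:space:]]+$", "", raw))
    if (nchar(raw) - lead - trail <= 0L) next
    off <- lo + lead
    out[[length(out) + 1L]] <- sentence_record(off, substr0(text, off, hi - trail))
  }
  out
}

default_sentence_starts <- function(text, abbreviations) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  starts <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(".", "!", "?")) {
      j <- i + 1L
      while (j <= n && chars[[j]] %in% c(" ", "\t", "\n", "\r")) j <- j + 1L
      if (j > i + 1L && j <= n && grepl("[[:upper:][:digit:]]", chars[[j]])) {
        guarded <- FALSE
        if (ch == ".") {
          before <- substr(text, max(1L, i - 12L), i - 1L)
          word <- regmatches(before, regexpr("[[:alpha:].]+$", before))
          if (length(word) == 1L) {
            w <- tolower(sub("\\.$", "", word))
            if (w %in% abbreviations || grepl("^[A-Z]$", word)) guarded <- TRUE
          }
        }
        if (!guarded) starts <- c(starts, j - 1L)
      }
    }
    i <- i + 1L
  }
  unique(starts)
}

#' Filter for plant-chemical co-occurrence sentences
#'
#' @param sentences List of [sentence_record()] with mentions populated.
#' @return Exactly the sentences containing at least one `PLANT` and at
#'   least one `CHEMICAL` mention.
#' @export
find_cooccurrence <- function(sentences) {
  Filter(function(s) {
    length(sentence_mentions(s, "PLANT")) >= 1L &&
      length(sentence_mentions(s, "CHEMICAL")) >= 1L
  }, sentences)
}

#' Expand a co-occurrence sentence into candidate corpus units
#'
#' Forms the Cartesian product of the sentence's plant and chemical
#' mentions: one `UNLABELED` unit per (plant, chemical) pair, ordered by
#' plant span then chemical span. A sentence with `p` plants and `c`
#' chemicals therefore yields exactly `p * c` units.
#'
#' @param sentence A [sentence_record()] that passed [find_cooccurrence()].
#' @param pmid Identifier of the source abstract, carried onto the units.
#' @return List of [corpus_unit()] objects with label `UNLABELED`.
#' @export
expand_units <- function(sentence, pmid = "") {
  plants <- sentence_mentions(sentence, "PLANT")
  chems <- sentence_mentions(sentence, "CHEMICAL")
  out <- list()
  for (p in plants) {
    for (ch in chems) {
      out[[length(out) + 1L]] <- corpus_unit(sentence, p, ch, pmid = pmid)
    }
  }
  out
}

#' Run the candidate-unit pipeline over raw abstracts
#'
#' Convenience composition of [split_sentences()], [annotate_abstract()],
#' [find_cooccurrence()] and [expand_units()].
#'
#' @param abstracts Named character vector (names = PMIDs) or list of
#'   [abstract_doc()]s without sentences.
#' @inheritParams annotate_abstract
#' @return List of `UNLABELED` [corpus_unit()] objects.
#' @export
candidate_units <- function(abstracts, plant_lexicon, chemical_recognizer) {
  if (is.character(abstracts)) {
    pmids <- names(abstracts) %||% as.character(seq_along(abstracts))
    abstracts <- Map(function(p, t) abstract_doc(p, t, split_sentences(t)),
                     pmids, abstracts)
  }
  units <- list()
  for (doc in abstracts) {
    if (length(doc$sentences) == 0L) {
      doc <- abstract_doc(doc$pmid, doc$text, split_sentences(doc$text))
    }
    doc <- annotate_abstract(doc, plant_lexicon, chemical_recognizer)
    for (s in find_cooccurrence(doc$sentences)) {
      units <- c(units, expand_units(s, pmid = doc$pmid))
    }
  }
  units
}

#' Seeded random sample of corpus units
#'
#' Candidate selection for manual annotation is a curation step; this
#' utility only provides the reproducible sampling primitive and takes no
#' stance on class balance.
#'
#' @param units List of [corpus_unit()].
#' @param n Sample size (capped at `length(units)`).
#' @param seed Integer seed.
#' @return A list of `n` units.
#' @export
sample_units <- function(units, n, seed) {
  n <- min(as.integer(n), length(units))
  idx <- withr::with_seed(as.integer(seed), sample.int(length(units), n))
  units[idx]
}
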