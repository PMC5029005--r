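# Dictionary-based exact-match NER. Matching is case-insensitive,
# longest-match, left-to-right and token-boundary anchored: tokens are
# maximal alphanumeric runs, so hyphens and other punctuation act as
# boundaries and no match can start or end inside a longer alphanumeric
# word.

tokenize_alnum <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(start = start, end = end,
             text = substring(text, start + 1L, end), stringsAsFactors = FALSE)
}

term_tokens <- function(term) tolower(tokenize_alnum(term)$text)

#' Match lexicon terms in a sentence
#'
#' Scans left to right over token positions; at each position the longest
#' matching lexicon term is selected (all terms matching that same span
#' contribute their identifiers) and scanning resumes after it, so matches
#' never overlap.
#'
#' @param sentence_text Sentence string.
#' @param lexicon A [name_lexicon()].
#' @return List of [entity_mention()] objects, ordered by span start.
#' @export
match_mentions <- function(sentence_text, lexicon) {
  stopifnot(inherits(lexicon, "name_lexicon"))
  toks <- tokenize_alnum(sentence_text)
  n <- nrow(toks)
  if (n == 0L || length(lexicon$entries) == 0L) return(list())
  terms <- names(lexicon$entries)
  term_toks <- lapply(terms, term_tokens)
  low <- tolower(toks$text)
  mentions <- list()
  i <- 1L
  while (i <= n) {
    best_end_tok <- 0L
    best_ids <- character(0)
    for (t in seq_along(terms)) {
      tt <- term_toks[[t]]
      k <- length(tt)
      if (k == 0L || i + k - 1L > n) next
      if (all(low[i:(i + k - 1L)] == tt)) {
        end_tok <- i + k - 1L
        if (end_tok > best_end_tok) {
          best_end_tok <- end_tok
          best_ids <- lexicon$entries[[terms[[t]]]]
        } else if (end_tok == best_end_tok) {
          best_ids <- unique(c(best_ids, lexicon$entries[[terms[[t]]]]))
        }
      }
    }
    if (best_end_tok > 0L) {
      start <- toks$start[[i]]
      end <- toks$end[[best_end_tok]]
      if (length(best_ids) > 1L) best_ids <- setdiff(best_ids, "NA")
      mentions[[length(mentions) + 1L]] <- entity_mention(
        lexicon$entity_class, start, end, substr0(sentence_text, start, end), best_ids)
      i <- best_end_tok + 1L
    } else {
      i <- i + 1L
    }
  }
  mentions
}

#' Wrap a name lexicon as a chemical recognizer
#'
#' The chemical recognizer slot of [annotate_abstract()] is any function
#' mapping sentence text to a list of [entity_mention()]s, so external
#' chemical NER engines can be plugged in; this adapter provides the
#' default dictionary behaviour.
#'
#' @param lexicon A `CHEMICAL` [name_lexicon()].
#' @return A function `function(sentence_text) -> list of entity_mention`.
#' @export
dictionary_recognizer <- function(lexicon) {
  stopifnot(inherits(lexicon, "name_lexicon"))
  function(sentence_text) match_mentions(sentence_text, lexicon)
}

resolve_cross_class <- function(mentions) {
  # Overlaps between a plant and a chemical mention: keep the longer span;
  # ties go to the plant.
  if (length(mentions) < 2L) return(mentions)
  keep <- rep(TRUE, length(mentions))
  for (i in seq_along(mentions)) {
    for (j in seq_along(mentions)) {
      if (i >= j || !keep[i] || !keep[j]) next
      a <- mentions[[i]]; b <- mentions[[j]]
      if (a$entity_class == b$entity_class) next
      if (a$start < b$end && b$start < a$end) {
        la <- a$end - a$start; lb <- b$end - b$start
        drop <- if (la > lb) j else if (lb > la) i
          else if (a$entity_class == "PLANT") j else i
        keep[drop] <- FALSE
      }
    }
  }
  mentions[keep]
}

#' Annotate an abstract with plant and chemical mentions
#'
#' Runs the plant dictionary matcher and the chemical recognizer on every
#' sentence. Cross-class overlapping spans are resolved by preferring the
#' longer mention, with ties going to the plant. A recognizer failure on
#' one sentence leaves that sentence unannotated with a warning rather than
#' aborting the abstract.
#'
#' @param doc An [abstract_doc()] with sentences already split.
#' @param plant_lexicon A `PLANT` [name_lexicon()].
#' @param chemical_recognizer A `CHEMICAL` [name_lexicon()] or a function
#'   from sentence text to a list of mentions (see
#'   [dictionary_recognizer()]).
#' @return The document with every sentence's mentions populated.
#' @export
annotate_abstract <- function(doc, plant_lexicon, chemical_recognizer) {
  stopifnot(inherits(doc, "abstract_doc"))
  if (inherits(chemical_recognizer, "name_lexicon")) {
    chemical_recognizer <- dictionary_recognizer(chemical_recognizer)
  }
  stopifnot(is.function(chemical_recognizer))
  sentences <- lapply(doc$sentences, function(s) {
    mentions <- tryCatch({
      plants <- match_mentions(s$text, plant_lexicon)
      chems <- chemical_recognizer(s$text)
      resolve_cross_class(c(plants, chems))
    }, error = function(e) {
      warning(sprintf("recognizer failed on sentence at offset %d: %s",
                      s$doc_offset, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(mentions)) s else sentence_record(s$doc_offset, s$text, mentions)
  })
  abstract_doc(doc$pmid, doc$text, sentences)
}
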