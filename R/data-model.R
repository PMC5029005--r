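# Shared document data model: abstracts, sentences, entity mentions and
# (plant, chemical) corpus units.  All character offsets are 0-based,
# half-open; mention spans are sentence-relative.

PLANT_ID_NAMESPACES <- c("Taxonomy", "TCMID")
CHEMICAL_ID_NAMESPACES <- c("MeSH", "CHEMBL", "CAS")
UNIT_LABELS <- c("POS", "NEG", "UNLABELED")

#' Create an entity mention
#'
#' A plant or chemical name occurrence in one sentence, with its character
#' span and database identifiers.
#'
#' @param entity_class `"PLANT"` or `"CHEMICAL"`.
#' @param start,end 0-based half-open character span, sentence-relative.
#' @param text Surface string; must equal the sentence substring at the span
#'   (checked when the mention is attached to a [sentence_record()]).
#' @param ids Character vector of identifiers, each either the literal
#'   `"NA"` or `"namespace:value"`. Plant namespaces are restricted to
#'   Taxonomy and TCMID; chemical namespaces to MeSH, CHEMBL and CAS.
#' @return An object of class `entity_mention`.
#' @examples
#' entity_mention("PLANT", 0, 15, "Punica granatum", "Taxonomy:22663")
#' @export
entity_mention <- function(entity_class, start, end, text, ids = "NA") {
  entity_class <- match.arg(entity_class, c("PLANT", "CHEMICAL"))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop("mention span must be non-empty with 0 <= start < end", call. = FALSE)
  }
  text <- as.character(text)
  if (nchar(text) != end - start) {
    stop(sprintf("mention text %s has %d characters but span [%d,%d) has length %d",
                 dQuote(text), nchar(text), start, end, end - start), call. = FALSE)
  }
  ids <- validate_mention_ids(as.character(ids), entity_class)
  structure(list(entity_class = entity_class, start = start, end = end,
                 text = text, ids = ids),
            class = "entity_mention")
}

validate_mention_ids <- function(ids, entity_class) {
  if (length(ids) == 0L) ids <- "NA"
  allowed <- if (entity_class == "PLANT") PLANT_ID_NAMESPACES else CHEMICAL_ID_NAMESPACES
  for (id in ids) {
    if (identical(id, "NA")) next
    ns <- sub(":.*$", "", id)
    if (!grepl(":", id, fixed = TRUE) || !(ns %in% allowed)) {
      stop(sprintf("identifier %s not allowed for %s entities (allowed namespaces: %s, or NA)",
                   dQuote(id), entity_class, paste(allowed, collapse = ", ")),
           call. = FALSE)
    }
  }
  unique(ids)
}

#' @export
print.entity_mention <- function(x, ...) {
  cat(sprintf("<%s> %s [%d,%d) ids: %s\n", x$entity_class, dQuote(x$text),
              x$start, x$end, paste(x$ids, collapse = "|")))
  invisible(x)
}

#' Extract a 0-based half-open substring
#'
#' @param text A string.
#' @param start,end 0-based half-open character interval.
#' @return The substring.
#' @keywords internal
substr0 <- function(text, start, end) substr(text, start + 1L, end)

#' Create a sentence record
#'
#' @param doc_offset 0-based character start of the sentence in its abstract.
#' @param text Sentence string.
#' @param mentions List of [entity_mention()] objects with sentence-relative
#'   spans. Mentions of the same class must not overlap and every mention
#'   text must match the sentence substring at its span.
#' @return An object of class `sentence_record`.
#' @export
sentence_record <- function(doc_offset, text, mentions = list()) {
  doc_offset <- as.integer(doc_offset)
  if (is.na(doc_offset) || doc_offset < 0L) stop("doc_offset must be >= 0", call. = FALSE)
  text <- as.character(text)
  mentions <- check_sentence_mentions(mentions, text)
  structure(list(doc_offset = doc_offset, text = text, mentions = mentions),
            class = "sentence_record")
}

check_sentence_mentions <- function(mentions, text) {
  stopifnot(is.list(mentions))
  n <- nchar(text)
  for (m in mentions) {
    stopifnot(inherits(m, "entity_mention"))
    if (m$end > n) stop("mention span extends beyond sentence", call. = FALSE)
    at <- substr0(text, m$start, m$end)
    if (!identical(at, m$text)) {
      stop(sprintf("mention text %s does not match sentence substring %s at [%d,%d)",
                   dQuote(m$text), dQuote(at), m$start, m$end), call. = FALSE)
    }
  }
  for (cls in c("PLANT", "CHEMICAL")) {
    ms <- Filter(function(m) m$entity_class == cls, mentions)
    if (length(ms) > 1L) {
      spans <- vapply(ms, function(m) c(m$start, m$end), integer(2))
      o <- order(spans[1L, ])
      spans <- spans[, o, drop = FALSE]
      if (any(spans[1L, -1L] < spans[2L, -ncol(spans)])) {
        stop(sprintf("overlapping %s mentions in sentence", cls), call. = FALSE)
      }
    }
  }
  mentions
}

#' Mentions of one class in a sentence
#'
#' @param sentence A [sentence_record()].
#' @param entity_class `"PLANT"` or `"CHEMICAL"`.
#' @return List of [entity_mention()], ordered by span start.
#' @export
sentence_mentions <- function(sentence, entity_class) {
  ms <- Filter(function(m) m$entity_class == entity_class, sentence$mentions)
  ms[order(vapply(ms, `[[`, integer(1), "start"))]
}

#' Create an abstract document
#'
#' @param pmid Non-empty document identifier (PubMed id or synthetic id).
#' @param text Full abstract text.
#' @param sentences List of [sentence_record()] with ordered, non-overlapping
#'   spans lying within the abstract text.
#' @return An object of class `abstract_doc`.
#' @export
abstract_doc <- function(pmid, text, sentences = list()) {
  pmid <- as.character(pmid)
  if (!nzchar(pmid)) stop("pmid must be non-empty", call. = FALSE)
  text <- as.character(text)
  stopifnot(is.list(sentences))
  last_end <- 0L
  for (s in sentences) {
    stopifnot(inherits(s, "sentence_record"))
    if (s$doc_offset < last_end) {
      stop("sentence spans must be ordered and non-overlapping", call. = FALSE)
    }
    s_end <- s$doc_offset + nchar(s$text)
    if (s_end > nchar(text)) stop("sentence extends beyond abstract text", call. = FALSE)
    if (!identical(substr0(text, s$doc_offset, s_end), s$text)) {
      stop(sprintf("sentence text does not match abstract at offset %d", s$doc_offset),
           call. = FALSE)
    }
    last_end <- s_end
  }
  structure(list(pmid = pmid, text = text, sentences = sentences),
            class = "abstract_doc")
}

#' @export
print.abstract_doc <- function(x, ...) {
  cat(sprintf("<abstract_doc> PMID %s: %d sentence(s), %d characters\n",
              x$pmid, length(x$sentences), nchar(x$text)))
  invisible(x)
}

default_provenance <- function() {
  list(p_check = "", p_note = "", c_check = "", c_note = "")
}

#' Create a corpus unit
#'
#' One (plant mention, chemical mention) pair in one sentence -- the unit of
#' annotation and evaluation. A positive (`POS`) label asserts that the plant
#' contains the chemical and requires both a weak trigger (a multi-word span)
#' and a strong trigger (one word); a negative (`NEG`) label carries no
#' triggers.
#'
#' @param sentence A [sentence_record()].
#' @param plant,chemical [entity_mention()] objects of class `PLANT` and
#'   `CHEMICAL` respectively, located in `sentence`.
#' @param label `"POS"`, `"NEG"` or `"UNLABELED"`.
#' @param weak_trigger Token sequence (single string) or `NULL`; required for
#'   `POS`, forbidden for `NEG`.
#' @param strong_trigger Single whitespace-free word or `NULL`; required for
#'   `POS`, forbidden for `NEG`.
#' @param provenance List with elements `p_check`, `p_note`, `c_check`,
#'   `c_note` mirroring the annotation-sheet bookkeeping fields.
#' @param pmid Identifier of the source abstract.
#' @return An object of class `corpus_unit`.
#' @export
corpus_unit <- function(sentence, plant, chemical, label = "UNLABELED",
                        weak_trigger = NULL, strong_trigger = NULL,
                        provenance = default_provenance(), pmid = "") {
  stopifnot(inherits(sentence, "sentence_record"),
            inherits(plant, "entity_mention"),
            inherits(chemical, "entity_mention"))
  if (plant$entity_class != "PLANT") stop("plant mention must have class PLANT", call. = FALSE)
  if (chemical$entity_class != "CHEMICAL") stop("chemical mention must have class CHEMICAL", call. = FALSE)
  label <- match.arg(label, UNIT_LABELS)
  check_sentence_mentions(list(plant, chemical), sentence$text)
  if (!is.null(weak_trigger)) weak_trigger <- as.character(weak_trigger)
  if (!is.null(strong_trigger)) strong_trigger <- as.character(strong_trigger)
  if (label == "POS") {
    if (is.null(weak_trigger) || !nzchar(weak_trigger)) {
      stop("POS unit requires a weak trigger", call. = FALSE)
    }
    if (is.null(strong_trigger) || !nzchar(strong_trigger)) {
      stop("POS unit requires a strong trigger", call. = FALSE)
    }
    if (length(strsplit(trimws(strong_trigger), "[[:space:]]+")[[1L]]) != 1L) {
      stop("strong trigger must be exactly one word", call. = FALSE)
    }
  } else if (label == "NEG" && (!is.null(weak_trigger) || !is.null(strong_trigger))) {
    stop("NEG unit must not carry triggers", call. = FALSE)
  }
  prov <- default_provenance()
  prov[names(provenance)] <- lapply(provenance, as.character)
  structure(list(sentence = sentence, plant = plant, chemical = chemical,
                 label = label, weak_trigger = weak_trigger,
                 strong_trigger = strong_trigger, provenance = prov,
                 pmid = as.character(pmid)),
            class = "corpus_unit")
}

#' @export
print.corpus_unit <- function(x, ...) {
  cat(sprintf("<corpus_unit> [%s] %s -- %s (PMID %s)\n", x$label,
              dQuote(x$plant$text), dQuote(x$chemical$text), x$pmid))
  if (identical(x$label, "POS")) {
    cat(sprintf("  weak trigger: %s; strong trigger: %s\n",
                dQuote(x$weak_trigger), dQuote(x$strong_trigger)))
  }
  cat("  ", x$sentence$text, "\n", sep = "")
  invisible(x)
}

# --- canonical forms used for round-trip comparison ------------------------

canon_mention <- function(m) {
  list(entity_class = m$entity_class, start = m$start, end = m$end,
       text = m$text, ids = sort(m$ids))
}

canon_unit <- function(u) {
  list(pmid = u$pmid,
       sentence = list(doc_offset = u$sentence$doc_offset, text = u$sentence$text),
       plant = canon_mention(u$plant), chemical = canon_mention(u$chemical),
       label = u$label,
       weak_trigger = if (is.null(u$weak_trigger)) NA_character_ else u$weak_trigger,
       strong_trigger = if (is.null(u$strong_trigger)) NA_character_ else u$strong_trigger,
       provenance = u$provenance)
}

canon_units <- function(units) {
  cs <- lapply(units, canon_unit)
  key <- vapply(cs, function(u) {
    paste(u$pmid, u$sentence$doc_offset, u$plant$start, u$chemical$start, sep = "\r")
  }, character(1))
  cs[order(key)]
}

canon_doc <- function(doc, units = list()) {
  sent_key <- vapply(doc$sentences, function(s) s$doc_offset, integer(1))
  sents <- lapply(doc$sentences[order(sent_key)], function(s) {
    ms <- s$mentions
    mkey <- vapply(ms, function(m) sprintf("%09d-%s", m$start, m$entity_class), character(1))
    list(doc_offset = s$doc_offset, text = s$text,
         mentions = lapply(ms[order(mkey)], canon_mention))
  })
  list(pmid = doc$pmid, text = doc$text, sentences = sents,
       units = canon_units(units))
}

canon_docs <- function(docs) {
  # docs: list of list(doc = abstract_doc, units = list of corpus_unit)
  cs <- lapply(docs, function(d) canon_doc(d$doc, d$units))
  cs[order(vapply(cs, `[[`, character(1), "pmid"))]
}
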