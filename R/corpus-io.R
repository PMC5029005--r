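# Corpus readers/writers: BioC XML interchange dialect and the 15-column
# tab-separated annotation-sheet layout.
#
# BioC dialect: collection > document(id = PMID) > passage(offset = sentence
# doc_offset, text = sentence) > annotation (infons "type" in {plant,
# chemical}, "identifier" = namespace:value ids joined by "|" or "NA";
# location offset/length, document-relative) > relation (infons "type" in
# {POS, NEG, UNLABELED}, triggers and sheet bookkeeping fields; two node
# refs with roles "plant" and "chemical").

#' Canonical annotation-sheet column names
#'
#' @return Character vector of the 15 sheet columns, in order.
#' @export
sheet_columns <- function() {
  c("PlantName", "P.ID", "P.Off", "P.Note", "P.Check",
    "ChemName", "C.ID", "C.Off", "C.Note", "C.Check",
    "Sentence", "PMID", "Label", "WeakTrigger", "StrongTrigger")
}

mention_key <- function(m) sprintf("%s:%d:%d", m$entity_class, m$start, m$end)

collect_passage_mentions <- function(sentence, units) {
  ments <- sentence$mentions
  for (u in units) ments <- c(ments, list(u$plant, u$chemical))
  keys <- vapply(ments, mention_key, character(1))
  out <- list()
  for (k in unique(keys)) {
    grp <- ments[keys == k]
    m <- grp[[1L]]
    ids <- unique(unlist(lapply(grp, `[[`, "ids")))
    if (length(ids) > 1L) ids <- setdiff(ids, "NA")
    m$ids <- ids
    out[[length(out) + 1L]] <- m
  }
  ord <- order(vapply(out, `[[`, integer(1), "start"),
               vapply(out, `[[`, character(1), "entity_class"))
  out[ord]
}

#' Write a corpus to BioC XML
#'
#' Documents are ordered by PMID and annotations by span start, so output is
#' deterministic; a written file re-read with [read_bioc()] reproduces the
#' corpus field-by-field. Positive units missing a trigger are rejected
#' before anything is written.
#'
#' @param docs A corpus: list whose elements are `list(doc = abstract_doc,
#'   units = list of corpus_unit)` (the structure returned by
#'   [read_bioc()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bioc <- function(docs, path) {
  for (d in docs) {
    stopifnot(inherits(d$doc, "abstract_doc"))
    for (u in d$units %||% list()) {
      stopifnot(inherits(u, "corpus_unit"))
      if (identical(u$label, "POS") &&
          (is.null(u$weak_trigger) || is.null(u$strong_trigger))) {
        stop("POS unit missing a trigger; refusing to write", call. = FALSE)
      }
    }
  }
  docs <- docs[order(vapply(docs, function(d) d$doc$pmid, character(1)))]
  root <- xml2::xml_new_root("collection")
  xml2::xml_add_child(root, "source", "plantchem")
  for (d in docs) {
    doc <- d$doc
    units <- d$units %||% list()
    dnode <- xml2::xml_add_child(root, "document")
    xml2::xml_add_child(dnode, "id", doc$pmid)
    ann_counter <- 0L
    rel_counter <- 0L
    for (s in doc$sentences) {
      key_of <- function(m) mention_key(m)
      s_units <- Filter(function(u) identical(u$sentence$doc_offset, s$doc_offset) &&
                          identical(u$sentence$text, s$text), units)
      ments <- collect_passage_mentions(s, s_units)
      ids_by_key <- character(0)
      pnode <- xml2::xml_add_child(dnode, "passage")
      xml2::xml_add_child(pnode, "offset", as.character(s$doc_offset))
      xml2::xml_add_child(pnode, "text", s$text)
      for (m in ments) {
        ann_counter <- ann_counter + 1L
        aid <- paste0("T", ann_counter)
        ids_by_key[key_of(m)] <- aid
        anode <- xml2::xml_add_child(pnode, "annotation", id = aid)
        add_infon(anode, "type", tolower(m$entity_class))
        add_infon(anode, "identifier", paste(m$ids, collapse = "|"))
        xml2::xml_add_child(anode, "location",
                            offset = as.character(s$doc_offset + m$start),
                            length = as.character(m$end - m$start))
        xml2::xml_add_child(anode, "text", m$text)
      }
      ord <- order(vapply(s_units, function(u) u$plant$start, integer(1)),
                   vapply(s_units, function(u) u$chemical$start, integer(1)))
      for (u in s_units[ord]) {
        rel_counter <- rel_counter + 1L
        rnode <- xml2::xml_add_child(pnode, "relation", id = paste0("R", rel_counter))
        add_infon(rnode, "type", u$label)
        if (identical(u$label, "POS")) {
          add_infon(rnode, "weak_trigger", u$weak_trigger)
          add_infon(rnode, "strong_trigger", u$strong_trigger)
        }
        for (f in names(default_provenance())) {
          if (nzchar(u$provenance[[f]])) add_infon(rnode, f, u$provenance[[f]])
        }
        xml2::xml_add_child(rnode, "node", refid = ids_by_key[[key_of(u$plant)]],
                            role = "plant")
        xml2::xml_add_child(rnode, "node", refid = ids_by_key[[key_of(u$chemical)]],
                            role = "chemical")
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

add_infon <- function(node, key, value) {
  xml2::xml_add_child(node, "infon", as.character(value), key = key)
}

infon <- function(node, key, default = NA_character_) {
  v <- xml2::xml_text(xml2::xml_find_first(node, sprintf("./infon[@key='%s']", key)))
  if (is.na(v)) default else v
}

#' Read a corpus from BioC XML
#'
#' @param path Path to a BioC XML file in the dialect written by
#'   [write_bioc()]. Malformed XML raises the parser error (which names the
#'   offending line); a relation referencing a missing annotation id raises
#'   an integrity error.
#' @return A list with one element per document, each
#'   `list(doc = abstract_doc, units = list of corpus_unit)`.
#' @export
read_bioc <- function(path) {
  xml <- xml2::read_xml(path)
  out <- list()
  for (dnode in xml2::xml_find_all(xml, "./document")) {
    pmid <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    sentences <- list()
    units <- list()
    doc_len <- 0L
    passages <- xml2::xml_find_all(dnode, "./passage")
    parsed <- lapply(passages, parse_bioc_passage, pmid = pmid)
    for (p in parsed) doc_len <- max(doc_len, p$sentence$doc_offset + nchar(p$sentence$text))
    text <- strrep(" ", doc_len)
    for (p in parsed) {
      s <- p$sentence
      substr(text, s$doc_offset + 1L, s$doc_offset + nchar(s$text)) <- s$text
      sentences <- c(sentences, list(s))
      units <- c(units, p$units)
    }
    ord <- order(vapply(sentences, `[[`, integer(1), "doc_offset"))
    doc <- abstract_doc(pmid, text, sentences[ord])
    out[[length(out) + 1L]] <- list(doc = doc, units = units)
  }
  out
}

parse_bioc_passage <- function(pnode, pmid) {
  p_off <- as.integer(xml2::xml_text(xml2::xml_find_first(pnode, "./offset")))
  p_text <- xml2::xml_text(xml2::xml_find_first(pnode, "./text"))
  mentions <- list()
  for (anode in xml2::xml_find_all(pnode, "./annotation")) {
    aid <- xml2::xml_attr(anode, "id")
    type <- infon(anode, "type")
    if (!type %in% c("plant", "chemical")) {
      stop(sprintf("annotation %s has unknown type %s", aid, dQuote(type)), call. = FALSE)
    }
    loc <- xml2::xml_find_first(anode, "./location")
    off <- as.integer(xml2::xml_attr(loc, "offset")) - p_off
    len <- as.integer(xml2::xml_attr(loc, "length"))
    m <- entity_mention(toupper(type), off, off + len,
                        xml2::xml_text(xml2::xml_find_first(anode, "./text")),
                        strsplit(infon(anode, "identifier", "NA"), "|", fixed = TRUE)[[1L]])
    mentions[[aid]] <- m
  }
  sentence <- sentence_record(p_off, p_text, unname(mentions))
  units <- list()
  for (rnode in xml2::xml_find_all(pnode, "./relation")) {
    rid <- xml2::xml_attr(rnode, "id")
    refs <- xml2::xml_find_all(rnode, "./node")
    roles <- xml2::xml_attr(refs, "role")
    refids <- xml2::xml_attr(refs, "refid")
    names(refids) <- roles
    for (role in c("plant", "chemical")) {
      if (!role %in% roles || is.null(mentions[[refids[[role]]]])) {
        stop(sprintf("relation %s in document %s references missing %s annotation",
                     rid, pmid, role), call. = FALSE)
      }
    }
    label <- infon(rnode, "type", "UNLABELED")
    wt <- infon(rnode, "weak_trigger")
    st <- infon(rnode, "strong_trigger")
    units[[length(units) + 1L]] <- corpus_unit(
      sentence, mentions[[refids[["plant"]]]], mentions[[refids[["chemical"]]]],
      label = label,
      weak_trigger = if (is.na(wt)) NULL else wt,
      strong_trigger = if (is.na(st)) NULL else st,
      provenance = list(p_check = infon(rnode, "p_check", ""),
                        p_note = infon(rnode, "p_note", ""),
                        c_check = infon(rnode, "c_check", ""),
                        c_note = infon(rnode, "c_note", "")),
      pmid = pmid)
  }
  list(sentence = sentence, units = units)
}

# --- annotation sheet ------------------------------------------------------

sheet_cell <- function(x) {
  x <- as.character(x)
  if (grepl("[\t\n\r]", x)) stop("sheet cells must not contain tabs or newlines", call. = FALSE)
  x
}

#' Export corpus units to an annotation sheet
#'
#' One row per corpus unit; a sentence with several entity pairs yields
#' several rows sharing the `Sentence` cell. Offsets are written as
#' `start-end` (0-based, half-open, sentence-relative). Unlabeled units
#' export with an empty `Label`; `NEG` units export with empty trigger
#' cells.
#'
#' @param units List of [corpus_unit()] objects.
#' @param path Optional output file path.
#' @return Character vector of tab-separated lines (header first),
#'   invisibly when `path` is given.
#' @export
export_sheet <- function(units, path = NULL) {
  rows <- vapply(units, function(u) {
    stopifnot(inherits(u, "corpus_unit"))
    cells <- c(u$plant$text, paste(u$plant$ids, collapse = "|"),
               sprintf("%d-%d", u$plant$start, u$plant$end),
               u$provenance$p_note, u$provenance$p_check,
               u$chemical$text, paste(u$chemical$ids, collapse = "|"),
               sprintf("%d-%d", u$chemical$start, u$chemical$end),
               u$provenance$c_note, u$provenance$c_check,
               u$sentence$text, u$pmid,
               if (u$label == "UNLABELED") "" else u$label,
               u$weak_trigger %||% "", u$strong_trigger %||% "")
    paste(vapply(cells, sheet_cell, character(1)), collapse = "\t")
  }, character(1))
  lines <- c(paste(sheet_columns(), collapse = "\t"), rows)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

parse_span <- function(cell, what, row) {
  m <- regmatches(cell, regexec("^([0-9]+)-([0-9]+)$", cell))[[1L]]
  if (length(m) != 3L) {
    stop(sprintf("row %d: malformed %s offset %s (expected start-end)", row, what,
                 dQuote(cell)), call. = FALSE)
  }
  as.integer(m[2:3])
}

#' Import corpus units from an annotation sheet
#'
#' The header must match [sheet_columns()] exactly. `"NA"` or empty trigger
#' cells map to absent triggers; a `POS` row with an empty weak or strong
#' trigger is a row-level validation error; an offset whose sentence
#' substring does not match the recorded name is an integrity error.
#'
#' @param x Path to a TSV sheet, or a character vector of its lines.
#' @return List of [corpus_unit()] objects.
#' @export
import_sheet <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  if (length(lines) == 0L) stop("empty sheet", call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, sheet_columns())) {
    stop("sheet header does not match the canonical column list", call. = FALSE)
  }
  units <- list()
  for (i in seq_along(lines)[-1L]) {
    if (!nzchar(lines[[i]])) next
    cells <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    length(cells) <- length(header)   # pad trailing empties
    cells[is.na(cells)] <- ""
    names(cells) <- header
    row <- i
    sent_text <- cells[["Sentence"]]
    pspan <- parse_span(cells[["P.Off"]], "plant", row)
    cspan <- parse_span(cells[["C.Off"]], "chemical", row)
    for (side in list(list(span = pspan, name = cells[["PlantName"]], what = "plant"),
                      list(span = cspan, name = cells[["ChemName"]], what = "chemical"))) {
      at <- substr0(sent_text, side$span[1L], side$span[2L])
      if (!identical(at, side$name)) {
        stop(sprintf("row %d: %s offset %d-%d selects %s, not %s", row, side$what,
                     side$span[1L], side$span[2L], dQuote(at), dQuote(side$name)),
             call. = FALSE)
      }
    }
    label_cell <- cells[["Label"]]
    label <- if (!nzchar(label_cell)) "UNLABELED" else label_cell
    if (!label %in% UNIT_LABELS) {
      stop(sprintf("row %d: unknown label %s", row, dQuote(label_cell)), call. = FALSE)
    }
    trig <- function(cell) if (!nzchar(cell) || identical(cell, "NA")) NULL else cell
    wt <- trig(cells[["WeakTrigger"]])
    st <- trig(cells[["StrongTrigger"]])
    if (identical(label, "POS") && (is.null(wt) || is.null(st))) {
      stop(sprintf("row %d: POS unit with missing trigger", row), call. = FALSE)
    }
    plant <- entity_mention("PLANT", pspan[1L], pspan[2L], cells[["PlantName"]],
                            strsplit(cells[["P.ID"]], "|", fixed = TRUE)[[1L]])
    chem <- entity_mention("CHEMICAL", cspan[1L], cspan[2L], cells[["ChemName"]],
                           strsplit(cells[["C.ID"]], "|", fixed = TRUE)[[1L]])
    sentence <- sentence_record(0L, sent_text, list(plant, chem))
    units[[length(units) + 1L]] <- corpus_unit(
      sentence, plant, chem, label = label, weak_trigger = wt, strong_trigger = st,
      provenance = list(p_check = cells[["P.Check"]], p_note = cells[["P.Note"]],
                        c_check = cells[["C.Check"]], c_note = cells[["C.Note"]]),
      pmid = cells[["PMID"]])
  }
  units
}

`%||%` <- function(a, b) if (is.null(a)) b else a
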