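# Name lexicons (plant / chemical gazetteers) and the curated trigger
# lexicon driving the rule engine.

#' Load a plant or chemical name lexicon
#'
#' Format: one `term<TAB>namespace:id` entry per line; lines starting with
#' `#` are ignored. Terms are whitespace-normalized; duplicate (term, id)
#' pairs are dropped. Identifier namespaces are checked against the entity
#' class (plants: Taxonomy, TCMID; chemicals: MeSH, CHEMBL, CAS; `NA`
#' always allowed).
#'
#' @param path Lexicon file.
#' @param entity_class `"PLANT"` or `"CHEMICAL"`.
#' @return An object of class `name_lexicon`: list with `entries` (named
#'   list mapping term to character vector of ids) and `entity_class`.
#' @export
load_name_lexicon <- function(path, entity_class) {
  entity_class <- match.arg(entity_class, c("PLANT", "CHEMICAL"))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  entries <- list()
  for (line in lines) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    term <- normalize_term(parts[[1L]])
    if (!nzchar(term)) stop("empty lexicon term", call. = FALSE)
    id <- if (length(parts) < 2L || !nzchar(trimws(parts[[2L]]))) "NA" else trimws(parts[[2L]])
    validate_mention_ids(id, entity_class)
    entries[[term]] <- unique(c(entries[[term]], id))
  }
  structure(list(entries = entries, entity_class = entity_class),
            class = "name_lexicon")
}

normalize_term <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Build a name lexicon from terms in memory
#'
#' @param terms Character vector of surface terms, optionally named;
#'   unnamed/empty names get identifier `"NA"`.
#' @param entity_class `"PLANT"` or `"CHEMICAL"`.
#' @return A `name_lexicon`.
#' @export
name_lexicon <- function(terms, entity_class) {
  entity_class <- match.arg(entity_class, c("PLANT", "CHEMICAL"))
  ids <- names(terms) %||% rep("", length(terms))
  ids[!nzchar(ids)] <- "NA"
  entries <- list()
  for (i in seq_along(terms)) {
    term <- normalize_term(terms[[i]])
    validate_mention_ids(ids[[i]], entity_class)
    entries[[term]] <- unique(c(entries[[term]], ids[[i]]))
  }
  structure(list(entries = entries, entity_class = entity_class),
            class = "name_lexicon")
}

#' @export
print.name_lexicon <- function(x, ...) {
  cat(sprintf("<name_lexicon> %s: %d terms, %d (term, id) pairs\n", x$entity_class,
              length(x$entries), sum(lengths(x$entries))))
  invisible(x)
}

TRIGGER_SECTIONS <- c("active", "passive", "intransitive", "gerund")

#' Load a trigger lexicon
#'
#' The trigger lexicon holds the verb surface forms licensing the verbal and
#' relative rule families: `active` (transitive active forms, e.g.
#' "contains"), `passive` (transitive passive / past-participle forms, e.g.
#' "obtained" -- the same word set serves the passive verbal rule and the
#' past-participle relative rule), `intransitive` ("consist", "consists")
#' and `gerund` (e.g. "containing"). Matching is on lowercased surface
#' tokens, so inflected forms are enumerated rather than lemmatized.
#'
#' @param path Optional sectioned file with headers `[active]`, `[passive]`,
#'   `[intransitive]`, `[gerund]` and one word per line (`#` comments
#'   allowed). When omitted, the packaged default lists are loaded.
#' @return An object of class `trigger_lexicon`: list of four lowercase
#'   character vectors named by section.
#' @export
load_trigger_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "triggers_table2.txt", package = "plantchem",
                        mustWork = TRUE)
  }
  lines <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- stats::setNames(rep(list(character(0)), length(TRIGGER_SECTIONS)),
                          TRIGGER_SECTIONS)
  current <- NULL
  for (line in lines) {
    if (startsWith(line, "[")) {
      sec <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!sec %in% TRIGGER_SECTIONS) {
        stop(sprintf("unknown trigger section %s", dQuote(sec)), call. = FALSE)
      }
      current <- sec
    } else {
      if (is.null(current)) stop("trigger word before any section header", call. = FALSE)
      word <- tolower(line)
      if (grepl("[[:space:]]", word)) stop("trigger words must be single tokens", call. = FALSE)
      sets[[current]] <- union(sets[[current]], word)
    }
  }
  trigger_lexicon(sets$active, sets$passive, sets$intransitive, sets$gerund)
}

#' Construct a trigger lexicon from word sets
#'
#' @param active,passive,intransitive,gerund Character vectors of
#'   single-token trigger words (lowercased on construction). The passive
#'   set doubles as the past-participle set of the relative rule family.
#' @return A `trigger_lexicon`.
#' @export
trigger_lexicon <- function(active = character(0), passive = character(0),
                            intransitive = character(0), gerund = character(0)) {
  as_set <- function(x) sort(unique(tolower(as.character(x))))
  structure(list(active = as_set(active), passive = as_set(passive),
                 intransitive = as_set(intransitive), gerund = as_set(gerund)),
            class = "trigger_lexicon")
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  cat(sprintf("<trigger_lexicon> active: %d, passive/past-participle: %d, intransitive: %d, gerund: %d\n",
              length(x$active), length(x$passive), length(x$intransitive),
              length(x$gerund)))
  invisible(x)
}

#' Path to a packaged fixture lexicon
#'
#' @param name One of `"plants_fixture.tsv"`, `"chemicals_fixture.tsv"`,
#'   `"triggers_table2.txt"`, `"fig3.conll"`.
#' @return Absolute file path.
#' @export
plantchem_extdata <- function(name) {
  system.file("extdata", name, package = "plantchem", mustWork = TRUE)
}
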