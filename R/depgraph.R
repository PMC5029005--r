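# Typed-dependency data model (Stanford basic-dependency label vocabulary),
# CoNLL-style fixture reader, and the subtree / noun-phrase utilities the
# rule engine is built on. Token indices are 1-based with head 0 denoting
# the root; character spans are 0-based half-open, sentence-relative.

STANFORD_LABELS <- c(
  "root", "nsubj", "nsubjpass", "csubj", "csubjpass", "dobj", "iobj",
  "prep", "pobj", "pcomp", "appos", "cop", "nn", "amod", "advmod", "det",
  "num", "number", "quantmod", "poss", "possessive", "partmod", "infmod",
  "rcmod", "ccomp", "xcomp", "advcl", "acomp", "conj", "cc", "preconj",
  "mark", "aux", "auxpass", "neg", "expl", "prt", "punct", "dep",
  "parataxis", "npadvmod", "tmod", "predet", "discourse", "mwe"
)

# Labels that terminate a noun phrase: clausal material, coordination,
# apposition, punctuation and clause-level arguments. prep/pobj chains and
# nominal modifiers are deliberately kept, so "oil ... of ginger" keeps
# "ginger" inside the NP.
NP_EDGE_BLACKLIST <- c(
  "partmod", "rcmod", "ccomp", "advcl", "conj", "appos", "punct",
  "nsubj", "nsubjpass", "csubj", "csubjpass", "cop", "aux", "auxpass",
  "mark", "dep", "cc", "preconj", "parataxis", "neg", "expl", "discourse"
)

.plantchem_env <- new.env(parent = emptyenv())

#' Construct a dependency graph
#'
#' @param tokens Character vector of token surface strings.
#' @param heads Integer vector: `heads[i]` is the 1-based index of token
#'   `i`'s head, with `0` for the (unique) root.
#' @param labels Character vector of typed-dependency labels in the
#'   Stanford vocabulary; the root token's label is `"root"`. Unknown
#'   labels are accepted (they simply never match a pattern) and reported
#'   once per label per session.
#' @param text Optional sentence text; when omitted it is reconstructed
#'   from the tokens with standard detokenization spacing. Token character
#'   spans are aligned against it.
#' @return An object of class `dep_graph` with elements `tokens` (a data
#'   frame `text`, `start`, `end`), `heads`, `labels` and `text`.
#' @export
dep_graph <- function(tokens, heads, labels, text = NULL) {
  tokens <- as.character(tokens)
  heads <- as.integer(heads)
  labels <- as.character(labels)
  n <- length(tokens)
  if (n == 0L) stop("dependency graph needs at least one token", call. = FALSE)
  if (length(heads) != n || length(labels) != n) {
    stop("tokens, heads and labels must have equal length", call. = FALSE)
  }
  if (any(is.na(heads)) || any(heads < 0L | heads > n)) {
    stop("heads must lie in 0..n", call. = FALSE)
  }
  roots <- which(heads == 0L)
  if (length(roots) != 1L) {
    stop(sprintf("graph must have exactly one root (found %d)", length(roots)),
         call. = FALSE)
  }
  for (i in seq_len(n)) {       # acyclicity: every token reaches the root
    j <- i; steps <- 0L
    while (j != 0L) {
      j <- heads[[j]]; steps <- steps + 1L
      if (steps > n) stop(sprintf("dependency cycle involving token %d", i), call. = FALSE)
    }
  }
  unknown <- setdiff(unique(labels), STANFORD_LABELS)
  for (lab in unknown) {
    if (is.null(.plantchem_env$warned_labels[[lab]])) {
      .plantchem_env$warned_labels[[lab]] <- TRUE
      message(sprintf("note: unknown dependency label %s (ignored by all patterns)",
                      dQuote(lab)))
    }
  }
  if (is.null(text)) text <- detokenize(tokens)
  spans <- align_tokens(text, tokens)
  structure(list(tokens = data.frame(text = tokens, start = spans$start,
                                     end = spans$end, stringsAsFactors = FALSE),
                 heads = heads, labels = labels, text = text),
            class = "dep_graph")
}

NO_SPACE_BEFORE <- c(".", ",", ";", ":", "!", "?", ")", "]", "'s")
NO_SPACE_AFTER <- c("(", "[")

#' Reconstruct sentence text from tokens
#'
#' @param tokens Character vector of tokens.
#' @return Single string with standard spacing (no space before closing
#'   punctuation, none after an opening bracket).
#' @export
detokenize <- function(tokens) {
  out <- tokens[[1L]]
  for (i in seq_along(tokens)[-1L]) {
    sep <- if (tokens[[i]] %in% NO_SPACE_BEFORE ||
               tokens[[i - 1L]] %in% NO_SPACE_AFTER) "" else " "
    out <- paste0(out, sep, tokens[[i]])
  }
  out
}

align_tokens <- function(text, tokens) {
  start <- integer(length(tokens)); end <- integer(length(tokens))
  pos <- 0L
  for (i in seq_along(tokens)) {
    hit <- regexpr(tokens[[i]], substr(text, pos + 1L, nchar(text)), fixed = TRUE)
    if (hit == -1L) {
      stop(sprintf("token %s not found in sentence text after position %d",
                   dQuote(tokens[[i]]), pos), call. = FALSE)
    }
    start[[i]] <- pos + as.integer(hit) - 1L
    end[[i]] <- start[[i]] + nchar(tokens[[i]])
    pos <- end[[i]]
  }
  list(start = start, end = end)
}

#' @export
print.dep_graph <- function(x, ...) {
  cat(sprintf("<dep_graph> %d tokens: %s\n", nrow(x$tokens), x$text))
  invisible(x)
}

graph_children <- function(graph, i, label = NULL) {
  idx <- which(graph$heads == i)
  if (!is.null(label)) idx <- idx[graph$labels[idx] %in% label]
  idx
}

#' All descendants of a token
#'
#' @param graph A [dep_graph()].
#' @param i Token index.
#' @param include_self Include `i` itself (default `TRUE`).
#' @return Sorted integer vector of token indices.
#' @export
descendants <- function(graph, i, include_self = TRUE) {
  acc <- i
  frontier <- i
  while (length(frontier) > 0L) {
    nxt <- which(graph$heads %in% frontier)
    frontier <- setdiff(nxt, acc)
    acc <- c(acc, frontier)
  }
  out <- sort(unique(acc))
  if (!include_self) out <- setdiff(out, i)
  out
}

#' Noun phrase headed by a token
#'
#' Members are all descendants of the head reachable without traversing a
#' clausal, coordinating, appositive or clause-argument edge (see
#' `NP_EDGE_BLACKLIST`); nominal modifiers and prep/pobj chains are kept.
#'
#' @param graph A [dep_graph()].
#' @param head Token index of the phrase head.
#' @return An object of class `noun_phrase`: list with `head` and sorted
#'   integer `members` (always containing `head`).
#' @export
np_subtree <- function(graph, head) {
  stopifnot(head >= 1L, head <= nrow(graph$tokens))
  acc <- head
  frontier <- head
  while (length(frontier) > 0L) {
    nxt <- which(graph$heads %in% frontier & !(graph$labels %in% NP_EDGE_BLACKLIST))
    frontier <- setdiff(nxt, acc)
    acc <- c(acc, frontier)
  }
  structure(list(head = head, members = sort(unique(acc))), class = "noun_phrase")
}

np_members <- function(np) if (inherits(np, "noun_phrase")) np$members else as.integer(np)

#' Token distance between two noun phrases
#'
#' Number of tokens strictly between the closest members of the two
#' phrases: `min(|i - j|) - 1` over member index pairs. Symmetric; `0` for
#' adjacent phrases. Overlapping phrases are an error.
#'
#' @param graph A [dep_graph()] (used only for validation).
#' @param np_a,np_b [np_subtree()] results or integer member vectors.
#' @return Non-negative integer.
#' @export
token_distance <- function(graph, np_a, np_b) {
  a <- np_members(np_a); b <- np_members(np_b)
  if (length(intersect(a, b)) > 0L) stop("noun phrases overlap", call. = FALSE)
  min(abs(outer(a, b, "-"))) - 1L
}

#' Syntactic head token of an entity mention
#'
#' Among the tokens overlapping the mention span, returns the one whose
#' head lies outside the mention (the mention's attachment point); if
#' several qualify, the right-most.
#'
#' @param graph A [dep_graph()].
#' @param mention An [entity_mention()] with spans relative to the graph's
#'   sentence.
#' @return Token index.
#' @export
mention_head <- function(graph, mention) {
  toks <- which(graph$tokens$start < mention$end & graph$tokens$end > mention$start)
  if (length(toks) == 0L) {
    stop(sprintf("mention %s overlaps no token", dQuote(mention$text)), call. = FALSE)
  }
  outside <- toks[!(graph$heads[toks] %in% toks)]
  if (length(outside) == 0L) outside <- toks
  max(outside)
}

# --- CoNLL-style fixture format -------------------------------------------

#' Read dependency graphs from a CoNLL-style fixture file
#'
#' Rows are `index<TAB>form<TAB>head<TAB>deprel` (whitespace-separated also
#' accepted); sentences are separated by blank lines; an optional
#' `# text = ...` comment supplies the sentence string. Parsers emitting
#' Universal Dependencies labels must be mapped to the Stanford set before
#' use (see [ud_to_stanford()]).
#'
#' @param path File path.
#' @return List with one element per sentence, each
#'   `list(text = sentence string, graph = dep_graph)`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  block <- list(); text <- NULL; rows <- integer(0)
  flush <- function() {
    if (length(block) == 0L) return()
    idx <- vapply(block, function(r) as.integer(r[[1L]]), integer(1))
    if (anyDuplicated(idx)) {
      stop(sprintf("multiple heads for token index %d (rows %s)",
                   idx[duplicated(idx)][1L],
                   paste(rows[idx %in% idx[duplicated(idx)]], collapse = ", ")),
           call. = FALSE)
    }
    if (!identical(sort(idx), seq_along(idx))) {
      stop(sprintf("token indices not contiguous near row %d", rows[[1L]]), call. = FALSE)
    }
    o <- order(idx)
    g <- tryCatch(
      dep_graph(vapply(block, `[[`, character(1), 2L)[o],
                vapply(block, function(r) as.integer(r[[3L]]), integer(1))[o],
                vapply(block, `[[`, character(1), 4L)[o],
                text = text),
      error = function(e) {
        stop(sprintf("%s (sentence starting at row %d)", conditionMessage(e),
                     rows[[1L]]), call. = FALSE)
      })
    out[[length(out) + 1L]] <<- list(text = g$text, graph = g)
    block <<- list(); text <<- NULL; rows <<- integer(0)
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) { flush(); next }
    if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*text\\s*=\\s*(.*)$", line))[[1L]]
      if (length(m) == 2L) text <- m[[2L]]
      next
    }
    fields <- strsplit(trimws(line), "[\t ]+")[[1L]]
    if (length(fields) < 4L) {
      stop(sprintf("row %d: expected 4 columns (index form head deprel)", i),
           call. = FALSE)
    }
    block[[length(block) + 1L]] <- fields[1:4]
    rows <- c(rows, i)
  }
  flush()
  out
}

#' Write dependency graphs to a CoNLL-style fixture file
#'
#' @param parses List of `list(text =, graph =)` as returned by
#'   [read_conll()], or of bare `dep_graph` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conll <- function(parses, path) {
  lines <- character(0)
  for (p in parses) {
    g <- if (inherits(p, "dep_graph")) p else p$graph
    lines <- c(lines, paste0("# text = ", g$text),
               sprintf("%d\t%s\t%d\t%s", seq_len(nrow(g$tokens)),
                       g$tokens$text, g$heads, g$labels),
               "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

UD_TO_STANFORD <- c(
  "nsubj:pass" = "nsubjpass", "csubj:pass" = "csubjpass", "obj" = "dobj",
  "compound" = "nn", "acl" = "partmod", "acl:relcl" = "rcmod",
  "obl" = "prep", "nmod" = "prep", "case" = "prep", "nummod" = "num",
  "aux:pass" = "auxpass", "oblique" = "prep"
)

#' Map Universal Dependencies labels to the Stanford set
#'
#' Adapter helper for parsers emitting UD labels; labels without a mapping
#' are passed through unchanged.
#'
#' @param labels Character vector of UD labels.
#' @return Character vector of Stanford-style labels.
#' @export
ud_to_stanford <- function(labels) {
  mapped <- unname(UD_TO_STANFORD[labels])
  ifelse(is.na(mapped), labels, mapped)
}
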