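# Rule-based POS/NEG classification of corpus units: six rule families
# over typed-dependency structure, gated by the trigger lexicon. A unit is
# positive iff at least one family fires (structure check first, then
# trigger check); families are evaluated in a fixed order (verbal,
# prepositional, relative, apposition, copula, compound noun) which only
# determines the reported rule id, never the label.

RULE_FAMILIES <- c("verbal", "prepositional", "relative", "apposition",
                   "copula", "compound")

rule_match <- function(rule_id, trigger_tokens, np_plant = NULL, np_chemical = NULL) {
  structure(list(rule_id = rule_id, trigger_tokens = as.integer(trigger_tokens),
                 np_plant = np_plant, np_chemical = np_chemical),
            class = "rule_match")
}

#' @export
print.rule_match <- function(x, ...) {
  cat(sprintf("<rule_match> %s (trigger tokens: %s)\n", x$rule_id,
              if (length(x$trigger_tokens)) paste(x$trigger_tokens, collapse = ", ")
              else "whitespace"))
  invisible(x)
}

tok_lower <- function(graph) tolower(graph$tokens$text)

in_desc <- function(graph, node, head) node %in% descendants(graph, head)

#' Verbal trigger rule (V1: active, V2: passive, V3: intransitive)
#'
#' * V1 `NP0 Vtr NP1`: an active-form trigger verb whose `nsubj` subtree
#'   contains the plant head and whose `dobj` subtree contains the chemical
#'   head.
#' * V2 `NP1 Vtr PP NP0`: a passive-form trigger verb whose `nsubjpass`
#'   subtree contains the chemical head, with any preposition under the
#'   verb whose `pobj` subtree contains the plant head.
#' * V3 `NP0 Vtr PP NP1`: an intransitive trigger verb ("consist(s)") whose
#'   `nsubj` subtree contains the plant head, with a preposition + `pobj`
#'   subtree containing the chemical head.
#'
#' @param graph A [dep_graph()].
#' @param plant_head,chem_head Token indices (see [mention_head()]).
#' @param triggers A [trigger_lexicon()].
#' @return A `rule_match` or `NULL`.
#' @export
match_verbal <- function(graph, plant_head, chem_head, triggers) {
  low <- tok_lower(graph)
  for (v in which(low %in% triggers$active)) {          # V1
    for (s in graph_children(graph, v, "nsubj")) {
      if (!in_desc(graph, plant_head, s)) next
      for (o in graph_children(graph, v, "dobj")) {
        if (in_desc(graph, chem_head, o)) {
          return(rule_match("V1", v, np_subtree(graph, s), np_subtree(graph, o)))
        }
      }
    }
  }
  for (v in which(low %in% triggers$passive)) {         # V2
    for (s in graph_children(graph, v, "nsubjpass")) {
      if (!in_desc(graph, chem_head, s)) next
      for (p in graph_children(graph, v, "prep")) {
        for (o in graph_children(graph, p, "pobj")) {
          if (in_desc(graph, plant_head, o)) {
            return(rule_match("V2", c(v, p), np_subtree(graph, o), np_subtree(graph, s)))
          }
        }
      }
    }
  }
  for (v in which(low %in% triggers$intransitive)) {    # V3
    for (s in graph_children(graph, v, "nsubj")) {
      if (!in_desc(graph, plant_head, s)) next
      for (p in graph_children(graph, v, "prep")) {
        for (o in graph_children(graph, p, "pobj")) {
          if (in_desc(graph, chem_head, o)) {
            return(rule_match("V3", c(v, p), np_subtree(graph, s), np_subtree(graph, o)))
          }
        }
      }
    }
  }
  NULL
}

#' Prepositional trigger rule (P1/P2)
#'
#' Fires when a `prep` edge attaches to a token whose noun phrase contains
#' one entity head (outside the preposition's own subtree) while the
#' preposition's `pobj` subtree contains the other. The trigger is the
#' preposition token itself; direction P1 (`NP0 PPtr NP1`, plant left) vs
#' P2 (`NP1 PPtr NP0`) is recorded from which entity sits on the attachment
#' side.
#'
#' @inheritParams match_verbal
#' @return A `rule_match` or `NULL`.
#' @export
match_prepositional <- function(graph, plant_head, chem_head) {
  for (p in which(graph$labels == "prep")) {
    h <- graph$heads[[p]]
    if (h == 0L) next
    left <- setdiff(np_subtree(graph, h)$members, descendants(graph, p))
    for (o in graph_children(graph, p, "pobj")) {
      right <- descendants(graph, o)
      if (plant_head %in% left && chem_head %in% right) {
        return(rule_match("P1", p, np_subtree(graph, h), np_subtree(graph, o)))
      }
      if (chem_head %in% left && plant_head %in% right) {
        return(rule_match("P2", p, np_subtree(graph, o), np_subtree(graph, h)))
      }
    }
  }
  NULL
}

#' Relative trigger rule (R1: past participle, R2: gerund)
#'
#' * R1 `NP1 Rtr PP NP0`: a past-participle trigger (the passive word set)
#'   modifying, via `partmod`/`amod`, a noun whose phrase contains the
#'   chemical head, with a preposition + `pobj` subtree under the
#'   participle containing the plant head.
#' * R2 `NP0 Rtr (PP) NP1`: a gerund trigger modifying a noun whose phrase
#'   contains the plant head, with the chemical head inside the gerund's
#'   `dobj` subtree; for the intransitive gerund "consisting" the object
#'   must instead be reached through the preposition "of".
#'
#' @inheritParams match_verbal
#' @return A `rule_match` or `NULL`.
#' @export
match_relative <- function(graph, plant_head, chem_head, triggers) {
  low <- tok_lower(graph)
  mod_lab <- c("partmod", "amod")
  for (r in which(low %in% triggers$passive & graph$labels %in% mod_lab)) {   # R1
    n <- graph$heads[[r]]
    if (n == 0L || !(chem_head %in% np_subtree(graph, n)$members)) next
    for (p in graph_children(graph, r, "prep")) {
      for (o in graph_children(graph, p, "pobj")) {
        if (in_desc(graph, plant_head, o)) {
          return(rule_match("R1", c(r, p), np_subtree(graph, o), np_subtree(graph, n)))
        }
      }
    }
  }
  for (g in which(low %in% triggers$gerund & graph$labels %in% mod_lab)) {    # R2
    n <- graph$heads[[g]]
    if (n == 0L || !(plant_head %in% np_subtree(graph, n)$members)) next
    if (identical(low[[g]], "consisting")) {
      for (p in graph_children(graph, g, "prep")) {
        if (!identical(low[[p]], "of")) next
        for (o in graph_children(graph, p, "pobj")) {
          if (in_desc(graph, chem_head, o)) {
            return(rule_match("R2", c(g, p), np_subtree(graph, n), np_subtree(graph, o)))
          }
        }
      }
    } else {
      for (o in graph_children(graph, g, "dobj")) {
        if (in_desc(graph, chem_head, o)) {
          return(rule_match("R2", g, np_subtree(graph, n), np_subtree(graph, o)))
        }
      }
    }
  }
  NULL
}

#' Apposition trigger rule (A1/A2)
#'
#' Fires when an `appos` edge links a governor and dependent such that one
#' entity head lies in the dependent's subtree and the other in the
#' governor's subtree outside it, and the two noun phrases are separated by
#' fewer than `max_dist` tokens. The trigger is the token carrying the
#' `appos` relation. A1 vs A2 records whether the plant-bearing phrase
#' comes first in the sentence.
#'
#' @inheritParams match_verbal
#' @param max_dist Maximum token distance (exclusive) between the phrases.
#' @return A `rule_match` or `NULL`.
#' @export
match_apposition <- function(graph, plant_head, chem_head, max_dist = 10L) {
  for (d in which(graph$labels == "appos")) {
    g <- graph$heads[[d]]
    if (g == 0L) next
    sub_d <- descendants(graph, d)
    sub_g <- setdiff(descendants(graph, g), sub_d)
    np_g <- np_subtree(graph, g); np_d <- np_subtree(graph, d)
    sides <- NULL
    if (plant_head %in% sub_d && chem_head %in% sub_g) {
      sides <- list(plant = np_d, chem = np_g)
    } else if (chem_head %in% sub_d && plant_head %in% sub_g) {
      sides <- list(plant = np_g, chem = np_d)
    }
    if (is.null(sides)) next
    dist <- tryCatch(token_distance(graph, np_g, np_d), error = function(e) NA_integer_)
    if (is.na(dist) || dist >= max_dist) next
    id <- if (min(sides$plant$members) < min(sides$chem$members)) "A1" else "A2"
    return(rule_match(id, d, sides$plant, sides$chem))
  }
  NULL
}

#' Copula trigger rule (C1/C2)
#'
#' Fires when a `cop` edge attaches a copular verb (any tense) to a
#' predicate token whose `nsubj` subtree contains one entity head while the
#' predicate subtree minus the subject contains the other, with the subject
#' and predicate phrases separated by fewer than `max_dist` tokens. The
#' trigger is the copula token. C1: plant in the subject; C2: chemical in
#' the subject.
#'
#' @inheritParams match_apposition
#' @return A `rule_match` or `NULL`.
#' @export
match_copula <- function(graph, plant_head, chem_head, max_dist = 10L) {
  for (cv in which(graph$labels == "cop")) {
    p <- graph$heads[[cv]]
    if (p == 0L) next
    for (s in graph_children(graph, p, c("nsubj", "nsubjpass"))) {
      sub_s <- descendants(graph, s)
      pred <- setdiff(descendants(graph, p), c(sub_s, cv))
      np_s <- np_subtree(graph, s); np_p <- np_subtree(graph, p)
      sides <- NULL
      if (plant_head %in% sub_s && chem_head %in% pred) {
        sides <- list(id = "C1", plant = np_s, chem = np_p)
      } else if (chem_head %in% sub_s && plant_head %in% pred) {
        sides <- list(id = "C2", plant = np_p, chem = np_s)
      }
      if (is.null(sides)) next
      dist <- tryCatch(token_distance(graph, np_s, np_p), error = function(e) NA_integer_)
      if (is.na(dist) || dist >= max_dist) next
      return(rule_match(sides$id, cv, sides$plant, sides$chem))
    }
  }
  NULL
}

#' Compound-noun trigger rule (CN1)
#'
#' Fires when the plant mention is immediately followed by the chemical
#' mention with exactly one whitespace character between them ("panax
#' notoginseng saponins", "Aloe emodin"). The trigger is the whitespace, so
#' the match carries no trigger tokens; only the plant-first direction is
#' licensed.
#'
#' @param x A [dep_graph()] or the sentence text.
#' @param plant_mention,chem_mention [entity_mention()]s from the same
#'   sentence.
#' @return A `rule_match` or `NULL`.
#' @export
match_compound <- function(x, plant_mention, chem_mention) {
  text <- if (inherits(x, "dep_graph")) x$text else as.character(x)
  if (chem_mention$start != plant_mention$end + 1L) return(NULL)
  gap <- substr0(text, plant_mention$end, chem_mention$start)
  if (!grepl("^[[:space:]]$", gap)) return(NULL)
  rule_match("CN1", integer(0))
}

#' Classify a corpus unit with the rule-based model
#'
#' Checks the unit's dependency structure against the six rule families in
#' order (verbal, prepositional, relative, apposition, copula, compound
#' noun) and the trigger lexicon; the unit is labeled `POS` iff at least
#' one family fires. All firing matches are returned; the first is the
#' reported rule.
#'
#' @param graph A [dep_graph()] of the unit's sentence; mention spans must
#'   align with the graph text.
#' @param unit A [corpus_unit()].
#' @param triggers A [trigger_lexicon()] (default: the packaged lists).
#' @param max_dist Token-distance bound for the apposition and copula
#'   families (exclusive; default 10).
#' @param families Subset of `RULE_FAMILIES` to evaluate.
#' @return List with elements `label` (`"POS"`/`"NEG"`) and `matches`
#'   (list of `rule_match`).
#' @export
classify_unit <- function(graph, unit, triggers = load_trigger_lexicon(),
                          max_dist = 10L, families = RULE_FAMILIES) {
  stopifnot(inherits(graph, "dep_graph"), inherits(unit, "corpus_unit"))
  families <- match.arg(families, RULE_FAMILIES, several.ok = TRUE)
  for (m in list(unit$plant, unit$chemical)) {
    at <- substr0(graph$text, m$start, m$end)
    if (!identical(at, m$text)) {
      stop(sprintf("mention %s does not align with parse text (found %s at [%d,%d))",
                   dQuote(m$text), dQuote(at), m$start, m$end), call. = FALSE)
    }
  }
  plant_head <- mention_head(graph, unit$plant)
  chem_head <- mention_head(graph, unit$chemical)
  matches <- list()
  add <- function(m) if (!is.null(m)) matches[[length(matches) + 1L]] <<- m
  if ("verbal" %in% families) add(match_verbal(graph, plant_head, chem_head, triggers))
  if ("prepositional" %in% families) add(match_prepositional(graph, plant_head, chem_head))
  if ("relative" %in% families) add(match_relative(graph, plant_head, chem_head, triggers))
  if ("apposition" %in% families) add(match_apposition(graph, plant_head, chem_head, max_dist))
  if ("copula" %in% families) add(match_copula(graph, plant_head, chem_head, max_dist))
  if ("compound" %in% families) add(match_compound(graph, unit$plant, unit$chemical))
  list(label = if (length(matches) > 0L) "POS" else "NEG", matches = matches)
}
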