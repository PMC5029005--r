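# Packaged worked examples with hand-built gold dependency parses, and a
# template-driven synthetic corpus generator. Gold parses are emitted by
# the template engine rather than a statistical parser, so the rule engine
# is testable offline and parser-independently.

#' Construct a fixture unit
#'
#' @param template_id Template / example identifier.
#' @param pmid Document identifier.
#' @param tokens,heads,labels Dependency graph (see [dep_graph()]).
#' @param plant_range,chem_range Token index ranges `c(first, last)` of the
#'   plant and chemical mentions (or `NULL` when a char span is given).
#' @param gold_label,expected_model_label `"POS"` or `"NEG"`: the
#'   annotation gold standard and the label the rule-based model is
#'   expected to produce (they differ for documented-error fixtures).
#' @param expected_rule_id Rule expected to be reported, or `NULL`.
#' @param weak_trigger,strong_trigger Triggers for gold-POS units.
#' @param plant_ids,chem_ids Identifier vectors.
#' @param plant_span,chem_span Explicit 0-based char spans overriding the
#'   token ranges (used for sub-token mentions such as "tobacco" inside
#'   "tobacco-specific").
#' @return An object of class `fixture_unit`: list with `unit`
#'   ([corpus_unit()]), `graph` ([dep_graph()]), `gold_label`,
#'   `expected_model_label`, `expected_rule_id`, `template_id`.
#' @keywords internal
fixture_unit <- function(template_id, pmid, tokens, heads, labels,
                         plant_range, chem_range, gold_label,
                         expected_model_label, expected_rule_id = NULL,
                         weak_trigger = NULL, strong_trigger = NULL,
                         plant_ids = "NA", chem_ids = "NA",
                         plant_span = NULL, chem_span = NULL) {
  graph <- dep_graph(tokens, heads, labels)
  span_of <- function(range, explicit) {
    if (!is.null(explicit)) return(as.integer(explicit))
    c(graph$tokens$start[[range[[1L]]]], graph$tokens$end[[range[[length(range)]]]])
  }
  ps <- span_of(plant_range, plant_span)
  cs <- span_of(chem_range, chem_span)
  plant <- entity_mention("PLANT", ps[[1L]], ps[[2L]],
                          substr0(graph$text, ps[[1L]], ps[[2L]]), plant_ids)
  chem <- entity_mention("CHEMICAL", cs[[1L]], cs[[2L]],
                         substr0(graph$text, cs[[1L]], cs[[2L]]), chem_ids)
  sentence <- sentence_record(0L, graph$text, list(plant, chem))
  unit <- corpus_unit(sentence, plant, chem, label = gold_label,
                      weak_trigger = weak_trigger, strong_trigger = strong_trigger,
                      pmid = pmid)
  structure(list(unit = unit, graph = graph, gold_label = gold_label,
                 expected_model_label = expected_model_label,
                 expected_rule_id = expected_rule_id, template_id = template_id),
            class = "fixture_unit")
}

#' @export
print.fixture_unit <- function(x, ...) {
  cat(sprintf("<fixture_unit> %s gold=%s expected=%s%s\n  %s\n", x$template_id,
              x$gold_label, x$expected_model_label,
              if (is.null(x$expected_rule_id)) "" else paste0(" (", x$expected_rule_id, ")"),
              x$graph$text))
  invisible(x)
}

#' Packaged worked-example fixtures
#'
#' Returns the twelve rule-structure examples (one per rule id, with the
#' passive verbal example doubling as the dependency-parse walkthrough
#' sentence) plus four documented-error fixtures: two semantic false
#' positives (solvent extract, agronomic treatment) the model is expected
#' to predict POS despite gold NEG, and two structural false negatives
#' ("plant-specific chemical", bracketed relation) with gold POS but
#' expected NEG. Each fixture carries a hand-built gold parse.
#'
#' @return List of `fixture_unit` objects.
#' @export
table1_fixtures <- function() {
  f <- list()

  f$V1 <- fixture_unit(
    "table1_V1", "15493960",
    c("Pomegranate", "derived", "from", "the", "tree", "Punica", "granatum",
      "contains", "anthocyanins", "."),
    c(8L, 1L, 2L, 5L, 3L, 7L, 5L, 0L, 8L, 8L),
    c("nsubj", "partmod", "prep", "det", "pobj", "nn", "appos",
      "root", "dobj", "punct"),
    plant_range = c(1L, 1L), chem_range = c(9L, 9L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "V1",
    weak_trigger = "contains", strong_trigger = "contains",
    chem_ids = "MeSH:D000872")

  f$V2 <- fixture_unit(
    "table1_V2_fig3", "23605447",
    c("About", "450", "mg", "of", "FB1", "were", "obtained", "from",
      "800", "g", "cultured", "corn", "."),
    c(2L, 3L, 7L, 3L, 4L, 7L, 0L, 7L, 10L, 12L, 12L, 8L, 7L),
    c("quantmod", "num", "nsubjpass", "prep", "pobj", "auxpass", "root",
      "prep", "num", "nn", "amod", "pobj", "punct"),
    plant_range = c(12L, 12L), chem_range = c(5L, 5L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "V2",
    weak_trigger = "were obtained from", strong_trigger = "obtained",
    plant_ids = "Taxonomy:4577", chem_ids = "CAS:116355-83-0")

  f$V3 <- fixture_unit(
    "table1_V3", "17637489",
    c("The", "volatile", "oil", "(", "2-3", "%", ")", "of", "ginger",
      "consists", "of", "mainly", "mono", "and", "sesquiterpenes", "."),
    c(3L, 3L, 10L, 6L, 6L, 3L, 6L, 3L, 8L, 0L, 10L, 13L, 11L, 13L, 13L, 10L),
    c("det", "amod", "nsubj", "punct", "num", "appos", "punct", "prep",
      "pobj", "root", "prep", "advmod", "pobj", "cc", "conj", "punct"),
    plant_range = c(9L, 9L), chem_range = c(15L, 15L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "V3",
    weak_trigger = "consists of", strong_trigger = "consists",
    plant_ids = "Taxonomy:94328", chem_ids = "MeSH:D012717")

  f$P1 <- fixture_unit(
    "table1_P1", "22354956",
    c("Switchgrass", "as", "a", "sole", "carbon", "(", "C", ")", "source", "."),
    c(0L, 1L, 9L, 9L, 9L, 7L, 5L, 7L, 2L, 1L),
    c("root", "prep", "det", "amod", "nn", "punct", "appos", "punct",
      "pobj", "punct"),
    plant_range = c(1L, 1L), chem_range = c(5L, 5L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "P1",
    weak_trigger = "as", strong_trigger = "as",
    plant_ids = "Taxonomy:38727", chem_ids = "MeSH:D002244")

  f$P2 <- fixture_unit(
    "table1_P2", "20518315",
    c("Saponins", "from", "the", "flowers", "of", "Panax", "notoginseng", "."),
    c(0L, 1L, 4L, 2L, 4L, 7L, 5L, 1L),
    c("root", "prep", "det", "pobj", "prep", "nn", "pobj", "punct"),
    plant_range = c(6L, 7L), chem_range = c(1L, 1L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "P2",
    weak_trigger = "from", strong_trigger = "from",
    plant_ids = "Taxonomy:44586", chem_ids = "MeSH:D012503")

  f$R1 <- fixture_unit(
    "table1_R1", "16457818",
    c("Anthocyanins", "isolated", "from", "black", "soybean", "seed", "coat", "."),
    c(0L, 1L, 2L, 5L, 7L, 7L, 3L, 1L),
    c("root", "partmod", "prep", "amod", "nn", "nn", "pobj", "punct"),
    plant_range = c(4L, 5L), chem_range = c(1L, 1L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "R1",
    weak_trigger = "isolated from", strong_trigger = "isolated",
    chem_ids = "MeSH:D000872")

  f$R2 <- fixture_unit(
    "table1_R2", "11603284",
    c("With", "thermally", "degraded", "Feverfew", "powder", "containing",
      "less", "contents", "of", "parthenolide", "no", "antiserotonergic",
      "responses", "were", "observed", "after", "one", "month", "."),
    c(15L, 3L, 5L, 5L, 1L, 5L, 8L, 6L, 8L, 9L, 13L, 13L, 15L, 15L, 0L,
      15L, 18L, 16L, 15L),
    c("prep", "advmod", "amod", "nn", "pobj", "partmod", "amod", "dobj",
      "prep", "pobj", "det", "amod", "nsubjpass", "auxpass", "root",
      "prep", "num", "pobj", "punct"),
    plant_range = c(4L, 4L), chem_range = c(10L, 10L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "R2",
    weak_trigger = "containing", strong_trigger = "containing",
    plant_ids = "Taxonomy:99611", chem_ids = "CAS:20554-84-1")

  f$A1 <- fixture_unit(
    "table1_A1", "19932903",
    c("Whereas", "that", "in", "PD", "is", "soybean", "oil", ",", "a",
      "source", "of", "unsaturated", "fatty", "acids", "."),
    c(7L, 7L, 2L, 3L, 7L, 7L, 0L, 7L, 10L, 7L, 10L, 14L, 14L, 11L, 7L),
    c("mark", "nsubj", "prep", "pobj", "cop", "nn", "root", "punct", "det",
      "appos", "prep", "amod", "amod", "pobj", "punct"),
    plant_range = c(6L, 7L), chem_range = c(13L, 14L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "A1",
    weak_trigger = "a source of", strong_trigger = "source",
    chem_ids = "MeSH:D005227")

  f$A2 <- fixture_unit(
    "table1_A2", "9129126",
    c("Delta9-tetrahydrocannabinol", "(", "THC", ")", ",", "the", "major",
      "active", "component", "of", "marijuana", "."),
    c(0L, 3L, 1L, 3L, 1L, 9L, 9L, 9L, 1L, 9L, 10L, 1L),
    c("root", "punct", "appos", "punct", "punct", "det", "amod", "amod",
      "appos", "prep", "pobj", "punct"),
    plant_range = c(11L, 11L), chem_range = c(1L, 1L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "A2",
    weak_trigger = "the major active component of", strong_trigger = "component",
    plant_ids = "Taxonomy:3483", chem_ids = "MeSH:D013759")

  f$C1 <- fixture_unit(
    "table1_C1", "23605447",
    c("Haematococcus", "pluvialis", "is", "one", "of", "the", "potent",
      "organisms", "for", "production", "of", "astaxanthin", "."),
    c(2L, 4L, 4L, 0L, 4L, 8L, 8L, 5L, 8L, 9L, 10L, 11L, 4L),
    c("nn", "nsubj", "cop", "root", "prep", "det", "amod", "pobj", "prep",
      "pobj", "prep", "pobj", "punct"),
    plant_range = c(1L, 2L), chem_range = c(12L, 12L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "C1",
    weak_trigger = "is one of the potent organisms for production of",
    strong_trigger = "production",
    plant_ids = "Taxonomy:44745", chem_ids = "CAS:472-61-7")

  f$C2 <- fixture_unit(
    "table1_C2", "21695915",
    c("The", "calcium", "contents", "were", "the", "highest", "in", "the",
      "papaya", "."),
    c(3L, 3L, 6L, 6L, 6L, 0L, 6L, 9L, 7L, 6L),
    c("det", "nn", "nsubj", "cop", "det", "root", "prep", "det", "pobj",
      "punct"),
    plant_range = c(9L, 9L), chem_range = c(2L, 2L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "C2",
    weak_trigger = "were the highest in", strong_trigger = "in",
    plant_ids = "Taxonomy:3649", chem_ids = "MeSH:D002118")

  f$CN1 <- fixture_unit(
    "table1_CN1", "19317166",
    c("To", "study", "the", "protective", "effect", "of", "panax",
      "notoginseng", "saponins", "(", "PNS", ")", "."),
    c(2L, 0L, 5L, 5L, 2L, 5L, 8L, 9L, 6L, 11L, 9L, 11L, 2L),
    c("aux", "root", "det", "amod", "dobj", "prep", "nn", "nn", "pobj",
      "punct", "appos", "punct", "punct"),
    plant_range = c(7L, 8L), chem_range = c(9L, 9L),
    gold_label = "POS", expected_model_label = "POS", expected_rule_id = "CN1",
    weak_trigger = "panax notoginseng saponins", strong_trigger = "saponins",
    plant_ids = "Taxonomy:44586", chem_ids = "MeSH:D012503")

  # Documented semantic false positives: solvent-extract and agronomic
  # treatment contexts fire the prepositional rule although no containment
  # relationship holds.
  f$err_fp_solvent <- fixture_unit(
    "error_fp_solvent_extract", "90000001",
    c("The", "dichloromethane", "extract", "of", "Feverfew", "inhibited",
      "platelet", "aggregation", "."),
    c(3L, 3L, 6L, 3L, 4L, 0L, 8L, 6L, 6L),
    c("det", "nn", "nsubj", "prep", "pobj", "root", "nn", "dobj", "punct"),
    plant_range = c(5L, 5L), chem_range = c(2L, 2L),
    gold_label = "NEG", expected_model_label = "POS", expected_rule_id = "P2",
    plant_ids = "Taxonomy:99611", chem_ids = "CAS:75-09-2")

  f$err_fp_treatment <- fixture_unit(
    "error_fp_treatment", "90000002",
    c("Ammonia", "treatment", "of", "rice", "straw", "increased",
      "moisture", "content", "."),
    c(2L, 6L, 2L, 5L, 3L, 0L, 8L, 6L, 6L),
    c("nn", "nsubj", "prep", "nn", "pobj", "root", "nn", "dobj", "punct"),
    plant_range = c(4L, 5L), chem_range = c(1L, 1L),
    gold_label = "NEG", expected_model_label = "POS", expected_rule_id = "P2",
    chem_ids = "MeSH:D000641")

  # Documented structural false negatives: no rule covers "plant-specific
  # chemical" or a relation expressed through brackets.
  fn1_tokens <- c("Smokeless", "products", "deliver", "tobacco-specific",
                  "nitrosamines", ".")
  fn1_text <- detokenize(fn1_tokens)
  f$err_fn_specific <- fixture_unit(
    "error_fn_plant_specific", "90000003",
    fn1_tokens,
    c(2L, 3L, 0L, 5L, 3L, 3L),
    c("amod", "nsubj", "root", "amod", "dobj", "punct"),
    plant_range = NULL, chem_range = c(5L, 5L),
    plant_span = {
      s <- regexpr("tobacco", fn1_text, fixed = TRUE)
      c(s - 1L, s - 1L + 7L)
    },
    gold_label = "POS", expected_model_label = "NEG",
    weak_trigger = "tobacco-specific", strong_trigger = "tobacco-specific",
    plant_ids = "Taxonomy:4097", chem_ids = "MeSH:D009602")

  f$err_fn_bracket <- fixture_unit(
    "error_fn_bracketed", "90000004",
    c("GC-olfactometry", "identified", "3-(methylthio)propanal", "(",
      "cooked", "potato", ")", "among", "the", "odorants", "."),
    c(2L, 0L, 2L, 6L, 6L, 3L, 6L, 2L, 10L, 8L, 2L),
    c("nsubj", "root", "dobj", "punct", "amod", "dep", "punct", "prep",
      "det", "pobj", "punct"),
    plant_range = c(6L, 6L), chem_range = c(3L, 3L),
    gold_label = "POS", expected_model_label = "NEG",
    weak_trigger = "( )", strong_trigger = "(",
    plant_ids = "Taxonomy:4113", chem_ids = "CAS:3268-49-3")

  unname(f)
}

# --- synthetic corpus generator -------------------------------------------

PLANT_POOL <- list(
  "Punica granatum", "ginger", "corn", "switchgrass", "Panax notoginseng",
  "black soybean", "Feverfew", "soybean", "marijuana",
  "Haematococcus pluvialis", "papaya", "rice", "tobacco", "potato",
  "masson pine", "Pinus massoniana", "aloe", "tomato", "kiwifruit",
  "Ginkgo biloba", "cucumber", "Cimicifuga racemosa"
)

CHEM_POOL <- list(
  "anthocyanins", "FB1", "sesquiterpenes", "saponins", "parthenolide",
  "astaxanthin", "calcium", "nitrogen", "ammonia", "nitrosamines",
  "emodin", "actinidin", "bilobalide", "anthocyanin", "carbon"
)

name_heads <- function(start, len, attach, label) {
  list(heads = c(rep.int(start + len - 1L, len - 1L), attach),
       labels = c(rep.int("nn", len - 1L), label))
}

split_name <- function(name) strsplit(name, " ", fixed = TRUE)[[1L]]

# Each template returns list(tokens, heads, labels, plant_range,
# chem_range, weak, strong, rule). pl/ch are token vectors of the sampled
# names; trig is drawn from the relevant trigger set.
TEMPLATES_POS <- list(
  V1 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    p <- name_heads(1L, k, k + 1L, "nsubj")
    c0 <- name_heads(k + 2L, m, k + 1L, "dobj")
    list(tokens = c(pl, trig, ch, "."),
         heads = c(p$heads, 0L, c0$heads, k + 1L),
         labels = c(p$labels, "root", c0$labels, "punct"),
         plant_range = c(1L, k), chem_range = c(k + 2L, k + 1L + m),
         weak = trig, strong = trig, rule = "V1")
  },
  V2 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    v <- 6L + m
    c0 <- name_heads(5L, m, 4L, "pobj")
    p <- name_heads(9L + m, k, 7L + m, "pobj")
    list(tokens = c("About", "450", "mg", "of", ch, "were", trig, "from",
                    "cultured", pl, "."),
         heads = c(2L, 3L, v, 3L, c0$heads, v, 0L, v, 8L + m + k, p$heads, v),
         labels = c("quantmod", "num", "nsubjpass", "prep", c0$labels,
                    "auxpass", "root", "prep", "amod", p$labels, "punct"),
         plant_range = c(9L + m, 8L + m + k), chem_range = c(5L, 4L + m),
         weak = paste("were", trig, "from"), strong = trig, rule = "V2")
  },
  V3 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    v <- 4L + k
    p <- name_heads(4L, k, 3L, "pobj")
    c0 <- name_heads(6L + k, m, 5L + k, "pobj")
    list(tokens = c("The", "oil", "of", pl, "consists", "of", ch, "."),
         heads = c(2L, v, 2L, p$heads, 0L, v, c0$heads, v),
         labels = c("det", "nsubj", "prep", p$labels, "root", "prep",
                    c0$labels, "punct"),
         plant_range = c(4L, 3L + k), chem_range = c(6L + k, 5L + k + m),
         weak = "consists of", strong = "consists", rule = "V3")
  },
  P1 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    p <- name_heads(1L, k, 0L, "root")
    c0 <- name_heads(k + 6L, m, k + 5L, "pobj")
    list(tokens = c(pl, "as", "a", "sole", "source", "of", ch, "."),
         heads = c(p$heads, k, k + 4L, k + 4L, k + 1L, k + 4L, c0$heads, k),
         labels = c(p$labels, "prep", "det", "amod", "pobj", "prep",
                    c0$labels, "punct"),
         plant_range = c(1L, k), chem_range = c(k + 6L, k + 5L + m),
         weak = "as", strong = "as", rule = "P1")
  },
  P2 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    c0 <- name_heads(1L, m, 0L, "root")
    p <- name_heads(m + 5L, k, m + 4L, "pobj")
    list(tokens = c(ch, "from", "the", "flowers", "of", pl, "."),
         heads = c(c0$heads, m, m + 3L, m + 1L, m + 3L, p$heads, m),
         labels = c(c0$labels, "prep", "det", "pobj", "prep", p$labels,
                    "punct"),
         plant_range = c(m + 5L, m + 4L + k), chem_range = c(1L, m),
         weak = "from", strong = "from", rule = "P2")
  },
  R1 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    c0 <- name_heads(1L, m, 0L, "root")
    p <- name_heads(m + 3L, k, m + 2L, "pobj")
    list(tokens = c(ch, trig, "from", pl, "."),
         heads = c(c0$heads, m, m + 1L, p$heads, m),
         labels = c(c0$labels, "partmod", "prep", p$labels, "punct"),
         plant_range = c(m + 3L, m + 2L + k), chem_range = c(1L, m),
         weak = paste(trig, "from"), strong = trig, rule = "R1")
  },
  R2 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    pw <- 2L + k            # "powder"
    gd <- 3L + k            # gerund
    p <- name_heads(2L, k, pw, "nn")
    if (identical(trig, "consisting")) {
      c0 <- name_heads(5L + k, m, 4L + k, "pobj")
      sh <- 5L + k + m
      list(tokens = c("Dried", pl, "powder", trig, "of", ch, "showed",
                      "activity", "."),
           heads = c(pw, p$heads, sh, pw, gd, c0$heads, 0L, sh, sh),
           labels = c("amod", p$labels, "nsubj", "partmod", "prep",
                      c0$labels, "root", "dobj", "punct"),
           plant_range = c(2L, 1L + k), chem_range = c(5L + k, 4L + k + m),
           weak = paste(trig, "of"), strong = trig, rule = "R2")
    } else {
      c0 <- name_heads(4L + k, m, gd, "dobj")
      sh <- 4L + k + m
      list(tokens = c("Dried", pl, "powder", trig, ch, "showed",
                      "activity", "."),
           heads = c(pw, p$heads, sh, pw, c0$heads, 0L, sh, sh),
           labels = c("amod", p$labels, "nsubj", "partmod", c0$labels,
                      "root", "dobj", "punct"),
           plant_range = c(2L, 1L + k), chem_range = c(4L + k, 3L + k + m),
           weak = trig, strong = trig, rule = "R2")
    }
  },
  A1 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    p <- name_heads(1L, k, 0L, "root")
    c0 <- name_heads(k + 5L, m, k + 4L, "pobj")
    list(tokens = c(pl, ",", "a", "source", "of", ch, "."),
         heads = c(p$heads, k, k + 3L, k, k + 3L, c0$heads, k),
         labels = c(p$labels, "punct", "det", "appos", "prep", c0$labels,
                    "punct"),
         plant_range = c(1L, k), chem_range = c(k + 5L, k + 4L + m),
         weak = "a source of", strong = "source", rule = "A1")
  },
  A2 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    c0 <- name_heads(1L, m, 0L, "root")
    cp <- m + 4L            # "component"
    p <- name_heads(m + 6L, k, m + 5L, "pobj")
    list(tokens = c(ch, ",", "the", "major", "component", "of", pl, "."),
         heads = c(c0$heads, m, cp, cp, m, cp, p$heads, m),
         labels = c(c0$labels, "punct", "det", "amod", "appos", "prep",
                    p$labels, "punct"),
         plant_range = c(m + 6L, m + 5L + k), chem_range = c(1L, m),
         weak = "the major component of", strong = "component", rule = "A2")
  },
  C1 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    sr <- k + 4L            # "source", copular predicate
    p <- name_heads(1L, k, sr, "nsubj")
    c0 <- name_heads(k + 6L, m, k + 5L, "pobj")
    list(tokens = c(pl, "is", "a", "rich", "source", "of", ch, "."),
         heads = c(p$heads, sr, sr, sr, 0L, sr, c0$heads, sr),
         labels = c(p$labels, "cop", "det", "amod", "root", "prep",
                    c0$labels, "punct"),
         plant_range = c(1L, k), chem_range = c(k + 6L, k + 5L + m),
         weak = "is a rich source of", strong = "source", rule = "C1")
  },
  C2 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    ct <- 2L + m            # "contents"
    hi <- 5L + m            # "highest", copular predicate
    c0 <- name_heads(2L, m, ct, "nn")
    p <- name_heads(8L + m, k, 6L + m, "pobj")
    list(tokens = c("The", ch, "contents", "were", "the", "highest", "in",
                    "the", pl, "."),
         heads = c(ct, c0$heads, hi, hi, hi, 0L, hi, 7L + m + k, p$heads, hi),
         labels = c("det", c0$labels, "nsubj", "cop", "det", "root", "prep",
                    "det", p$labels, "punct"),
         plant_range = c(8L + m, 7L + m + k), chem_range = c(2L, 1L + m),
         weak = "were the highest in", strong = "in", rule = "C2")
  },
  CN1 = function(pl, ch, trig) {
    k <- length(pl); m <- length(ch)
    ch_head <- 3L + k + m
    p <- name_heads(4L, k, ch_head, "nn")
    c0 <- name_heads(4L + k, m, 3L, "dobj")
    list(tokens = c("This", "study", "investigated", pl, ch, "."),
         heads = c(2L, 3L, 0L, p$heads, c0$heads, 3L),
         labels = c("det", "nsubj", "root", p$labels, c0$labels, "punct"),
         plant_range = c(4L, 3L + k), chem_range = c(4L + k, 3L + k + m),
         weak = paste(c(pl, ch), collapse = " "), strong = ch[[m]],
         rule = "CN1")
  }
)

TEMPLATES_NEG <- list(
  treated_with = function(pl, ch) {
    k <- length(pl); m <- length(ch)
    v <- k + 2L
    p <- name_heads(1L, k, v, "nsubjpass")
    c0 <- name_heads(k + 4L, m, k + 3L, "pobj")
    list(tokens = c(pl, "was", "treated", "with", ch, "."),
         heads = c(p$heads, v, 0L, v, c0$heads, v),
         labels = c(p$labels, "auxpass", "root", "prep", c0$labels, "punct"),
         plant_range = c(1L, k), chem_range = c(k + 4L, k + 3L + m))
  },
  outperformed = function(pl, ch) {
    k <- length(pl); m <- length(ch)
    tr <- 2L + m            # "treatment"
    v <- 3L + m             # "outperformed"
    yd <- 7L + m + k        # "yield"
    c0 <- name_heads(2L, m, tr, "nn")
    p <- name_heads(7L + m, k, yd, "nn")
    list(tokens = c("The", ch, "treatment", "outperformed", "all",
                    "controls", "in", pl, "yield", "."),
         heads = c(tr, c0$heads, v, 0L, 5L + m, v, v, p$heads, 6L + m, v),
         labels = c("det", c0$labels, "nsubj", "root", "det", "dobj",
                    "prep", p$labels, "pobj", "punct"),
         plant_range = c(7L + m, 6L + m + k), chem_range = c(2L, 1L + m))
  },
  not_affected = function(pl, ch) {
    k <- length(pl); m <- length(ch)
    gw <- k + 1L            # "growth"
    v <- k + 4L             # "affected"
    p <- name_heads(1L, k, gw, "nn")
    c0 <- name_heads(k + 6L, m, k + 5L, "pobj")
    list(tokens = c(pl, "growth", "was", "not", "affected", "by", ch, "."),
         heads = c(p$heads, v, v, v, 0L, v, c0$heads, v),
         labels = c(p$labels, "nsubjpass", "auxpass", "neg", "root", "prep",
                    c0$labels, "punct"),
         plant_range = c(1L, k), chem_range = c(k + 6L, k + 5L + m))
  }
)

# Confounder templates reproduce the documented semantic false positives:
# gold NEG, model expected to fire the prepositional rule (P2).
TEMPLATES_CONFOUNDER <- list(
  solvent_extract = function(pl, ch) {
    k <- length(pl); m <- length(ch)
    ex <- 2L + m            # "extract"
    sh <- 4L + m + k        # "showed"
    c0 <- name_heads(2L, m, ex, "nn")
    p <- name_heads(4L + m, k, 3L + m, "pobj")
    list(tokens = c("The", ch, "extract", "of", pl, "showed",
                    "antimicrobial", "activity", "."),
         heads = c(ex, c0$heads, sh, ex, p$heads, 0L, 6L + m + k, sh, sh),
         labels = c("det", c0$labels, "nsubj", "prep", p$labels, "root",
                    "amod", "dobj", "punct"),
         plant_range = c(4L + m, 3L + m + k), chem_range = c(2L, 1L + m))
  },
  treatment = function(pl, ch) {
    k <- length(pl); m <- length(ch)
    tr <- m + 1L            # "treatment"
    cr <- m + 3L + k        # "crops"
    v <- m + 4L + k         # "improved"
    c0 <- name_heads(1L, m, tr, "nn")
    p <- name_heads(m + 3L, k, cr, "nn")
    list(tokens = c(ch, "treatment", "of", pl, "crops", "improved",
                    "growth", "."),
         heads = c(c0$heads, v, tr, p$heads, m + 2L, 0L, v, v),
         labels = c(c0$labels, "nsubj", "prep", p$labels, "pobj", "root",
                    "dobj", "punct"),
         plant_range = c(m + 3L, m + 2L + k), chem_range = c(1L, m))
  }
)

build_template_fixture <- function(template_id, spec, pmid, gold_label,
                                   expected_model_label, expected_rule_id) {
  # sentence-initial capitalization, as in real abstracts
  substr(spec$tokens[[1L]], 1L, 1L) <- toupper(substr(spec$tokens[[1L]], 1L, 1L))
  fixture_unit(template_id, pmid, spec$tokens, spec$heads, spec$labels,
               plant_range = spec$plant_range, chem_range = spec$chem_range,
               gold_label = gold_label,
               expected_model_label = expected_model_label,
               expected_rule_id = expected_rule_id,
               weak_trigger = if (identical(gold_label, "POS")) spec$weak,
               strong_trigger = if (identical(gold_label, "POS")) spec$strong)
}

#' Generate a synthetic labeled corpus with gold parses
#'
#' Builds `n` fixture units from parameterized sentence templates:
#' positives from the twelve rule structures (each positive is matched by
#' exactly its template's rule family), negatives from trigger-free
#' templates, and confounders from the documented false-positive patterns
#' (solvent extract, agronomic treatment: gold NEG but the model fires the
#' prepositional rule). The realized class mix equals the requested counts
#' exactly (`round(n * confounder_fraction)` confounders,
#' `round(n * positive_fraction)` positives, the rest negatives), shuffled
#' by the seed; the whole corpus is a deterministic function of the
#' arguments.
#'
#' @param n Number of units (>= 0).
#' @param positive_fraction,confounder_fraction Fractions in \[0, 1\]
#'   (their implied counts must not exceed `n`).
#' @param seed Integer seed.
#' @return List of `fixture_unit` objects (see [table1_fixtures()]).
#' @export
generate_units <- function(n, positive_fraction = 0.5,
                           confounder_fraction = 0, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 0L, positive_fraction >= 0, positive_fraction <= 1,
            confounder_fraction >= 0, confounder_fraction <= 1)
  n_conf <- as.integer(round(n * confounder_fraction))
  n_pos <- as.integer(round(n * positive_fraction))
  n_neg <- n - n_pos - n_conf
  if (n_neg < 0L) stop("positive_fraction + confounder_fraction exceed 1", call. = FALSE)
  if (n == 0L) return(list())
  triggers <- load_trigger_lexicon()
  withr::with_seed(as.integer(seed), {
    kinds <- sample(c(rep("POS", n_pos), rep("NEG", n_neg), rep("CONF", n_conf)))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      pl <- split_name(PLANT_POOL[[sample.int(length(PLANT_POOL), 1L)]])
      ch <- split_name(CHEM_POOL[[sample.int(length(CHEM_POOL), 1L)]])
      pmid <- sprintf("SYN%05d", i)
      kind <- kinds[[i]]
      if (kind == "POS") {
        ti <- (i - 1L) %% length(TEMPLATES_POS) + 1L
        rule <- names(TEMPLATES_POS)[[ti]]
        trig <- switch(substr(rule, 1L, 1L),
          V = switch(rule,
                     V1 = sample(triggers$active, 1L),
                     V2 = sample(triggers$passive, 1L),
                     V3 = "consists"),
          R = if (rule == "R1") sample(triggers$passive, 1L)
              else sample(triggers$gerund, 1L),
          NA_character_)
        spec <- TEMPLATES_POS[[ti]](pl, ch, trig)
        out[[i]] <- build_template_fixture(paste0("syn_", rule), spec, pmid,
                                           "POS", "POS", spec$rule)
      } else if (kind == "NEG") {
        ti <- (i - 1L) %% length(TEMPLATES_NEG) + 1L
        spec <- TEMPLATES_NEG[[ti]](pl, ch)
        out[[i]] <- build_template_fixture(
          paste0("syn_neg_", names(TEMPLATES_NEG)[[ti]]), spec, pmid,
          "NEG", "NEG", NULL)
      } else {
        ti <- (i - 1L) %% length(TEMPLATES_CONFOUNDER) + 1L
        spec <- TEMPLATES_CONFOUNDER[[ti]](pl, ch)
        out[[i]] <- build_template_fixture(
          paste0("syn_confounder_", names(TEMPLATES_CONFOUNDER)[[ti]]), spec,
          pmid, "NEG", "POS", "P2")
      }
    }
    out
  })
}

#' Classify fixture units with the rule-based model
#'
#' @param fixtures List of `fixture_unit` objects.
#' @param triggers A [trigger_lexicon()].
#' @param ... Passed to [classify_unit()].
#' @return Data frame with columns `template_id`, `gold`, `expected`,
#'   `predicted`, `rule_id` (reported rule or `NA`).
#' @export
classify_fixtures <- function(fixtures, triggers = load_trigger_lexicon(), ...) {
  rows <- lapply(fixtures, function(fx) {
    res <- classify_unit(fx$graph, fx$unit, triggers, ...)
    data.frame(template_id = fx$template_id, gold = fx$gold_label,
               expected = fx$expected_model_label, predicted = res$label,
               rule_id = if (length(res$matches)) res$matches[[1L]]$rule_id
                         else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Package fixture units as abstract documents
#'
#' Groups fixture units by PMID; sentences sharing a PMID are laid out
#' sequentially (single space between them) and unit offsets updated, so
#' the result satisfies the document invariants and can be written with
#' [write_bioc()].
#'
#' @param fixtures List of `fixture_unit` objects.
#' @return Corpus list (`list(doc =, units =)` per document) as used by
#'   [write_bioc()].
#' @export
fixtures_to_docs <- function(fixtures) {
  pmids <- vapply(fixtures, function(fx) fx$unit$pmid, character(1))
  out <- list()
  for (pmid in unique(pmids)) {
    group <- fixtures[pmids == pmid]
    texts <- unique(vapply(group, function(fx) fx$unit$sentence$text, character(1)))
    offsets <- cumsum(c(0L, utils::head(nchar(texts) + 1L, -1L)))
    names(offsets) <- texts
    sentences <- list()
    units <- list()
    for (txt in texts) {
      g_units <- Filter(function(fx) identical(fx$unit$sentence$text, txt), group)
      mentions <- list()
      for (fx in g_units) mentions <- c(mentions, list(fx$unit$plant, fx$unit$chemical))
      keys <- vapply(mentions, mention_key, character(1))
      mentions <- mentions[!duplicated(keys)]
      srec <- sentence_record(offsets[[txt]], txt, mentions)
      sentences <- c(sentences, list(srec))
      for (fx in g_units) {
        u <- fx$unit
        units <- c(units, list(corpus_unit(srec, u$plant, u$chemical,
                                           label = u$label,
                                           weak_trigger = u$weak_trigger,
                                           strong_trigger = u$strong_trigger,
                                           provenance = u$provenance,
                                           pmid = u$pmid)))
      }
    }
    doc <- abstract_doc(pmid, paste(texts, collapse = " "), sentences)
    out[[length(out) + 1L]] <- list(doc = doc, units = units)
  }
  out
}
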