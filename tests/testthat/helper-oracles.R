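# Independent brute-force oracles used by the property suites.

# Enumerate every (start token, term) dictionary match, then greedily pick
# the left-most, longest, non-overlapping matches.
brute_match_spans <- function(text, lexicon) {
  toks <- plantchem:::tokenize_alnum(text)
  low <- tolower(toks$text)
  cands <- list()
  for (term in names(lexicon$entries)) {
    tt <- plantchem:::term_tokens(term)
    k <- length(tt)
    if (k == 0L) next
    for (i in seq_len(max(0L, nrow(toks) - k + 1L))) {
      if (all(low[i:(i + k - 1L)] == tt)) {
        cands[[length(cands) + 1L]] <- c(i, i + k - 1L)
      }
    }
  }
  if (length(cands) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, cands)
  m <- m[order(m[, 1L], -m[, 2L]), , drop = FALSE]
  sel <- list()
  blocked <- -1L
  for (r in seq_len(nrow(m))) {
    if (m[r, 1L] <= blocked) next
    sel[[length(sel) + 1L]] <- m[r, ]
    blocked <- m[r, 2L]
  }
  s <- do.call(rbind, sel)
  data.frame(start = toks$start[s[, 1L]], end = toks$end[s[, 2L]])
}

mention_spans <- function(mentions) {
  data.frame(start = vapply(mentions, `[[`, integer(1), "start"),
             end = vapply(mentions, `[[`, integer(1), "end"))
}

# Random single-rooted labeled tree on n tokens (node i's parent is an
# earlier node under a random permutation, guaranteeing acyclicity).
random_tree <- function(n, labels = c("nsubj", "dobj", "prep", "pobj", "nn",
                                      "amod", "det", "conj", "appos",
                                      "partmod", "punct", "advmod", "cop")) {
  order <- sample.int(n)
  heads <- integer(n)
  labs <- character(n)
  heads[order[1L]] <- 0L
  labs[order[1L]] <- "root"
  if (n > 1L) {
    for (i in 2:n) {
      heads[order[i]] <- order[sample.int(i - 1L, 1L)]
      labs[order[i]] <- sample(labels, 1L)
    }
  }
  dep_graph(paste0("w", seq_len(n)), heads, labs)
}

brute_reachable <- function(graph, head, blocked = character(0)) {
  acc <- head
  repeat {
    nxt <- which(graph$heads %in% acc & !(graph$labels %in% blocked))
    nxt <- setdiff(nxt, acc)
    if (length(nxt) == 0L) break
    acc <- c(acc, nxt)
  }
  sort(acc)
}

brute_mention_head <- function(graph, mention) {
  toks <- which(graph$tokens$start < mention$end & graph$tokens$end > mention$start)
  cand <- toks[!(graph$heads[toks] %in% toks)]
  if (length(cand) == 0L) cand <- toks
  max(cand)
}

brute_kappa <- function(m) {
  total <- sum(m)
  po <- sum(diag(m)) / total
  pe <- sum(rowSums(m) * colSums(m)) / total^2
  (po - pe) / (1 - pe)
}

fixture_by_id <- function(fixtures, id) {
  hit <- Filter(function(fx) identical(fx$template_id, id), fixtures)
  stopifnot(length(hit) == 1L)
  hit[[1L]]
}

unit_heads <- function(fx) {
  list(plant = mention_head(fx$graph, fx$unit$plant),
       chem = mention_head(fx$graph, fx$unit$chemical))
}
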