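# shared resources (loaded once per test run) and reference clauses
test_res <- ft_resources()

# printed clause of Quercus salicifolia used throughout as a reference case
quercus_clause <- paste(
  "hojas simples, alternas, 4-10 (-14) × 1-3.3 cm., elípticas,",
  "ápice acuminado, caudado o agudo, base caudada u obtusa,",
  "glabras o a veces con tricomas dispersos a lo largo de la vena central",
  "por el envés")

# clause of the shrub Hydrangea asterolasia whose association the
# gender/number heuristic is known to get wrong
hydrangea_clause <- paste(
  "lámina 3-12 (-13) x 2-6 (-7) cm, oblonga o elíptica,",
  "obtusa o redondeada en la base, aguda o cortamente acuminada en el ápice,",
  "muy espaciadamente serrada a subentera o entera,",
  "esparcidamente pubescente con tricomas rojos (raramente crema rojizo),",
  "usualmente con puntuaciones negras en el envés.")

# character rows joined with the name of their structure
chars_with_structure <- function(ad) {
  idx <- match(ad$characters$structure_id, ad$structures$id)
  out <- ad$characters
  out$structure <- ad$structures$name[idx]
  out
}

# brute-force association oracle: enumerate all (character, structure)
# pairs, keep those whose gender and number agree (unknown wildcards),
# prefer the most recent; fall back to the main structure
oracle_associate <- function(gender, number, context, main) {
  ok <- function(a, b) a == b | a == "unknown" | b == "unknown"
  idx <- which(ok(gender, context$gender) & ok(number, context$number))
  if (length(idx)) context$id[max(idx)] else main
}

# gender/number of a structure or state token as the pipeline sees it
token_gn <- function(token, res = test_res) {
  hit <- match(token, res$lexicon$token)
  if (!is.na(hit) && res$lexicon$tag[hit] %in% c("E", "A")) {
    return(c(res$lexicon$gender[hit], res$lexicon$number[hit]))
  }
  m <- morphology(token, res$gender_exceptions)
  c(m$gender, m$number)
}

# exhaustive closure oracle for the bootstrap: build the word graph of
# "w1 <sep> w2" adjacencies (sep = "a" or a coordinating conjunction) over
# the whole corpus and label every out-of-lexicon word whose connected
# component contains a known character state
oracle_bootstrap_closure <- function(chunk_texts, res = test_res) {
  seps <- c("a", "o", "u", "y", "e")
  nodes <- character(); edges <- list()
  for (text in chunk_texts) {
    t <- tokenize_chunk(text)$norm
    w <- !(t %in% seps)
    nodes <- c(nodes, t[w])
    for (i in seq_along(t)) {
      if (i + 2L <= length(t) && t[i + 1L] %in% seps && w[i] && w[i + 2L]) {
        edges[[length(edges) + 1L]] <- c(t[i], t[i + 2L])
      }
    }
  }
  nodes <- unique(nodes)
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (e in edges) {
      m <- min(comp[e]); if (any(comp[e] != m)) {
        comp[comp %in% comp[e]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  known_a <- res$lexicon$token[res$lexicon$tag == "A"]
  a_comps <- unique(comp[names(comp) %in% known_a])
  learned <- names(comp)[comp %in% a_comps]
  sort(setdiff(learned, res$lexicon$token))
}
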