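#' Fixture grammar for synthetic telegraphic descriptions
#'
#' Defines the chunk-pattern mixture and vocabularies the generator draws
#' from. The four base patterns mirror the dominant grammar of telegraphic
#' botanical Spanish -- noun+adjective (NA), bare adjective (A), measurement
#' with a dimension noun (ZUSE, e.g. `6-30 m de altura`) and two-dimension
#' expressions (ZGZU, e.g. `6-30 × 2-10.5 cm`) -- weighted by their printed
#' corpus frequencies (17.5, 12.5, 9.8 and 4.2 percent, renormalized).
#' Clause-level features exercise the remaining code paths: a conjunction
#' chunk (`noun adj o adj`), a con/sin prepositional phrase creating a
#' relation, and an agreement-fallback chunk whose adjective skips the
#' nearest structure and must resolve to an earlier one.
#'
#' All vocabulary is drawn from the bundled lexicon and glossary, so every
#' generated state resolves to at least one character name.
#'
#' @param weights Named numeric mixture over `c("na", "a", "zuse", "zgzu")`;
#'   normalized to sum to 1.
#' @param p_conjunction,p_con,p_fallback Probabilities that a clause carries
#'   a conjunction chunk, a con/sin relation chunk, or an agreement-fallback
#'   chunk.
#' @param resources An [ft_resources()] list supplying the vocabularies.
#' @return A list of class `fixture_grammar`.
#' @export
fixture_grammar <- function(weights = c(na = 17.5, a = 12.5, zuse = 9.8,
                                        zgzu = 4.2),
                            p_conjunction = 0.15, p_con = 0.15,
                            p_fallback = 0.15,
                            resources = ft_resources()) {
  stopifnot(setequal(names(weights), c("na", "a", "zuse", "zgzu")),
            all(weights >= 0), sum(weights) > 0)
  lex <- resources$lexicon
  nouns <- lex[lex$tag == "E" &
                 !(lex$token %in% dimension_nouns) &
                 lex$gender %in% c("m", "f") &
                 lex$number %in% c("singular", "plural"), ]
  states <- lex[lex$tag == "A", ]
  # states usable in agreement-sensitive positions need an overtly gendered
  # and numbered form
  structure(
    list(
      weights = weights / sum(weights),
      p_conjunction = p_conjunction, p_con = p_con, p_fallback = p_fallback,
      nouns = nouns, states = states,
      units = c("cm", "mm", "m"),
      dim_nouns = c("altura", "longitud", "grosor"),
      resources = resources
    ),
    class = "fixture_grammar"
  )
}

# pick one matching state form; exact = require overt gender match
draw_state <- function(grammar, gender, number, exact = FALSE) {
  st <- grammar$states
  ok <- if (exact) {
    st$gender == gender & st$number == number
  } else {
    (st$gender == gender | st$gender == "unknown") & st$number == number
  }
  cand <- st$token[ok]
  cand[sample.int(length(cand), 1L)]
}

draw_noun <- function(grammar, exclude = character()) {
  cand <- grammar$nouns[!(grammar$nouns$token %in% exclude), ]
  cand[sample.int(nrow(cand), 1L), ]
}

fmt_num <- function(x) sub("\\.0$", "", sprintf("%.1f", x))

draw_range <- function(max_from = 20) {
  from <- round(stats::runif(1, 0.5, max_from), 1)
  to <- round(from + stats::runif(1, 0.5, 15), 1)
  atyp <- if (stats::runif(1) < 0.3) round(to + stats::runif(1, 0.5, 5), 1)
          else NA_real_
  list(from = fmt_num(from), to = fmt_num(to),
       atypical_to = if (is.na(atyp)) NA_character_ else fmt_num(atyp))
}

range_text <- function(r) {
  paste0(r$from, "-", r$to,
         if (!is.na(r$atypical_to)) paste0(" (-", r$atypical_to, ")") else "")
}

add_gold_measurement <- function(acc, counter, structure_id, name, r, unit) {
  acc_add_character(acc, counter, structure_id, name,
                    value = paste0(r$from, "-", r$to),
                    char_type = "range_value", from = r$from, to = r$to,
                    from_unit = unit, to_unit = unit,
                    atypical_to = r$atypical_to)
}

#' Generate synthetic descriptions with gold annotations
#'
#' Builds `n_clauses` telegraphic clauses (grouped into descriptions of up
#' to three clauses), together with the exact structures, characters and
#' relations an annotator must produce -- the gold is known by construction,
#' including for non-adjacent agreement cases where a state must skip the
#' nearest structure. Deterministic given `seed`.
#'
#' @param n_clauses Number of clauses to generate (>= 0).
#' @param seed Integer seed.
#' @param grammar A [fixture_grammar()].
#' @return A list with elements `records` (tibble: `taxon`, `description`)
#'   and `gold` (list of [annotated_description()] objects, aligned with
#'   the records).
#' @export
generate_fixtures <- function(n_clauses, seed = 1L,
                              grammar = fixture_grammar()) {
  stopifnot(n_clauses >= 0)
  withr::local_seed(seed)
  res <- grammar$resources
  records <- tibble::tibble(taxon = character(), description = character())
  gold <- list()
  if (n_clauses == 0) return(list(records = records, gold = gold))

  per_desc <- 3L
  n_desc <- ceiling(n_clauses / per_desc)
  clause_of_desc <- rep(seq_len(n_desc), each = per_desc)[seq_len(n_clauses)]

  for (d in seq_len(n_desc)) {
    counter <- new_id_counter()
    acc <- new_accumulator()
    clause_texts <- character()
    n_cl <- sum(clause_of_desc == d)
    for (li in seq_len(n_cl)) {
      cl <- build_fixture_clause(grammar, res, acc, counter,
                                 sprintf("T%dL%d", d, li))
      clause_texts <- c(clause_texts, cl)
    }
    taxon <- sprintf("Synthetica fixta %03d", d)
    description <- paste0(paste(clause_texts, collapse = "; "), ".")
    clause_ids <- sprintf("T%dL%d", d, seq_len(n_cl))
    chunk_rows <- purrr::map2_dfr(clause_ids, clause_texts, function(cid, txt) {
      ch <- segment_chunks(txt)
      tibble::tibble(chunk_id = paste0(cid, "S", seq_along(ch)),
                     clause_id = cid, text = ch)
    })
    parts <- acc_tibbles(acc)
    gold[[d]] <- annotated_description(
      taxon_name = taxon,
      clauses = tibble::tibble(clause_id = clause_ids, text = clause_texts),
      chunks = chunk_rows,
      structures = parts$structures, characters = parts$characters,
      relations = parts$relations, constraint_spans = parts$constraint_spans)
    records <- dplyr::bind_rows(records, tibble::tibble(
      taxon = taxon, description = description))
  }
  list(records = records, gold = gold)
}

# build one clause; writes gold objects into acc and returns the clause text
build_fixture_clause <- function(grammar, res, acc, counter, clause_id) {
  add_state_chars <- function(structure_id, state, conj = NA_character_,
                              names_tbl = NULL) {
    if (is.null(names_tbl)) names_tbl <- resolve_state(state, res)
    for (j in seq_along(names_tbl$name)) {
      acc_add_character(acc, counter, structure_id, names_tbl$name[j], state,
                        notes = join_notes(names_tbl$notes[j], conj))
    }
    names_tbl
  }
  ctx <- new_clause_context()
  add_structure <- function(noun_row) {
    id <- acc_add_structure(acc, counter, clause_id, noun_row$token)
    ctx_add_structure(ctx, id, noun_row$token, noun_row$gender,
                      noun_row$number)
    id
  }

  chunks <- character()

  # first chunk always introduces the clause's main structure (noun + state)
  main_noun <- draw_noun(grammar)
  main_id <- add_structure(main_noun)
  state <- draw_state(grammar, main_noun$gender, main_noun$number)
  add_state_chars(main_id, state)
  chunks <- c(chunks, paste(main_noun$token, state))

  n_extra <- sample.int(3L, 1L)
  patterns <- sample(names(grammar$weights), n_extra, replace = TRUE,
                     prob = grammar$weights)
  for (p in patterns) {
    if (p == "na") {
      noun <- draw_noun(grammar, exclude = ctx$names)
      sid <- add_structure(noun)
      st <- draw_state(grammar, noun$gender, noun$number)
      add_state_chars(sid, st)
      chunks <- c(chunks, paste(noun$token, st))
    } else if (p == "a") {
      # bare-adjective chunk: the state associates by agreement with the
      # most recent agreeing structure
      st <- draw_state(grammar, ctx$genders[length(ctx$ids)],
                       ctx$numbers[length(ctx$ids)])
      lexrow <- match(st, res$lexicon$token)
      target <- associate_vec(res$lexicon$gender[lexrow],
                              res$lexicon$number[lexrow], ctx)
      add_state_chars(target, st)
      chunks <- c(chunks, st)
    } else if (p == "zuse") {
      r <- draw_range()
      unit <- grammar$units[sample.int(length(grammar$units), 1L)]
      dim_noun <- grammar$dim_nouns[sample.int(length(grammar$dim_nouns), 1L)]
      name <- translate_term(dim_noun, res$glossary)$term_en
      add_gold_measurement(acc, counter, ctx$ids[length(ctx$ids)], name, r,
                           unit)
      chunks <- c(chunks, paste(range_text(r), unit, "de", dim_noun))
    } else if (p == "zgzu") {
      r1 <- draw_range(); r2 <- draw_range()
      unit <- grammar$units[sample.int(length(grammar$units), 1L)]
      target <- ctx$ids[length(ctx$ids)]
      add_gold_measurement(acc, counter, target, "length", r1, unit)
      add_gold_measurement(acc, counter, target, "width", r2, unit)
      chunks <- c(chunks, paste(range_text(r1), "×", range_text(r2), unit))
    }
  }

  if (stats::runif(1) < grammar$p_conjunction) {
    # noun + two coordinated states sharing the first conjunct's names
    noun <- draw_noun(grammar, exclude = ctx$names)
    sid <- add_structure(noun)
    st1 <- draw_state(grammar, noun$gender, noun$number)
    names1 <- resolve_state(st1, res)
    st2 <- st1
    while (st2 == st1) st2 <- draw_state(grammar, noun$gender, noun$number)
    add_state_chars(sid, st1, names_tbl = names1)
    add_state_chars(sid, st2, conj = "o", names_tbl = names1)
    chunks <- c(chunks, paste(noun$token, st1, "o", st2))
  }

  if (stats::runif(1) < grammar$p_con) {
    prep <- if (stats::runif(1) < 0.5) "con" else "sin"
    from_id <- ctx$ids[length(ctx$ids)]
    noun <- draw_noun(grammar, exclude = ctx$names)
    sid <- add_structure(noun)
    acc_add_relation(acc, counter, prep, from_id, sid,
                     negated = prep == "sin")
    st <- draw_state(grammar, noun$gender, noun$number)
    add_state_chars(sid, st)
    chunks <- c(chunks, paste(prep, noun$token, st))
  }

  if (stats::runif(1) < grammar$p_fallback && length(ctx$ids) >= 2L) {
    # a state that disagrees with the most recent structure and must fall
    # back to an earlier (or the main) one
    last <- length(ctx$ids)
    older <- which(ctx$genders != ctx$genders[last] |
                     ctx$numbers != ctx$numbers[last])
    if (length(older)) {
      tgt <- older[length(older)]
      st <- tryCatch(draw_state(grammar, ctx$genders[tgt], ctx$numbers[tgt],
                                exact = TRUE),
                     error = function(e) NA_character_)
      if (!is.na(st)) {
        lexrow <- match(st, res$lexicon$token)
        target <- associate_vec(res$lexicon$gender[lexrow],
                                res$lexicon$number[lexrow], ctx)
        add_state_chars(target, st)
        chunks <- c(chunks, st)
      }
    }
  }

  paste(chunks, collapse = ", ")
}
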