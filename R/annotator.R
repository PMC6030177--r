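# --- clause context and association ----------------------------------------

articles <- c("el", "la", "los", "las", "un", "una", "unos", "unas", "lo")

agree <- function(a, b) a == b || a == "unknown" || b == "unknown"

new_clause_context <- function() {
  env <- new.env(parent = emptyenv())
  env$ids <- character(); env$names <- character()
  env$genders <- character(); env$numbers <- character()
  env$main <- NA_character_
  env
}

ctx_add_structure <- function(ctx, id, name, gender, number) {
  ctx$ids <- c(ctx$ids, id)
  ctx$names <- c(ctx$names, name)
  ctx$genders <- c(ctx$genders, gender)
  ctx$numbers <- c(ctx$numbers, number)
  if (is.na(ctx$main)) ctx$main <- id
}

#' Associate a character with a structure by gender/number agreement
#'
#' Scans the clause's structures from the most recently created to the
#' oldest and returns the first whose gender and number both agree with the
#' character's head token; `unknown` agrees with anything (invariant
#' adjectives must not block association). If none agrees, the clause's
#' main structure (the first of the clause) is returned. This is the
#' paper-style heuristic, including its documented failure mode on clauses
#' whose later chunks refer back to the main structure.
#'
#' @param gender,number Gender (`"m"`, `"f"`, `"unknown"`) and number
#'   (`"singular"`, `"plural"`, `"unknown"`) of the character's head token.
#' @param context A tibble with columns `id`, `gender`, `number` listing the
#'   clause's structures in order of appearance.
#' @param main Id of the clause's main structure (defaults to the first row
#'   of `context`).
#' @return The id of the chosen structure, or `NA` if the context is empty.
#' @export
associate_structure <- function(gender, number, context, main = NULL) {
  if (is.environment(context)) {
    return(associate_vec(gender, number, context))
  }
  if (!nrow(context)) return(NA_character_)
  if (is.null(main)) main <- context$id[1]
  for (i in rev(seq_len(nrow(context)))) {
    if (agree(gender, context$gender[i]) && agree(number, context$number[i])) {
      return(context$id[i])
    }
  }
  main
}

associate_vec <- function(gender, number, ctx) {
  n <- length(ctx$ids)
  if (!n) return(NA_character_)
  for (i in rev(seq_len(n))) {
    if (agree(gender, ctx$genders[i]) && agree(number, ctx$numbers[i])) {
      return(ctx$ids[i])
    }
  }
  ctx$main
}

# --- accumulators (parallel vectors; tibbles are built once per description)

new_accumulator <- function() {
  env <- new.env(parent = emptyenv())
  env$s_id <- env$s_clause <- env$s_name <- env$s_constraint <-
    env$s_modifier <- env$s_notes <- character()
  env$c_id <- env$c_structure <- env$c_name <- env$c_value <-
    env$c_char_type <- env$c_from <- env$c_to <- env$c_from_unit <-
    env$c_to_unit <- env$c_atypical_from <- env$c_atypical_to <-
    env$c_constraint <- env$c_notes <- character()
  env$r_id <- env$r_name <- env$r_from <- env$r_to <- character()
  env$r_negated <- logical()
  env$sp_clause <- env$sp_kind <- env$sp_text <- env$sp_attached <-
    character()
  env
}

acc_add_structure <- function(acc, counter, clause_id, name,
                              modifier = NA_character_,
                              constraint = NA_character_,
                              notes = NA_character_) {
  id <- next_id(counter)
  acc$s_id <- c(acc$s_id, id)
  acc$s_clause <- c(acc$s_clause, clause_id)
  acc$s_name <- c(acc$s_name, name)
  acc$s_constraint <- c(acc$s_constraint, constraint)
  acc$s_modifier <- c(acc$s_modifier, modifier)
  acc$s_notes <- c(acc$s_notes, notes)
  id
}

acc_add_character <- function(acc, counter, structure_id, name, value,
                              char_type = NA_character_,
                              from = NA_character_, to = NA_character_,
                              from_unit = NA_character_,
                              to_unit = NA_character_,
                              atypical_from = NA_character_,
                              atypical_to = NA_character_,
                              constraint = NA_character_,
                              notes = NA_character_) {
  id <- next_id(counter)
  acc$c_id <- c(acc$c_id, id)
  acc$c_structure <- c(acc$c_structure, structure_id)
  acc$c_name <- c(acc$c_name, name)
  acc$c_value <- c(acc$c_value, value)
  acc$c_char_type <- c(acc$c_char_type, char_type)
  acc$c_from <- c(acc$c_from, from)
  acc$c_to <- c(acc$c_to, to)
  acc$c_from_unit <- c(acc$c_from_unit, from_unit)
  acc$c_to_unit <- c(acc$c_to_unit, to_unit)
  acc$c_atypical_from <- c(acc$c_atypical_from, atypical_from)
  acc$c_atypical_to <- c(acc$c_atypical_to, atypical_to)
  acc$c_constraint <- c(acc$c_constraint, constraint)
  acc$c_notes <- c(acc$c_notes, notes)
  id
}

acc_add_relation <- function(acc, counter, name, from, to, negated) {
  id <- next_id(counter)
  acc$r_id <- c(acc$r_id, id)
  acc$r_name <- c(acc$r_name, name)
  acc$r_from <- c(acc$r_from, from)
  acc$r_to <- c(acc$r_to, to)
  acc$r_negated <- c(acc$r_negated, negated)
  id
}

acc_add_span <- function(acc, clause_id, kind, text, attached_to) {
  acc$sp_clause <- c(acc$sp_clause, clause_id)
  acc$sp_kind <- c(acc$sp_kind, kind)
  acc$sp_text <- c(acc$sp_text, text)
  acc$sp_attached <- c(acc$sp_attached, attached_to)
  invisible(NULL)
}

append_text <- function(old, text) {
  ifelse(is.na(old), text, paste(old, text, sep = "; "))
}

acc_append_structure_constraint <- function(acc, id, text) {
  i <- which(acc$s_id == id)
  acc$s_constraint[i] <- append_text(acc$s_constraint[i], text)
}

acc_append_character_constraint <- function(acc, ids, text) {
  i <- match(ids, acc$c_id)
  acc$c_constraint[i] <- append_text(acc$c_constraint[i], text)
}

acc_tibbles <- function(acc) {
  list(
    structures = tibble::tibble(
      id = acc$s_id, clause_id = acc$s_clause, name = acc$s_name,
      constraint = acc$s_constraint, modifier = acc$s_modifier,
      ontology_id = rep(NA_character_, length(acc$s_id)),
      notes = acc$s_notes),
    characters = tibble::tibble(
      id = acc$c_id, structure_id = acc$c_structure, name = acc$c_name,
      value = acc$c_value, char_type = acc$c_char_type, from = acc$c_from,
      to = acc$c_to, from_unit = acc$c_from_unit, to_unit = acc$c_to_unit,
      atypical_from = acc$c_atypical_from, atypical_to = acc$c_atypical_to,
      constraint = acc$c_constraint, notes = acc$c_notes),
    relations = tibble::tibble(
      id = acc$r_id, name = acc$r_name, from_structure_id = acc$r_from,
      to_structure_id = acc$r_to, negated = acc$r_negated),
    constraint_spans = tibble::tibble(
      clause_id = acc$sp_clause, kind = acc$sp_kind, text = acc$sp_text,
      attached_to = acc$sp_attached)
  )
}

join_notes <- function(...) {
  parts <- c(...)
  parts <- parts[!is.na(parts)]
  if (!length(parts)) NA_character_ else paste(parts, collapse = "; ")
}

# --- per-chunk processing ---------------------------------------------------

normalize_conj <- function(word) {
  norm <- c(u = "o", e = "y")[word]
  ifelse(is.na(norm), word, unname(norm))
}

# split the head-region state tokens into units and conjunction groups
build_state_units <- function(tokens, rows, resources) {
  units <- list()
  pending_conj <- NULL
  pending_a <- NULL
  group_n <- 0L
  for (r in rows) {
    t <- tokens$tag[r]; nm <- tokens$norm[r]
    if (tokens$in_parens[r]) next
    if (t == "C") { pending_conj <- nm; pending_a <- NULL; next }
    if (t == "S" && nm == "a") { pending_a <- r; next }
    if (!(t %in% c("A", "X", "Z"))) next
    if (t == "Z") next  # numerals are the measurement parser's business
    names_tbl <- resolve_state(nm, resources)
    k <- length(units)
    mergeable <- is.null(pending_conj) && k > 0L &&
      identical(units[[k]]$names$name, names_tbl$name)
    if (mergeable) {
      units[[k]]$rows <- c(units[[k]]$rows, pending_a, r)
    } else if (!is.null(pending_conj)) {
      group_n_use <- if (k > 0L) units[[k]]$group else (group_n <- group_n + 1L)
      units[[k + 1L]] <- list(rows = r, group = group_n_use,
                              conj = normalize_conj(pending_conj),
                              names = names_tbl)
    } else {
      group_n <- group_n + 1L
      units[[k + 1L]] <- list(rows = r, group = group_n, conj = NA_character_,
                              names = names_tbl)
    }
    pending_conj <- NULL
    pending_a <- NULL
  }
  units
}

unit_value <- function(tokens, unit) {
  rows <- sort(unit$rows)
  paste(tokens$surface[rows], collapse = " ")
}

unit_head <- function(tokens, unit) {
  # agreement head: last state token of the unit
  rows <- sort(unit$rows)
  arows <- rows[tokens$tag[rows] %in% c("A", "X")]
  r <- if (length(arows)) arows[length(arows)] else rows[length(rows)]
  list(gender = tokens$gender[r], number = tokens$number[r])
}

emit_unit_characters <- function(acc, counter, tokens, unit, link,
                                 names_tbl, conj_note) {
  value <- unit_value(tokens, unit)
  vapply(seq_along(names_tbl$name), function(j) {
    acc_add_character(acc, counter, link, names_tbl$name[j], value,
                      notes = join_notes(names_tbl$notes[j], conj_note))
  }, "")
}

process_chunk <- function(tokens, raw, clause_id, ctx, acc, counter,
                          resources) {
  n <- nrow(tokens)
  if (n == 0L) return(invisible())
  tree <- parse_chunk(tokens)
  top <- !tokens$in_parens
  consumed <- tokens$tag == "F"
  row_seq <- seq_len(n)

  ensure_context <- function() {
    if (!length(ctx$ids)) {
      id <- acc_add_structure(acc, counter, clause_id, "planta",
                              notes = "estructura implícita")
      ctx_add_structure(ctx, id, "planta", "f", "singular")
    }
  }
  current_structure <- function() {
    ensure_context()
    ctx$ids[length(ctx$ids)]
  }

  # verb tail: everything from the first top-level verb on is delimited
  vstart <- which(top & tokens$tag == "V")[1]
  verb_rows <- NULL
  if (!is.na(vstart)) {
    verb_rows <- vstart:n
    consumed[verb_rows] <- TRUE
  }

  # measurement run (only in the part before any verb)
  pre <- if (is.na(vstart)) tokens else tokens[seq_len(vstart - 1L), ]
  run <- if (nrow(pre)) find_measurement_run(pre) else NULL
  if (!is.null(run)) consumed[run] <- TRUE

  # region boundaries: top-level prepositions not consumed; "a" between two
  # states is a connector, not a boundary
  is_boundary <- function(r) {
    if (!(top[r] && !consumed[r] && tokens$tag[r] == "S")) return(FALSE)
    if (tokens$norm[r] != "a") return(TRUE)
    prev <- row_seq[row_seq < r & top & tokens$tag %in% c("A", "X")]
    nxt <- row_seq[row_seq > r & top & !(tokens$tag %in% c("R"))]
    !(length(prev) && length(nxt) &&
        max(prev) == max(row_seq[row_seq < r & top]) &&
        tokens$tag[min(nxt)] %in% c("A", "X"))
  }
  boundaries <- row_seq[vapply(row_seq, is_boundary, TRUE)]
  head_end <- if (length(boundaries)) boundaries[1] - 1L else
    if (is.na(vstart)) n else vstart - 1L
  head_rows <- row_seq[row_seq <= head_end & !consumed]

  obj_of_row <- vector("list", n)  # row -> list(kind, ids)

  # ---- head region: structure(s) -------------------------------------------
  chunk_struct <- NA_character_
  e_rows <- head_rows[tokens$tag[head_rows] == "E" & top[head_rows]]
  if (length(e_rows)) {
    first_e <- e_rows[1]
    mods <- integer()
    for (r in e_rows[-1]) {
      between <- row_seq[row_seq > first_e & row_seq < r]
      if (all(tokens$tag[between] %in% c("E", "D", "F"))) {
        mods <- c(mods, r)
      }
    }
    modifier <- if (length(mods)) {
      paste(tokens$surface[mods], collapse = " ")
    } else NA_character_
    chunk_struct <- acc_add_structure(acc, counter, clause_id,
                                      tokens$surface[first_e],
                                      modifier = modifier)
    ctx_add_structure(ctx, chunk_struct, tokens$surface[first_e],
                      tokens$gender[first_e], tokens$number[first_e])
    obj_of_row[[first_e]] <- list(kind = "structure", ids = chunk_struct)
    # stray nouns in the head region beyond the modifier group become their
    # own structures
    for (r in setdiff(e_rows[-1], mods)) {
      sid <- acc_add_structure(acc, counter, clause_id, tokens$surface[r])
      ctx_add_structure(ctx, sid, tokens$surface[r], tokens$gender[r],
                        tokens$number[r])
      obj_of_row[[r]] <- list(kind = "structure", ids = sid)
    }
  }

  # ---- head region: quantifiers --------------------------------------------
  d_rows <- head_rows[tokens$tag[head_rows] == "D" & top[head_rows]]
  for (r in d_rows) {
    if (tokens$norm[r] %in% articles) next  # articles are consumed silently
    target <- if (!is.na(chunk_struct)) chunk_struct else current_structure()
    acc_append_structure_constraint(acc, target, tokens$surface[r])
  }

  # ---- head region: character states ---------------------------------------
  chunk_char_ids <- character()
  head_link <- NA_character_  # structure the head-region states attached to
  units <- build_state_units(tokens, head_rows, resources)
  groups <- split(seq_along(units), vapply(units, `[[`, 0L, "group"))
  for (g in groups) {
    first <- units[[g[1]]]
    link <- if (!is.na(chunk_struct)) {
      chunk_struct
    } else {
      ensure_context()
      h <- unit_head(tokens, first)
      associate_vec(h$gender, h$number, ctx)
    }
    head_link <- link
    group_names <- first$names
    for (ui in g) {
      unit <- units[[ui]]
      names_tbl <- if (length(g) > 1L) group_names else unit$names
      conj_note <- if (ui != g[1]) unit$conj else NA_character_
      ids <- emit_unit_characters(acc, counter, tokens, unit, link,
                                  names_tbl, conj_note)
      chunk_char_ids <- c(chunk_char_ids, ids)
      for (r in unit$rows) {
        obj_of_row[[r]] <- list(kind = "character", ids = ids)
      }
    }
  }

  # ---- measurement characters ----------------------------------------------
  if (!is.null(run)) {
    meas <- parse_measurement(tokens[run, ], resources)
    link <- if (!is.na(chunk_struct)) chunk_struct else current_structure()
    ids <- vapply(seq_len(nrow(meas)), function(j) {
      acc_add_character(acc, counter, link, meas$name[j], meas$value[j],
                        char_type = meas$char_type[j], from = meas$from[j],
                        to = meas$to[j], from_unit = meas$from_unit[j],
                        to_unit = meas$to_unit[j],
                        atypical_from = meas$atypical_from[j],
                        atypical_to = meas$atypical_to[j],
                        notes = meas$notes[j])
    }, "")
    chunk_char_ids <- c(chunk_char_ids, ids)
    for (r in run) obj_of_row[[r]] <- list(kind = "character", ids = ids)
  }

  # ---- prepositional regions -----------------------------------------------
  if (length(boundaries)) {
    ends <- c(boundaries[-1] - 1L, if (is.na(vstart)) n else vstart - 1L)
    for (k in seq_along(boundaries)) {
      rows <- row_seq[row_seq >= boundaries[k] & row_seq <= ends[k] &
                        !consumed]
      if (!length(rows)) next
      s_row <- rows[1]
      inner_e <- rows[tokens$tag[rows] == "E" & top[rows]]
      if (tokens$norm[s_row] %in% c("con", "sin") && length(inner_e)) {
        from_id <- if (!is.na(chunk_struct)) chunk_struct else
          if (!is.na(head_link)) head_link else current_structure()
        inner_first <- inner_e[1]
        inner_id <- acc_add_structure(acc, counter, clause_id,
                                      tokens$surface[inner_first])
        ctx_add_structure(ctx, inner_id, tokens$surface[inner_first],
                          tokens$gender[inner_first],
                          tokens$number[inner_first])
        obj_of_row[[inner_first]] <- list(kind = "structure", ids = inner_id)
        acc_add_relation(acc, counter, tokens$surface[s_row], from_id,
                         inner_id, negated = tokens$norm[s_row] == "sin")
        for (r in inner_e[-1]) {
          sid <- acc_add_structure(acc, counter, clause_id,
                                   tokens$surface[r])
          ctx_add_structure(ctx, sid, tokens$surface[r], tokens$gender[r],
                            tokens$number[r])
          obj_of_row[[r]] <- list(kind = "structure", ids = sid)
        }
        inner_units <- build_state_units(tokens, rows[-1], resources)
        for (unit in inner_units) {
          ids <- emit_unit_characters(acc, counter, tokens, unit, inner_id,
                                      unit$names, unit$conj)
          chunk_char_ids <- c(chunk_char_ids, ids)
          for (r in unit$rows) {
            obj_of_row[[r]] <- list(kind = "character", ids = ids)
          }
        }
      } else {
        attached <- if (!is.na(chunk_struct)) chunk_struct else
          if (length(ctx$ids)) ctx$ids[length(ctx$ids)] else NA_character_
        acc_add_span(acc, clause_id, "constraint_preposition",
                     paste(tokens$surface[rows], collapse = " "), attached)
        # entities inside an undelimited phrase are still extracted for
        # subsequent use during association
        for (r in inner_e) {
          sid <- acc_add_structure(acc, counter, clause_id,
                                   tokens$surface[r])
          ctx_add_structure(ctx, sid, tokens$surface[r], tokens$gender[r],
                            tokens$number[r])
          obj_of_row[[r]] <- list(kind = "structure", ids = sid)
        }
        consumed[rows] <- TRUE
      }
    }
  }

  # ---- verb region ----------------------------------------------------------
  if (!is.null(verb_rows)) {
    attached <- if (!is.na(chunk_struct)) chunk_struct else
      if (length(ctx$ids)) ctx$ids[length(ctx$ids)] else NA_character_
    # NA is fixed up to the clause's main structure once known
    acc_add_span(acc, clause_id, "verb_string",
                 paste(tokens$surface[verb_rows], collapse = " "), attached)
  }

  # ---- adverb constraints ----------------------------------------------------
  content <- c("A", "V", "Z", "U", "E", "R", "X")
  r_rows <- row_seq[tokens$tag == "R" & top & !consumed]
  r_target <- stats::setNames(rep(NA_integer_, length(r_rows)),
                              as.character(r_rows))
  for (r in r_rows) {
    nb <- neighbors(tree, tokens$index[r])
    pick <- function(idxs) {
      rows <- match(idxs, tokens$index)
      rows <- rows[tokens$tag[rows] %in% content & !consumed[rows]]
      if (!length(rows)) return(NA_integer_)
      rows[which.min(abs(rows - r))]
    }
    tgt <- pick(nb$children)
    if (is.na(tgt)) tgt <- pick(nb$siblings)
    if (is.na(tgt) && !is.na(nb$ancestor)) tgt <- pick(nb$ancestor)
    r_target[as.character(r)] <- tgt
  }
  resolve_final <- function(r) {
    visited <- integer()
    cur <- r
    repeat {
      if (cur %in% visited) break
      visited <- c(visited, cur)
      tgt <- unname(r_target[as.character(cur)])
      if (length(tgt) != 1L || is.na(tgt)) break
      if (tokens$tag[tgt] != "R") return(tgt)
      cur <- tgt
    }
    # adverbs chaining onto each other: climb the tree to the first non-R
    node <- tokens$index[r]
    repeat {
      p <- tree$parent[match(node, tree$index)]
      if (is.na(p)) return(NA_integer_)
      prow <- match(p, tree$index)
      if (tokens$tag[prow] != "R") return(prow)
      node <- p
    }
  }
  finals <- vapply(r_rows, resolve_final, 0L)
  for (tgt in unique(finals)) {
    group <- sort(r_rows[which(finals %in% tgt)])
    text <- paste(tokens$surface[group], collapse = " ")
    applied <- FALSE
    if (!is.na(tgt)) {
      obj <- obj_of_row[[tgt]]
      if (!is.null(obj)) {
        if (obj$kind == "character") {
          acc_append_character_constraint(acc, obj$ids, text)
        } else {
          acc_append_structure_constraint(acc, obj$ids[1], text)
        }
        applied <- TRUE
      }
    }
    if (!applied) {
      target <- if (!is.na(chunk_struct)) chunk_struct else
        current_structure()
      acc_append_structure_constraint(acc, target, text)
    }
  }

  # ---- parenthetical constraints --------------------------------------------
  pg <- rle(tokens$in_parens)
  pos <- cumsum(pg$lengths)
  starts <- c(1L, utils::head(pos, -1) + 1L)
  for (k in seq_along(pg$values)) {
    if (!pg$values[k]) next
    rows <- starts[k]:pos[k]
    if (all(tokens$tag[rows] == "Z")) next  # atypical ranges, already parsed
    text <- paste(tokens$surface[rows], collapse = " ")
    prev <- row_seq[row_seq < rows[1] & top]
    obj <- if (length(prev)) obj_of_row[[max(prev)]] else NULL
    if (!is.null(obj) && obj$kind == "character") {
      acc_append_character_constraint(acc, obj$ids, text)
    } else if (!is.null(obj)) {
      acc_append_structure_constraint(acc, obj$ids[1], text)
    } else {
      target <- if (!is.na(chunk_struct)) chunk_struct else
        current_structure()
      acc_append_structure_constraint(acc, target, text)
    }
  }

  invisible()
}

# --- description-level driver -----------------------------------------------

#' Annotate one morphological description
#'
#' Runs the full pipeline on a single description: normalization, clause and
#' chunk segmentation, tagging, dependency parsing and rule-based semantic
#' annotation. Chunks of a clause are processed strictly left to right; the
#' clause context (its structures, in order of appearance, with the gender
#' and number of their head tokens) drives the association of characters
#' with structures.
#'
#' @param taxon_name Scientific name for the record.
#' @param text Raw description text.
#' @param resources An [ft_resources()] list.
#' @param taxon_index Positive integer used in clause ids
#'   (`T{taxon}L{clause}S{chunk}`).
#' @return An [annotated_description()].
#' @examples
#' ad <- annotate_description("Quercus sp.", "hojas simples, alternas.")
#' ad$characters[, c("structure_id", "name", "value")]
#' @export
annotate_description <- function(taxon_name, text,
                                 resources = ft_resources(),
                                 taxon_index = 1L) {
  counter <- new_id_counter()
  acc <- new_accumulator()
  normalized <- normalize_text(text, resources$abbreviations)
  clause_texts <- segment_clauses(normalized)
  clause_ids <- sprintf("T%dL%d", taxon_index, seq_along(clause_texts))
  chunk_ids <- character(); chunk_clauses <- character()
  chunk_texts_all <- character()
  for (li in seq_along(clause_texts)) {
    ctx <- new_clause_context()
    chunk_texts <- segment_chunks(clause_texts[li])
    for (si in seq_along(chunk_texts)) {
      chunk_ids <- c(chunk_ids, paste0(clause_ids[li], "S", si))
      chunk_clauses <- c(chunk_clauses, clause_ids[li])
      chunk_texts_all <- c(chunk_texts_all, chunk_texts[si])
      tokens <- tag_chunk(chunk_texts[si], resources)
      process_chunk(tokens, chunk_texts[si], clause_ids[li], ctx, acc,
                    counter, resources)
    }
    # spans recorded before any structure existed attach to the clause's
    # main structure once known
    open <- is.na(acc$sp_attached) & acc$sp_clause == clause_ids[li]
    if (any(open)) {
      if (is.na(ctx$main)) {
        ctx$main <- acc_add_structure(acc, counter, clause_ids[li], "planta",
                                      notes = "estructura implícita")
      }
      acc$sp_attached[open] <- ctx$main
    }
  }
  parts <- acc_tibbles(acc)
  annotated_description(
    taxon_name = taxon_name,
    clauses = tibble::tibble(clause_id = clause_ids, text = clause_texts),
    chunks = tibble::tibble(chunk_id = chunk_ids, clause_id = chunk_clauses,
                            text = chunk_texts_all),
    structures = parts$structures,
    characters = parts$characters,
    relations = parts$relations,
    constraint_spans = parts$constraint_spans
  )
}

#' Annotate a table of descriptions
#'
#' Data-frame-first entry point: takes a tibble of records (columns `taxon`
#' and `description`) and annotates each row.
#'
#' @param records A data frame with columns `taxon` and `description`.
#' @param resources An [ft_resources()] list.
#' @return A list of [annotated_description()] objects, one per row.
#' @export
ft_annotate <- function(records, resources = ft_resources()) {
  stopifnot(all(c("taxon", "description") %in% names(records)))
  purrr::map(seq_len(nrow(records)), function(i) {
    annotate_description(records$taxon[i], records$description[i],
                         resources, taxon_index = i)
  })
}
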