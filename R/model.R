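#' Annotated description objects
#'
#' The central container of the package: one annotated taxon description,
#' holding the clause/chunk segmentation and tibbles of the extracted
#' structures, characters, relations and constraint spans. All numeric range
#' bounds (`from`, `to`, `atypical_from`, `atypical_to`) are kept as character
#' strings so that values such as `"3.3"` round-trip textually through XML.
#'
#' Columns:
#' * `clauses`: `clause_id` (`T{taxon}L{clause}`), `text`
#' * `chunks`: `chunk_id` (`T{taxon}L{clause}S{chunk}`), `clause_id`, `text`
#' * `structures`: `id`, `clause_id`, `name`, `constraint`, `modifier`,
#'   `ontology_id`, `notes`
#' * `characters`: `id`, `structure_id`, `name`, `value`, `char_type`,
#'   `from`, `to`, `from_unit`, `to_unit`, `atypical_from`, `atypical_to`,
#'   `constraint`, `notes`
#' * `relations`: `id`, `name`, `from_structure_id`, `to_structure_id`,
#'   `negated`
#' * `constraint_spans`: `clause_id`, `kind` (one of
#'   `constraint_preposition`, `constraint_verb`, `verb_string`), `text`,
#'   `attached_to`
#'
#' @param taxon_name Scientific name of the taxon.
#' @param clauses,chunks,structures,characters,relations,constraint_spans
#'   Component tibbles; defaults are empty prototypes.
#' @return An object of class `annotated_description`.
#' @export
annotated_description <- function(taxon_name,
                                  clauses = empty_clauses(),
                                  chunks = empty_chunks(),
                                  structures = empty_structures(),
                                  characters = empty_characters(),
                                  relations = empty_relations(),
                                  constraint_spans = empty_spans()) {
  structure(
    list(taxon_name = taxon_name, clauses = clauses, chunks = chunks,
         structures = structures, characters = characters,
         relations = relations, constraint_spans = constraint_spans),
    class = "annotated_description"
  )
}

empty_clauses <- function() {
  tibble::tibble(clause_id = character(), text = character())
}
empty_chunks <- function() {
  tibble::tibble(chunk_id = character(), clause_id = character(),
                 text = character())
}
empty_structures <- function() {
  tibble::tibble(id = character(), clause_id = character(),
                 name = character(), constraint = character(),
                 modifier = character(), ontology_id = character(),
                 notes = character())
}
empty_characters <- function() {
  tibble::tibble(id = character(), structure_id = character(),
                 name = character(), value = character(),
                 char_type = character(), from = character(),
                 to = character(), from_unit = character(),
                 to_unit = character(), atypical_from = character(),
                 atypical_to = character(), constraint = character(),
                 notes = character())
}
empty_relations <- function() {
  tibble::tibble(id = character(), name = character(),
                 from_structure_id = character(),
                 to_structure_id = character(), negated = logical())
}
empty_spans <- function() {
  tibble::tibble(clause_id = character(), kind = character(),
                 text = character(), attached_to = character())
}

#' Deterministic object-id counter
#'
#' Ids are assigned sequentially as `"o1"`, `"o2"`, ... in order of object
#' creation within one description, so re-annotating identical input yields
#' an identical id assignment.
#'
#' @return `new_id_counter()` returns a counter; `next_id(counter)` returns
#'   the next id string.
#' @export
new_id_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env
}

#' @rdname new_id_counter
#' @param counter A counter created by [new_id_counter()].
#' @export
next_id <- function(counter) {
  counter$n <- counter$n + 1L
  paste0("o", counter$n)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Validate an annotated description
#'
#' Checks the model invariants: every character's `structure_id` and both
#' relation endpoints resolve to an existing structure, ids are unique,
#' structure names are non-empty, range characters have `from <= to`, and
#' atypical bounds lie strictly outside the typical range. Violations are
#' returned as data, not raised.
#'
#' @param x An `annotated_description`.
#' @return A character vector of violation messages; empty if the object is
#'   valid.
#' @export
validate_description <- function(x) {
  stopifnot(inherits(x, "annotated_description"))
  v <- character()
  ids <- c(x$structures$id, x$characters$id, x$relations$id)
  if (anyDuplicated(ids)) {
    v <- c(v, paste0("duplicate object ids: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(x$structures$name) | is.na(x$structures$name))) {
    v <- c(v, "structure with empty name")
  }
  bad <- setdiff(x$characters$structure_id, x$structures$id)
  if (length(bad)) {
    v <- c(v, paste0("character linked to missing structure: ",
                     paste(bad, collapse = ", ")))
  }
  bad <- setdiff(c(x$relations$from_structure_id, x$relations$to_structure_id),
                 x$structures$id)
  if (length(bad)) {
    v <- c(v, paste0("relation endpoint missing: ",
                     paste(bad, collapse = ", ")))
  }
  bad <- setdiff(stats::na.omit(x$constraint_spans$attached_to),
                 c(x$structures$id, x$characters$id))
  if (length(bad)) {
    v <- c(v, paste0("constraint span attached to missing object: ",
                     paste(bad, collapse = ", ")))
  }
  ch <- x$characters
  if (nrow(ch)) {
    from <- num_or_na(ch$from); to <- num_or_na(ch$to)
    rng <- !is.na(ch$char_type) & ch$char_type == "range_value"
    miss <- rng & (is.na(from) | is.na(to))
    if (any(miss)) {
      v <- c(v, paste0("range_value character without from/to: ",
                       paste(ch$id[miss], collapse = ", ")))
    }
    bad <- rng & !is.na(from) & !is.na(to) & from > to
    if (any(bad)) {
      v <- c(v, paste0("character range violates from <= to: ",
                       paste(ch$id[bad], collapse = ", ")))
    }
    a_to <- num_or_na(ch$atypical_to)
    bad <- !is.na(a_to) & !is.na(to) & a_to <= to
    if (any(bad)) {
      v <- c(v, paste0("atypical_to not above to: ",
                       paste(ch$id[bad], collapse = ", ")))
    }
    a_from <- num_or_na(ch$atypical_from)
    bad <- !is.na(a_from) & !is.na(from) & a_from >= from
    if (any(bad)) {
      v <- c(v, paste0("atypical_from not below from: ",
                       paste(ch$id[bad], collapse = ", ")))
    }
  }
  v
}

#' @export
print.annotated_description <- function(x, ...) {
  cat("<annotated_description> ", x$taxon_name, "\n", sep = "")
  cat("  clauses: ", nrow(x$clauses),
      "  chunks: ", nrow(x$chunks),
      "  structures: ", nrow(x$structures),
      "  characters: ", nrow(x$characters),
      "  relations: ", nrow(x$relations),
      "  spans: ", nrow(x$constraint_spans), "\n", sep = "")
  invisible(x)
}
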