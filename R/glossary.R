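#' Translate Spanish terms to English
#'
#' Lookup through a fallback chain: user glossary entries layered over the
#' bundled glossary, then identity (the term is returned unchanged with
#' source `"untranslated"`). Total and deterministic -- never fails.
#'
#' @param term_es Character vector of Spanish terms (lower-cased,
#'   accent-preserving).
#' @param glossary Glossary tibble from [ft_glossary()] (columns `es`,
#'   `en`), or an [ft_resources()] list.
#' @return A tibble with columns `term_es`, `term_en`, `source`.
#' @examples
#' translate_term(c("hojas", "zzz"))
#' @export
translate_term <- function(term_es, glossary = ft_glossary()) {
  if (inherits(glossary, "ft_resources")) glossary <- glossary$glossary
  hit <- match(term_es, glossary$es)
  tibble::tibble(
    term_es = term_es,
    term_en = ifelse(is.na(hit), term_es, glossary$en[hit]),
    source = ifelse(is.na(hit), "untranslated", "glossary")
  )
}

#' Character names indexed by an English state
#'
#' Returns every character name whose controlled vocabulary includes the
#' given state, alphabetically ordered; an unknown state returns an empty
#' vector. Mirrors the state-to-character lookup of an ontology term
#' organiser, frozen into a bundled index.
#'
#' @param state_en An English state term (single string).
#' @param index Index tibble from [ft_character_names()] (columns
#'   `state_en`, `character`), or an [ft_resources()] list.
#' @return Character vector of character names (possibly empty).
#' @examples
#' character_names("elliptic")
#' character_names("simple")
#' @export
character_names <- function(state_en, index = ft_character_names()) {
  if (inherits(index, "ft_resources")) index <- index$character_names
  stopifnot(length(state_en) == 1L)
  sort(index$character[index$state_en == state_en])
}

# verbatim note attached when one state resolves to several characters
repeated_character_note <- "Carácter repetido"

# full resolution pipeline for one Spanish state token:
# translate -> character_names -> one name per entry (alphabetical), with the
# repeated-character note when more than one, "unknown_character" when none
resolve_state <- function(state_es, resources) {
  hit <- match(state_es, resources$glossary$es)
  en <- if (is.na(hit)) state_es else resources$glossary$en[hit]
  idx <- resources$character_names
  names <- sort(idx$character[idx$state_en == en])
  if (!length(names)) {
    return(list(name = "unknown_character", notes = "estado no indexado"))
  }
  list(
    name = names,
    notes = rep(if (length(names) > 1) repeated_character_note
                else NA_character_, length(names))
  )
}
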