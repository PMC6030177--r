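#' Bundled language resources
#'
#' The annotator is driven by plain-text tables shipped with the package:
#' a Spanish botanical lexicon (token, tag, gender, number), a
#' Spanish-to-English term glossary, an index from English character states
#' to character names, an abbreviation-expansion table, and a small list of
#' noun gender/number exceptions for the suffix heuristic. Each loader reads
#' the bundled TSV and optionally layers a user-supplied TSV of the same
#' shape on top (user entries win).
#'
#' Tags follow the single-letter scheme used throughout the package:
#' E noun/entity, A adjective/state, Z numeral, R adverb, D determiner,
#' C conjunction, S preposition, U measurement unit, G area symbol,
#' V verb, F punctuation, X unknown.
#'
#' @param path Optional path to a user TSV layered over the bundled one.
#' @return A tibble (see each function's section for columns).
#' @name resources
NULL

ft_extdata <- function(file) {
  system.file("extdata", file, package = "floratrait", mustWork = TRUE)
}

read_layered_tsv <- function(bundled, path, key) {
  base <- readr::read_tsv(bundled, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  if (!is.null(path)) {
    user <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    if (!all(names(base) %in% names(user))) {
      stop("FORMAT_ERROR: user table must have columns ",
           paste(names(base), collapse = ", "), call. = FALSE)
    }
    base <- dplyr::bind_rows(user[names(base)], base)
    base <- dplyr::distinct(base, .data[[key]], .keep_all = TRUE)
  }
  base
}

#' @rdname resources
#' @export
ft_lexicon <- function(path = NULL) {
  read_layered_tsv(ft_extdata("lexicon.tsv"), path, "token")
}

#' @rdname resources
#' @export
ft_glossary <- function(path = NULL) {
  read_layered_tsv(ft_extdata("glossary_es_en.tsv"), path, "es")
}

#' @rdname resources
#' @export
ft_character_names <- function(path = NULL) {
  tab <- read_layered_tsv(ft_extdata("character_names.tsv"), path, "state_en")
  # the key is (state, character); redo dedup on the pair
  dplyr::distinct(tab, .data$state_en, .data$character)
}

#' @rdname resources
#' @export
ft_abbreviations <- function(path = NULL) {
  tab <- read_layered_tsv(ft_extdata("abbreviations.tsv"), path, "abbrev")
  stopifnot(!any(grepl("\\.", tab$expansion)))
  tab
}

#' @rdname resources
#' @export
ft_gender_exceptions <- function(path = NULL) {
  read_layered_tsv(ft_extdata("gender_exceptions.tsv"), path, "token")
}

#' Assemble the full resource set used by the pipeline
#'
#' Convenience constructor collecting lexicon, knowledge base, glossaries and
#' abbreviation table into one list that the high-level functions accept.
#'
#' @param lexicon,glossary,character_names,abbreviations,gender_exceptions
#'   Optional paths to user TSVs layered over the bundled tables.
#' @param kb A knowledge base tibble as returned by [empty_kb()] or
#'   [bootstrap_kb()].
#' @return A list of class `ft_resources`.
#' @export
ft_resources <- function(lexicon = NULL, glossary = NULL,
                         character_names = NULL, abbreviations = NULL,
                         gender_exceptions = NULL, kb = empty_kb()) {
  structure(
    list(
      lexicon = ft_lexicon(lexicon),
      glossary = ft_glossary(glossary),
      character_names = ft_character_names(character_names),
      abbreviations = ft_abbreviations(abbreviations),
      gender_exceptions = ft_gender_exceptions(gender_exceptions),
      kb = kb
    ),
    class = "ft_resources"
  )
}
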