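# nouns that name a measured dimension in "de <noun>" phrases
dimension_nouns <- c("altura", "largo", "alto", "ancho", "longitud",
                     "diámetro", "grosor")

# indices (rows) of the maximal measurement run starting at the first
# numeral, or NULL if the chunk has none
find_measurement_run <- function(tokens) {
  n <- nrow(tokens)
  start <- which(tokens$tag == "Z")[1]
  if (is.na(start)) return(NULL)
  end <- start
  i <- start + 1L
  while (i <= n) {
    t <- tokens$tag[i]; nm <- tokens$norm[i]
    ok <-
      t %in% c("Z", "G", "U") ||
      (nm == "a" && i < n && tokens$tag[i + 1L] == "Z") ||
      (nm == "de" && i < n && tokens$norm[i + 1L] %in% dimension_nouns) ||
      (nm %in% dimension_nouns && i > 1L && tokens$norm[i - 1L] == "de")
    if (!ok) break
    end <- i
    i <- i + 1L
  }
  start:end
}

parse_one_dimension <- function(toks) {
  # toks: token rows of one dimension (no G, no unit, no "de <noun>")
  main <- NULL; atypical_from <- NA_character_; atypical_to <- NA_character_
  i <- 1L
  while (i <= nrow(toks)) {
    nm <- toks$norm[i]
    if (toks$tag[i] == "Z" && toks$in_parens[i]) {
      if (grepl("-$", nm)) {
        if (!is.null(main)) return(NULL)       # "(a-)" must precede the range
        atypical_from <- sub("-$", "", nm)
      } else if (grepl("^-", nm)) {
        if (is.null(main)) return(NULL)        # "(-b)" must follow the range
        atypical_to <- sub("^-", "", nm)
      } else {
        return(NULL)
      }
      i <- i + 1L
      next
    }
    if (toks$tag[i] == "Z") {
      if (!is.null(main)) return(NULL)
      if (grepl("-", nm)) {
        main <- strsplit(nm, "-", fixed = TRUE)[[1]]
      } else if (i + 2L <= nrow(toks) && toks$norm[i + 1L] == "a" &&
                 toks$tag[i + 2L] == "Z") {
        main <- c(nm, toks$norm[i + 2L])
        i <- i + 2L
      } else {
        main <- c(nm, nm)
      }
      i <- i + 1L
      next
    }
    if (nm == "a") { i <- i + 1L; next }
    return(NULL)
  }
  if (is.null(main) || length(main) != 2L) return(NULL)
  from <- main[1]; to <- main[2]
  if (as.numeric(from) > as.numeric(to)) return(NULL)
  if (!is.na(atypical_to) && as.numeric(atypical_to) <= as.numeric(to)) {
    return(NULL)
  }
  if (!is.na(atypical_from) && as.numeric(atypical_from) >= as.numeric(from)) {
    return(NULL)
  }
  list(from = from, to = to, atypical_from = atypical_from,
       atypical_to = atypical_to)
}

#' Parse a measurement expression into range characters
#'
#' Implements the numeral rules for dimension chunks. A numeric range fills
#' `from`/`to` (`char_type = "range_value"`); in a two-dimension expression
#' (`5-18 × 1.5-9 cm`) the part before the area symbol is the length and
#' the part after it the width, and the trailing unit propagates to both
#' dimensions (`from_unit` and `to_unit`). Parenthesized numerals carrying
#' a hyphen are atypical extremes: `(-22)` after `9.5-19` sets
#' `atypical_to = 22` (the rarely observed interval 19--22, 19 excluded);
#' `(2-)` before a range sets `atypical_from`. One-dimension expressions
#' take their character name from an adjacent `de <noun>` phrase through
#' the glossary (`6-30 m de altura` gives a `height` character), defaulting
#' to `length`. Bounds are kept as the original strings.
#'
#' @param tokens A tagged token tibble (the measurement run of a chunk), or
#'   a chunk text which is then normalized and tagged.
#' @param resources An [ft_resources()] list.
#' @return A tibble of character rows (columns `name`, `value`,
#'   `char_type`, `from`, `to`, `from_unit`, `to_unit`, `atypical_from`,
#'   `atypical_to`, `notes`). An unparseable sequence yields a single plain
#'   character preserving the whole expression with a note.
#' @examples
#' parse_measurement("5-18 x 1.5-9 cm")
#' parse_measurement("6-30 m de altura")
#' @export
parse_measurement <- function(tokens, resources = ft_resources()) {
  if (is.character(tokens)) {
    tokens <- tag_chunk(normalize_text(tokens, resources$abbreviations),
                        resources)
  }
  fail <- function() tibble::tibble(
    name = "measurement",
    value = paste(tokens$surface, collapse = " "),
    char_type = NA_character_, from = NA_character_, to = NA_character_,
    from_unit = NA_character_, to_unit = NA_character_,
    atypical_from = NA_character_, atypical_to = NA_character_,
    notes = "valor no analizable"
  )
  unit <- tokens$norm[tokens$tag == "U"][1]
  dim_noun <- intersect(tokens$norm[tokens$tag != "U"], dimension_nouns)[1]
  core <- tokens[tokens$tag %in% c("Z", "G") |
                   (tokens$norm == "a" & tokens$tag == "S"), , drop = FALSE]
  # split at the area symbol
  gpos <- which(core$tag == "G")
  if (length(gpos) > 1L || (length(gpos) && gpos %in% c(1L, nrow(core)))) {
    return(fail())
  }
  parts <- if (length(gpos)) {
    list(core[seq_len(gpos - 1L), , drop = FALSE],
         core[seq(gpos + 1L, nrow(core)), , drop = FALSE])
  } else {
    list(core)
  }
  dims <- lapply(parts, parse_one_dimension)
  if (any(vapply(dims, is.null, TRUE))) return(fail())
  names <- if (length(dims) == 2L) {
    c("length", "width")
  } else if (!is.na(dim_noun)) {
    translate_term(dim_noun, resources$glossary)$term_en
  } else {
    "length"
  }
  purrr::map2_dfr(dims, names, function(d, nm) tibble::tibble(
    name = nm,
    value = if (d$from == d$to) d$from else paste0(d$from, "-", d$to),
    char_type = "range_value",
    from = d$from, to = d$to,
    from_unit = ifelse(is.na(unit), NA_character_, unit),
    to_unit = ifelse(is.na(unit), NA_character_, unit),
    atypical_from = d$atypical_from, atypical_to = d$atypical_to,
    notes = NA_character_
  ))
}

#' Render a measurement character row back to text
#'
#' Inverse of [parse_measurement()] on canonical forms: useful to check
#' that parsing is lossless.
#'
#' @param chars A tibble of measurement character rows (length first).
#' @return A single measurement string, e.g. `"5-18 × 1.5-9 cm"`.
#' @export
format_measurement <- function(chars) {
  one <- function(row) {
    out <- if (row$from == row$to) row$from else paste0(row$from, "-", row$to)
    if (!is.na(row$atypical_from)) {
      out <- paste0("(", row$atypical_from, "-) ", out)
    }
    if (!is.na(row$atypical_to)) out <- paste0(out, " (-", row$atypical_to, ")")
    out
  }
  body <- paste(vapply(seq_len(nrow(chars)),
                       function(i) one(chars[i, ]), ""),
                collapse = " × ")
  unit <- chars$from_unit[1]
  if (!is.na(unit)) body <- paste(body, unit)
  body
}
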