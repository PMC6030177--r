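#' Normalize raw description text
#'
#' Applies the standardisation pass that precedes segmentation: Unicode NFC
#' normalization, removal of double and single quotes, expansion of
#' abbreviations (keys carry their trailing period), normalization of a
#' literal `x` between numbers to the area symbol `×`, and collapsing of
#' runs of whitespace to single spaces.
#'
#' @param text Character vector of raw description texts (UTF-8).
#' @param abbreviations Abbreviation table as returned by
#'   [ft_abbreviations()]: columns `abbrev` (with trailing period) and
#'   `expansion` (period-free).
#' @return Character vector of normalized texts.
#' @examples
#' normalize_text('"hojas" simples')
#' normalize_text("5-18 x 1.5-9 cm")
#' @export
normalize_text <- function(text, abbreviations = ft_abbreviations()) {
  out <- stringi::stri_trans_nfc(text)
  out <- stringr::str_replace_all(out, "[\"'«»“”‘’]", "")
  for (i in seq_len(nrow(abbreviations))) {
    key <- abbreviations$abbrev[i]
    out <- stringr::str_replace_all(
      out,
      stringr::regex(paste0("(?<!\\p{L})", stringr::str_escape(key)),
                     ignore_case = FALSE),
      abbreviations$expansion[i]
    )
  }
  out <- stringr::str_replace_all(out, "(?<=[\\d)])\\s*x\\s*(?=[\\d(])",
                                  " × ")
  out <- stringr::str_squish(out)
  out
}

units_regex <- "(?:mm|cm|dm|km|m)"

# positions of characters sitting inside parentheses (depth > 0)
paren_depth <- function(chars) {
  cumsum((chars == "(")) - cumsum(c(0, utils::head(chars == ")", -1)))
}

split_outside_parens <- function(text, is_sep) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (!length(chars)) return(character())
  depth <- paren_depth(chars)
  cut <- is_sep(chars) & depth == 0
  grp <- cumsum(c(TRUE, utils::head(cut, -1))) # new group after each cut
  pieces <- vapply(split(chars[!cut], grp[!cut]), paste, "", collapse = "")
  pieces <- stringr::str_squish(pieces)
  unname(pieces[nzchar(pieces)])
}

#' Segment a description into clauses
#'
#' Clauses are delimited by end points, colons and semicolons outside
#' parentheses. A period does not terminate a clause when it sits inside a
#' decimal number (`3.3`) or directly after a measurement unit (`cm.`), and
#' it only splits when followed by whitespace or the end of the text, so
#' mid-clause strings such as `"1-3.3 cm., elípticas"` stay together.
#'
#' @param text A normalized description text (single string).
#' @return Character vector of clause texts, separators dropped.
#' @export
segment_clauses <- function(text) {
  stopifnot(length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (!n) return(character())
  is_sep <- function(ch) {
    sep <- ch %in% c(":", ";")
    dots <- which(ch == ".")
    for (i in dots) {
      prev <- if (i > 1) ch[i - 1] else ""
      nxt <- if (i < n) ch[i + 1] else ""
      if (grepl("\\d", prev) && grepl("\\d", nxt)) next    # decimal point
      if (!(i == n || grepl("\\s", nxt))) next             # needs space/EOT
      # period directly after a unit abbreviation never terminates
      before <- paste(ch[max(1, i - 3):(i - 1)], collapse = "")
      if (grepl(paste0("(^|[\\s\\d(])", units_regex, "$"), before,
                perl = TRUE)) next
      sep[i] <- TRUE
    }
    sep
  }
  split_outside_parens(text, is_sep)
}

#' Segment a clause into chunks
#'
#' Chunks -- the atomic processing units -- are delimited by commas outside
#' parentheses, so parenthetical asides such as `"(rara vez opuestas)"`
#' remain attached to their chunk.
#'
#' @param clause A clause text (single string).
#' @return Character vector of chunk texts in order, trimmed.
#' @export
segment_chunks <- function(clause) {
  stopifnot(length(clause) == 1L)
  split_outside_parens(clause, function(ch) ch == ",")
}
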