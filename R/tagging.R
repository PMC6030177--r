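range_regex <- "\\d+(?:\\.\\d+)?\\s?-\\s?\\d+(?:\\.\\d+)?"
num_regex <- "\\d+(?:\\.\\d+)?"
token_regex <- paste0(
  range_regex, "|",            # 5-18, 1.5-9
  "-", num_regex, "|",         # -22  (atypical upper, inside parens)
  num_regex, "-|",             # 22-  (atypical lower, inside parens)
  num_regex, "|",
  "×|[()]|",
  "\\p{L}+(?:-\\p{L}+)*|",     # words incl. hyphenated compounds
  "[.;:/]"
)

numeric_norm <- function(norm) {
  grepl(paste0("^(", range_regex, "|-", num_regex, "|", num_regex, "-|",
               num_regex, ")$"), norm)
}

#' Tokenize a chunk
#'
#' Splits a chunk text into word, numeral, range and symbol tokens.
#' Numeric ranges such as `5-18` form a single token; parentheses are
#' consumed and the enclosed tokens flagged with `in_parens`. Token indices
#' are 0-based and contiguous.
#'
#' @param text A chunk text.
#' @return A tibble with columns `surface`, `norm` (lower-cased,
#'   accent-preserving), `index`, `in_parens`.
#' @export
tokenize_chunk <- function(text) {
  raw <- stringr::str_extract_all(text, token_regex)[[1]]
  depth <- 0L
  keep <- character(); flags <- logical()
  for (tok in raw) {
    if (tok == "(") { depth <- depth + 1L; next }
    if (tok == ")") { depth <- max(0L, depth - 1L); next }
    keep <- c(keep, tok)
    flags <- c(flags, depth > 0L)
  }
  norm <- stringr::str_to_lower(keep)
  norm <- stringr::str_replace_all(norm, "\\s*-\\s*", "-")
  tibble::tibble(surface = keep, norm = norm,
                 index = seq_along(keep) - 1L, in_parens = flags)
}

#' Gender and number of a Spanish token
#'
#' Suffix heuristic with an explicit exception list consulted first:
#' `-as` feminine plural, `-os` masculine plural, `-a` feminine singular,
#' `-o` masculine singular, `-es`/`-s` unknown-gender plural, `-e` and
#' consonant endings unknown-gender singular. Gender-invariant adjectives
#' (e.g. `"verde"`) therefore get `unknown` gender, which the association
#' predicate treats as agreeing with anything. Non-alphabetic tokens get
#' `(unknown, unknown)`.
#'
#' @param norm Lower-cased token (character vector).
#' @param exceptions Exception table from [ft_gender_exceptions()].
#' @return A tibble with columns `gender`, `number`.
#' @export
morphology <- function(norm, exceptions = ft_gender_exceptions()) {
  m <- morphology_vec(norm, exceptions)
  tibble::tibble(gender = m$gender, number = m$number)
}

morphology_vec <- function(norm, exceptions) {
  one <- function(tok) {
    hit <- match(tok, exceptions$token)
    if (!is.na(hit)) {
      return(c(exceptions$gender[hit], exceptions$number[hit]))
    }
    if (!grepl("^[\\p{L}-]+$", tok, perl = TRUE)) {
      return(c("unknown", "unknown"))
    }
    if (grepl("as$", tok)) return(c("f", "plural"))
    if (grepl("os$", tok)) return(c("m", "plural"))
    if (grepl("a$", tok)) return(c("f", "singular"))
    if (grepl("o$", tok)) return(c("m", "singular"))
    if (grepl("(es|s)$", tok)) return(c("unknown", "plural"))
    c("unknown", "singular")
  }
  m <- vapply(norm, one, character(2))
  list(gender = unname(m[1, ]), number = unname(m[2, ]))
}

#' Tag the tokens of a chunk
#'
#' Assigns the single-letter role tags. Numerals, ranges and the area
#' symbol get `Z`/`G` regardless of the lexicon; lexicon entries (closed
#' classes first by construction) take precedence over the knowledge base;
#' tokens known to neither get `X`. Gender and number come from the lexicon
#' where recorded, otherwise from [morphology()].
#'
#' @param text Chunk text (already normalized).
#' @param resources An [ft_resources()] list (carries lexicon, KB and the
#'   gender-exception table).
#' @return A token tibble with columns `surface`, `norm`, `tag`, `gender`,
#'   `number`, `index`, `in_parens`; the chunk text is kept in the `raw`
#'   attribute.
#' @export
tag_chunk <- function(text, resources = ft_resources()) {
  toks <- tokenize_chunk(text)
  lex <- resources$lexicon
  kb <- resources$kb
  n <- nrow(toks)
  tag <- character(n); gender <- character(n); number <- character(n)
  fallback <- morphology_vec(toks$norm, resources$gender_exceptions)
  for (i in seq_len(n)) {
    nm <- toks$norm[i]
    if (numeric_norm(nm)) {
      tag[i] <- "Z"; gender[i] <- "unknown"; number[i] <- "unknown"
      next
    }
    if (nm == "×") {
      tag[i] <- "G"; gender[i] <- "unknown"; number[i] <- "unknown"
      next
    }
    if (grepl("^[.;:/]$", nm)) {
      tag[i] <- "F"; gender[i] <- "unknown"; number[i] <- "unknown"
      next
    }
    hit <- match(nm, lex$token)
    if (!is.na(hit)) {
      tag[i] <- lex$tag[hit]
      if (lex$gender[hit] == "unknown" && lex$tag[hit] %in% c("E", "A")) {
        gender[i] <- "unknown"; number[i] <- lex$number[hit]
      } else if (lex$tag[hit] %in% c("E", "A")) {
        gender[i] <- lex$gender[hit]; number[i] <- lex$number[hit]
      } else {
        gender[i] <- "unknown"; number[i] <- "unknown"
      }
      next
    }
    hit <- if (nrow(kb)) match(nm, kb$token) else NA_integer_
    if (!is.na(hit)) {
      tag[i] <- kb$tag[hit]
      gender[i] <- fallback$gender[i]; number[i] <- fallback$number[i]
      next
    }
    tag[i] <- "X"
    gender[i] <- fallback$gender[i]; number[i] <- fallback$number[i]
  }
  out <- tibble::tibble(surface = toks$surface, norm = toks$norm, tag = tag,
                        gender = gender, number = number, index = toks$index,
                        in_parens = toks$in_parens)
  attr(out, "raw") <- text
  out
}

#' Empty knowledge base
#'
#' @return A zero-row KB tibble (`token`, `tag`, `rule`, `iteration`).
#' @export
empty_kb <- function() {
  tibble::tibble(token = character(), tag = character(), rule = character(),
                 iteration = integer())
}

#' Read / write a knowledge base TSV
#'
#' @param path Path to a TSV with columns `token`, `tag`, `rule`,
#'   `iteration`.
#' @return `read_kb()` returns the KB tibble; `write_kb()` writes `kb` and
#'   returns `path` invisibly.
#' @export
read_kb <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    token = "c", tag = "c", rule = "c", iteration = "i"
  ), progress = FALSE)
}

#' @rdname read_kb
#' @param kb A KB tibble.
#' @export
write_kb <- function(kb, path) {
  readr::write_tsv(kb, path)
  invisible(path)
}

# --- bootstrap rules --------------------------------------------------------

propagate_over_separator <- function(tokens, is_sep) {
  # maximal runs  w sep w sep w ...  of word tokens joined by the separator;
  # returns indices of X-tagged members of runs containing at least one A
  word <- tokens$tag %in% c("A", "X", "E")
  out <- integer()
  i <- 1L; n <- nrow(tokens)
  while (i <= n) {
    if (!word[i]) { i <- i + 1L; next }
    run <- i; j <- i
    while (j + 2L <= n && is_sep(j + 1L) && word[j + 2L]) {
      run <- c(run, j + 2L); j <- j + 2L
    }
    if (length(run) > 1L && any(tokens$tag[run] == "A")) {
      out <- c(out, run[tokens$tag[run] == "X"])
    }
    i <- j + 1L
  }
  unique(out)
}

#' Default bootstrapping rules
#'
#' Two role-propagation rules over tagged chunks: `a_propagation` -- tokens
#' separated by the preposition `"a"` share the character-state role when at
#' least one of them is already tagged `A`; `coord_propagation` -- the same
#' propagation across the coordinating conjunctions `o`/`u`/`y`/`e` (an
#' extension of the same idea to coordination). Each rule maps a tagged
#' token tibble to the norms it proposes to label `A`.
#'
#' @return A named list of rule functions.
#' @export
default_bootstrap_rules <- function() {
  list(
    a_propagation = function(tokens) {
      idx <- propagate_over_separator(
        tokens, function(k) tokens$norm[k] == "a")
      tokens$norm[idx]
    },
    coord_propagation = function(tokens) {
      idx <- propagate_over_separator(
        tokens, function(k) tokens$tag[k] == "C")
      tokens$norm[idx]
    }
  )
}

#' Grow the knowledge base by bootstrapping
#'
#' Iterative, incremental role learning: chunks are (re)tagged with the
#' current lexicon + KB, every rule proposes roles for still-unknown tokens,
#' and new entries are added with their provenance rule and iteration
#' number. Entries are never overwritten (the KB only grows) and closed
#' -class/lexicon tokens are never added. Iteration stops at the fixpoint or
#' after `max_iterations`.
#'
#' @param chunk_texts Character vector of chunk texts (the corpus).
#' @param resources An [ft_resources()] list; its `kb` is the starting KB.
#' @param rules Named list of rule functions (see
#'   [default_bootstrap_rules()]).
#' @param max_iterations Iteration cap (default 10).
#' @return The updated KB tibble.
#' @export
bootstrap_kb <- function(chunk_texts, resources = ft_resources(),
                         rules = default_bootstrap_rules(),
                         max_iterations = 10L) {
  kb <- resources$kb
  for (iter in seq_len(max_iterations)) {
    res_iter <- resources
    res_iter$kb <- kb
    added <- FALSE
    for (text in chunk_texts) {
      tokens <- tag_chunk(text, res_iter)
      for (rid in names(rules)) {
        new <- setdiff(rules[[rid]](tokens),
                       c(kb$token, resources$lexicon$token))
        if (length(new)) {
          kb <- dplyr::bind_rows(kb, tibble::tibble(
            token = new, tag = "A", rule = rid, iteration = iter))
          added <- TRUE
          res_iter$kb <- kb
        }
      }
    }
    if (!added) break
  }
  kb
}
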