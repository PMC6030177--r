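multiset_matches <- function(pred, gold) {
  # size of the multiset intersection of two character vectors of keys
  pt <- table(pred); gt <- table(gold)
  common <- intersect(names(pt), names(gt))
  sum(pmin(pt[common], gt[common]))
}

structure_keys <- function(x) {
  paste(x$structures$name, dplyr::coalesce(x$structures$modifier, ""),
        sep = "\r")
}

character_keys <- function(x) {
  ch <- x$characters
  paste(ch$name, ch$value, dplyr::coalesce(ch$char_type, ""),
        dplyr::coalesce(ch$from, ""), dplyr::coalesce(ch$to, ""),
        dplyr::coalesce(ch$from_unit, ""), dplyr::coalesce(ch$to_unit, ""),
        dplyr::coalesce(ch$atypical_from, ""),
        dplyr::coalesce(ch$atypical_to, ""), sep = "\r")
}

association_keys <- function(x) {
  sname <- x$structures$name[match(x$characters$structure_id,
                                   x$structures$id)]
  paste(sname, character_keys(x), sep = "\r")
}

#' Coordinated character groups of an annotated description
#'
#' Reconstructs conjunction groups from the character table: a group is a
#' maximal run of characters (in creation order) on the same structure with
#' the same character name in which every character after the first carries
#' a conjunction word (`o`/`y`) in its notes.
#'
#' @param x An [annotated_description()].
#' @return A character vector of group keys (structure name, character
#'   name, ordered conjunct values), one per group of two or more
#'   conjuncts.
#' @export
conjunction_groups <- function(x) {
  ch <- x$characters
  if (!nrow(ch)) return(character())
  sname <- x$structures$name[match(ch$structure_id, x$structures$id)]
  conj <- !is.na(ch$notes) & grepl("(^|; )(o|y)($|; )", ch$notes)
  keys <- character()
  for (sub in split(seq_len(nrow(ch)), paste(ch$structure_id, ch$name))) {
    i <- 1L
    while (i <= length(sub)) {
      j <- i
      while (j + 1L <= length(sub) && conj[sub[j + 1L]]) j <- j + 1L
      if (j > i) {
        keys <- c(keys, paste(sname[sub[i]],
                              paste(ch$value[sub[i:j]], collapse = "|"),
                              sep = "\r"))
      }
      i <- j + 1L
    }
  }
  # a state resolving to several character names repeats its group once per
  # name; collapse those duplicates
  unique(keys)
}

prf <- function(matches, n_pred, n_gold) {
  p <- if (n_pred == 0) 0 else matches / n_pred
  r <- if (n_gold == 0) 0 else matches / n_gold
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = 100 * p, recall = 100 * r, f1 = 100 * f)
}

#' Score predicted annotations against gold annotations
#'
#' Computes precision, recall and F-1 (percent) for the four evaluation
#' aspects: identification of structures (name + modifier), character
#' structuring (name + value + range fields), association of characters to
#' structures (a matched character linked to a matched structure), and
#' association of conjunctions (a coordinated group fully recovered).
#' Matching is exact-string on normalized fields over multisets, so scores
#' are invariant under relabeling of object ids. Undefined precision (zero
#' predictions) is reported as 0 and flagged in the `undefined_precision`
#' attribute.
#'
#' @param predicted,gold Aligned lists of [annotated_description()] objects.
#' @return A tibble of class `aspect_scores` with columns `aspect`,
#'   `precision`, `recall`, `f1`.
#' @export
score_annotations <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    stop("ALIGNMENT_ERROR: ", length(predicted), " predicted vs ",
         length(gold), " gold descriptions", call. = FALSE)
  }
  aspects <- c("structures", "characters", "association", "conjunctions")
  keyfun <- list(structures = structure_keys, characters = character_keys,
                 association = association_keys,
                 conjunctions = conjunction_groups)
  m <- matrix(0, nrow = 4, ncol = 3,
              dimnames = list(aspects, c("matches", "n_pred", "n_gold")))
  for (i in seq_along(predicted)) {
    for (a in aspects) {
      pk <- keyfun[[a]](predicted[[i]])
      gk <- keyfun[[a]](gold[[i]])
      m[a, ] <- m[a, ] + c(multiset_matches(pk, gk), length(pk), length(gk))
    }
  }
  out <- tibble::tibble(
    aspect = aspects,
    precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  for (a in aspects) {
    s <- prf(m[a, "matches"], m[a, "n_pred"], m[a, "n_gold"])
    out[out$aspect == a, c("precision", "recall", "f1")] <- as.list(s)
  }
  attr(out, "undefined_precision") <- aspects[m[, "n_pred"] == 0]
  class(out) <- c("aspect_scores", class(out))
  out
}

#' Clause complexity
#'
#' A clause is simple if it describes two or fewer structures and complex
#' otherwise.
#'
#' @param x An [annotated_description()].
#' @return A tibble with columns `clause_id`, `n_structures`, `complexity`.
#' @export
clause_complexity <- function(x) {
  counts <- table(x$structures$clause_id)
  n <- as.integer(counts[match(x$clauses$clause_id, names(counts))])
  n[is.na(n)] <- 0L
  tibble::tibble(
    clause_id = x$clauses$clause_id,
    n_structures = n,
    complexity = ifelse(n > 2, "complex", "simple"))
}
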