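#' Build a dependency tree for a tagged chunk
#'
#' A deterministic heuristic parser producing the minimal tree shapes the
#' annotation rules consume (the pluggable-backend contract: any parser
#' satisfying the same postconditions may replace it). Head priority is
#' E > A > Z > first token, mirroring the dominant noun-plus-states shape of
#' telegraphic chunks. Adjectives and numerals attach under the root as
#' siblings; an adverb attaches to the nearest following content token
#' (A/V/Z/U/E/R), else the nearest preceding one; parenthetical tokens
#' attach under the token immediately preceding the opening parenthesis;
#' a preposition or verb heads a subtree containing the tokens that follow
#' it (up to the next preposition/verb); a coordinating conjunction attaches
#' under the first conjunct and later conjuncts become siblings of the
#' first.
#'
#' @param tokens A tagged token tibble from [tag_chunk()].
#' @return The same tibble with an integer `parent` column (0-based token
#'   index of the parent; `NA` for the root).
#' @export
parse_chunk <- function(tokens) {
  n <- nrow(tokens)
  if (n == 0L) stop("MALFORMED_CHUNK: chunk has zero tokens", call. = FALSE)
  tag <- tokens$tag
  inp <- tokens$in_parens
  parent <- rep(NA_integer_, n)

  top <- which(!inp)
  root <- top[tag[top] == "E"][1]
  if (is.na(root)) root <- top[tag[top] == "A"][1]
  if (is.na(root)) root <- top[tag[top] == "Z"][1]
  if (is.na(root)) root <- top[1]
  if (is.na(root)) root <- 1L

  content <- c("A", "V", "Z", "U", "E", "R")
  # current subtree head: root, or the last S/V opened at top level
  head <- root
  last_conjunct <- NA_integer_
  for (i in seq_len(n)) {
    if (i == root) next
    if (inp[i]) {
      # attach under the token immediately preceding the open parenthesis
      prev <- which(!inp & seq_len(n) < i)
      parent[i] <- if (length(prev)) max(prev) else root
      next
    }
    t <- tag[i]
    if (t == "S" && tokens$norm[i] == "a") {
      # "a" linking two states is a connector, not a phrase head
      prev <- which(!inp & seq_len(n) < i & !(tag %in% c("R", "D")))
      nxt <- which(!inp & seq_len(n) > i & !(tag %in% c("R", "D")))
      if (length(prev) && length(nxt) && tag[max(prev)] %in% c("A", "X") &&
            tag[min(nxt)] %in% c("A", "X")) {
        parent[i] <- head
        next
      }
    }
    if (t %in% c("S", "V")) {
      parent[i] <- root
      head <- i
      next
    }
    if (t == "R") {
      after <- which(seq_len(n) > i & tag %in% content & !inp)
      # backward attachment never targets another adverb (a pair of adverbs
      # attaching to each other would make a cycle)
      before <- which(seq_len(n) < i & tag %in% setdiff(content, "R") & !inp &
                        seq_len(n) != root)
      parent[i] <- if (length(after)) min(after)
                   else if (length(before)) max(before) else root
      next
    }
    if (t == "C") {
      prev <- which(seq_len(n) < i & tag %in% c("A", "E", "Z") & !inp)
      last_conjunct <- if (length(prev)) max(prev) else NA_integer_
      parent[i] <- if (!is.na(last_conjunct)) last_conjunct else head
      next
    }
    if (t %in% c("A", "Z") && !is.na(last_conjunct) && head == root) {
      # conjunct following a C: sibling of the first conjunct
      parent[i] <- parent[last_conjunct]
      if (is.na(parent[i])) parent[i] <- root
      last_conjunct <- NA_integer_
      next
    }
    if (t == "E" && head == root && i > root && tag[root] == "E" &&
        all(tag[seq(root, i - 1)][!inp[seq(root, i - 1)]] %in% c("E", "D"))) {
      # apposed noun right after the head noun: modifier of the head
      parent[i] <- root
      next
    }
    if (t == "U") {
      prevz <- which(seq_len(n) < i & tag == "Z" & !inp)
      parent[i] <- if (length(prevz)) max(prevz) else head
      next
    }
    if (t == "D") {
      nxt <- which(seq_len(n) > i & tag == "E" & !inp)
      parent[i] <- if (length(nxt)) min(nxt) else head
      next
    }
    parent[i] <- head
  }
  # tokens before the root (e.g. leading adverbs/determiners already handled;
  # anything still unattached hangs off the root)
  parent[is.na(parent) & seq_len(n) != root] <- root
  # 0-based like token indices
  out <- tokens
  out$parent <- ifelse(seq_len(n) == root, NA_integer_,
                       tokens$index[parent])
  attr(out, "root") <- tokens$index[root]
  out
}

#' Neighbouring nodes of a tree node
#'
#' Returns the relations the adverb rules test: the ancestor (parent), the
#' siblings (same parent) and the children of the node.
#'
#' @param tree A parsed chunk from [parse_chunk()].
#' @param index 0-based token index of the node.
#' @return A list with elements `ancestor` (0-based index or `NA`),
#'   `siblings` and `children` (integer vectors of 0-based indices).
#' @export
neighbors <- function(tree, index) {
  row <- match(index, tree$index)
  stopifnot(!is.na(row))
  parent <- tree$parent[row]
  sibs <- tree$index[!is.na(tree$parent) & tree$parent %in% parent &
                       tree$index != index]
  if (is.na(parent)) sibs <- integer()
  children <- tree$index[!is.na(tree$parent) & tree$parent == index]
  list(ancestor = parent, siblings = sibs, children = children)
}

#' One-line bracketed rendering of a parsed chunk (debug aid)
#'
#' @param tree A parsed chunk from [parse_chunk()].
#' @return A single string, e.g. `"(margen (aserrado (finamente)))"`.
#' @export
format_tree <- function(tree) {
  render <- function(idx) {
    kids <- tree$index[!is.na(tree$parent) & tree$parent == idx]
    label <- tree$surface[match(idx, tree$index)]
    if (!length(kids)) return(paste0("(", label, ")"))
    paste0("(", label, " ", paste(vapply(kids, render, ""), collapse = " "),
           ")")
  }
  render(attr(tree, "root"))
}
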