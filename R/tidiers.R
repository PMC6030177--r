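#' Tidy an annotated description
#'
#' One row per extracted character, joined with the name of the structure
#' it describes -- the "trait triple" view (structure, character, value)
#' plus range fields and notes.
#'
#' @param x An [annotated_description()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy annotated_description
#' @export
tidy.annotated_description <- function(x, ...) {
  st <- x$structures
  ch <- x$characters
  idx <- match(ch$structure_id, st$id)
  tibble::tibble(
    taxon = x$taxon_name,
    clause_id = st$clause_id[idx],
    structure = st$name[idx],
    modifier = st$modifier[idx],
    character = ch$name,
    value = ch$value,
    from = ch$from, to = ch$to,
    from_unit = ch$from_unit, to_unit = ch$to_unit,
    atypical_from = ch$atypical_from, atypical_to = ch$atypical_to,
    constraint = ch$constraint, notes = ch$notes)
}

#' @rdname tidy.annotated_description
#' @method glance annotated_description
#' @export
glance.annotated_description <- function(x, ...) {
  cc <- clause_complexity(x)
  tibble::tibble(
    taxon = x$taxon_name,
    n_clauses = nrow(x$clauses),
    n_chunks = nrow(x$chunks),
    n_structures = nrow(x$structures),
    n_characters = nrow(x$characters),
    n_relations = nrow(x$relations),
    n_spans = nrow(x$constraint_spans),
    n_simple_clauses = sum(cc$complexity == "simple"),
    n_complex_clauses = sum(cc$complexity == "complex"))
}

#' @method tidy aspect_scores
#' @export
tidy.aspect_scores <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"aspect",
                      names_to = "metric", values_to = "percent")
}

#' @method glance aspect_scores
#' @export
glance.aspect_scores <- function(x, ...) {
  tibble::tibble(mean_precision = mean(x$precision),
                 mean_recall = mean(x$recall),
                 mean_f1 = mean(x$f1))
}

#' Plot evaluation scores by aspect
#'
#' Bar chart of precision, recall and F-1 for the four annotation aspects.
#'
#' @param object An `aspect_scores` tibble from [score_annotations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aspect_scores
#' @export
autoplot.aspect_scores <- function(object, ...) {
  long <- tidy.aspect_scores(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$aspect, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "%", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the object counts of an annotated description
#'
#' Number of structures and characters extracted per clause.
#'
#' @param object An [annotated_description()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot annotated_description
#' @export
autoplot.annotated_description <- function(object, ...) {
  counts <- dplyr::bind_rows(
    dplyr::count(object$structures, .data$clause_id, name = "n") |>
      dplyr::mutate(what = "structures"),
    dplyr::count(
      dplyr::mutate(object$characters,
                    clause_id = object$structures$clause_id[
                      match(.data$structure_id, object$structures$id)]),
      .data$clause_id, name = "n") |>
      dplyr::mutate(what = "characters"))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$clause_id, y = .data$n,
                                       fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "clause", y = "objects", fill = NULL,
                  title = object$taxon_name) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
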