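#' Read a table of taxon descriptions
#'
#' Reads a delimited UTF-8 file with one morphological description per row.
#' The header must name a taxon column and a description column; rows with
#' an empty cell are skipped with a warning.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default TAB).
#' @param taxon_col,description_col Column names (defaults `taxon`,
#'   `description`).
#' @return A tibble with columns `taxon`, `description`.
#' @export
read_description_table <- function(path, delimiter = "\t",
                                   taxon_col = "taxon",
                                   description_col = "description") {
  if (!file.exists(path)) {
    stop("IO_ERROR: file not found: ", path, call. = FALSE)
  }
  tab <- readr::read_delim(path, delim = delimiter,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (!all(c(taxon_col, description_col) %in% names(tab))) {
    stop("FORMAT_ERROR: expected columns '", taxon_col, "' and '",
         description_col, "'", call. = FALSE)
  }
  out <- tibble::tibble(taxon = tab[[taxon_col]],
                        description = tab[[description_col]])
  bad <- is.na(out$taxon) | !nzchar(out$taxon) |
    is.na(out$description) | !nzchar(out$description)
  if (any(bad)) {
    warning(sum(bad), " row(s) with empty cells skipped", call. = FALSE)
    out <- out[!bad, ]
  }
  out
}

#' @rdname read_description_table
#' @param records A tibble with columns `taxon`, `description`.
#' @export
write_description_table <- function(records, path, delimiter = "\t") {
  readr::write_delim(records, path, delim = delimiter)
  invisible(path)
}

# --- XML writing -------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

attr_string <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return("")
  paste0(" ", paste0(names(values), "=\"", xml_escape(unlist(values)), "\"",
                     collapse = " "))
}

# fixed attribute orders (golden files depend on them)
structure_attrs <- c("id", "name", "constraint", "modifier", "ontology_id",
                     "notes")
character_attrs <- c("id", "name", "value", "char_type", "from", "to",
                     "from_unit", "to_unit", "atypical_from", "atypical_to",
                     "constraint", "notes")

#' Write an annotated description as XML
#'
#' Serializes the model with a fixed element and attribute order, UTF-8 and
#' two-space indentation, so identical models produce byte-identical files.
#' One `<description>` root per taxon; one `<statement>` per clause carrying
#' the clause text; `<structure>` elements with their `<character>` children
#' nested inside; `<relation>` elements; constraint spans as
#' `<constraint_preposition>`, `<constraint_verb>` or `<verb_string>`
#' elements.
#'
#' @param x An [annotated_description()]; it must validate cleanly.
#' @param path Output file path. If `NULL`, the XML is returned as a
#'   character vector of lines.
#' @return `path` (or the lines when `path` is `NULL`), invisibly.
#' @export
write_trait_xml <- function(x, path = NULL) {
  issues <- validate_description(x)
  if (length(issues)) {
    stop("VALIDATION_ERROR: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<description taxon_name=\"",
                    xml_escape(x$taxon_name), "\">"))
  for (li in seq_len(nrow(x$clauses))) {
    cid <- x$clauses$clause_id[li]
    lines <- c(lines, paste0("  <statement id=\"", xml_escape(cid),
                             "\" text=\"", xml_escape(x$clauses$text[li]),
                             "\">"))
    sts <- x$structures[x$structures$clause_id == cid, ]
    for (si in seq_len(nrow(sts))) {
      st <- sts[si, ]
      vals <- stats::setNames(as.list(st[structure_attrs]), structure_attrs)
      chars <- x$characters[x$characters$structure_id == st$id, ]
      open <- paste0("    <structure", attr_string(vals))
      if (!nrow(chars)) {
        lines <- c(lines, paste0(open, "/>"))
      } else {
        lines <- c(lines, paste0(open, ">"))
        for (ci in seq_len(nrow(chars))) {
          cvals <- stats::setNames(as.list(chars[ci, character_attrs]),
                                   character_attrs)
          lines <- c(lines, paste0("      <character", attr_string(cvals),
                                   "/>"))
        }
        lines <- c(lines, "    </structure>")
      }
    }
    rel_ids <- x$structures$id[x$structures$clause_id == cid]
    rels <- x$relations[x$relations$from_structure_id %in% rel_ids |
                          x$relations$to_structure_id %in% rel_ids, ]
    for (ri in seq_len(nrow(rels))) {
      r <- rels[ri, ]
      lines <- c(lines, paste0(
        "    <relation",
        attr_string(list(id = r$id, name = r$name,
                         from = r$from_structure_id,
                         to = r$to_structure_id,
                         negated = tolower(as.character(r$negated)))),
        "/>"))
    }
    spans <- x$constraint_spans[x$constraint_spans$clause_id == cid, ]
    for (pi in seq_len(nrow(spans))) {
      p <- spans[pi, ]
      lines <- c(lines, paste0(
        "    <", p$kind,
        attr_string(list(text = p$text, attached_to = p$attached_to)),
        "/>"))
    }
    lines <- c(lines, "  </statement>")
  }
  lines <- c(lines, "</description>")
  if (is.null(path)) return(invisible(lines))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Mirror an annotated description as JSON
#'
#' A 1:1 convenience mirror of the XML content (same fields, same nesting);
#' not a second schema.
#'
#' @param x An [annotated_description()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trait_json <- function(x, path) {
  obj <- list(
    taxon_name = x$taxon_name,
    statements = purrr::map(seq_len(nrow(x$clauses)), function(li) {
      cid <- x$clauses$clause_id[li]
      sts <- x$structures[x$structures$clause_id == cid, ]
      list(
        id = cid,
        text = x$clauses$text[li],
        structures = purrr::map(seq_len(nrow(sts)), function(si) {
          st <- as.list(sts[si, ])
          st$characters <-
            x$characters[x$characters$structure_id == st$id, ]
          st
        }),
        relations = x$relations[
          x$relations$from_structure_id %in% sts$id |
            x$relations$to_structure_id %in% sts$id, ],
        constraint_spans =
          x$constraint_spans[x$constraint_spans$clause_id == cid, ]
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  invisible(path)
}

# --- XML reading -------------------------------------------------------------

known_attrs <- list(
  structure = structure_attrs,
  character = character_attrs,
  relation = c("id", "name", "from", "to", "negated"),
  span = c("text", "attached_to")
)

collect_extras <- function(attrs, known, where, extras_env) {
  extra <- setdiff(names(attrs), known)
  if (length(extra)) {
    extras_env$map[[where]] <- c(extras_env$map[[where]], attrs[extra])
    warning("unknown attribute(s) ", paste(extra, collapse = ", "),
            " on <", where, "> preserved in the pass-through map",
            call. = FALSE)
  }
}

na_if_null <- function(x) if (is.null(x)) NA_character_ else x

#' Read an annotated description from XML
#'
#' Parses a file written by [write_trait_xml()] (or any schema-valid file)
#' back into the in-memory model, so that `read(write(x))` is structurally
#' equal to `x`. Unknown attributes are preserved in a pass-through map
#' (attribute `extras` of the result) with a warning; malformed files raise
#' a `SCHEMA_ERROR`.
#'
#' @param path Path to the XML file.
#' @return An [annotated_description()].
#' @export
read_trait_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("SCHEMA_ERROR: ", conditionMessage(e),
                         call. = FALSE)
                  })
  root <- xml2::xml_name(doc)
  if (root != "description") {
    stop("SCHEMA_ERROR: root element is <", root, ">, expected <description>",
         call. = FALSE)
  }
  extras <- new.env(parent = emptyenv())
  extras$map <- list()
  taxon <- xml2::xml_attr(doc, "taxon_name")
  clauses <- empty_clauses(); structures <- empty_structures()
  characters <- empty_characters(); relations <- empty_relations()
  spans <- empty_spans()
  for (st_node in xml2::xml_find_all(doc, "./statement")) {
    cid <- xml2::xml_attr(st_node, "id")
    clauses <- dplyr::bind_rows(clauses, tibble::tibble(
      clause_id = cid, text = xml2::xml_attr(st_node, "text")))
    for (node in xml2::xml_children(st_node)) {
      nm <- xml2::xml_name(node)
      attrs <- as.list(xml2::xml_attrs(node))
      if (nm == "structure") {
        collect_extras(attrs, known_attrs$structure, "structure", extras)
        structures <- dplyr::bind_rows(structures, tibble::tibble(
          id = na_if_null(attrs$id), clause_id = cid,
          name = na_if_null(attrs$name),
          constraint = na_if_null(attrs$constraint),
          modifier = na_if_null(attrs$modifier),
          ontology_id = na_if_null(attrs$ontology_id),
          notes = na_if_null(attrs$notes)))
        for (ch in xml2::xml_find_all(node, "./character")) {
          cattrs <- as.list(xml2::xml_attrs(ch))
          collect_extras(cattrs, known_attrs$character, "character", extras)
          characters <- dplyr::bind_rows(characters, tibble::tibble(
            id = na_if_null(cattrs$id),
            structure_id = na_if_null(attrs$id),
            name = na_if_null(cattrs$name),
            value = na_if_null(cattrs$value),
            char_type = na_if_null(cattrs$char_type),
            from = na_if_null(cattrs$from), to = na_if_null(cattrs$to),
            from_unit = na_if_null(cattrs$from_unit),
            to_unit = na_if_null(cattrs$to_unit),
            atypical_from = na_if_null(cattrs$atypical_from),
            atypical_to = na_if_null(cattrs$atypical_to),
            constraint = na_if_null(cattrs$constraint),
            notes = na_if_null(cattrs$notes)))
        }
      } else if (nm == "relation") {
        collect_extras(attrs, known_attrs$relation, "relation", extras)
        relations <- dplyr::bind_rows(relations, tibble::tibble(
          id = na_if_null(attrs$id), name = na_if_null(attrs$name),
          from_structure_id = na_if_null(attrs$from),
          to_structure_id = na_if_null(attrs$to),
          negated = identical(attrs$negated, "true")))
      } else if (nm %in% c("constraint_preposition", "constraint_verb",
                           "verb_string")) {
        collect_extras(attrs, known_attrs$span, nm, extras)
        spans <- dplyr::bind_rows(spans, tibble::tibble(
          clause_id = cid, kind = nm, text = na_if_null(attrs$text),
          attached_to = na_if_null(attrs$attached_to)))
      } else {
        stop("SCHEMA_ERROR: unexpected element <", nm, ">", call. = FALSE)
      }
    }
  }
  # nesting groups characters under their structure; restore creation order
  if (nrow(characters) && all(grepl("^o[0-9]+$", characters$id))) {
    characters <- characters[order(as.integer(sub("^o", "",
                                                  characters$id))), ]
  }
  out <- annotated_description(
    taxon_name = taxon, clauses = clauses,
    structures = structures, characters = characters,
    relations = relations, constraint_spans = spans)
  if (length(extras$map)) attr(out, "extras") <- extras$map
  out
}
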