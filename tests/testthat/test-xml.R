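test_that("description tables read with header detection and row skipping", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tdescription",
               "Quercus salicifolia\thojas simples, alternas.",
               "Ficus sp.\tflores blancas."), path)
  tab <- read_description_table(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$taxon[1], "Quercus salicifolia")

  writeLines(c("taxon\tdescription", "X\t", "Y\thojas simples."), path)
  expect_warning(tab2 <- read_description_table(path), "skipped")
  expect_equal(tab2$taxon, "Y")

  writeLines(c("a\tb", "1\t2"), path)
  expect_error(read_description_table(path), "FORMAT_ERROR")
  expect_error(read_description_table(file.path(tempdir(), "nope.tsv")),
               "IO_ERROR")
})

test_that("descriptions round-trip byte-identically through the table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rec <- tibble::tibble(taxon = "Quercus salicifolia",
                        description = quercus_clause)
  write_description_table(rec, path)
  back <- read_description_table(path)
  expect_identical(back$description, rec$description)
})

test_that("XML writing is deterministic and reading inverts it", {
  ad <- annotate_description("Quercus salicifolia",
                             paste0(quercus_clause, "."), test_res)
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_trait_xml(ad, p1)
  write_trait_xml(ad, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_trait_xml(p1)
  for (comp in c("taxon_name", "clauses", "structures", "characters",
                 "relations", "constraint_spans")) {
    expect_identical(back[[comp]], ad[[comp]])
  }
  # writing the re-read model reproduces the bytes
  p3 <- withr::local_tempfile(fileext = ".xml")
  write_trait_xml(back, p3)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p3, "raw", file.size(p3)))
})

test_that("the emitted XML carries the documented fragments", {
  ad <- annotate_description("Q", "hojas simples, elípticas.", test_res)
  lines <- write_trait_xml(ad)
  expect_true(any(grepl("<structure id=\"o1\" name=\"hojas\">", lines)))
  expect_true(any(grepl(
    "<character id=\"o2\" name=\"architecture\" value=\"simples\"/>",
    lines)))
  expect_true(any(grepl(
    paste0("<character id=\"o3\" name=\"arrangement\" value=\"elípticas\"",
           " notes=\"Carácter repetido\"/>"), lines)))
})

test_that("an empty description writes a minimal valid document", {
  lines <- write_trait_xml(annotated_description("Nada spec"))
  expect_equal(lines[2], "<description taxon_name=\"Nada spec\">")
  expect_equal(lines[3], "</description>")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(lines, path)
  back <- read_trait_xml(path)
  expect_equal(nrow(back$clauses), 0L)
})

test_that("malformed or truncated files raise SCHEMA_ERROR", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<description taxon_name=\"X\"><statement", path)
  expect_error(read_trait_xml(path), "SCHEMA_ERROR")
  writeLines("<wrong/>", path)
  expect_error(read_trait_xml(path), "SCHEMA_ERROR")
})

test_that("unknown attributes are passed through with a warning", {
  ad <- annotate_description("Q", "hojas simples.", test_res)
  path <- withr::local_tempfile(fileext = ".xml")
  lines <- write_trait_xml(ad)
  lines <- sub("name=\"hojas\"", "name=\"hojas\" provenance=\"legacy\"",
               lines)
  writeLines(lines, path)
  expect_warning(back <- read_trait_xml(path), "provenance")
  expect_equal(attr(back, "extras")$structure$provenance, "legacy")
  expect_equal(back$structures$name, "hojas")
})

test_that("invalid models are refused by the writer", {
  ad <- annotated_description("X")
  ad$characters <- tibble::tibble(
    id = "o1", structure_id = "o99", name = "n", value = "v",
    char_type = NA_character_, from = NA_character_, to = NA_character_,
    from_unit = NA_character_, to_unit = NA_character_,
    atypical_from = NA_character_, atypical_to = NA_character_,
    constraint = NA_character_, notes = NA_character_)
  expect_error(write_trait_xml(ad), "VALIDATION_ERROR")
})

test_that("the JSON mirror carries the same objects as the XML", {
  ad <- annotate_description("Q", "hojas simples, con tricomas.", test_res)
  path <- withr::local_tempfile(fileext = ".json")
  write_trait_json(ad, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$taxon_name, "Q")
  sts <- obj$statements[[1]]$structures
  expect_equal(vapply(sts, function(s) s$name, ""),
               c("hojas", "tricomas"))
})
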