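test_that("the generator is deterministic and honours n = 0", {
  z <- generate_fixtures(0, seed = 1)
  expect_equal(nrow(z$records), 0L)
  expect_length(z$gold, 0L)
  a <- generate_fixtures(15, seed = 9)
  b <- generate_fixtures(15, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$gold, b$gold)
  c <- generate_fixtures(15, seed = 10)
  expect_false(identical(a$records, c$records))
})

test_that("pattern shares track the configured mixture weights", {
  grammar <- fixture_grammar(resources = test_res)
  fx <- generate_fixtures(1000, seed = 2, grammar = grammar)
  chunks <- unlist(lapply(fx$gold, function(g) g$chunks$text))
  # classify extra chunks (clause-initial noun+state chunks excluded by
  # looking only at chunks beyond S1)
  ids <- unlist(lapply(fx$gold, function(g) g$chunks$chunk_id))
  extra <- chunks[!grepl("S1$", ids)]
  is_meas <- grepl("^[0-9]", extra)
  is_zgzu <- is_meas & grepl("×", extra)
  is_zuse <- is_meas & !is_zgzu
  is_bare <- !is_meas & !grepl(" ", extra)
  # conjunction/con/fallback chunks are clause-features, not mixture draws
  feature <- grepl(" o | u |^con |^sin ", extra)
  is_na_pat <- !is_meas & !is_bare & !feature
  n_mix <- sum(is_zgzu + is_zuse + is_bare + is_na_pat)
  shares <- c(na = sum(is_na_pat), a = sum(is_bare),
              zuse = sum(is_zuse), zgzu = sum(is_zgzu)) / n_mix
  expect_true(all(abs(shares - grammar$weights[names(shares)]) < 0.03))
})

test_that("perfect and degenerate predictions score as expected", {
  fx <- generate_fixtures(12, seed = 4)
  perfect <- score_annotations(fx$gold, fx$gold)
  expect_true(all(perfect$precision == 100))
  expect_true(all(perfect$recall == 100))
  expect_true(all(perfect$f1 == 100))

  none <- lapply(fx$gold, function(g) annotated_description(g$taxon_name))
  zero <- score_annotations(none, fx$gold)
  expect_true(all(zero$precision == 0))
  expect_true(all(zero$recall == 0))
  expect_true(length(attr(zero, "undefined_precision")) > 0)

  expect_error(score_annotations(fx$gold[-1], fx$gold), "ALIGNMENT_ERROR")
})

test_that("one wrong association among ten costs exactly ten points", {
  res <- test_res
  gold <- list(annotate_description(
    "X",
    paste("hojas glabras, hojas alternas, hojas enteras, hojas ovadas,",
          "frutos rojos, frutos negros, tallo erecto, tallo liso,",
          "corteza lisa, corteza rugosa."),
    res))
  expect_equal(nrow(gold[[1]]$characters), 10L)
  pred <- gold
  # move one character to a different (existing) structure
  wrong <- pred[[1]]
  other <- wrong$structures$id[wrong$structures$name == "tallo"][1]
  wrong$characters$structure_id[1] <- other
  pred[[1]] <- wrong
  sc <- score_annotations(pred, gold)
  assoc <- sc[sc$aspect == "association", ]
  expect_equal(assoc$precision, 90)
  expect_equal(assoc$recall, 90)
  # structure and character aspects are untouched by the re-linking
  expect_equal(sc$f1[sc$aspect == "structures"], 100)
  expect_equal(sc$f1[sc$aspect == "characters"], 100)
})

test_that("scores are invariant under relabeling of ids", {
  fx <- generate_fixtures(9, seed = 6)
  relabel <- lapply(fx$gold, function(g) {
    map <- stats::setNames(paste0("z", seq_along(g$structures$id)),
                           g$structures$id)
    g$structures$id <- unname(map[g$structures$id])
    g$characters$structure_id <- unname(map[g$characters$structure_id])
    g$characters$id <- paste0("c", seq_along(g$characters$id))
    g$relations$from_structure_id <- unname(map[g$relations$from_structure_id])
    g$relations$to_structure_id <- unname(map[g$relations$to_structure_id])
    g
  })
  sc <- score_annotations(relabel, fx$gold)
  expect_true(all(sc$f1 == 100))
})

test_that("clause complexity counts structures per clause", {
  ad <- annotate_description(
    "X", "hojas simples; flores blancas, ápice agudo, base obtusa.",
    test_res)
  cc <- clause_complexity(ad)
  expect_equal(cc$complexity, c("simple", "complex"))
  expect_equal(cc$n_structures, c(1L, 3L))
  empty <- clause_complexity(annotated_description("X"))
  expect_equal(nrow(empty), 0L)
})

test_that("tidy and glance views summarise an annotation", {
  ad <- annotate_description("Q", "hojas simples, 5-18 × 1.5-9 cm.",
                             test_res)
  td <- tidy(ad)
  expect_equal(td$structure, rep("hojas", 3))
  expect_true(all(c("character", "value", "from", "to") %in% names(td)))
  gl <- glance(ad)
  expect_equal(gl$n_structures, 1L)
  expect_equal(gl$n_characters, 3L)
  expect_equal(gl$n_simple_clauses, 1L)
})

test_that("autoplot returns ggplot objects", {
  fx <- generate_fixtures(6, seed = 8)
  sc <- score_annotations(fx$gold, fx$gold)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(autoplot(fx$gold[[1]]), "ggplot")
})
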