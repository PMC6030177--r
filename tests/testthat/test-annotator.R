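quercus <- annotate_description("Quercus salicifolia", quercus_clause,
                                test_res)
qchars <- chars_with_structure(quercus)

test_that("the reference clause yields the printed structure set", {
  expect_setequal(quercus$structures$name,
                  c("hojas", "ápice", "base", "tricomas", "vena", "envés"))
  # prepositional-phrase structures carry no characters of their own here
  vena_id <- quercus$structures$id[quercus$structures$name == "vena"]
  expect_false(vena_id %in% quercus$characters$structure_id)
})

test_that("noun+state chunks create a structure and its character", {
  ad <- annotate_description("X", "hojas simples.", test_res)
  expect_equal(ad$structures$name, "hojas")
  expect_equal(ad$characters$name, "architecture")
  expect_equal(ad$characters$value, "simples")
})

test_that("apposed nouns merge into one structure with a modifier", {
  ad <- annotate_description("X", "frutos nueces.", test_res)
  expect_equal(nrow(ad$structures), 1L)
  expect_equal(ad$structures$name, "frutos")
  expect_equal(ad$structures$modifier, "nueces")
})

test_that("same-name adjective runs merge into one character value", {
  ad <- annotate_description("X",
                             "flores verde amarillento pálido a verdosas.",
                             test_res)
  expect_equal(ad$structures$name, "flores")
  expect_equal(nrow(ad$characters), 1L)
  expect_equal(ad$characters$name, "colouration")
  expect_equal(ad$characters$value, "verde amarillento pálido a verdosas")
})

test_that("multi-name states emit one character per name with the note", {
  rows <- qchars[qchars$value == "elípticas", ]
  expect_equal(rows$name, c("arrangement", "shape"))
  expect_equal(rows$notes, rep("Carácter repetido", 2))
  expect_equal(rows$structure, rep("hojas", 2))
})

test_that("association follows gender/number agreement with recency", {
  expect_equal(qchars$structure[qchars$value == "glabras"], "hojas")
  expect_equal(qchars$structure[qchars$value == "acuminado"], "ápice")
  expect_equal(qchars$structure[qchars$value == "caudada"], "base")
  expect_equal(qchars$structure[qchars$value == "obtusa"], "base")
})

test_that("conjunct states become separate characters sharing the link", {
  caud <- qchars[qchars$value %in% c("caudado", "agudo"), ]
  expect_equal(caud$structure, c("ápice", "ápice"))
  expect_equal(caud$name, c("shape", "shape"))
  expect_equal(caud$notes, c(NA, "o"))
  # "u" is normalized to "o" in the notes
  expect_equal(qchars$notes[qchars$value == "obtusa"], "o")
})

test_that("the documented association failure mode is reproduced", {
  ad <- annotate_description("Hydrangea asterolasia", hydrangea_clause,
                             test_res)
  ch <- chars_with_structure(ad)
  # "aguda o cortamente acuminada en el ápice" lands on "base", not "lámina"
  expect_equal(ch$structure[ch$value == "aguda"], "base")
  expect_equal(ch$structure[ch$value == "acuminada"], "base")
  expect_equal(ch$constraint[ch$value == "acuminada"], "cortamente")
  # while "oblonga o elíptica" correctly stays on the main structure
  expect_equal(ch$structure[ch$value == "oblonga"], "lámina")
})

test_that("con/sin phrases produce relations with inner characters", {
  ad <- annotate_description("X", "semillas varias, con arilo anaranjado.",
                             test_res)
  expect_equal(ad$relations$name, "con")
  expect_false(ad$relations$negated)
  from <- ad$structures$name[ad$structures$id ==
                               ad$relations$from_structure_id]
  to <- ad$structures$name[ad$structures$id == ad$relations$to_structure_id]
  expect_equal(from, "semillas")
  expect_equal(to, "arilo")
  ch <- chars_with_structure(ad)
  expect_equal(ch$structure[ch$value == "anaranjado"], "arilo")
  # the quantifier lands on the structure as a constraint
  expect_equal(ad$structures$constraint[ad$structures$name == "semillas"],
               "varias")

  neg <- annotate_description("X", "hojas simples, sin tricomas.", test_res)
  expect_equal(neg$relations$name, "sin")
  expect_true(neg$relations$negated)
})

test_that("other prepositional phrases become spans, entities extracted", {
  spans <- quercus$constraint_spans
  expect_true("constraint_preposition" %in% spans$kind)
  expect_true(any(grepl("por el envés", spans$text)))
  expect_true(all(c("vena", "envés") %in% quercus$structures$name))
})

test_that("adverbs land in the constraint of their target", {
  ad <- annotate_description("X", "margen finamente aserrado.", test_res)
  expect_equal(ad$characters$value, "aserrado")
  expect_equal(ad$characters$constraint, "finamente")
  ad2 <- annotate_description("X", "hojas levemente revolutas.", test_res)
  expect_equal(ad2$characters$constraint, "levemente")
})

test_that("parenthetical asides become constraints on the preceding state", {
  ad <- annotate_description("X", "hojas alternas (rara vez opuestas).",
                             test_res)
  expect_equal(ad$characters$value, "alternas")
  expect_equal(ad$characters$constraint, "rara vez opuestas")
})

test_that("articles are consumed silently", {
  ad <- annotate_description("X", "el margen entero.", test_res)
  expect_equal(ad$structures$name, "margen")
  expect_true(is.na(ad$structures$constraint))
  expect_equal(ad$characters$value, "entero")
})

test_that("verb tails are delimited as verb_string spans", {
  ad <- annotate_description(
    "X", "flores blancas, que salen en grupos de 3.", test_res)
  spans <- ad$constraint_spans
  expect_equal(spans$kind, "verb_string")
  expect_match(spans$text, "^salen en grupos de 3")
  expect_equal(spans$attached_to,
               ad$structures$id[ad$structures$name == "flores"])
  none <- annotate_description("X", "hojas simples.", test_res)
  expect_equal(nrow(none$constraint_spans), 0L)
})

test_that("a verb before any structure defers to the clause main structure", {
  ad <- annotate_description("X", "salen en grupos, flores blancas.",
                             test_res)
  expect_equal(ad$constraint_spans$kind, "verb_string")
  expect_equal(ad$constraint_spans$attached_to,
               ad$structures$id[ad$structures$name == "flores"])
})

test_that("a clause with states but no noun gets a whole-plant structure", {
  ad <- annotate_description("X", "deciduas.", test_res)
  expect_equal(ad$structures$name, "planta")
  expect_equal(ad$structures$notes, "estructura implícita")
  expect_equal(chars_with_structure(ad)$structure, "planta")
})

test_that("pure measurement chunks attach to the current structure", {
  ad <- annotate_description("X", "hojas simples, 4-10 (-14) × 1-3.3 cm.",
                             test_res)
  ch <- chars_with_structure(ad)
  expect_equal(ch$structure[ch$name == "length"], "hojas")
  expect_equal(ch$atypical_to[ch$name == "length"], "14")
})

test_that("associate_structure agrees with the brute-force oracle", {
  set.seed(42)
  genders <- c("m", "f", "unknown")
  numbers <- c("singular", "plural", "unknown")
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    ctx <- tibble::tibble(
      id = paste0("o", seq_len(n)),
      gender = sample(genders, n, replace = TRUE),
      number = sample(numbers, n, replace = TRUE))
    g <- sample(genders, 1); nn <- sample(numbers, 1)
    expect_equal(associate_structure(g, nn, ctx),
                 oracle_associate(g, nn, ctx, ctx$id[1]))
  }
})

test_that("all tokens of the fixture corpus are accounted for", {
  fx <- generate_fixtures(30, seed = 5)
  pred <- ft_annotate(fx$records, test_res)
  skipwords <- c("el", "la", "los", "las", "un", "una",
                 "o", "u", "y", "e", "de", "con", "sin", "×")
  for (ad in pred) {
    fields <- c(ad$structures$name, ad$structures$modifier,
                ad$structures$constraint, ad$characters$value,
                ad$characters$from_unit, ad$characters$constraint,
                ad$relations$name, ad$constraint_spans$text,
                ad$characters$name)
    bag <- tolower(unlist(strsplit(stats::na.omit(fields), " ")))
    for (k in seq_len(nrow(ad$chunks))) {
      toks <- tokenize_chunk(ad$chunks$text[k])
      for (tok in toks$norm) {
        if (tok %in% skipwords) next
        if (grepl("^[0-9(]", tok) || grepl("^-", tok)) next  # range pieces
        if (tok %in% c("altura", "longitud", "grosor")) next # named dims
        expect_true(tok %in% bag,
                    label = paste0("token '", tok, "' of chunk '",
                                   ad$chunks$text[k], "' accounted for"))
      }
    }
  }
})
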