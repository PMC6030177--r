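test_that("tagging assigns the documented tag sequences", {
  tags <- function(text) tag_chunk(text, test_res)$tag
  expect_equal(tags("hojas simples"), c("E", "A"))
  expect_equal(tags("6-30 m de altura"), c("Z", "U", "S", "E"))
  expect_equal(tags("zzz"), "X")
  expect_equal(tags("5-18 × 1.5-9 cm"), c("Z", "G", "Z", "U"))
  expect_equal(tags("margen finamente aserrado"), c("E", "R", "A"))
  expect_equal(tags("el margen dentado"), c("D", "E", "A"))
})

test_that("tokenization flags parentheticals and keeps indices contiguous", {
  toks <- tag_chunk("4-10 (-14) × 1-3.3 cm.", test_res)
  expect_equal(toks$index, seq_len(nrow(toks)) - 1L)
  expect_equal(toks$norm[toks$in_parens], "-14")
  expect_equal(toks$tag[toks$norm == "-14"], "Z")
  # every Z token matches a numeric/range pattern
  expect_true(all(grepl("^-?[0-9][0-9.:-]*-?$",
                        toks$norm[toks$tag == "Z"])))
})

test_that("closed-class tokens never come out as E/A/V", {
  closed <- c("de", "en", "con", "sin", "o", "u", "el", "las",
              "finamente", "cm")
  for (tok in closed) {
    expect_false(tag_chunk(tok, test_res)$tag %in% c("E", "A", "V"),
                 label = tok)
  }
})

test_that("morphology follows suffix rules with the exception list", {
  m <- morphology(c("glabras", "acuminado", "base", "x1", "verde",
                    "simples"), test_res$gender_exceptions)
  expect_equal(m$gender, c("f", "m", "f", "unknown", "unknown", "unknown"))
  expect_equal(m$number, c("plural", "singular", "singular", "unknown",
                           "singular", "plural"))
})

test_that("bootstrap learns states across 'a' and records provenance", {
  chunk <- "redondeada a pandurada a cuneiformada"
  kb <- bootstrap_kb(chunk, test_res)
  expect_setequal(kb$token, c("pandurada", "cuneiformada"))
  expect_true(all(kb$tag == "A"))
  expect_true(all(kb$rule == "a_propagation"))
  res2 <- test_res; res2$kb <- kb
  expect_equal(tag_chunk(chunk, res2)$tag, c("A", "S", "A", "S", "A"))
})

test_that("bootstrap on an empty corpus leaves the KB unchanged", {
  expect_identical(bootstrap_kb(character(), test_res), empty_kb())
})

test_that("bootstrap chains across chunks and reaches the exhaustive closure", {
  corpus <- c("pandurada a cuneiformada",      # no anchor yet
              "redondeada a pandurada",        # anchors pandurada
              "escuarrosa o cuneiformada",     # coordination propagation
              "margen entero")                 # inert chunk
  kb <- bootstrap_kb(corpus, test_res)
  expect_setequal(kb$token, oracle_bootstrap_closure(corpus))
  expect_gte(max(kb$iteration), 2L)  # the chain needs a second pass
  # monotone and idempotent at the fixpoint
  res2 <- test_res; res2$kb <- kb
  kb2 <- bootstrap_kb(corpus, res2)
  expect_identical(kb2, kb)
})

test_that("bootstrap fixpoint is independent of chunk order", {
  corpus <- c("pandurada a cuneiformada", "redondeada a pandurada",
              "escuarrosa o cuneiformada")
  base <- sort(bootstrap_kb(corpus, test_res)$token)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(sort(bootstrap_kb(corpus[perm], test_res)$token), base)
  }
})

test_that("knowledge bases round-trip through TSV", {
  kb <- bootstrap_kb("redondeada a pandurada", test_res)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kb, path)
  expect_equal(as.data.frame(read_kb(path)), as.data.frame(kb))
})
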