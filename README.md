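# floratrait

Rule-based extraction of morphological characters from Spanish plant
descriptions.

Taxonomic literature describes plants in telegraphic Spanish — dense,
verb-poor strings of nouns, states and measurements such as *"hojas
simples, alternas, 4-10 (-14) × 1-3.3 cm., elípticas, ápice acuminado,
…"*. The trait data locked in that prose (which structure has which
character in which state) is what biodiversity databases actually need.
`floratrait` converts such descriptions into structured records:

* **structures** — the plant parts described (hojas, ápice, base, …),
* **characters** — named properties with a state or a numeric range
  (`architecture = "simples"`, `length` from 4 to 10 cm with an atypical
  extreme of 14), where the character *name* is resolved through a
  bundled Spanish→English glossary and a state→character-name index,
  since names are rarely written in the text,
* **relations** — `con`/`sin` links between structures ("semillas …
  con arilo" → a `con` relation from seeds to aril),

emitted as deterministic, byte-reproducible XML. The pipeline is
lexicon tagging with an unsupervised bootstrapping knowledge base →
heuristic dependency parsing → rule-based semantic annotation. Characters
are linked to structures by the field's gender–number agreement
heuristic: scan the clause's structures from most recent to oldest and
take the first that agrees with the state's gender and number, falling
back to the clause's main structure. It is intended for biodiversity
informaticians structuring floras and field guides, and for anyone who
needs a reproducible, inspectable baseline for trait extraction from
telegraphic Romance-language text.

## Worked example

```r
library(floratrait)

ad <- annotate_description(
  "Quercus salicifolia",
  paste("hojas simples, alternas, 4-10 (-14) x 1-3.3 cm., elípticas,",
        "ápice acuminado, caudado o agudo, base caudada u obtusa, glabras.")
)
ad
#> <annotated_description> Quercus salicifolia
#>   clauses: 1  chunks: 8  structures: 3  characters: 12  relations: 0  spans: 0

tidy(ad)[, c("structure", "character", "value", "from", "to",
             "atypical_to", "notes")]
#>    structure    character     value from   to atypical_to             notes
#> 1      hojas architecture   simples <NA> <NA>        <NA>              <NA>
#> 2      hojas  arrangement  alternas <NA> <NA>        <NA>              <NA>
#> 3      hojas       length      4-10    4   10          14              <NA>
#> 4      hojas        width     1-3.3    1  3.3        <NA>              <NA>
#> 5      hojas  arrangement elípticas <NA> <NA>        <NA> Carácter repetido
#> 6      hojas        shape elípticas <NA> <NA>        <NA> Carácter repetido
#> 7      ápice        shape acuminado <NA> <NA>        <NA>              <NA>
#> 8      ápice        shape   caudado <NA> <NA>        <NA>              <NA>
#> 9      ápice        shape     agudo <NA> <NA>        <NA>                 o
#> 10      base        shape   caudada <NA> <NA>        <NA>              <NA>
#> 11      base        shape    obtusa <NA> <NA>        <NA>                 o
#> 12     hojas   pubescence   glabras <NA> <NA>        <NA>              <NA>
```

Reading the output: the `x` was normalized to `×` and the dimension chunk
split into a length (4–10 cm, rarely up to 14) and a width character on
`hojas`; "elípticas" maps to two candidate character names, so both are
emitted with the note `Carácter repetido` for an expert to disambiguate;
the coordinated states "caudado o agudo" became two characters on `ápice`
(the conjunction recorded in the notes of the non-first conjunct); and
"glabras" — feminine plural — skipped `base` (f. sg.) and `ápice` (m. sg.)
to land on `hojas` (f. pl.) by gender–number agreement.

`write_trait_xml(ad, "quercus.xml")` serializes this model with nested
`<structure>`/`<character>` elements; `read_trait_xml()` inverts it
byte-stably. `ft_annotate()` maps the same pipeline over a whole
`taxon`/`description` table.

## Synthetic corpora and evaluation

`generate_fixtures(n, seed)` builds telegraphic clauses with gold
annotations known by construction, and `score_annotations(pred, gold)`
computes precision/recall/F-1 for the four evaluation aspects
(identification of structures, character structuring, association of
characters to structures, association of conjunctions):

```r
fx <- generate_fixtures(200, seed = 1)
score_annotations(ft_annotate(fx$records), fx$gold)
#> # A tibble: 4 × 4
#>   aspect       precision recall    f1
#>   <chr>            <dbl>  <dbl> <dbl>
#> 1 structures         100    100   100
#> 2 characters         100    100   100
#> 3 association        100    100   100
#> 4 conjunctions       100    100   100
```

## Command line

A thin CLI over the same functions lives at
`system.file("cli", "floratrait", package = "floratrait")`:

```sh
floratrait annotate --input records.tsv --out xml/ [--json] [--debug-trees]
floratrait fixtures --n 200 --seed 1 --out fixtures/
floratrait evaluate --pred xml/ --gold fixtures/gold/ --out scores.csv
```

Exit codes: 0 success, 1 validation/alignment error, 2 config/IO error.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "floratrait", load_package = "installed")'
```

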