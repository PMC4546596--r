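# cnemr

Structured **(time, event, description)** triples from free-text Chinese
clinical narratives.

Chinese electronic medical records — in particular the History of Present
Illness — are short, comma-dense, period-delimited narratives in which
temporal phrases, medical terms, negated mentions and free-text description
clauses are interleaved ("3天前咳嗽，色黄。" — *cough three days ago, colour
yellow*).  Off-the-shelf segmenters and parsers perform poorly on this
register, so `cnemr` takes a dictionary-driven, weakly supervised approach:

1. **Categorized lexica** — six term dictionaries (disease, symptom, drug,
   body part, procedure, clinical test) with per-term provenance
   (`lexicon_set`, `load_lexica`, `save_lexica`).
2. **Pattern bootstrapping** — the disease and drug lexica are enriched
   iteratively from raw text.  Around every known-term occurrence, literal
   character-context patterns (up to 3 characters each side) are harvested
   and scored by *Pattern Selectivity* `PS(P)` = number of unique known
   terms P extracts, and *Pattern Precision* `PP(P)` = PS divided by the
   number of unique terms P extracts.  Patterns with `PS > PST` and
   `PP > PPT` survive; a new term is accepted when its *Term Frequency*
   (number of accepting patterns) exceeds `TFT`.  Iteration stops when
   nothing new is found (`bootstrap`, `grid_search_thresholds`).
3. **Compound-term assembly** — body-part enumerations `B1、B2 D` and
   `B D1、D2` are expanded into compounds (`B1D`, `BD2`, ...) gated by the
   corpus adjacency probability `P(D follows | B)`, and directional or
   extensional prefixes (左, 右, 双, ...) are absorbed by a three-character
   look-back (`build_adjacency_table`, `assemble_enumeration`,
   `expand_directional_prefix`).
4. **Longest-match tagging** — terms are recognized by a recursive
   longest-match scan with boundary-character blocking; negated ("无恶寒")
   and future ("拟行...") mentions of symptoms, procedures and clinical
   tests are demoted to non-events (`tag_terms`, `filter_events`).
5. **Temporal extraction and scoping** — a nine-part grammar (approximation
   words, numbers, units, temporal units, prepositions, day words, periods
   and points of day) plus six idioms recognizes time expressions; three
   scoping rules assign every event a time, carrying the last time forward
   across statements (`extract_temporal_terms`, `assign_time_scopes`).
6. **Description linking** — the uncovered clause segments become candidate
   descriptions; each (event, candidate) pair is featurized with local
   context characters, positional counts and the Normalized Google
   Distance

   ```
   NGD(x, y) = (max{log f(x), log f(y)} − log f(x, y))
             / (log M − min{log f(x), log f(y)})
   ```

   computed from a pluggable frequency provider (corpus document
   frequencies by default, cached search-engine counts optionally), and
   classified true/false by a linear SVM with balanced class weights
   (`ngd`, `featurize`, `train_linker`, `link_pairs`,
   `baseline_adjacent`).

A seeded synthetic-corpus generator (`synth_config`, `make_toy_lexica`,
`generate_corpus`, `build_linker_training`) emits EMR-like documents with
complete gold structure — spans, times, links, triples — so every stage and
the end-to-end pipeline (`extract_document`, `evaluate`) are testable
without access to hospital data.

## Worked example

```r
library(cnemr)

lex <- add_term(lexicon_set(), c("咳嗽", "发热"), "symptom", "core")
lex <- add_term(lex, "头孢呋辛", "drug", "core")

doc <- "3天前咳嗽，色黄。给予头孢呋辛。今晨发热。"
triples <- extract_document(doc, extraction_resources(lex))
triples[c("time_surface", "event_surface", "event_category", "desc_surface")]
#>   time_surface event_surface event_category desc_surface
#> 1        3天前          咳嗽        symptom         色黄
#> 2        3天前      头孢呋辛           drug         <NA>
#> 3         今晨          发热        symptom         <NA>
```

The cough is anchored to "3天前" (*3 days ago*) and linked to its
description "色黄" (*colour yellow*); the drug administration in the second
statement inherits the carried-forward time; the fever is anchored to the
idiom "今晨" (*this morning*).  Offsets (0-based, half-open, in characters)
are carried alongside every component.

Pattern harvesting around a tagged drug reproduces the nine-pattern context
grid:

```r
generate_candidate_patterns(",给予头孢呋抗感染", 3, 6, "drug")
#> # A tibble: 9 × 3
#>   left  category right
#>   <chr> <chr>    <chr>
#> 1 予    drug     抗
#> 2 给予  drug     抗
#> 3 ,给予 drug     抗
#> 4 予    drug     抗感
#> ...
```

A command-line front end over the same functions lives in
`inst/cli/cnemr.R` (subcommands `synth`, `enrich`, `tag`, `extract`,
`eval`).

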