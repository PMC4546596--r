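make_assembly_lex <- function() {
  lex <- add_term(lexicon_set(), c("口腔", "黏膜", "腹"), "body_part", "core")
  add_term(lex, c("出血", "痛", "呕吐"), "symptom", "core")
}

test_that("adjacency probabilities are conditional on B occurrences", {
  lex <- make_assembly_lex()
  tab <- build_adjacency_table(c("腹痛。腹痛。"), lex)
  row <- tab$pairs[tab$pairs$b == "腹" & tab$pairs$d == "痛", ]
  expect_equal(row$adjacent_count, 2L)
  expect_equal(row$prob, 1.0)
  expect_equal(adjacency_prob(tab, "腹", "呕吐"), 0)
  expect_true(all(tab$pairs$prob >= 0 & tab$pairs$prob <= 1))
})

test_that("B1,B2,D enumerations distribute the trailing term", {
  lex <- make_assembly_lex()
  # corpus where both 口腔出血 and 黏膜出血 are seen adjacent
  corpus <- c(paste(rep("口腔出血。黏膜出血。", 3), collapse = ""))
  tab <- build_adjacency_table(corpus, lex, threshold = 0.1)
  st <- "口腔、黏膜出血"
  spans <- tag_terms(st, lex)
  comp <- assemble_enumeration(st, spans, tab, lex)
  expect_setequal(comp$surface, c("口腔出血", "黏膜出血"))
  expect_equal(unique(comp$category), "symptom")
  expect_equal(unique(comp$provenance), "body_part_assembly")
  # the adjacent compound is contiguous; the distributed one is not
  expect_true(comp$contiguous[comp$surface == "黏膜出血"])
  expect_false(comp$contiguous[comp$surface == "口腔出血"])
})

test_that("B,D1,D2 enumerations never invent unseen pairs", {
  lex <- make_assembly_lex()
  tab <- build_adjacency_table(c("腹痛。腹痛。呕吐。"), lex, threshold = 0.01)
  st <- "腹痛、呕吐"
  comp <- assemble_enumeration(st, tag_terms(st, lex), tab, lex)
  expect_equal(comp$surface, "腹痛")   # never 腹呕吐: prob 0
  expect_equal(nrow(assemble_enumeration("腹痛", tag_terms("腹痛", lex)[1, ],
                                         tab, lex)), 0L)
})

test_that("raising the threshold never enlarges the assembled set", {
  lex <- make_assembly_lex()
  corpus <- c("口腔出血。黏膜出血。腹痛。")
  st <- "口腔、黏膜出血"
  spans <- tag_terms(st, lex)
  sizes <- vapply(c(0.001, 0.5, 2), function(th) {
    tab <- build_adjacency_table(corpus, lex, threshold = th)
    nrow(assemble_enumeration(st, spans, tab, lex))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("compounds already in the lexicon are not re-emitted", {
  lex <- make_assembly_lex()
  lex <- add_term(lex, "腹痛", "symptom", "core")
  tab <- build_adjacency_table(c("腹痛。"), lex)
  st <- "腹痛、呕吐"
  spans <- tag_terms(st, lex)   # tags 腹痛 as one span already
  comp <- assemble_enumeration(st, spans, tab, lex)
  expect_false("腹痛" %in% comp$surface)
})

test_that("directional prefixes expand spans with the original category", {
  lex <- add_term(lexicon_set(), c("输尿管结石", "肾结石"), "disease", "core")
  doc <- "左侧输尿管结石"
  span <- tag_terms(doc, lex)
  got <- expand_directional_prefix(doc, span)
  expect_equal(got$surface, "左侧输尿管结石")
  expect_equal(got$start, 0L)
  expect_equal(got$category, "disease")

  doc2 <- "双肾结石"
  got2 <- expand_directional_prefix(doc2, tag_terms(doc2, lex))
  expect_equal(got2$surface, "双肾结石")
})

test_that("prefix expansion is an identity without directional context", {
  lex <- add_term(lexicon_set(), "肾结石", "disease", "core")
  doc <- "既往肾结石"
  span <- tag_terms(doc, lex)
  expect_identical(expand_directional_prefix(doc, span), span)
  # idempotence: expanding an expanded span changes nothing
  doc3 <- "有双肾结石"
  sp <- tag_terms(doc3, lex)
  once <- expand_directional_prefix(doc3, sp)
  expect_identical(expand_directional_prefix(doc3, once), once)
})
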