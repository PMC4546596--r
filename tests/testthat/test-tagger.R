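test_that("longest matches claim characters before shorter ones", {
  lex <- add_term(lexicon_set(), c("咳嗽", "咳痰", "咳"), "symptom", "core")
  spans <- tag_terms("咳嗽咳痰", lex)
  expect_equal(spans$surface, c("咳嗽", "咳痰"))
  expect_equal(spans$start, c(0L, 2L))
  expect_equal(spans$end, c(2L, 4L))
  expect_equal(nrow(tag_terms("", lex)), 0L)
})

test_that("multi-category terms emit one span per category", {
  lex <- add_term(lexicon_set(), "穿刺", "procedure", "core")
  lex <- add_term(lex, "穿刺", "clinical_test", "core")
  spans <- tag_terms("行穿刺明确", lex)
  expect_equal(nrow(spans), 2L)
  expect_setequal(spans$category, c("procedure", "clinical_test"))
  expect_equal(unique(spans$start), 1L)
})

test_that("tagging agrees with the brute-force oracle on random strings", {
  fix <- random_tag_fixture(205)
  for (i in 1:150) {
    s <- fix$rand_string()
    got <- tag_terms(s, fix$lex)
    want <- oracle_tag(s, fix$lex_table)
    expect_equal(as.data.frame(got[c("surface", "category", "start", "end")]),
                 want, ignore_attr = TRUE,
                 info = paste("string:", s))
  }
})

test_that("spans never overlap and tagging is deterministic", {
  fix <- random_tag_fixture(99)
  for (i in 1:40) {
    s <- fix$rand_string()
    spans <- tag_terms(s, fix$lex)
    if (nrow(spans) > 1) {
      uniq <- spans[!duplicated(spans[c("start", "end")]), ]
      uniq <- uniq[order(uniq$start), ]
      expect_true(all(uniq$end[-nrow(uniq)] <= uniq$start[-1]))
    }
    expect_identical(spans, tag_terms(s, fix$lex))
  }
})

test_that("negated and future mentions are demoted to non-events", {
  lex <- add_term(lexicon_set(), "恶寒", "symptom", "core")
  lex <- add_term(lex, "前列腺电切术", "procedure", "core")
  lex <- add_term(lex, "咳嗽", "symptom", "core")

  spans <- filter_events("无恶寒", tag_terms("无恶寒", lex))
  expect_false(spans$is_event)

  spans <- filter_events("拟行前列腺电切术", tag_terms("拟行前列腺电切术", lex))
  expect_false(spans$is_event)

  spans <- filter_events("咳嗽3天", tag_terms("咳嗽3天", lex))
  expect_true(spans$is_event)
})

test_that("negation scope is clause-local and precedes the span", {
  lex <- add_term(lexicon_set(), c("咳嗽", "恶寒"), "symptom", "core")
  doc <- "咳嗽，无恶寒"
  spans <- filter_events(doc, tag_terms(doc, lex))
  expect_equal(spans$is_event[spans$surface == "咳嗽"], TRUE)
  expect_equal(spans$is_event[spans$surface == "恶寒"], FALSE)
  # marker after the span does not negate it
  doc2 <- "恶寒无"
  spans2 <- filter_events(doc2, tag_terms(doc2, lex))
  expect_true(spans2$is_event[1])
})

test_that("diseases and drugs are always events; body parts never are", {
  lex <- add_term(lexicon_set(), "糖尿病", "disease", "core")
  lex <- add_term(lex, "阿司匹林", "drug", "core")
  lex <- add_term(lex, "肺", "body_part", "core")
  doc <- "无糖尿病，无阿司匹林，肺"
  spans <- filter_events(doc, tag_terms(doc, lex))
  expect_true(spans$is_event[spans$category == "disease"])
  expect_true(spans$is_event[spans$category == "drug"])
  expect_false(spans$is_event[spans$category == "body_part"])
})
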