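test_that("uncovered clause segments become candidate descriptions", {
  got <- extract_candidates("色黄，质粘")
  expect_equal(got$surface, c("色黄", "质粘"))
  expect_equal(got$contains_digit, c(FALSE, FALSE))

  lex <- add_term(lexicon_set(), "咳痰", "symptom", "core")
  st <- "咳痰，色黄"
  spans <- tag_terms(st, lex)
  got2 <- extract_candidates(st, spans, extract_temporal_terms(st))
  expect_equal(got2$surface, "色黄")

  # fully covered statement yields nothing
  st3 <- "咳痰"
  expect_equal(nrow(extract_candidates(st3, tag_terms(st3, lex))), 0L)

  got4 <- extract_candidates("FEV1/FVC小于70%")
  expect_equal(nrow(got4), 1L)
  expect_true(got4$contains_digit)
})

test_that("candidates overlapping non-events or containing stop words drop", {
  lex <- add_term(lexicon_set(), "恶寒", "symptom", "core")
  st <- "无恶寒发冷，于我院住院治疗，色黄"
  spans <- filter_events(st, tag_terms(st, lex))
  cands <- extract_candidates(st, spans)
  kept <- filter_candidates(cands, spans)
  expect_true("色黄" %in% kept$surface)
  expect_false(any(grepl("住院", kept$surface)))
  # the run 恶寒发冷 overlaps the negated span: dropped
  expect_false(any(kept$start < spans$end[1] & spans$start[1] < kept$end))
  expect_true(nrow(kept) <= nrow(cands))
})

test_that("ngd matches the analytic value and handles degenerate cases", {
  fp <- cached_frequency_provider(
    c(x = 4, y = 2, z = 0), data.frame(x = "x", y = "y", count = 1), 16)
  expect_equal(ngd("x", "y", fp), 2 / 3, tolerance = 1e-12)
  expect_equal(ngd("x", "z", fp), 10)   # zero frequency -> cap
  expect_equal(ngd("x", "q", fp), 10)   # unknown term -> cap
  expect_error(ngd("x", "y", cached_frequency_provider(
    c(x = 1, y = 1), data.frame(x = "x", y = "y", count = 1), 1)), "2")
})

test_that("ngd is symmetric, zero on self, monotone in co-occurrence", {
  set.seed(1234)
  for (i in 1:200) {
    M <- sample(10:10000, 1)
    fx <- sample(1:M, 1); fy <- sample(1:M, 1)
    fxy <- sample(0:min(fx, fy), 1)
    fp <- cached_frequency_provider(
      c(x = fx, y = fy), data.frame(x = "x", y = "y", count = fxy), M)
    expect_identical(ngd("x", "y", fp), ngd("y", "x", fp))
    expect_equal(ngd("x", "x", fp), 0)
  }
  # monotone: more co-occurrence, smaller distance
  vals <- vapply(1:8, function(fxy) {
    fp <- cached_frequency_provider(
      c(x = 20, y = 8), data.frame(x = "x", y = "y", count = fxy), 1000)
    ngd("x", "y", fp)
  }, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("corpus frequency provider counts document co-occurrence", {
  fp <- corpus_frequency_provider(c("甲乙丙", "甲丁", "乙丁", "戊"))
  expect_equal(fp$M, 4)
  expect_equal(fp$f("甲"), 2)
  expect_equal(fp$f2("甲", "乙"), 1)
  expect_equal(fp$f2("甲", "戊"), 0)
  expect_lte(fp$f2("甲", "乙"), min(fp$f("甲"), fp$f("乙")))
})

test_that("pair features count terms, descriptions and commas between", {
  lex <- add_term(lexicon_set(), c("咳痰", "发热"), "symptom", "core")
  st <- "咳痰，色黄，质粘"
  spans <- filter_events(st, tag_terms(st, lex))
  cands <- extract_candidates(st, spans)
  fp <- corpus_frequency_provider(c(st, "咳痰，质粘"))
  f <- featurize(st, spans[1, ], cands[cands$surface == "质粘", ],
                 spans, cands, fp)
  expect_equal(f$n_descs_between, 1L)      # 色黄 sits between
  expect_equal(f$n_commas_between, 2L)
  expect_equal(f$n_terms_between, 0L)
  expect_equal(f$term_type, "symptom")
  # event at statement start: left context is all sentinel
  expect_equal(c(f$etl1, f$etl2, f$etl3), c("#", "#", "#"))
  f2 <- featurize(st, spans[1, ], cands[1, ], spans, cands, fp)
  expect_equal(f2$n_descs_between, 0L)
  expect_equal(f2$n_commas_between, 1L)
  expect_error(featurize(st, spans[1, ],
                         tibble::tibble(surface = "x", start = 90, end = 91,
                                        contains_digit = FALSE),
                         spans, cands, fp), "within")
})

test_that("a separable toy problem is fit perfectly and deterministically", {
  set.seed(5)
  n <- 60
  feats <- tibble::tibble(
    etl1 = "#", etl2 = "#", etl3 = "#", etr1 = "#", etr2 = "#", etr3 = "#",
    dtl1 = "#", dtl2 = "#", dtl3 = "#", dtr1 = "#", dtr2 = "#", dtr3 = "#",
    has_digit = FALSE,
    ngd = c(runif(n / 2, 0, 1), runif(n / 2, 5, 10)),
    n_terms_between = 0L, n_descs_between = 0L, n_commas_between = 1L,
    term_type = "symptom")
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  m1 <- train_linker(feats, labels, seed = 11)
  expect_equal(pair_f1(predict(m1, feats), labels), 1.0)
  m2 <- train_linker(feats, labels, seed = 11)
  expect_identical(predict(m1, feats), predict(m2, feats))
  expect_error(train_linker(feats, rep(TRUE, n)), "class")
})

test_that("link_pairs accepts many-to-many links and baseline takes nearest", {
  events <- tibble::tibble(surface = c("E1", "E2"), category = "symptom",
                           start = c(0L, 3L), end = c(2L, 5L),
                           is_event = TRUE)
  cands <- tibble::tibble(surface = c("C1", "C2"), start = c(6L, 9L),
                          end = c(8L, 11L), contains_digit = FALSE)
  base <- baseline_adjacent(events, cands)
  expect_equal(base$event_id, c(1L, 2L))
  expect_equal(base$cand_id, c(1L, 1L))   # both take the nearest following
  expect_equal(nrow(baseline_adjacent(events, cands[0, ])), 0L)
  # an event after every candidate gets no link
  late <- tibble::tibble(surface = "E3", category = "symptom",
                         start = 20L, end = 22L, is_event = TRUE)
  expect_equal(nrow(baseline_adjacent(late, cands)), 0L)
})

test_that("the trained linker recovers gold links on synthetic statements", {
  w <- synth_world()
  fp <- corpus_frequency_provider(w$texts)
  td <- build_linker_training(w$gold, fp)
  expect_gt(sum(td$labels), 5)
  m <- train_linker(td$features, td$labels, seed = 3)
  pred <- predict(m, td$features)
  expect_gt(pair_f1(pred, td$labels), pair_f1(td$baseline, td$labels))
  # every accepted pair has an event side by construction of the features
  acc <- link_pairs(m, td$features)
  expect_true(all(acc$event_id >= 1))
})
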