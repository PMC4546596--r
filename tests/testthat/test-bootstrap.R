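test_that("full-context spans yield the 3x3 grid of nine patterns", {
  doc <- "甲乙丙丁戊己庚辛壬"
  p <- generate_candidate_patterns(doc, 3, 6, "drug")
  expect_equal(nrow(p), 9L)
  expect_setequal(paste0(p$left, "|", p$right),
                  as.vector(outer(c("丙", "乙丙", "甲乙丙"),
                                  c("庚", "庚辛", "庚辛壬"), paste, sep = "|")))
  expect_error(generate_candidate_patterns(doc, 5, 20, "drug"), "bounds")
})

test_that("boundary truncation deduplicates patterns", {
  # span at position 0 with a single character of right context
  p <- generate_candidate_patterns("药X", 0, 1, "drug")
  expect_equal(nrow(p), 1L)
  expect_equal(p$left, "")
  expect_equal(p$right, "X")
})

test_that("apply_pattern finds shortest fillers and bars punctuation", {
  expect_equal(apply_pattern("予", "抗", "给予阿莫西林抗感染"), "阿莫西林")
  expect_equal(apply_pattern("缺", "失", "给予阿莫西林抗感染"), character(0))
  # a comma inside the would-be filler blocks extraction
  expect_equal(apply_pattern("予", "抗", "予甲，乙抗"), character(0))
})

test_that("apply_pattern agrees with the brute-force scan on small corpora", {
  fix <- random_tag_fixture(31)
  set.seed(32)
  corpus <- replicate(12, fix$rand_string())
  for (i in 1:25) {
    left <- paste(sample(fix$alphabet, sample(1:2, 1)), collapse = "")
    right <- paste(sample(fix$alphabet, sample(1:2, 1)), collapse = "")
    expect_setequal(apply_pattern(left, right, corpus, 5),
                    oracle_apply_pattern(left, right, corpus, 5))
  }
})

test_that("pattern scoring counts unique known fillers", {
  lex <- add_term(lexicon_set(), c("甲甲", "乙乙"), "drug", "core")
  corpus <- c("前甲甲后", "前乙乙后", "前丙丙后")
  pats <- tibble::tibble(left = "前", category = "drug", right = "后")
  scored <- score_patterns(pats, corpus, lex)
  expect_equal(scored$ps, 2L)
  expect_equal(scored$pp, 2 / 3)
  # a pattern that extracts nothing has undefined precision
  none <- score_patterns(tibble::tibble(left = "缺", category = "drug",
                                        right = "失"), corpus, lex)
  expect_equal(none$ps, 0L)
  expect_true(is.na(none$pp))
  # only-known fillers give precision 1
  all_known <- score_patterns(pats, corpus[1:2], lex)
  expect_equal(all_known$pp, 1)
})

test_that("pattern selection applies strict thresholds", {
  cfg <- bootstrap_config(pst = 7, ppt = 0.7)
  pats <- tibble::tibble(left = c("a", "b", "c"), category = "drug",
                         right = c("x", "y", "z"),
                         ps = c(7L, 8L, 9L), pp = c(0.7, 0.75, NA))
  kept <- select_patterns(pats, cfg)
  expect_equal(kept$left, "b")   # 7/0.7 fails strict >, NA pp dropped
  expect_equal(nrow(select_patterns(pats[0, ], cfg)), 0L)
})

test_that("term selection requires extraction by more than tft patterns", {
  cfg <- bootstrap_config(tft = 1)
  cand <- tibble::tibble(surface = c("a", "b", "c"), tf = c(1L, 2L, 0L),
                         category = "drug")
  expect_equal(select_terms(cand, cfg)$surface, "b")
})

test_that("bootstrap accretes unknown terms seen in known-term contexts", {
  core <- c("甲甲素", "乙乙素", "丙丙素", "丁丁素", "戊戊素")
  planted <- c("庚庚素", "辛辛素")
  lex <- add_term(lexicon_set(), core, "drug", "core")
  corpus <- c(paste0("予", core, "口服。"),
              paste0("予", planted, "口服。"),
              paste0("予", planted, "口服治之。"))
  cfg <- bootstrap_config(pst = 3, ppt = 0.5, tft = 1)
  res <- bootstrap(corpus, lex, "drug", cfg)
  added <- lexicon_provenance(res$lexicon)
  added <- added$term[added$origin == "pattern_iteration"]
  expect_setequal(added, planted)
  # lexicon growth is monotone and terminates with a zero-growth iteration
  expect_true(all(diff(res$history$iteration) == 1))
  expect_equal(res$history$n_terms_added[nrow(res$history)], 0L)
})

test_that("bootstrap is deterministic on a generated corpus", {
  w <- synth_world()
  cfg <- bootstrap_config(pst = 3, ppt = 0.5, tft = 1)
  res1 <- bootstrap(w$texts, w$lex$core, "drug", cfg)
  res2 <- bootstrap(w$texts, w$lex$core, "drug", cfg)
  expect_identical(lexicon_provenance(res1$lexicon),
                   lexicon_provenance(res2$lexicon))
  expect_identical(res1$history, res2$history)
})

test_that("bootstrap leaves the lexicon unchanged without category mentions", {
  lex <- add_term(lexicon_set(), "甲甲", "drug", "core")
  res <- bootstrap(c("丙丙丁丁", "戊戊己己"), lex, "drug")
  expect_equal(lexicon_size(res$lexicon), lexicon_size(lex))
  expect_equal(sum(res$history$n_terms_added), 0L)
})

test_that("planted-term recall never rises when thresholds tighten", {
  w <- synth_world()
  recall_at <- function(pst, ppt) {
    res <- bootstrap(w$texts, w$lex$core, "drug",
                     bootstrap_config(pst = pst, ppt = ppt, tft = 1,
                                      max_iterations = 3))
    added <- lexicon_provenance(res$lexicon)
    added <- added$term[added$origin == "pattern_iteration"]
    mean(w$lex$planted$drug %in% added)
  }
  r_loose <- recall_at(2, 0.4)
  r_mid <- recall_at(5, 0.4)
  r_tight <- recall_at(12, 0.4)
  expect_true(r_loose >= r_mid && r_mid >= r_tight)
  expect_gte(recall_at(2, 0.4), recall_at(2, 0.95))
})

test_that("grid search returns the winning pair with the tie rule", {
  w <- synth_world()
  docs <- w$texts[1:12]
  gold <- do.call(rbind, lapply(1:12, function(d) {
    sp <- w$gold[[d]]$spans[w$gold[[d]]$spans$category == "drug",
                            c("start", "end", "category")]
    if (!nrow(sp)) return(NULL)
    cbind(doc_id = d, sp)
  }))
  gs <- grid_search_thresholds(docs, w$lex$core, "drug", gold,
                               pst_grid = c(2, 4), ppt_grid = c(0.4, 0.6),
                               cfg = bootstrap_config(max_iterations = 2))
  expect_equal(nrow(gs$table), 4L)
  top <- max(gs$table$f1)
  tied <- gs$table[gs$table$f1 == top, ]
  expect_equal(gs$best_ppt, max(tied$ppt))
  expect_equal(gs$best_pst, max(tied$pst[tied$ppt == gs$best_ppt]))
  expect_error(grid_search_thresholds(docs, w$lex$core, "drug", gold[0, ]),
               "gold")
})
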