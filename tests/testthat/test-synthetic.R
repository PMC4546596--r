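test_that("toy lexica are deterministic, disjoint and plant unknown terms", {
  cfg <- synth_config(seed = 21, n_docs = 5)
  a <- make_toy_lexica(cfg)
  b <- make_toy_lexica(cfg)
  expect_identical(lexicon_provenance(a$core), lexicon_provenance(b$core))
  expect_identical(a$planted, b$planted)
  # planted terms are withheld from the core lexica
  for (cat_ in names(a$planted))
    expect_false(any(a$planted[[cat_]] %in% lexicon_terms(a$core, cat_)))
  # category vocabularies are pairwise disjoint
  terms_by_cat <- lapply(lexicon_categories_all(),
                         function(c_) lexicon_terms(a$full, c_))
  for (i in 1:5) for (j in (i + 1):6)
    expect_length(intersect(terms_by_cat[[i]], terms_by_cat[[j]]), 0)
})

test_that("generation is reproducible and honours template probabilities", {
  cfg <- synth_config(seed = 33, n_docs = 20)
  lex <- make_toy_lexica(cfg)
  g1 <- generate_corpus(cfg, lex)
  g2 <- generate_corpus(cfg, lex)
  expect_identical(vapply(g1, `[[`, "", "text"),
                   vapply(g2, `[[`, "", "text"))

  # p_description = 0 leaves every triple without a description
  cfg0 <- synth_config(seed = 33, n_docs = 20, p_description = 0)
  g0 <- generate_corpus(cfg0, make_toy_lexica(cfg0))
  descs <- unlist(lapply(g0, function(d) d$triples$desc_surface))
  expect_true(all(is.na(descs)))

  # multi-time statements appear and carry two or more temporal terms
  cfgm <- synth_config(seed = 33, n_docs = 40, p_multi_time = 0.6)
  gm <- generate_corpus(cfgm, make_toy_lexica(cfgm))
  multi <- unlist(lapply(gm, function(d)
    table(d$times$statement_idx)))
  expect_true(any(multi >= 2))
})

test_that("tagging generated text with full lexica reproduces gold spans", {
  w <- synth_world()
  for (gd in w$gold[1:30]) {
    spans <- tag_terms(gd$text, w$lex$full)
    g <- gd$spans[order(gd$spans$start), ]
    p <- spans[order(spans$start), ]
    expect_equal(p$surface, g$surface, info = gd$text)
    expect_equal(p$start, g$start, info = gd$text)
    expect_equal(p$end, g$end, info = gd$text)
    expect_equal(p$category, g$category, info = gd$text)
  }
})

test_that("gold temporal terms are exactly re-extractable", {
  w <- synth_world()
  for (gd in w$gold[1:30]) {
    sts <- split_statements(gd$text)
    pt <- do.call(rbind, lapply(seq_len(nrow(sts)), function(si) {
      tm <- extract_temporal_terms(sts$text[si])
      if (!nrow(tm)) return(NULL)
      tm$start <- tm$start + sts$start[si]
      tm$end <- tm$end + sts$start[si]
      tm
    }))
    n_pred <- if (is.null(pt)) 0L else nrow(pt)
    expect_equal(n_pred, nrow(gd$times), info = gd$text)
    if (n_pred) {
      expect_equal(pt$start, gd$times$start, info = gd$text)
      expect_equal(pt$surface, gd$times$surface, info = gd$text)
    }
  }
})

test_that("gold triples are consistent with the scoping rules", {
  w <- synth_world()
  for (gd in w$gold[1:25]) {
    sts <- split_statements(gd$text)
    input <- lapply(seq_len(nrow(sts)), function(si) {
      st <- sts[si, ]
      list(times = gd$times[gd$times$statement_idx == si,
                            c("surface", "start", "end")],
           events = gd$spans[gd$spans$is_event &
                               gd$spans$start >= st$start &
                               gd$spans$end <= st$end, ])
    })
    scoped <- assign_time_scopes(input)
    tr <- gd$triples[order(gd$triples$event_start), ]
    scoped <- scoped[order(scoped$start), ]
    expect_equal(nrow(scoped), nrow(tr))
    same <- mapply(function(a, b) (is.na(a) && is.na(b)) ||
                     (!is.na(a) && !is.na(b) && a == b),
                   scoped$time_surface, tr$time_surface)
    expect_true(all(same), info = gd$text)
  }
})

test_that("every planted drug appears in at least two distinct contexts", {
  w <- synth_world()
  corpus <- w$texts
  for (term in w$lex$planted$drug) {
    ctxs <- unique(unlist(lapply(corpus, function(doc) {
      loc <- stringi::stri_locate_all_fixed(doc, term)[[1]]
      if (is.na(loc[1, 1])) return(NULL)
      apply(loc, 1, function(m)
        paste0(stringi::stri_sub(doc, max(1, m[1] - 1), m[1] - 1), "|",
               stringi::stri_sub(doc, m[2] + 1, m[2] + 1)))
    })))
    expect_gte(length(ctxs), 2)
  }
})
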