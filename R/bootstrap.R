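#' Configuration for iterative lexicon enrichment
#'
#' The bootstrap keeps a candidate context pattern when its Pattern
#' Selectivity exceeds `pst` and its Pattern Precision exceeds `ppt` (both
#' strictly), and accepts a candidate term when its Term Frequency — the
#' number of accepted patterns that extract it — exceeds `tft` (strictly).
#' With `tft = 1` a term must be extracted by more than one pattern to be
#' trusted.
#'
#' The defaults `pst = 7, ppt = 0.7` are the grid-searched optimum for the
#' disease lexicon; `default_bootstrap_config("drug")` gives the drug optimum
#' `pst = 6, ppt = 0.85`.
#'
#' @param pst Pattern Selectivity Threshold (integer >= 1).
#' @param ppt Pattern Precision Threshold in (0, 1].
#' @param tft Term Frequency Threshold (integer >= 0).
#' @param max_term_len maximum slot-filler length in characters.
#' @param max_iterations iteration cap; the published runs converge in
#'   no more than 10 iterations.
#' @return a list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(pst = 7L, ppt = 0.7, tft = 1L,
                             max_term_len = 10L, max_iterations = 10L) {
  stopifnot(pst >= 1, ppt > 0, ppt <= 1, tft >= 0, max_term_len >= 1,
            max_iterations >= 1)
  structure(list(pst = pst, ppt = ppt, tft = tft,
                 max_term_len = max_term_len,
                 max_iterations = max_iterations),
            class = "bootstrap_config")
}

#' @rdname bootstrap_config
#' @param category `"disease"` or `"drug"`.
#' @export
default_bootstrap_config <- function(category = c("disease", "drug")) {
  category <- match.arg(category)
  if (category == "disease") bootstrap_config(pst = 7L, ppt = 0.7)
  else bootstrap_config(pst = 6L, ppt = 0.85)
}

#' Generate candidate context patterns around a tagged span
#'
#' Takes up to 3 characters (punctuation included) on each side of the span
#' and emits one pattern per (left length, right length) combination with
#' both lengths in 1..3 — nine patterns when full context is available.
#' Windows crossing the document boundary are truncated to the available
#' context, and the truncated grid is deduplicated, so a span at the very
#' start of a document with one character of right context yields a single
#' pattern.
#'
#' @param doc the document text.
#' @param start,end 0-based half-open offsets of the tagged span.
#' @param category the span's category (becomes the pattern slot).
#' @return tibble with columns `left`, `category`, `right`.
#' @examples
#' generate_candidate_patterns(",给予头孢呋抗感染", 3, 6, "drug")
#' @export
generate_candidate_patterns <- function(doc, start, end, category) {
  n <- n_chars(doc)
  if (start < 0 || end > n || start >= end)
    stop("span offsets out of bounds", call. = FALSE)
  .check_category(category)
  left_ctx <- str_slice(doc, max(0L, start - 3L), start)
  right_ctx <- str_slice(doc, end, min(n, end + 3L))
  nl <- n_chars(left_ctx); nr <- n_chars(right_ctx)
  grid <- expand.grid(l = 1:3, r = 1:3)
  grid$l <- pmin(grid$l, nl)
  grid$r <- pmin(grid$r, nr)
  grid <- unique(grid)
  lefts <- stringi::stri_sub(left_ctx, nl - grid$l + 1L, nl)
  lefts[grid$l == 0L] <- ""
  rights <- stringi::stri_sub(right_ctx, 1L, grid$r)
  rights[grid$r == 0L] <- ""
  out <- tibble::tibble(left = lefts, category = category, right = rights)
  unique(out)
}

#' Extract slot fillers of a pattern from a corpus
#'
#' A filler is the shortest substring `s` at each occurrence of `left` such
#' that `left + s + right` occurs in a document, `1 <= nchar(s) <=
#' max_term_len`, and `s` contains no statement/clause punctuation.
#'
#' @param left,right literal context strings of the pattern (either may be
#'   empty for boundary-truncated patterns).
#' @param corpus character vector of documents.
#' @param max_term_len maximum filler length in characters.
#' @return character vector of unique fillers.
#' @export
apply_pattern <- function(left, right, corpus, max_term_len = 10L) {
  nr <- n_chars(right)
  fillers <- character()
  for (doc in corpus) {
    n <- n_chars(doc)
    if (n == 0L) next
    if (left == "") {
      anchors <- 0:(n - 1L)          # filler may start at any position
    } else {
      loc <- stringi::stri_locate_all_fixed(doc, left, overlap = TRUE)[[1]]
      if (is.na(loc[1, 1])) next
      anchors <- loc[, 2]            # 1-based end of left == 0-based filler start
    }
    for (a in anchors) {
      for (len in seq_len(max(0L, min(max_term_len, n - a - nr)))) {
        ch <- stringi::stri_sub(doc, a + len, a + len)
        if (ch %in% FILLER_PUNCT) break  # longer fillers contain it too
        if (nr == 0L ||
            stringi::stri_sub(doc, a + len + 1L, a + len + nr) == right) {
          fillers <- c(fillers, stringi::stri_sub(doc, a + 1L, a + len))
          break                      # shortest match per anchor
        }
      }
    }
  }
  unique(fillers)
}

#' Score candidate patterns by selectivity and precision
#'
#' Pattern Selectivity (PS) is the number of unique *correct* fillers a
#' pattern extracts from the corpus — fillers already in the slot-category
#' lexicon (core terms plus accretions from earlier iterations).  Pattern
#' Precision (PP) is PS divided by the number of unique fillers; it is `NA`
#' (undefined) when the pattern extracts nothing.
#'
#' @param patterns tibble from [generate_candidate_patterns()] (one slot
#'   category).
#' @param corpus character vector of documents.
#' @param lex the current [lexicon_set()].
#' @param cfg a [bootstrap_config()].
#' @return `patterns` with columns `ps`, `pp` and `n_fillers` added.
#' @export
score_patterns <- function(patterns, corpus, lex, cfg = bootstrap_config()) {
  stopifnot(length(unique(patterns$category)) <= 1)
  known <- lexicon_terms(lex, unique(patterns$category))
  ps <- integer(nrow(patterns)); pp <- rep(NA_real_, nrow(patterns))
  nf <- integer(nrow(patterns))
  for (k in seq_len(nrow(patterns))) {
    fills <- apply_pattern(patterns$left[k], patterns$right[k], corpus,
                           cfg$max_term_len)
    nf[k] <- length(fills)
    ps[k] <- sum(fills %in% known)
    if (nf[k] > 0) pp[k] <- ps[k] / nf[k]
  }
  patterns$ps <- ps; patterns$pp <- pp; patterns$n_fillers <- nf
  patterns
}

#' Keep high-quality patterns
#'
#' Retains exactly the patterns with `ps > pst` and `pp > ppt` (strict
#' inequalities); patterns with undefined precision are dropped.
#'
#' @param patterns scored tibble from [score_patterns()].
#' @param cfg a [bootstrap_config()].
#' @return the retained subset.
#' @export
select_patterns <- function(patterns, cfg = bootstrap_config()) {
  keep <- !is.na(patterns$pp) & patterns$ps > cfg$pst & patterns$pp > cfg$ppt
  patterns[keep, , drop = FALSE]
}

#' Keep reliable candidate terms
#'
#' Retains candidates with `tf > tft` (strict), where `tf` is the number of
#' accepted patterns that extracted the candidate.
#'
#' @param candidates tibble with columns `surface`, `tf`, `category`.
#' @param cfg a [bootstrap_config()].
#' @return the retained subset.
#' @export
select_terms <- function(candidates, cfg = bootstrap_config()) {
  candidates[candidates$tf > cfg$tft, , drop = FALSE]
}

#' Iteratively enrich a lexicon by pattern induction
#'
#' Each iteration (i) tags the corpus with the current lexica and harvests
#' candidate context patterns around every occurrence of the target
#' category, (ii) scores and thresholds the patterns, (iii) extracts slot
#' fillers with the accepted patterns and (iv) adds fillers extracted by
#' more than `tft` patterns to the lexicon with provenance
#' `pattern_iteration`.  Iteration stops when no new term is added or
#' `max_iterations` is reached.  Enrichment is intended for the disease and
#' drug lexica, whose local contexts are discriminative.
#'
#' @param corpus character vector of documents.
#' @param lex the starting [lexicon_set()].
#' @param category slot category to enrich (`"disease"` or `"drug"` in
#'   typical use; any category is accepted).
#' @param cfg a [bootstrap_config()]; see [default_bootstrap_config()].
#' @param tag_categories categories used when tagging the corpus each
#'   iteration (default: all categories present in `lex`).
#' @return list with elements `lexicon` (the enriched [lexicon_set()]) and
#'   `history` (tibble: `iteration`, `n_patterns_kept`, `n_terms_added`).
#' @export
bootstrap <- function(corpus, lex, category, cfg = bootstrap_config(),
                      tag_categories = NULL) {
  .check_category(category)
  tag_categories <- tag_categories %||% unique(lex$terms$category)
  history <- tibble::tibble(iteration = integer(), n_patterns_kept = integer(),
                            n_terms_added = integer())
  for (iter in seq_len(cfg$max_iterations)) {
    # harvest patterns from every tagged occurrence of the slot category
    pats <- vector("list", length(corpus))
    for (d in seq_along(corpus)) {
      spans <- tag_terms(corpus[[d]], lex, tag_categories)
      spans <- spans[spans$category == category, , drop = FALSE]
      if (!nrow(spans)) next
      pats[[d]] <- do.call(rbind, lapply(seq_len(nrow(spans)), function(k) {
        generate_candidate_patterns(corpus[[d]], spans$start[k],
                                    spans$end[k], category)
      }))
    }
    pats <- unique(do.call(rbind, pats))
    if (is.null(pats) || !nrow(pats)) break
    scored <- score_patterns(pats, corpus, lex, cfg)
    kept <- select_patterns(scored, cfg)
    n_added <- 0L
    if (nrow(kept)) {
      fills <- lapply(seq_len(nrow(kept)), function(k)
        apply_pattern(kept$left[k], kept$right[k], corpus, cfg$max_term_len))
      tf_tab <- table(unlist(fills))
      known <- lexicon_terms(lex, category)
      cand <- tibble::tibble(surface = names(tf_tab),
                             tf = as.integer(tf_tab),
                             category = category)
      cand <- cand[!cand$surface %in% known, , drop = FALSE]
      acc <- select_terms(cand, cfg)
      n_added <- nrow(acc)
      if (n_added)
        lex <- add_term(lex, acc$surface, category, "pattern_iteration")
    }
    history <- rbind(history,
                     tibble::tibble(iteration = iter,
                                    n_patterns_kept = nrow(kept),
                                    n_terms_added = n_added))
    if (n_added == 0L) break
  }
  list(lexicon = lex, history = history)
}

#' Grid-search the pattern-selection thresholds
#'
#' Runs [bootstrap()] at every (pst, ppt) grid point, tags the tuning corpus
#' with the enriched lexicon and scores exact-match F1 of the target-category
#' spans against gold annotations.  The default grids are PST 3..10 step 1
#' and PPT 0.3..0.9 step 0.05 (104 configurations).  Ties are broken by
#' higher ppt, then higher pst.
#'
#' @param corpus character vector of documents (also the tuning set).
#' @param lex the starting [lexicon_set()].
#' @param category category being enriched.
#' @param gold tibble of gold spans with columns `doc_id` (index into
#'   `corpus`), `start`, `end`, `category`.
#' @param pst_grid,ppt_grid threshold grids.
#' @param cfg base [bootstrap_config()] supplying tft and the other fields.
#' @return list with `best_pst`, `best_ppt` and `table` (tibble of
#'   `pst`, `ppt`, `f1`).
#' @export
grid_search_thresholds <- function(corpus, lex, category, gold,
                                   pst_grid = 3:10,
                                   ppt_grid = seq(0.3, 0.9, by = 0.05),
                                   cfg = bootstrap_config()) {
  if (is.null(gold) || !nrow(gold)) stop("gold annotations required",
                                         call. = FALSE)
  grid <- expand.grid(pst = pst_grid, ppt = ppt_grid)
  f1s <- numeric(nrow(grid))
  gold <- gold[gold$category == category, , drop = FALSE]
  for (g in seq_len(nrow(grid))) {
    cfg_g <- cfg
    cfg_g$pst <- grid$pst[g]; cfg_g$ppt <- grid$ppt[g]
    enriched <- bootstrap(corpus, lex, category, cfg_g)$lexicon
    pred <- do.call(rbind, lapply(seq_along(corpus), function(d) {
      spans <- tag_terms(corpus[[d]], enriched)
      spans <- spans[spans$category == category, , drop = FALSE]
      if (!nrow(spans)) return(NULL)
      cbind(doc_id = d, spans)
    }))
    if (is.null(pred)) pred <- tibble::tibble(doc_id = integer(),
                                              start = integer(),
                                              end = integer(),
                                              category = character())
    f1s[g] <- evaluate_spans(pred, gold, mode = "exact")$f1
  }
  tab <- tibble::tibble(pst = grid$pst, ppt = grid$ppt, f1 = f1s)
  ord <- order(-tab$f1, -tab$ppt, -tab$pst)
  best <- tab[ord[1], ]
  list(best_pst = best$pst, best_ppt = best$ppt, table = tab)
}
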