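# Independent brute-force oracles and small fixture builders shared by the
# test files.  The oracles deliberately avoid the package's internals: plain
# vector scans over a precomputed substring table instead of hashed lookup.

# Brute-force longest-first tagger: enumerate every (start, length) substring,
# longest first then left to right, blocking on the first/last character.
oracle_tag <- function(s, lex_table) {
  # lex_table: data.frame(term, category)
  n <- stringi::stri_length(s)
  if (n == 0) return(data.frame(surface = character(), category = character(),
                                start = integer(), end = integer()))
  grid <- expand.grid(start = seq_len(n), len = seq_len(n))
  grid <- grid[grid$start + grid$len - 1 <= n, ]
  grid <- grid[order(-grid$len, grid$start), ]
  tagged <- logical(n)
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    a <- grid$start[r]; b <- a + grid$len[r] - 1
    if (tagged[a] || tagged[b]) next
    sub <- stringi::stri_sub(s, a, b)
    cats <- lex_table$category[lex_table$term == sub]
    if (length(cats)) {
      for (cat_ in cats)
        rows[[length(rows) + 1]] <- data.frame(
          surface = sub, category = cat_, start = a - 1L, end = b)
      tagged[a:b] <- TRUE
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(surface = character(),
                                      category = character(),
                                      start = integer(), end = integer()))
  out[order(out$start, out$category), ]
}

# Brute-force pattern application: scan every (position, filler length) pair.
oracle_apply_pattern <- function(left, right, corpus, max_term_len = 10) {
  punct <- c("。", "，", "、", "；", "：",
             "!", "！", "?", "？")
  hits <- character(0)
  for (doc in corpus) {
    n <- stringi::stri_length(doc)
    nl <- stringi::stri_length(left); nr <- stringi::stri_length(right)
    for (pos in seq_len(n)) {       # pos = 1-based start of filler
      if (nl > 0) {
        if (pos - nl < 1) next
        if (stringi::stri_sub(doc, pos - nl, pos - 1) != left) next
      }
      for (len in seq_len(max_term_len)) {
        if (pos + len - 1 + nr > n) break
        fill <- stringi::stri_sub(doc, pos, pos + len - 1)
        chars <- stringi::stri_sub(fill, seq_len(len), length = 1)
        if (any(chars %in% punct)) break
        if (nr == 0 ||
            stringi::stri_sub(doc, pos + len, pos + len + nr - 1) == right) {
          hits <- c(hits, fill)
          break                      # shortest per anchor
        }
      }
    }
  }
  unique(hits)
}

# Random tagging fixture: a 20-character alphabet, random strings, a random
# lexicon of 50 terms spread over the six categories.
random_tag_fixture <- function(seed) {
  set.seed(seed)
  alphabet <- c("一", "二", "三", "四", "五",
                "六", "七", "八", "九", "十",
                "甲", "乙", "丙", "丁", "戊",
                "己", "庚", "辛", "壬", "癸")
  terms <- unique(replicate(80, paste(
    sample(alphabet, sample(1:4, 1), replace = TRUE), collapse = "")))
  terms <- head(terms, 50)
  lex_table <- data.frame(
    term = terms,
    category = sample(lexicon_categories_all(), length(terms),
                      replace = TRUE))
  lex <- lexicon_set(tibble::tibble(term = lex_table$term,
                                    category = lex_table$category,
                                    origin = "core"))
  rand_string <- function() paste(
    sample(alphabet, sample(0:30, 1), replace = TRUE), collapse = "")
  list(alphabet = alphabet, lex_table = lex_table, lex = lex,
       rand_string = rand_string)
}

# F1 of a logical prediction vector against logical gold labels.
pair_f1 <- function(pred, gold) {
  tp <- sum(pred & gold)
  precision <- if (sum(pred)) tp / sum(pred) else 0
  recall <- if (sum(gold)) tp / sum(gold) else 0
  if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
}

# Shared mid-sized synthetic world for tests that need corpus + lexica.
synth_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 7, n_docs = 60)
      lex <- make_toy_lexica(cfg)
      gold <- generate_corpus(cfg, lex)
      cache <<- list(cfg = cfg, lex = lex, gold = gold,
                     texts = vapply(gold, `[[`, "", "text"))
    }
    cache
  }
})
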