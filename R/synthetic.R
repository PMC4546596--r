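#' Configuration for the synthetic EMR generator
#'
#' The generator emulates the structure of History-of-Present-Illness
#' narratives: short, comma-dense, period-delimited statements in which
#' temporal phrases, lexicon terms, negated mentions and description clauses
#' co-occur.  It emits complete gold structure (spans, times, triples,
#' linker pairs) so every stage is testable without real records.
#'
#' @param seed integer seed; all generation is deterministic given it.
#' @param n_docs number of documents.
#' @param vocab_sizes named integer vector: lexicon size per category.
#' @param n_planted named integer vector: how many disease/drug terms are
#'   withheld from the core lexica but used in documents inside shared
#'   high-frequency contexts, so that pattern bootstrapping can recover
#'   them.
#' @param p_time probability that an eligible statement opens with a
#'   temporal phrase.
#' @param p_multi_time probability that a symptom statement carries two
#'   temporal phrases (exercising the multi-time scoping rule).
#' @param p_description probability that an event is followed by a
#'   description clause.
#' @param p_negation,p_future weights of negated-mention and future-action
#'   statement templates.
#' @param template_weights named weights of the statement templates
#'   (`symptom`, `drug`, `disease`, `test`, `multi_event`).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_docs = 100L,
                         vocab_sizes = c(disease = 30L, symptom = 40L,
                                         drug = 30L, body_part = 15L,
                                         procedure = 10L,
                                         clinical_test = 10L),
                         n_planted = c(disease = 10L, drug = 20L),
                         p_time = 0.6, p_multi_time = 0.15,
                         p_description = 0.5,
                         p_negation = 0.08, p_future = 0.05,
                         template_weights = c(symptom = 0.40, drug = 0.20,
                                              disease = 0.12, test = 0.08,
                                              multi_event = 0.20)) {
  stopifnot(n_docs >= 1,
            all(c(p_time, p_multi_time, p_description, p_negation,
                  p_future) >= 0),
            all(c(p_time, p_multi_time, p_description, p_negation,
                  p_future) <= 1))
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 vocab_sizes = vocab_sizes, n_planted = n_planted,
                 p_time = p_time, p_multi_time = p_multi_time,
                 p_description = p_description, p_negation = p_negation,
                 p_future = p_future, template_weights = template_weights),
            class = "synth_config")
}

# Per-category character inventories.  Pools are disjoint from each other,
# from template glue, from the temporal vocabulary and from directional
# prefixes, so generated terms can only match where they were placed and
# character-level context features behave realistically.
.SYN_POOLS <- list(
  disease = list(pool = c("风", "寒", "湿", "痹", "疸", "痢", "疟", "痨",
                          "瘀", "滞", "郁", "络", "痿", "厥", "痞", "疳"),
                 suffix = c("症", "病")),
  symptom = list(pool = c("咳", "喘", "呕", "泻", "晕", "麻", "闷", "悸",
                          "汗", "涕", "嗽", "酸"),
                 suffix = c("痛", "肿", "痒", "胀")),
  drug = list(pool = c("阿", "莫", "氟", "康", "唑", "酮", "苯", "妥",
                       "拉", "克", "罗", "沙", "米", "舒"),
              suffix = c("素", "林", "平", "星", "汀")),
  procedure = list(pool = c("切", "除", "引", "流", "置", "换", "修",
                            "补", "吻", "扎"),
                   suffix = c("术")),
  clinical_test = list(pool = c("超", "声", "影", "穿", "刺", "培",
                                "养", "涂"),
                       suffix = c("检查", "试验")))

.SYN_BODY_PARTS <- c("肺", "肝", "肾", "胃", "肠", "心", "脑", "咽",
                     "喉", "鼻", "口腔", "黏膜", "膀胱", "胆", "脾",
                     "胰", "关节", "皮肤", "食管", "气管")

.DESC_POOL <- c("色", "质", "量", "稀", "稠", "浓", "淡", "紫", "黯",
                "清", "浊", "白", "黄", "黑", "灰", "稳")

.syn_terms <- function(category, n) {
  if (category == "body_part") return(head(.SYN_BODY_PARTS, n))
  inv <- .SYN_POOLS[[category]]
  out <- character(0)
  while (length(out) < n) {
    len <- sample(2:3, 1)
    t <- paste0(paste(sample(inv$pool, len, replace = TRUE), collapse = ""),
                sample(inv$suffix, 1))
    out <- unique(c(out, t))
  }
  out[seq_len(n)]
}

#' Generate seeded toy lexica with planted unknown terms
#'
#' Builds pronounceable pseudo-terms per category from category-specific
#' character inventories (symptoms end in 痛/肿/..., drugs in 素/林/...,
#' diseases in 病/症), pairwise disjoint across categories.  The disease and
#' drug vocabularies are split into a core part (loaded into the returned
#' lexicon) and a planted-unknown part, withheld from the core lexica but
#' used in generated documents.
#'
#' @param cfg a [synth_config()].
#' @return list with `core` (a [lexicon_set()]), `planted` (named list of
#'   withheld term vectors) and `full` (core plus planted).
#' @export
make_toy_lexica <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  vocab <- lapply(stats::setNames(nm = names(cfg$vocab_sizes)), function(cat_)
    .syn_terms(cat_, cfg$vocab_sizes[[cat_]]))
  planted <- list()
  core <- vocab
  for (cat_ in names(cfg$n_planted)) {
    k <- cfg$n_planted[[cat_]]
    stopifnot(k < length(vocab[[cat_]]))
    planted[[cat_]] <- utils::tail(vocab[[cat_]], k)
    core[[cat_]] <- utils::head(vocab[[cat_]],
                                length(vocab[[cat_]]) - k)
  }
  rows <- do.call(rbind, lapply(names(core), function(cat_)
    tibble::tibble(term = core[[cat_]], category = cat_, origin = "core")))
  core_lex <- lexicon_set(rows)
  full <- core_lex
  for (cat_ in names(planted))
    full <- add_term(full, planted[[cat_]], cat_, "core")
  list(core = core_lex, planted = planted, full = full)
}

# drug / disease bootstrap context templates: left glue, right glue
.DRUG_CTX <- list(c("给予", "抗感染"), c("予", "口服"), c("服用", "好转"))
.DISEASE_CTX <- list(c("诊断为", "明确"), c("考虑", "可能"))

.syn_time <- function() {
  kind <- sample(c("duration", "idiom", "day"), 1,
                 prob = c(0.5, 0.25, 0.25))
  if (kind == "duration") {
    unit <- sample(c("天", "年", "周", "小时", "月"), 1)
    paste0(if (stats::runif(1) < 0.3) "约" else "",
           sample(c(as.character(1:9), "一", "两", "三", "十"), 1),
           if (unit == "月") "个" else "",
           unit, "前")
  } else if (kind == "idiom") {
    sample(c("昨夜", "昨晚", "今夜", "今晚", "今早", "今晨"), 1)
  } else {
    paste0(sample(c("昨天", "今天", "昨日", "前天"), 1),
           if (stats::runif(1) < 0.6)
             sample(c("上午", "下午", "凌晨", "晚上"), 1) else "",
           if (stats::runif(1) < 0.4)
             paste0(sample(2:11, 1), "点") else "")
  }
}

#' Generate a synthetic gold-annotated corpus
#'
#' Documents are sequences of period-delimited statements built from
#' templates: symptom onset (optionally time-anchored, optionally followed
#' by a description clause), drug administration and disease diagnosis
#' inside shared bootstrap contexts, clinical-test statements with
#' digit-bearing readings, negated mentions and planned procedures, and
#' two-event statements whose single description belongs to a randomly
#' chosen one of the two events (so nearest-description linking cannot
#' resolve ownership, while co-occurrence can).  Planted unknown
#' disease/drug terms are guaranteed to appear in at least two distinct
#' contexts each.  Descriptions are drawn from a term-conditioned vocabulary
#' so that corpus co-occurrence (hence NGD) is informative.
#'
#' @param cfg a [synth_config()].
#' @param lexica result of [make_toy_lexica()] (regenerated from `cfg` when
#'   omitted).
#' @return list of gold documents; each has `doc_id`, `text`, `statements`
#'   (tibble of statement text and offsets), `spans`, `times`, `triples`
#'   (document-offset tibbles) and `desc_map` metadata is attached to the
#'   result as an attribute.
#' @export
generate_corpus <- function(cfg = synth_config(), lexica = NULL) {
  if (is.null(lexica)) lexica <- make_toy_lexica(cfg)
  set.seed(cfg$seed + 1L)
  core <- lexica$core
  symptoms <- lexicon_terms(core, "symptom")
  tests <- lexicon_terms(core, "clinical_test")
  procedures <- lexicon_terms(core, "procedure")
  core_drugs <- lexicon_terms(core, "drug")
  core_diseases <- lexicon_terms(core, "disease")
  all_drugs <- c(core_drugs, lexica$planted$drug)
  all_diseases <- c(core_diseases, lexica$planted$disease)
  cat_of <- function(term) {
    if (term %in% all_drugs) "drug"
    else if (term %in% all_diseases) "disease"
    else if (term %in% symptoms) "symptom"
    else if (term %in% tests) "clinical_test"
    else "procedure"
  }

  # term-conditioned description vocabulary: two descriptions per event
  # term, unique across terms, so co-occurrence identifies the owner
  desc_terms <- c(symptoms, tests, core_drugs, core_diseases)
  desc_inventory <- character(0)
  while (length(desc_inventory) < 2 * length(desc_terms))
    desc_inventory <- unique(c(desc_inventory,
                               paste(sample(.DESC_POOL, 3), collapse = "")))
  desc_map <- lapply(stats::setNames(seq_along(desc_terms), desc_terms),
                     function(i) desc_inventory[c(2 * i - 1, 2 * i)])
  digit_desc <- function() paste0("测值", sample(10:99, 1), "%")

  # coverage queue: every planted term must hit >= 2 distinct contexts
  queue <- list()
  for (term in lexica$planted$drug)
    for (ci in 1:2) queue[[length(queue) + 1L]] <- list(term = term,
                                                        ctx = .DRUG_CTX[[ci]],
                                                        cat = "drug")
  for (term in lexica$planted$disease)
    for (ci in 1:2) queue[[length(queue) + 1L]] <-
    list(term = term, ctx = .DISEASE_CTX[[ci]], cat = "disease")
  queue <- sample(queue)
  q_pos <- 0L

  neg_markers <- c("无", "否认", "未见")

  make_statement <- function(type) {
    # returns list(pieces = tibble(text, role, category), desc_owner)
    pieces <- tibble::tibble(text = character(), role = character(),
                             category = character())
    add <- function(text, role = "glue", category = NA_character_) {
      pieces <<- rbind(pieces, tibble::tibble(text = text, role = role,
                                              category = category))
    }
    if (type == "symptom" || type == "multi_event") {
      multi_time <- type == "symptom" && stats::runif(1) < cfg$p_multi_time
      if (stats::runif(1) < cfg$p_time || multi_time)
        add(.syn_time(), "time")
      s1 <- sample(symptoms, 1)
      add(s1, "term", "symptom")
      if (type == "multi_event") {
        s2 <- sample(setdiff(symptoms, s1), 1)
        add("，"); add(s2, "term", "symptom")
        if (stats::runif(1) < cfg$p_description) {
          # either event may own the trailing description: position alone
          # cannot decide the link, only co-occurrence can
          owner <- sample(c(s1, s2), 1)
          add("，"); add(sample(desc_map[[owner]], 1), "desc", owner)
        }
      } else {
        if (multi_time) {
          s2 <- sample(setdiff(symptoms, s1), 1)
          add("，"); add(.syn_time(), "time"); add(s2, "term", "symptom")
        } else if (stats::runif(1) < cfg$p_description) {
          add("，"); add(sample(desc_map[[s1]], 1), "desc", s1)
        }
        if (stats::runif(1) < cfg$p_negation) {
          add("，"); add(sample(neg_markers, 1), "neg")
          add(sample(setdiff(symptoms, s1), 1), "term_negated", "symptom")
        }
      }
    } else if (type == "drug" || type == "disease") {
      if (q_pos < length(queue) && stats::runif(1) < 0.35) {
        q_pos <<- q_pos + 1L
        item <- queue[[q_pos]]
        if (item$cat != type) {          # keep queue order but honour type
          q_pos <<- q_pos - 1L
          item <- NULL
        }
      } else item <- NULL
      if (is.null(item)) {
        ctx <- if (type == "drug") sample(.DRUG_CTX, 1)[[1]]
        else sample(.DISEASE_CTX, 1)[[1]]
        pool <- if (type == "drug") c(core_drugs, lexica$planted$drug)
        else c(core_diseases, lexica$planted$disease)
        # core terms dominate so patterns score as known-term extractors
        term <- if (stats::runif(1) < 0.75)
          sample(if (type == "drug") core_drugs else core_diseases, 1)
        else sample(pool, 1)
        item <- list(term = term, ctx = ctx, cat = type)
      }
      if (stats::runif(1) < cfg$p_time * 0.5) add(.syn_time(), "time")
      add(item$ctx[1]); add(item$term, "term", item$cat); add(item$ctx[2])
      if (item$cat %in% c("drug", "disease") &&
          item$term %in% names(desc_map) &&
          stats::runif(1) < cfg$p_description * 0.4) {
        add("，"); add(sample(desc_map[[item$term]], 1), "desc", item$term)
      }
    } else if (type == "test") {
      if (stats::runif(1) < cfg$p_time) add(.syn_time(), "time")
      t1 <- sample(tests, 1)
      add("复查"); add(t1, "term", "clinical_test")
      if (stats::runif(1) < cfg$p_description) {
        add("，")
        add(if (stats::runif(1) < 0.5) digit_desc()
            else sample(desc_map[[t1]], 1), "desc", t1)
      }
    } else if (type == "negation") {
      add(sample(neg_markers, 1), "neg")
      add(sample(symptoms, 1), "term_negated", "symptom")
    } else if (type == "future") {
      add("拟行", "future_marker")
      add(sample(procedures, 1), "term_future", "procedure")
    }
    pieces
  }

  docs <- vector("list", cfg$n_docs)
  tw <- cfg$template_weights / sum(cfg$template_weights)
  for (d in seq_len(cfg$n_docs)) {
    n_st <- sample(2:4, 1)
    types <- sample(names(tw), n_st, replace = TRUE, prob = tw)
    # negation / future statements replace a slot with their own probability
    extra <- stats::runif(n_st)
    types[extra < cfg$p_negation] <- "negation"
    types[extra >= cfg$p_negation &
            extra < cfg$p_negation + cfg$p_future] <- "future"
    docs[[d]] <- lapply(types, make_statement)
  }
  # drain the coverage queue with dedicated single-statement documents
  while (q_pos < length(queue)) {
    q_pos <- q_pos + 1L
    item <- queue[[q_pos]]
    pieces <- tibble::tibble(
      text = c(item$ctx[1], item$term, item$ctx[2]),
      role = c("glue", "term", "glue"),
      category = c(NA, item$cat, NA))
    docs[[length(docs) + 1L]] <- list(pieces)
  }

  gold <- lapply(seq_along(docs), function(d)
    .assemble_gold(docs[[d]], d, cat_of))
  attr(gold, "desc_map") <- desc_map
  gold
}

# Turn per-statement piece tables into text + gold annotations with
# document-level 0-based offsets, applying the temporal scoping rules.
.assemble_gold <- function(statements, doc_id, cat_of) {
  text <- ""
  pos <- 0L
  spans <- list(); times <- list(); triples <- list(); pairs_meta <- list()
  st_rows <- list()
  carry <- NULL
  for (si in seq_along(statements)) {
    pieces <- statements[[si]]
    st_start <- pos
    st_text <- paste(pieces$text, collapse = "")
    st_times <- list(); st_events <- list(); st_descs <- list()
    negated <- FALSE  # a neg/future marker demotes the following term
    p <- pos
    for (k in seq_len(nrow(pieces))) {
      len <- n_chars(pieces$text[k])
      role <- pieces$role[k]
      if (role == "time") {
        st_times[[length(st_times) + 1L]] <- tibble::tibble(
          surface = pieces$text[k], start = p, end = p + len)
      } else if (role %in% c("neg", "future_marker")) {
        negated <- TRUE
      } else if (role %in% c("term", "term_negated", "term_future")) {
        is_ev <- role == "term" && !negated
        spans[[length(spans) + 1L]] <- tibble::tibble(
          surface = pieces$text[k],
          category = cat_of(pieces$text[k]),
          start = p, end = p + len, is_event = is_ev)
        if (is_ev)
          st_events[[length(st_events) + 1L]] <-
          spans[[length(spans)]]
        negated <- FALSE
      } else if (role == "desc") {
        st_descs[[length(st_descs) + 1L]] <- tibble::tibble(
          surface = pieces$text[k], start = p, end = p + len,
          owner = pieces$category[k])
      }
      p <- p + len
    }
    st_times <- if (length(st_times)) do.call(rbind, st_times) else NULL
    # scoping rules, applied by construction
    for (ev in st_events) {
      tm <- if (!is.null(st_times) && nrow(st_times) == 1L) st_times[1, ]
      else if (!is.null(st_times) && nrow(st_times) > 1L) {
        before <- which(st_times$start <= ev$start)
        if (length(before)) st_times[max(before), ] else carry
      } else carry
      own_desc <- Filter(function(dd) dd$owner == ev$surface, st_descs)
      dd <- if (length(own_desc)) own_desc[[1]] else NULL
      triples[[length(triples) + 1L]] <- tibble::tibble(
        doc_id = doc_id, statement_idx = si,
        time_surface = if (is.null(tm)) NA_character_ else tm$surface,
        time_start = if (is.null(tm)) NA_integer_ else as.integer(tm$start),
        time_end = if (is.null(tm)) NA_integer_ else as.integer(tm$end),
        event_surface = ev$surface, event_category = ev$category,
        event_start = ev$start, event_end = ev$end,
        desc_surface = if (is.null(dd)) NA_character_ else dd$surface,
        desc_start = if (is.null(dd)) NA_integer_ else as.integer(dd$start),
        desc_end = if (is.null(dd)) NA_integer_ else as.integer(dd$end))
    }
    if (!is.null(st_times))
      for (k in seq_len(nrow(st_times)))
        times[[length(times) + 1L]] <- cbind(st_times[k, ],
                                             statement_idx = si)
    if (!is.null(st_times) && nrow(st_times)) carry <- st_times[nrow(st_times), ]
    st_rows[[si]] <- tibble::tibble(statement_idx = si, text = st_text,
                                    start = st_start,
                                    end = st_start + n_chars(st_text))
    text <- paste0(text, st_text, "。")
    pos <- pos + n_chars(st_text) + 1L
  }
  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  list(
    doc_id = doc_id, text = text,
    statements = do.call(rbind, st_rows),
    spans = bind(spans, tibble::tibble(surface = character(),
                                       category = character(),
                                       start = integer(), end = integer(),
                                       is_event = logical())),
    times = bind(times, tibble::tibble(surface = character(),
                                       start = integer(), end = integer(),
                                       statement_idx = integer())),
    triples = bind(triples, tibble::tibble(
      doc_id = integer(), statement_idx = integer(),
      time_surface = character(), time_start = integer(),
      time_end = integer(), event_surface = character(),
      event_category = character(), event_start = integer(),
      event_end = integer(), desc_surface = character(),
      desc_start = integer(), desc_end = integer())))
}

#' Build linker training data from gold documents
#'
#' Runs candidate extraction and filtering on every statement of the gold
#' documents, featurizes all (event, candidate) pairs and labels a pair
#' positive exactly when the candidate's interval equals the gold
#' description of that event.  The generator thus supplies supervised
#' training pairs without human labels.
#'
#' @param gold_docs result of [generate_corpus()].
#' @param fp a frequency provider (defaults to corpus document frequency
#'   over the gold document texts).
#' @param cap cap passed to [ngd()].
#' @return list with `features` (tibble, one row per pair, including
#'   `doc_id` and `statement_idx`), `labels` (logical vector) and
#'   `baseline` (logical vector: would [baseline_adjacent()] accept the
#'   pair?).
#' @export
build_linker_training <- function(gold_docs, fp = NULL, cap = 10) {
  if (is.null(fp))
    fp <- corpus_frequency_provider(vapply(gold_docs, `[[`, "", "text"))
  feats <- list(); labels <- logical(0); baseline <- logical(0)
  for (gd in gold_docs) {
    for (si in seq_len(nrow(gd$statements))) {
      st <- gd$statements[si, ]
      sel <- gd$spans$start >= st$start & gd$spans$end <= st$end
      spans <- gd$spans[sel, , drop = FALSE]
      tsel <- gd$times$statement_idx == si
      times <- gd$times[tsel, , drop = FALSE]
      # statement-local offsets
      loc <- function(tab) { tab$start <- tab$start - st$start
        tab$end <- tab$end - st$start; tab }
      spans_l <- loc(spans); times_l <- loc(times)
      cands <- extract_candidates(st$text, spans_l, times_l)
      cands <- filter_candidates(cands, spans_l)
      events <- spans_l[!is.na(spans_l$is_event) & spans_l$is_event, ,
                        drop = FALSE]
      if (!nrow(events) || !nrow(cands)) next
      pf <- featurize_pairs(st$text, events, cands, spans_l, fp, cap)
      if (!nrow(pf)) next
      tr <- gd$triples[gd$triples$statement_idx == si, , drop = FALSE]
      lab <- vapply(seq_len(nrow(pf)), function(g) {
        ev <- events[pf$event_id[g], ]; cd <- cands[pf$cand_id[g], ]
        any(!is.na(tr$desc_start) &
              tr$event_start - st$start == ev$start &
              tr$desc_start - st$start == cd$start &
              tr$desc_end - st$start == cd$end)
      }, logical(1))
      base <- baseline_adjacent(events, cands)
      base_key <- paste(base$event_id, base$cand_id)
      pf$doc_id <- gd$doc_id; pf$statement_idx <- si
      feats[[length(feats) + 1L]] <- pf
      labels <- c(labels, lab)
      baseline <- c(baseline, paste(pf$event_id, pf$cand_id) %in% base_key)
    }
  }
  list(features = if (length(feats)) do.call(rbind, feats)
       else tibble::tibble(), labels = labels, baseline = baseline)
}
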