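#' Split a document into statements
#'
#' A statement is the segment of text up to a period symbol (。by default;
#' ！ and ？ can be added).  The boundary character is not part of the
#' statement text; a trailing segment without a boundary is kept.
#'
#' @param doc document text.
#' @param boundary statement-boundary characters.
#' @return tibble with `statement_idx`, `text`, `start`, `end` (0-based
#'   half-open document offsets of the statement text).
#' @export
split_statements <- function(doc, boundary = c("。")) {
  empty <- tibble::tibble(statement_idx = integer(), text = character(),
                          start = integer(), end = integer())
  n <- n_chars(doc)
  if (!n) return(empty)
  chars <- stringi::stri_sub(doc, seq_len(n), length = 1L)
  cuts <- which(chars %in% boundary)
  starts <- c(0L, cuts)                 # 0-based starts of segments
  ends <- c(cuts - 1L, n)               # 0-based half-open ends
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)
  tibble::tibble(statement_idx = seq_along(starts),
                 text = str_slice(doc, starts, ends),
                 start = starts, end = ends)
}

#' Bundle the resources needed for end-to-end extraction
#'
#' @param lexicon a [lexicon_set()].
#' @param model optional [train_linker()] model; without one, descriptions
#'   are attached with the nearest-following [baseline_adjacent()] rule.
#' @param fp frequency provider for pair features (required with a model).
#' @param adjacency optional [build_adjacency_table()] for enumeration
#'   assembly.
#' @param prefix_cfg optional [prefix_config()] for directional expansion
#'   (`NULL` disables it).
#' @param filter_cfg a [filter_config()].
#' @param temporal_cfg a [temporal_config()].
#' @param stoplist description stop words, see [filter_candidates()].
#' @param cap NGD cap.
#' @return a list of class `extraction_resources`.
#' @export
extraction_resources <- function(lexicon, model = NULL, fp = NULL,
                                 adjacency = NULL, prefix_cfg = NULL,
                                 filter_cfg = filter_config(),
                                 temporal_cfg = temporal_config(),
                                 stoplist = c("入院", "出院", "住院",
                                              "就诊", "治疗"),
                                 cap = 10) {
  stopifnot(inherits(lexicon, "lexicon_set"))
  if (!is.null(model) && is.null(fp))
    stop("a frequency provider is required when a linker model is given",
         call. = FALSE)
  structure(list(lexicon = lexicon, model = model, fp = fp,
                 adjacency = adjacency, prefix_cfg = prefix_cfg,
                 filter_cfg = filter_cfg, temporal_cfg = temporal_cfg,
                 stoplist = stoplist, cap = cap),
            class = "extraction_resources")
}

#' Extract (time, event, description) triples from one document
#'
#' Runs the full workflow: statement splitting; longest-match tagging;
#' optional enumeration assembly and directional-prefix expansion; negation
#' and future filtering; temporal extraction and scoping; candidate
#' description extraction, filtering and linking.  Events that link to no
#' description yield a triple with an `NA` description; an event accepted
#' with several descriptions yields one triple per accepted pair.
#'
#' @param doc document text.
#' @param resources an [extraction_resources()] bundle.
#' @param doc_id identifier recorded in the output.
#' @return tibble of triples with document-level 0-based offsets:
#'   `doc_id`, `statement_idx`, `time_surface`, `time_start`, `time_end`,
#'   `event_surface`, `event_category`, `event_start`, `event_end`,
#'   `desc_surface`, `desc_start`, `desc_end`.
#' @export
extract_document <- function(doc, resources, doc_id = 1L) {
  stopifnot(inherits(resources, "extraction_resources"))
  res <- resources
  sts <- split_statements(doc)
  proto <- tibble::tibble(
    doc_id = integer(), statement_idx = integer(),
    time_surface = character(), time_start = integer(),
    time_end = integer(), event_surface = character(),
    event_category = character(), event_start = integer(),
    event_end = integer(), desc_surface = character(),
    desc_start = integer(), desc_end = integer())
  if (!nrow(sts)) return(proto)
  scope_input <- vector("list", nrow(sts))
  st_state <- vector("list", nrow(sts))
  for (si in seq_len(nrow(sts))) {
    st <- sts$text[si]
    spans <- tag_terms(st, res$lexicon)
    if (!is.null(res$adjacency) && nrow(spans) >= 2) {
      comp <- assemble_enumeration(st, spans, res$adjacency, res$lexicon)
      if (nrow(comp))
        spans <- rbind(spans,
                       tibble::tibble(surface = comp$surface,
                                      category = comp$category,
                                      start = comp$start, end = comp$end,
                                      is_event = NA))
    }
    if (!is.null(res$prefix_cfg) && nrow(spans)) {
      spans <- do.call(rbind, lapply(seq_len(nrow(spans)), function(k)
        expand_directional_prefix(st, spans[k, ], res$prefix_cfg)))
      spans <- spans[!duplicated(spans[c("start", "end", "category")]), ]
    }
    spans <- filter_events(st, spans, res$filter_cfg)
    times <- extract_temporal_terms(st, res$temporal_cfg)
    cands <- filter_candidates(extract_candidates(st, spans, times),
                               spans, res$stoplist)
    events <- spans[spans$is_event, , drop = FALSE]
    links <- if (!nrow(events) || !nrow(cands)) {
      tibble::tibble(event_id = integer(), cand_id = integer())
    } else if (is.null(res$model)) {
      baseline_adjacent(events, cands)
    } else {
      link_pairs(res$model,
                 featurize_pairs(st, events, cands, spans, res$fp, res$cap))
    }
    shift <- function(tab) {
      if (nrow(tab)) { tab$start <- tab$start + sts$start[si]
        tab$end <- tab$end + sts$start[si] }
      tab
    }
    events <- shift(events); times_d <- shift(times); cands <- shift(cands)
    scope_input[[si]] <- list(times = times_d, events = events)
    st_state[[si]] <- list(events = events, cands = cands, links = links)
  }
  scoped <- assign_time_scopes(scope_input)
  out <- list()
  for (si in seq_len(nrow(sts))) {
    state <- st_state[[si]]
    ev <- state$events
    if (!nrow(ev)) next
    for (k in seq_len(nrow(ev))) {
      srow <- scoped[scoped$start == ev$start[k] &
                       scoped$end == ev$end[k] &
                       scoped$category == ev$category[k], ][1, ]
      cids <- state$links$cand_id[state$links$event_id == k]
      descs <- if (length(cids)) state$cands[cids, , drop = FALSE] else NULL
      n_rows <- max(1L, length(cids))
      for (r in seq_len(n_rows)) {
        dd <- if (!is.null(descs) && r <= nrow(descs)) descs[r, ] else NULL
        out[[length(out) + 1L]] <- tibble::tibble(
          doc_id = doc_id, statement_idx = si,
          time_surface = srow$time_surface,
          time_start = srow$time_start, time_end = srow$time_end,
          event_surface = ev$surface[k], event_category = ev$category[k],
          event_start = ev$start[k], event_end = ev$end[k],
          desc_surface = if (is.null(dd)) NA_character_ else dd$surface,
          desc_start = if (is.null(dd)) NA_integer_ else dd$start,
          desc_end = if (is.null(dd)) NA_integer_ else dd$end)
      }
    }
  }
  if (!length(out)) return(proto)
  do.call(rbind, out)
}

# Greedy one-to-one matching between pred and gold rows given a
# compatibility function; returns c(matched_pred, matched_gold).
.match_count <- function(pred, gold, compatible) {
  used <- logical(nrow(gold)); matched <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(nrow(gold))) {
      if (!used[j] && compatible(pred[i, ], gold[j, ])) {
        used[j] <- TRUE; matched <- matched + 1L; break
      }
    }
  }
  matched
}

.prf <- function(tp_pred, tp_gold, n_pred, n_gold, mode, level) {
  precision <- if (n_pred > 0) tp_pred / n_pred else 0
  recall <- if (n_gold > 0) tp_gold / n_gold else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  tibble::tibble(recall = recall, precision = precision, f1 = f1,
                 mode = mode, level = level)
}

#' Score predicted spans against gold spans
#'
#' Exact match requires identical document, offsets and category; inexact
#' match accepts any character overlap with a gold span of the same
#' category.
#'
#' @param pred,gold tibbles with columns `doc_id`, `start`, `end`,
#'   `category`.
#' @param mode `"exact"` or `"inexact"`.
#' @return one-row tibble: `recall`, `precision`, `f1`, `mode`, `level`.
#' @export
evaluate_spans <- function(pred, gold, mode = c("exact", "inexact")) {
  mode <- match.arg(mode)
  if (nrow(pred) && length(setdiff(pred$doc_id, gold$doc_id)) &&
      nrow(gold))
    stop("prediction references documents absent from gold", call. = FALSE)
  if (mode == "exact") {
    compatible <- function(p, g)
      p$doc_id == g$doc_id && p$start == g$start && p$end == g$end &&
      p$category == g$category
    tp <- .match_count(pred, gold, compatible)
    return(.prf(tp, tp, nrow(pred), nrow(gold), mode, "span"))
  }
  overlaps <- function(p, g)
    p$doc_id == g$doc_id && p$category == g$category &&
    p$start < g$end && g$start < p$end
  tp_pred <- sum(vapply(seq_len(nrow(pred)), function(i)
    any(vapply(seq_len(nrow(gold)), function(j)
      overlaps(pred[i, ], gold[j, ]), logical(1))), logical(1)))
  tp_gold <- sum(vapply(seq_len(nrow(gold)), function(j)
    any(vapply(seq_len(nrow(pred)), function(i)
      overlaps(pred[i, ], gold[j, ]), logical(1))), logical(1)))
  .prf(tp_pred, tp_gold, nrow(pred), nrow(gold), mode, "span")
}

#' Score predictions against gold at span, time-link or triple level
#'
#' Span level compares tagged spans (see [evaluate_spans()]).  Time-link
#' level requires the event to match (per `mode`) and the assigned time
#' surface to equal the gold one (unspecified matches unspecified).  Triple
#' level additionally requires the description interval to be identical
#' (`NA` matches `NA`).
#'
#' @param pred,gold span tibbles (level `"span"`) or triple tibbles as
#'   returned by [extract_document()] (levels `"time_link"`, `"triple"`).
#' @param mode `"exact"` or `"inexact"` event matching.
#' @param level `"span"`, `"time_link"` or `"triple"`.
#' @return one-row tibble: `recall`, `precision`, `f1`, `mode`, `level`.
#' @export
evaluate <- function(pred, gold, mode = c("exact", "inexact"),
                     level = c("span", "time_link", "triple")) {
  mode <- match.arg(mode); level <- match.arg(level)
  if (level == "span") return(evaluate_spans(pred, gold, mode))
  if (nrow(pred) && nrow(gold) &&
      length(setdiff(pred$doc_id, gold$doc_id)))
    stop("prediction references documents absent from gold", call. = FALSE)
  same_or_na <- function(a, b)
    (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  event_ok <- function(p, g) {
    if (p$doc_id != g$doc_id || p$event_category != g$event_category)
      return(FALSE)
    if (mode == "exact")
      p$event_start == g$event_start && p$event_end == g$event_end
    else
      p$event_start < g$event_end && g$event_start < p$event_end
  }
  compatible <- function(p, g) {
    if (!event_ok(p, g)) return(FALSE)
    if (!same_or_na(p$time_surface, g$time_surface)) return(FALSE)
    if (level == "triple") {
      if (!same_or_na(p$desc_start, g$desc_start)) return(FALSE)
      if (!same_or_na(p$desc_end, g$desc_end)) return(FALSE)
    }
    TRUE
  }
  tp <- .match_count(pred, gold, compatible)
  .prf(tp, tp, nrow(pred), nrow(gold), mode, level)
}

#' Write triples as JSONL interchange records
#'
#' One JSON object per line:
#' `{doc_id, time: {surface, start, end} | null, event: {surface, category,
#' start, end}, description: {surface, start, end} | null}`.
#'
#' @param triples tibble from [extract_document()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_triples_jsonl <- function(triples, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_len(nrow(triples))) {
    r <- triples[k, ]
    rec <- list(
      doc_id = r$doc_id,
      time = if (is.na(r$time_surface)) NULL else
        list(surface = r$time_surface, start = r$time_start,
             end = r$time_end),
      event = list(surface = r$event_surface, category = r$event_category,
                   start = r$event_start, end = r$event_end),
      description = if (is.na(r$desc_surface)) NULL else
        list(surface = r$desc_surface, start = r$desc_start,
             end = r$desc_end))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Read documents from a JSONL file
#'
#' Each line is a JSON object with fields `doc_id` and `text`.
#'
#' @param path input file path.
#' @return tibble with columns `doc_id` and `text`.
#' @export
read_documents_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(doc_id = vapply(recs, function(r) r$doc_id, numeric(1)),
                 text = vapply(recs, function(r) r$text, character(1)))
}
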