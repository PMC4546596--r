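#' Temporal grammar configuration
#'
#' A temporal term is built from up to nine parts: a prepositional
#' approximation word ("about"), numbers, a measure-word unit, a temporal
#' unit ("year", "month", ...), a postpositional approximation word
#' ("around"), a preposition ("before"), a day word ("yesterday"), a period
#' of the day ("afternoon") and a point in the day ("15:00", "3点").  Two
#' regular-expression forms combine them:
#'
#' * relative durations: `(Pre-AW)? Numbers (Unit)? TemporalUnit (Post-AW)?
#'   Preposition` — e.g. 约3个月前;
#' * day references: `Day (Period)? ((Pre-AW)? Point (Post-AW)?)?` — e.g.
#'   昨天下午3点左右.
#'
#' Six idioms not covered by the forms (昨夜, 昨晚, 今夜, 今晚, 今早, 今晨)
#' are matched directly.  Numbers match Arabic, full-width and Chinese
#' numerals.  All vocabularies are editable.
#'
#' @param pre_aw,post_aw approximation words before/after the time.
#' @param unit measure words between number and temporal unit.
#' @param temporal_unit duration units.
#' @param preposition trailing prepositions of the duration form.
#' @param day_words,period_words day and period-of-day vocabularies.
#' @param idioms the idiomatic time words.
#' @return a list of class `temporal_config`.
#' @export
temporal_config <- function(
    pre_aw = c("约", "大约", "近"),
    post_aw = c("左右", "余", "多"),
    unit = c("个"),
    temporal_unit = c("年", "月", "周", "星期", "天", "日",
                      "小时", "分钟", "晚", "夜"),
    preposition = c("之前", "之后", "以来", "以前", "以后",
                    "前", "后", "来", "内"),
    day_words = c("昨天", "昨日", "今天", "今日", "前天",
                  "前日", "当天", "当日", "次日"),
    period_words = c("上午", "下午", "中午", "凌晨", "清晨",
                     "早晨", "早上", "傍晚", "晚上", "夜间"),
    idioms = c("昨夜", "昨晚", "今夜", "今晚", "今早", "今晨")) {
  cfg <- list(pre_aw = pre_aw, post_aw = post_aw, unit = unit,
              temporal_unit = temporal_unit, preposition = preposition,
              day_words = day_words, period_words = period_words,
              idioms = idioms)
  num <- "(?:[0-9０-９]+(?:\\.[0-9０-９]+)?|[一二三四五六七八九十两百零]+|半|数)"
  point <- paste0("(?:[0-9０-９]{1,2}[:：][0-9０-９]{2}|",
                  num, "(?:点|时)(?:半|", num, "分)?)")
  cfg$re_duration <- paste0(.alt(pre_aw), "?", num, .alt(unit), "?",
                            .alt(temporal_unit), .alt(post_aw), "?",
                            .alt(preposition))
  cfg$re_day <- paste0(.alt(day_words), .alt(period_words), "?",
                       "(?:", .alt(pre_aw), "?", point, .alt(post_aw), "?)?")
  cfg$re_idiom <- .alt(idioms)
  structure(cfg, class = "temporal_config")
}

#' Extract temporal terms from a statement
#'
#' Returns all non-overlapping instances of the temporal grammar (see
#' [temporal_config()]), preferring longer matches when matches of the
#' different forms overlap.
#'
#' @param statement text without statement-boundary punctuation.
#' @param cfg a [temporal_config()].
#' @return tibble with columns `surface`, `start`, `end` (0-based,
#'   half-open) and `kind` (`relative_duration`, `day_reference`, `idiom`).
#' @examples
#' extract_temporal_terms("约3个月前出现咳嗽")
#' @export
extract_temporal_terms <- function(statement, cfg = temporal_config()) {
  empty <- tibble::tibble(surface = character(), start = integer(),
                          end = integer(), kind = character())
  if (!n_chars(statement)) return(empty)
  res <- list()
  forms <- list(relative_duration = cfg$re_duration,
                day_reference = cfg$re_day,
                idiom = cfg$re_idiom)
  for (kind in names(forms)) {
    loc <- stringi::stri_locate_all_regex(statement, forms[[kind]])[[1]]
    if (is.na(loc[1, 1])) next
    res[[kind]] <- tibble::tibble(
      surface = stringi::stri_sub(statement, loc[, 1], loc[, 2]),
      start = unname(loc[, 1]) - 1L, end = unname(loc[, 2]), kind = kind)
  }
  if (!length(res)) return(empty)
  cand <- do.call(rbind, res)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), ]
  # greedy non-overlapping selection, longest first at each position
  keep <- logical(nrow(cand)); cur_end <- -1L
  for (k in seq_len(nrow(cand))) {
    if (cand$start[k] >= cur_end) { keep[k] <- TRUE; cur_end <- cand$end[k] }
  }
  cand[keep, ]
}

#' Assign a time scope to every event
#'
#' Applies the three scoping rules over the ordered statements of a
#' document: (1) a single temporal term covers its whole statement; (2) with
#' several temporal terms, each covers the segment from its own start to the
#' start of the next one, the prefix before the first term inheriting the
#' carried-forward time (or the first term when none is carried); (3) a
#' statement without temporal terms inherits the last temporal term of the
#' preceding statements, and events before any temporal term in the document
#' get an unspecified time (`NA`).
#'
#' @param statements a list; each element is a list with components
#'   `times` (tibble from [extract_temporal_terms()]) and `events` (tibble
#'   of event spans), all offsets in one common (document) coordinate
#'   system, statements in document order.
#' @return tibble with one row per event: the event columns plus
#'   `time_surface`, `time_start`, `time_end` (`NA` when unspecified).
#' @export
assign_time_scopes <- function(statements) {
  carry <- NULL
  out <- list()
  for (st in statements) {
    times <- st$times
    events <- st$events
    if (!is.null(times) && nrow(times)) times <- times[order(times$start), ]
    if (is.null(events) || !nrow(events)) {
      if (!is.null(times) && nrow(times)) carry <- times[nrow(times), ]
      next
    }
    assigned <- vector("list", nrow(events))
    for (k in seq_len(nrow(events))) {
      ev_start <- events$start[k]
      if (is.null(times) || !nrow(times)) {
        assigned[k] <- list(carry)   # carry may be NULL
      } else if (nrow(times) == 1L) {
        # rule 1: a single time covers the whole statement
        assigned[[k]] <- times[1, ]
      } else {
        before <- which(times$start <= ev_start)
        if (length(before)) {
          assigned[[k]] <- times[max(before), ]
        } else {
          # prefix before the first time: carried time, else the first time
          assigned[k] <- list(carry %||% times[1, ])
        }
      }
    }
    row <- events
    row$time_surface <- vapply(assigned, function(a)
      if (is.null(a)) NA_character_ else a$surface, character(1))
    row$time_start <- vapply(assigned, function(a)
      if (is.null(a)) NA_integer_ else as.integer(a$start), integer(1))
    row$time_end <- vapply(assigned, function(a)
      if (is.null(a)) NA_integer_ else as.integer(a$end), integer(1))
    out[[length(out) + 1L]] <- row
    if (!is.null(times) && nrow(times)) carry <- times[nrow(times), ]
  }
  if (!length(out))
    return(tibble::tibble(surface = character(), category = character(),
                          start = integer(), end = integer(),
                          is_event = logical(),
                          time_surface = character(),
                          time_start = integer(), time_end = integer()))
  do.call(rbind, out)
}
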