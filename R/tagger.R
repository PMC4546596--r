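#' Tag lexicon terms in text by recursive longest match
#'
#' Implements the longest-match term tagging algorithm: candidate substring
#' lengths are tried from the full sequence length down to 1; at each length,
#' start positions run left to right; a substring is looked up in the
#' dictionaries only if neither its first nor its last character has already
#' been claimed by a longer match, and on a hit all its characters are
#' marked claimed.  A substring present in several dictionaries yields one
#' span per category at the same offsets.
#'
#' Only the first and last character are checked before lookup (boundary-
#' character blocking), exactly as the published procedure states; a shorter
#' term strictly inside the untouched middle of a longer non-matching region
#' can therefore still be tagged.
#'
#' @param s the text to tag (one sentence/statement or a whole document).
#' @param lex a [lexicon_set()].
#' @param categories categories to tag against (default: all six).
#' @return tibble of spans with columns `surface`, `category`, `start`,
#'   `end` (0-based half-open character offsets) and `is_event` (`NA` until
#'   [filter_events()] is applied), sorted by `start`.
#' @examples
#' lex <- add_term(lexicon_set(), c("咳嗽", "咳痰"), "symptom")
#' tag_terms("咳嗽咳痰", lex)
#' @export
tag_terms <- function(s, lex, categories = lexicon_categories_all()) {
  stopifnot(inherits(lex, "lexicon_set"))
  .check_category(categories)
  empty <- tibble::tibble(surface = character(), category = character(),
                          start = integer(), end = integer(),
                          is_event = logical())
  n <- n_chars(s)
  if (is.na(n) || n == 0L) return(empty)
  idx <- .lex_index(lex, categories)
  if (idx$max_len == 0L) return(empty)
  has_tagged <- logical(n)
  out_surface <- character(); out_cat <- character(); out_start <- integer()
  # lengths > the longest dictionary term can never match and touch no state
  for (i in seq(min(n, idx$max_len), 1L)) {
    for (j in seq_len(n - i + 1L)) {
      if (!has_tagged[j] && !has_tagged[j + i - 1L]) {
        s0 <- stringi::stri_sub(s, j, j + i - 1L)
        cats <- get0(s0, envir = idx$env, inherits = FALSE)
        if (!is.null(cats)) {
          out_surface <- c(out_surface, rep(s0, length(cats)))
          out_cat <- c(out_cat, cats)
          out_start <- c(out_start, rep(j - 1L, length(cats)))
          has_tagged[j:(j + i - 1L)] <- TRUE
        }
      }
    }
  }
  if (!length(out_surface)) return(empty)
  res <- tibble::tibble(
    surface = out_surface, category = out_cat,
    start = out_start,
    end = out_start + stringi::stri_length(out_surface),
    is_event = NA)
  res[order(res$start, res$category), ]
}

#' Configuration for the event filter
#'
#' Mentions of symptoms, procedures and clinical tests that are negated
#' (e.g. "no chills") or marked as future actions (e.g. "scheduled for ...")
#' describe things the patient did *not* experience and are filtered out of
#' the event stream.  Marker lists are editable; the defaults seed the
#' negations "no / refuse to / deny / haven't seen" and the future markers
#' "scheduled to / suggest to".
#'
#' @param negation_prefixes negation marker strings.
#' @param future_markers future-action marker strings.
#' @param filtered_categories categories subject to the filter.  Diseases and
#'   drugs always count as events; body parts are never events on their own
#'   (they feed compound-term assembly).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(
    negation_prefixes = c("无", "拒绝", "否认",
                          "未见"),
    future_markers = c("拟", "建议"),
    filtered_categories = c("symptom", "procedure", "clinical_test")) {
  stopifnot(all(nzchar(negation_prefixes)), all(nzchar(future_markers)))
  .check_category(filtered_categories)
  structure(list(negation_prefixes = negation_prefixes,
                 future_markers = future_markers,
                 filtered_categories = filtered_categories),
            class = "filter_config")
}

#' Mark tagged spans as medical events or non-events
#'
#' A span is demoted to non-event (`is_event = FALSE`) when its category is
#' in `cfg$filtered_categories` and a negation prefix or future marker occurs
#' in the same clause before the span's start.  Clauses are the segments
#' between the punctuation marks \code{， 、 。 ； ：}.
#' Body-part spans are never events.  All other spans get `is_event = TRUE`.
#'
#' @param doc the text the spans were tagged on.
#' @param spans tibble from [tag_terms()].
#' @param cfg a [filter_config()].
#' @return `spans` with `is_event` filled in.
#' @export
filter_events <- function(doc, spans, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  if (!nrow(spans)) { spans$is_event <- logical(0); return(spans) }
  chars <- stringi::stri_sub(doc, seq_len(n_chars(doc)),
                             length = 1L)
  boundary <- which(chars %in% CLAUSE_PUNCT)  # 1-based positions
  markers <- c(cfg$negation_prefixes, cfg$future_markers)
  is_event <- rep(TRUE, nrow(spans))
  for (k in seq_len(nrow(spans))) {
    if (spans$category[k] == "body_part") { is_event[k] <- FALSE; next }
    if (!spans$category[k] %in% cfg$filtered_categories) next
    start1 <- spans$start[k] + 1L  # 1-based first char of span
    before <- boundary[boundary < start1]
    clause_from <- if (length(before)) max(before) + 1L else 1L
    if (clause_from >= start1) next  # span begins the clause
    prefix <- stringi::stri_sub(doc, clause_from, start1 - 1L)
    if (any(stringi::stri_detect_fixed(prefix, markers)))
      is_event[k] <- FALSE
  }
  spans$is_event <- is_event
  spans
}
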