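#' Build a body-part / term adjacency table from a corpus
#'
#' Counts, over the corpus text, how often each body-part term B is
#' immediately followed by a term D from the disease, symptom, procedure or
#' clinical-test lexica, and estimates the conditional probability
#' `P(D follows | B) = adjacent_count(B, D) / occurrence_count(B)`.
#' Enumerated compounds (e.g. "B1、B2 D") are only assembled for pairs whose
#' adjacency probability exceeds the table threshold, which prevents
#' mistakes like turning "abdominal pain, vomiting" into "abdominal
#' vomiting".
#'
#' @param corpus character vector of documents.
#' @param lex a [lexicon_set()] with a non-empty body-part lexicon.
#' @param threshold adjacency-probability threshold used by
#'   [assemble_enumeration()] (default 0.01).
#' @param d_categories categories eligible as the D component; drugs are
#'   excluded because compound drug names do not take body-part prefixes.
#' @return an object of class `adjacency_table` with a `pairs` tibble
#'   (`b`, `d`, `adjacent_count`, `occurrence_count`, `prob`).
#' @export
build_adjacency_table <- function(corpus, lex, threshold = 0.01,
                                  d_categories = c("disease", "symptom",
                                                   "procedure",
                                                   "clinical_test")) {
  b_terms <- lexicon_terms(lex, "body_part")
  if (!length(b_terms)) stop("body_part lexicon is empty", call. = FALSE)
  d_terms <- lexicon_terms(lex, d_categories)
  d_by_len <- split(d_terms, stringi::stri_length(d_terms))
  occ <- integer(length(b_terms)); names(occ) <- b_terms
  adj <- list()
  for (doc in corpus) {
    n <- n_chars(doc)
    for (b in b_terms) {
      loc <- stringi::stri_locate_all_fixed(doc, b, overlap = TRUE)[[1]]
      if (is.na(loc[1, 1])) next
      occ[[b]] <- occ[[b]] + nrow(loc)
      for (e in loc[, 2]) {             # 1-based end of B
        for (len in names(d_by_len)) {
          len <- as.integer(len)
          if (e + len > n) next
          nxt <- stringi::stri_sub(doc, e + 1L, e + len)
          if (nxt %in% d_by_len[[as.character(len)]]) {
            key <- paste(b, nxt, sep = "\r")
            adj[[key]] <- (adj[[key]] %||% 0L) + 1L
          }
        }
      }
    }
  }
  if (length(adj)) {
    parts <- stringi::stri_split_fixed(names(adj), "\r", simplify = TRUE)
    pairs <- tibble::tibble(b = parts[, 1], d = parts[, 2],
                            adjacent_count = as.integer(unlist(adj)),
                            occurrence_count = as.integer(occ[parts[, 1]]))
    pairs$prob <- pairs$adjacent_count / pairs$occurrence_count
  } else {
    pairs <- tibble::tibble(b = character(), d = character(),
                            adjacent_count = integer(),
                            occurrence_count = integer(), prob = numeric())
  }
  structure(list(pairs = pairs, threshold = threshold,
                 occurrence = occ, d_categories = d_categories),
            class = "adjacency_table")
}

#' @export
print.adjacency_table <- function(x, ...) {
  cat("<adjacency_table>", nrow(x$pairs), "observed (B, D) pairs, threshold",
      x$threshold, "\n")
  invisible(x)
}

#' Adjacency probability of a (B, D) pair
#' @param table an `adjacency_table`.
#' @param b,d body-part and D-component terms.
#' @return the observed probability, 0 for unobserved pairs.
#' @export
adjacency_prob <- function(table, b, d) {
  hit <- table$pairs$b == b & table$pairs$d == d
  if (any(hit)) table$pairs$prob[which(hit)[1]] else 0
}

# can `s` be written as a concatenation of strings from `parts`?
.decomposable <- function(s, parts) {
  n <- n_chars(s)
  ok <- logical(n + 1L); ok[1] <- TRUE
  lens <- unique(stringi::stri_length(parts))
  for (i in seq_len(n)) {
    for (l in lens) {
      if (i - l >= 0 && ok[i - l + 1L] &&
          stringi::stri_sub(s, i - l + 1L, i) %in% parts) {
        ok[i + 1L] <- TRUE; break
      }
    }
  }
  ok[n + 1L]
}

#' Assemble compound terms from body-part enumerations
#'
#' Handles the two enumeration conventions `B1、…、Bn D` (several body parts
#' sharing one trailing term) and `B D1、…、Dn` (one body part distributing
#' over several terms).  The directly adjacent pair (`Bn D`, resp. `B D1`)
#' is always emitted as a compound when its concatenation is not already a
#' lexicon term; every distributed pair `Bi D` / `B Dj` is emitted only when
#' its adjacency probability exceeds the table threshold.
#'
#' Distributed compounds are not contiguous in the text: their `surface` is
#' the concatenation of the two components while `[start, end)` covers the
#' whole enumeration region; the `contiguous` column distinguishes the two
#' cases.
#'
#' @param statement the statement text.
#' @param spans tibble of tagged spans within the statement (offsets into
#'   `statement`), e.g. from [tag_terms()].
#' @param table an [build_adjacency_table()] result.
#' @param lex optional [lexicon_set()] used to suppress adjacent compounds
#'   that are already dictionary terms.
#' @return tibble of new compound spans with columns `surface`, `category`,
#'   `start`, `end`, `provenance` (= "body_part_assembly") and `contiguous`.
#' @export
assemble_enumeration <- function(statement, spans, table, lex = NULL) {
  empty <- tibble::tibble(surface = character(), category = character(),
                          start = integer(), end = integer(),
                          provenance = character(), contiguous = logical())
  if (nrow(spans) < 2) return(empty)
  d_cats <- table$d_categories
  # collapse multi-category duplicates at identical offsets: prefer body_part,
  # then the first D category
  spans <- spans[order(spans$start, spans$category != "body_part"), ]
  spans <- spans[!duplicated(spans[c("start", "end")]), ]
  spans <- spans[order(spans$start), ]
  # chain spans separated by nothing or by a single enumeration mark
  gap_ok <- function(i) {
    gap <- str_slice(statement, spans$end[i], spans$start[i + 1])
    gap %in% c("", "、", "，")
  }
  out <- list()
  emit <- function(b_row, d_row, region_start, region_end) {
    surf <- paste0(spans$surface[b_row], spans$surface[d_row])
    tibble::tibble(surface = surf, category = spans$category[d_row],
                   start = region_start, end = region_end,
                   provenance = "body_part_assembly",
                   contiguous = identical(
                     str_slice(statement, region_start, region_end), surf))
  }
  i <- 1L
  while (i < nrow(spans)) {
    # grow a maximal chain starting at i
    j <- i
    while (j < nrow(spans) && gap_ok(j)) j <- j + 1L
    chain <- i:j
    if (length(chain) >= 2) {
      cats <- spans$category[chain]
      n_b <- match(FALSE, cats == "body_part", nomatch = length(chain) + 1L) - 1L
      if (n_b >= 1L && n_b < length(chain) &&
          all(cats[(n_b + 1):length(chain)] %in% d_cats)) {
        n_d <- length(chain) - n_b
        if (n_b >= 1L && n_d == 1L) {
          # case 1: B1, ..., Bn, D  (adjacent pair is Bn D)
          d_row <- chain[length(chain)]
          for (kk in seq_len(n_b)) {
            b_row <- chain[kk]
            adjacent <- kk == n_b
            pr <- adjacency_prob(table, spans$surface[b_row],
                                 spans$surface[d_row])
            keep <- if (adjacent) {
              is.null(lex) ||
                !length(lookup(lex, paste0(spans$surface[b_row],
                                           spans$surface[d_row])))
            } else pr > table$threshold
            if (keep)
              out[[length(out) + 1L]] <-
                emit(b_row, d_row, spans$start[b_row], spans$end[d_row])
          }
        } else if (n_b == 1L && n_d >= 1L) {
          # case 2: B, D1, ..., Dn  (adjacent pair is B D1)
          b_row <- chain[1]
          for (kk in seq_len(n_d)) {
            d_row <- chain[1 + kk]
            adjacent <- kk == 1L
            pr <- adjacency_prob(table, spans$surface[b_row],
                                 spans$surface[d_row])
            keep <- if (adjacent) {
              is.null(lex) ||
                !length(lookup(lex, paste0(spans$surface[b_row],
                                           spans$surface[d_row])))
            } else pr > table$threshold
            if (keep)
              out[[length(out) + 1L]] <-
                emit(b_row, d_row, spans$start[b_row], spans$end[d_row])
          }
        }
      }
    }
    i <- j + 1L
  }
  if (!length(out)) return(empty)
  unique(do.call(rbind, out))
}

#' Directional/extensional prefix configuration
#'
#' Modifiers such as "left", "right", "bilateral", "upper" routinely extend
#' dictionary terms into unlisted variants ("left ureteral stones",
#' "bilateral kidney stones").  The vocabulary ships as an editable list; a
#' look-back window of 3 characters is examined before each tagged term.
#'
#' @param directional prefix strings (1-3 characters each).
#' @param lookback look-back window in characters.
#' @return a list of class `prefix_config`.
#' @export
prefix_config <- function(
    directional = c("左", "右", "双", "上", "下", "侧",
                    "内", "外", "全"),
    lookback = 3L) {
  stopifnot(all(stringi::stri_length(directional) >= 1),
            all(stringi::stri_length(directional) <= 3), lookback >= 1)
  structure(list(directional = directional, lookback = lookback),
            class = "prefix_config")
}

#' Expand a tagged span over a directional/extensional prefix
#'
#' Examines up to `cfg$lookback` characters immediately preceding the span;
#' the longest suffix of that window that is a concatenation of configured
#' directional/extensional strings is absorbed into the span, which keeps
#' its original category.  When no directional characters precede the term
#' the span is returned unchanged.
#'
#' @param doc the text the span was tagged on.
#' @param span one-row tibble (or list) with `surface`, `category`,
#'   `start`, `end`.
#' @param cfg a [prefix_config()].
#' @return the (possibly expanded) one-row span tibble; expanded spans carry
#'   a `provenance` of "prefix_update" if the column is present.
#' @export
expand_directional_prefix <- function(doc, span, cfg = prefix_config()) {
  span <- tibble::as_tibble(span)
  start <- span$start[1]
  win_from <- max(0L, start - cfg$lookback)
  window <- str_slice(doc, win_from, start)
  nw <- n_chars(window)
  for (k in rev(seq_len(nw))) {
    suf <- stringi::stri_sub(window, nw - k + 1L, nw)
    if (.decomposable(suf, cfg$directional)) {
      span$start[1] <- start - k
      span$surface[1] <- paste0(suf, span$surface[1])
      if ("provenance" %in% names(span)) span$provenance[1] <- "prefix_update"
      return(span)
    }
  }
  span
}
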