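#' Extract candidate descriptions from a statement
#'
#' After terms and temporal expressions are recognized, the remaining
#' segments of a statement are candidate descriptions of the medical events
#' (e.g. a sputum's colour, a spirometry reading).  The statement is split
#' at clause punctuation; within each clause the maximal character runs not
#' covered by any tagged span or temporal term, stripped of punctuation and
#' whitespace, become candidates.
#'
#' @param statement the statement text.
#' @param spans tibble of tagged spans (offsets into `statement`).
#' @param times tibble of temporal terms (offsets into `statement`).
#' @return tibble with columns `surface`, `start`, `end`, `contains_digit`.
#' @export
extract_candidates <- function(statement, spans = NULL, times = NULL) {
  empty <- tibble::tibble(surface = character(), start = integer(),
                          end = integer(), contains_digit = logical())
  n <- n_chars(statement)
  if (!n) return(empty)
  covered <- logical(n)
  mark <- function(tab) {
    if (!is.null(tab) && nrow(tab))
      for (k in seq_len(nrow(tab)))
        covered[(tab$start[k] + 1L):tab$end[k]] <<- TRUE
  }
  mark(spans); mark(times)
  chars <- stringi::stri_sub(statement, seq_len(n), length = 1L)
  strip <- c(CLAUSE_PUNCT, "！", "？", "!", "?", ",", ";", ":",
             " ", "　", "\t")
  boundary <- covered | chars %in% strip
  out <- list()
  run_start <- NA_integer_
  for (i in seq_len(n + 1L)) {
    inside <- i <= n && !boundary[i]
    if (inside && is.na(run_start)) run_start <- i
    if (!inside && !is.na(run_start)) {
      surf <- stringi::stri_sub(statement, run_start, i - 1L)
      out[[length(out) + 1L]] <- tibble::tibble(
        surface = surf, start = run_start - 1L, end = i - 1L,
        contains_digit = stringi::stri_detect_regex(surf, "[0-9０-９]"))
      run_start <- NA_integer_
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Filter candidate descriptions by rule
#'
#' Drops candidates that overlap a non-event span (negated or future
#' mentions describe things that did not happen) and candidates containing a
#' stop word — administrative vocabulary like "hospital admission" that
#' never describes an event.
#'
#' @param cands tibble from [extract_candidates()].
#' @param spans tibble of tagged spans with `is_event` filled
#'   (see [filter_events()]).
#' @param stoplist stop words; the default is 入院, 出院, 住院, 就诊, 治疗.
#' @return the retained subset of `cands`.
#' @export
filter_candidates <- function(cands, spans,
                              stoplist = c("入院", "出院", "住院",
                                           "就诊", "治疗")) {
  if (!nrow(cands)) return(cands)
  keep <- rep(TRUE, nrow(cands))
  non_event <- spans[!is.na(spans$is_event) & !spans$is_event, , drop = FALSE]
  for (k in seq_len(nrow(cands))) {
    if (nrow(non_event) &&
        any(cands$start[k] < non_event$end & non_event$start < cands$end[k])) {
      keep[k] <- FALSE
      next
    }
    if (length(stoplist) &&
        any(stringi::stri_detect_fixed(cands$surface[k], stoplist)))
      keep[k] <- FALSE
  }
  cands[keep, , drop = FALSE]
}

# ≤3 context characters on each side, padded with the sentinel "#" so each
# position is a stable categorical feature.  *_1 is the character nearest
# the span.
.context_chars <- function(statement, start, end, width = 3L) {
  n <- n_chars(statement)
  left <- character(width); right <- character(width)
  for (k in seq_len(width)) {
    lp <- start - k        # 0-based position of k-th char to the left
    left[k] <- if (lp >= 0) str_slice(statement, lp, lp + 1L) else "#"
    rp <- end + k - 1L
    right[k] <- if (rp < n) str_slice(statement, rp, rp + 1L) else "#"
  }
  list(left = left, right = right)
}

#' Featurize an (event, candidate-description) pair
#'
#' Computes the eight feature groups used by the pair classifier: the three
#' characters before and after the event term, the three characters before
#' and after the candidate description, whether the description contains
#' digits, the Normalized Google Distance between the two surfaces, the
#' numbers of recognized terms, candidate descriptions and commas strictly
#' between the pair, and the event's category.
#'
#' @param statement the statement text.
#' @param event one-row tibble/list with `surface`, `category`, `start`,
#'   `end`.
#' @param cand one-row tibble/list with `surface`, `start`, `end`,
#'   `contains_digit`.
#' @param spans all tagged spans in the statement (for the between-count).
#' @param cands all candidate descriptions in the statement.
#' @param fp a frequency provider for [ngd()].
#' @param cap cap passed to [ngd()].
#' @return a one-row tibble of features.
#' @export
featurize <- function(statement, event, cand, spans, cands, fp, cap = 10) {
  ev <- tibble::as_tibble(event); cd <- tibble::as_tibble(cand)
  n <- n_chars(statement)
  if (ev$end[1] > n || cd$end[1] > n)
    stop("event and candidate must lie within the statement", call. = FALSE)
  ec <- .context_chars(statement, ev$start[1], ev$end[1])
  dc <- .context_chars(statement, cd$start[1], cd$end[1])
  gap_start <- min(ev$end[1], cd$end[1])
  gap_end <- max(ev$start[1], cd$start[1])
  within_gap <- function(tab) {
    if (is.null(tab) || !nrow(tab) || gap_start >= gap_end) return(0L)
    sum(tab$start >= gap_start & tab$end <= gap_end)
  }
  gap_text <- if (gap_start < gap_end)
    str_slice(statement, gap_start, gap_end) else ""
  tibble::tibble(
    etl1 = ec$left[1], etl2 = ec$left[2], etl3 = ec$left[3],
    etr1 = ec$right[1], etr2 = ec$right[2], etr3 = ec$right[3],
    dtl1 = dc$left[1], dtl2 = dc$left[2], dtl3 = dc$left[3],
    dtr1 = dc$right[1], dtr2 = dc$right[2], dtr3 = dc$right[3],
    has_digit = isTRUE(cd$contains_digit[1]),
    ngd = ngd(ev$surface[1], cd$surface[1], fp, cap),
    n_terms_between = within_gap(spans),
    n_descs_between = within_gap(cands),
    n_commas_between = stringi::stri_count_regex(gap_text, "[，,]"),
    term_type = ev$category[1])
}

#' Featurize every (event, candidate) pair in a statement
#'
#' @param statement the statement text.
#' @param events tibble of event spans (`is_event = TRUE`).
#' @param cands tibble of filtered candidate descriptions.
#' @param spans all tagged spans in the statement.
#' @param fp a frequency provider.
#' @param cap cap passed to [ngd()].
#' @return tibble with `event_id`, `cand_id` (row indices into `events` and
#'   `cands`) followed by the feature columns; zero rows when either side is
#'   empty.
#' @export
featurize_pairs <- function(statement, events, cands, spans, fp, cap = 10) {
  if (!nrow(events) || !nrow(cands))
    return(tibble::tibble(event_id = integer(), cand_id = integer()))
  grid <- expand.grid(event_id = seq_len(nrow(events)),
                      cand_id = seq_len(nrow(cands)))
  feats <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    featurize(statement, events[grid$event_id[g], ], cands[grid$cand_id[g], ],
              spans, cands, fp, cap)
  }))
  cbind(tibble::as_tibble(grid), feats)
}

.CATEG_FEATS <- c("etl1", "etl2", "etl3", "etr1", "etr2", "etr3",
                  "dtl1", "dtl2", "dtl3", "dtr1", "dtr2", "dtr3",
                  "term_type")
.NUMERIC_FEATS <- c("ngd", "n_terms_between", "n_descs_between",
                    "n_commas_between")

# One-hot encoding with an out-of-vocabulary bucket per categorical column;
# numeric columns standardized with training mean/sd.
.encode_features <- function(features, enc = NULL) {
  if (is.null(enc)) {
    enc <- list(vocab = lapply(features[.CATEG_FEATS],
                               function(col) sort(unique(col))),
                center = vapply(features[.NUMERIC_FEATS], mean, numeric(1)),
                scale = vapply(features[.NUMERIC_FEATS], function(x) {
                  s <- stats::sd(x); if (!is.finite(s) || s == 0) 1 else s
                }, numeric(1)))
  }
  blocks <- lapply(.CATEG_FEATS, function(cn) {
    vocab <- enc$vocab[[cn]]
    idx <- match(features[[cn]], vocab, nomatch = length(vocab) + 1L)
    m <- matrix(0, nrow(features), length(vocab) + 1L)
    m[cbind(seq_len(nrow(features)), idx)] <- 1
    colnames(m) <- paste0(cn, "=", c(vocab, "<OOV>"))
    m
  })
  num <- vapply(.NUMERIC_FEATS, function(cn)
    (features[[cn]] - enc$center[[cn]]) / enc$scale[[cn]],
    numeric(nrow(features)))
  if (nrow(features) == 1L) num <- matrix(num, nrow = 1,
                                          dimnames = list(NULL, .NUMERIC_FEATS))
  X <- cbind(do.call(cbind, blocks), num,
             has_digit = as.numeric(features$has_digit))
  list(X = X, enc = enc)
}

#' Train the event-description pair classifier
#'
#' Fits a binary max-margin classifier (linear-kernel support vector
#' machine, balanced class weights) on featurized pairs.  Categorical
#' features are one-hot encoded over the training vocabulary with an
#' out-of-vocabulary bucket; numeric features are standardized.  Fitting is
#' deterministic given the seed.
#'
#' @param features tibble of feature rows from [featurize()] /
#'   [featurize_pairs()] (extra columns such as `event_id` are ignored).
#' @param labels logical vector: is the pair a true event-description link?
#' @param seed integer seed.
#' @param cost SVM cost parameter.
#' @return an object of class `linker_model`.
#' @export
train_linker <- function(features, labels, seed = 1L, cost = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("need at least 2 examples of each class", call. = FALSE)
  encoded <- .encode_features(features)
  y <- factor(labels, levels = c(FALSE, TRUE))
  n <- length(y)
  w <- n / (2 * table(y))
  set.seed(seed)
  fit <- e1071::svm(encoded$X, y, kernel = "linear", cost = cost,
                    class.weights = w, scale = FALSE, probability = FALSE)
  structure(list(fit = fit, enc = encoded$enc, seed = seed),
            class = "linker_model")
}

#' @export
print.linker_model <- function(x, ...) {
  cat("<linker_model> linear SVM,", x$fit$tot.nSV, "support vectors\n")
  invisible(x)
}

#' Predict labels for featurized pairs
#'
#' @param object a [train_linker()] model.
#' @param features tibble of feature rows.
#' @param ... unused.
#' @return logical vector of predicted labels.
#' @export
predict.linker_model <- function(object, features, ...) {
  if (!nrow(features)) return(logical(0))
  X <- .encode_features(features, object$enc)$X
  as.logical(predict(object$fit, X))
}

#' Accept event-description pairs with a trained classifier
#'
#' Scores every pair and keeps those classified true.  No one-to-one
#' constraint is imposed: one description may serve several events and one
#' event may take several descriptions.
#'
#' @param model a [train_linker()] model.
#' @param pair_features tibble from [featurize_pairs()] (must carry
#'   `event_id` and `cand_id`).
#' @return the accepted rows of `pair_features` (`event_id`, `cand_id`).
#' @export
link_pairs <- function(model, pair_features) {
  if (!nrow(pair_features))
    return(tibble::tibble(event_id = integer(), cand_id = integer()))
  acc <- predict(model, pair_features)
  pair_features[acc, c("event_id", "cand_id"), drop = FALSE]
}

#' Nearest-following-description baseline
#'
#' Links every event to the candidate description immediately after it (the
#' nearest candidate whose start is at or past the event's end), if any.
#'
#' @param events tibble of event spans.
#' @param cands tibble of candidate descriptions.
#' @return tibble of `event_id`, `cand_id` pairs.
#' @export
baseline_adjacent <- function(events, cands) {
  out <- tibble::tibble(event_id = integer(), cand_id = integer())
  if (!nrow(events) || !nrow(cands)) return(out)
  for (k in seq_len(nrow(events))) {
    after <- which(cands$start >= events$end[k])
    if (length(after)) {
      j <- after[which.min(cands$start[after])]
      out <- rbind(out, tibble::tibble(event_id = k, cand_id = j))
    }
  }
  out
}
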