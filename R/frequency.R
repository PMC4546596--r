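#' Corpus document-frequency provider
#'
#' The Normalized Google Distance needs term frequencies `f(x)`, joint
#' frequencies `f(x, y)` and a collection size `M`.  The original recipe
#' queries a web search engine; this provider replaces it with document
#' frequencies over a local corpus: `M` is the number of documents, `f(x)`
#' the number of documents containing `x` as a substring, and `f(x, y)` the
#' number of documents containing both.  Detection vectors are memoised per
#' term.
#'
#' @param corpus character vector of documents.
#' @return an object of class `frequency_provider`.
#' @seealso [cached_frequency_provider()] for precomputed (e.g. search
#'   engine) counts, [ngd()].
#' @export
corpus_frequency_provider <- function(corpus) {
  force(corpus)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  detect <- function(term) {
    v <- get0(term, envir = cache, inherits = FALSE)
    if (is.null(v)) {
      v <- stringi::stri_detect_fixed(corpus, term)
      assign(term, v, envir = cache)
    }
    v
  }
  structure(list(
    M = length(corpus),
    f = function(x) sum(detect(x)),
    f2 = function(x, y) sum(detect(x) & detect(y))),
    class = "frequency_provider")
}

#' Frequency provider backed by cached counts
#'
#' Serves precomputed counts, e.g. saved search-engine hit counts, so that
#' search-based distances can be reproduced offline.  Unknown terms and
#' pairs count 0.
#'
#' @param f named numeric vector of term counts.
#' @param f2 tibble/data.frame with columns `x`, `y`, `count` (symmetric
#'   pairs need only be listed once).
#' @param M total collection size (must satisfy `M >= max(f)`).
#' @return an object of class `frequency_provider`.
#' @export
cached_frequency_provider <- function(f, f2, M) {
  stopifnot(M >= 1, all(f <= M))
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  pair <- stats::setNames(f2$count, key(f2$x, f2$y))
  structure(list(
    M = M,
    f = function(x) unname(f[x]) %|NA|% 0,
    f2 = function(x, y) {
      hit <- unname(pair[key(x, y)])
      if (length(hit) && !is.na(hit)) hit
      else if (identical(x, y)) unname(f[x]) %|NA|% 0  # a term co-occurs with itself
      else 0
    }),
    class = "frequency_provider")
}

`%|NA|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.frequency_provider <- function(x, ...) {
  cat("<frequency_provider> M =", x$M, "\n")
  invisible(x)
}

#' Normalized Google Distance
#'
#' \deqn{NGD(x,y) = \frac{\max\{\log f(x), \log f(y)\} - \log f(x,y)}
#'                       {\log M - \min\{\log f(x), \log f(y)\}}}
#'
#' where `f` and `M` come from a frequency provider.  The distance is 0 for
#' terms that always co-occur and grows as co-occurrence becomes rarer.
#' Undefined cases — `f(x) = 0`, `f(y) = 0`, `f(x, y) = 0`, or a degenerate
#' denominator (`f = M`) — return `cap`, and the result is clamped to
#' `[0, cap]` so feature vectors stay finite.  The log base cancels;
#' natural logarithms are used.
#'
#' @param x,y terms.
#' @param fp a [corpus_frequency_provider()] or
#'   [cached_frequency_provider()].
#' @param cap value returned for undefined cases and upper clamp
#'   (default 10).
#' @return a non-negative number in `[0, cap]`.
#' @export
ngd <- function(x, y, fp, cap = 10) {
  stopifnot(inherits(fp, "frequency_provider"))
  if (fp$M < 2) stop("frequency provider must index at least 2 documents",
                     call. = FALSE)
  fx <- fp$f(x); fy <- fp$f(y)
  if (fx == 0 || fy == 0) return(cap)
  fxy <- fp$f2(x, y)
  if (fxy == 0) return(cap)
  num <- max(log(fx), log(fy)) - log(fxy)
  if (num <= 0) return(0)           # full co-occurrence, e.g. ngd(x, x)
  denom <- log(fp$M) - min(log(fx), log(fy))
  if (denom <= 0) return(cap)
  min(num / denom, cap)
}
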