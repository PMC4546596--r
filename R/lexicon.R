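#' The six medical term categories
#'
#' The cross-domain dictionary distinguishes diseases, symptoms, drugs,
#' body parts, procedures and clinical tests.
#'
#' @return character vector of the six category names.
#' @export
lexicon_categories_all <- function() {
  c("disease", "symptom", "drug", "body_part", "procedure", "clinical_test")
}

.PROVENANCE <- c("core", "pattern_iteration", "body_part_assembly", "prefix_update")

.check_category <- function(category) {
  bad <- setdiff(category, lexicon_categories_all())
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  category
}

#' Create a lexicon set
#'
#' A `lexicon_set` holds the six categorized term dictionaries together with
#' the provenance of every term: `core` (loaded from files),
#' `pattern_iteration` (accrued by [bootstrap()]), `body_part_assembly`
#' (compound terms from [assemble_enumeration()]) or `prefix_update`
#' (directional/extensional expansions).  A term may belong to several
#' categories; each (term, category) pair carries exactly one provenance tag,
#' and the first origin recorded for a pair wins.
#'
#' @param terms optional tibble with columns `term`, `category`, `origin`.
#' @return an object of class `lexicon_set`.
#' @seealso [load_lexica()], [add_term()], [lookup()]
#' @export
lexicon_set <- function(terms = NULL) {
  if (is.null(terms)) {
    terms <- tibble::tibble(term = character(), category = character(),
                            origin = character())
  }
  stopifnot(all(c("term", "category", "origin") %in% names(terms)))
  .check_category(unique(terms$category))
  if (any(terms$term == "" | is.na(terms$term)))
    stop("lexicon terms must be non-empty", call. = FALSE)
  if (any(stringi::stri_detect_fixed(terms$term, "\n")))
    stop("lexicon terms must not contain newlines", call. = FALSE)
  # first origin wins on duplicated (term, category)
  key <- paste(terms$term, terms$category, sep = "\r")
  terms <- terms[!duplicated(key), , drop = FALSE]
  structure(list(terms = tibble::as_tibble(terms)), class = "lexicon_set")
}

#' @export
print.lexicon_set <- function(x, ...) {
  cat("<lexicon_set>", nrow(x$terms), "terms\n")
  tab <- table(factor(x$terms$category, levels = lexicon_categories_all()))
  for (cat_ in names(tab)) cat(sprintf("  %-13s %d\n", cat_, tab[[cat_]]))
  invisible(x)
}

#' Load categorized lexica from term-per-line files
#'
#' Each file is UTF-8, one term per line; blank lines are skipped, duplicate
#' lines collapse, and leading/trailing whitespace is stripped.  All loaded
#' terms get provenance `core`.
#'
#' @param paths named character vector or list mapping category names (a
#'   subset of [lexicon_categories_all()]) to file paths.
#' @return a [lexicon_set()].
#' @export
load_lexica <- function(paths) {
  paths <- unlist(paths)
  .check_category(names(paths))
  rows <- lapply(names(paths), function(cat_) {
    path <- paths[[cat_]]
    if (!file.exists(path))
      stop("lexicon file for category '", cat_, "' not found: ", path,
           call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    ok <- stringi::stri_enc_isutf8(lines)
    if (!all(ok))
      stop("non-UTF-8 bytes in '", path, "' at line ", which(!ok)[1],
           call. = FALSE)
    lines <- stringi::stri_trim_both(lines)
    lines <- unique(lines[lines != ""])
    if (!length(lines)) return(NULL)
    tibble::tibble(term = lines, category = cat_, origin = "core")
  })
  lexicon_set(do.call(rbind, rows))
}

#' Persist a lexicon set to a directory
#'
#' Writes one `<category>.txt` file per non-empty category (term per line,
#' UTF-8, LF) plus a `provenance.tsv` with columns term, category, provenance.
#'
#' @param lex a [lexicon_set()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_lexica <- function(lex, dir) {
  stopifnot(inherits(lex, "lexicon_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cat_ in unique(lex$terms$category)) {
    terms <- sort(lex$terms$term[lex$terms$category == cat_])
    writeLines(terms, file.path(dir, paste0(cat_, ".txt")), useBytes = FALSE)
  }
  tsv <- lex$terms[order(lex$terms$category, lex$terms$term), ]
  writeLines(paste(tsv$term, tsv$category, tsv$origin, sep = "\t"),
             file.path(dir, "provenance.tsv"))
  invisible(dir)
}

#' Add a term to a lexicon set
#'
#' If the (term, category) pair already exists the set is returned unchanged
#' (the first provenance wins).
#'
#' @param lex a [lexicon_set()].
#' @param term non-empty term string(s).
#' @param category category for the term(s) (recycled).
#' @param origin provenance tag, one of core, pattern_iteration,
#'   body_part_assembly, prefix_update.
#' @return the updated [lexicon_set()].
#' @export
add_term <- function(lex, term, category, origin = "core") {
  stopifnot(inherits(lex, "lexicon_set"))
  if (!length(term)) return(lex)
  if (any(term == "" | is.na(term))) stop("term must be non-empty", call. = FALSE)
  .check_category(unique(category))
  stopifnot(all(origin %in% .PROVENANCE))
  new <- tibble::tibble(term = term, category = category, origin = origin)
  lexicon_set(rbind(lex$terms, new))  # first-wins dedup in constructor
}

#' Look up the categories containing a string
#'
#' Exact, case-sensitive membership over all six dictionaries.
#'
#' @param lex a [lexicon_set()].
#' @param s a string.
#' @return character vector of categories containing `s` (possibly empty).
#' @export
lookup <- function(lex, s) {
  stopifnot(inherits(lex, "lexicon_set"))
  if (!length(s) || is.na(s) || s == "") return(character())
  unique(lex$terms$category[lex$terms$term == s])
}

#' Test membership of a term in one category
#' @inheritParams lookup
#' @param category a category name.
#' @return `TRUE` if `s` is in that category's dictionary.
#' @export
lexicon_contains <- function(lex, s, category) {
  category %in% lookup(lex, s)
}

#' Terms of a lexicon set
#' @param lex a [lexicon_set()].
#' @param category optional category filter.
#' @return character vector of terms.
#' @export
lexicon_terms <- function(lex, category = NULL) {
  stopifnot(inherits(lex, "lexicon_set"))
  if (is.null(category)) return(unique(lex$terms$term))
  .check_category(category)
  unique(lex$terms$term[lex$terms$category %in% category])
}

#' Provenance table of a lexicon set
#' @param lex a [lexicon_set()].
#' @return tibble with columns term, category, origin.
#' @export
lexicon_provenance <- function(lex) {
  stopifnot(inherits(lex, "lexicon_set"))
  lex$terms
}

#' Number of (term, category) entries
#' @param lex a [lexicon_set()].
#' @return integer count.
#' @export
lexicon_size <- function(lex) nrow(lex$terms)

# Hashed term -> categories index for fast tagging.  Internal.
.lex_index <- function(lex, categories = lexicon_categories_all()) {
  sub <- lex$terms[lex$terms$category %in% categories, , drop = FALSE]
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(16L, nrow(sub)))
  if (nrow(sub)) {
    split_cats <- split(sub$category, sub$term)
    for (term in names(split_cats)) assign(term, split_cats[[term]], envir = env)
  }
  max_len <- if (nrow(sub)) max(stringi::stri_length(sub$term)) else 0L
  list(env = env, max_len = max_len)
}
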