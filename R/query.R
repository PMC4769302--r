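#' Parse a single search term
#'
#' Terms follow the stub syntax used for dictionary searches in primary care
#' databases:
#'
#' * word stubs match anywhere inside the description field: `"angin"`
#'   matches "Ludwig's angina" and "Head-banging";
#' * underscores build exact phrases: `"ischemic_cardiomyopathy"` searches
#'   for "ischemic cardiomyopathy";
#' * plus signs require several stubs within one description:
#'   `"alcohol+depend"` matches descriptions containing both "alcohol" and
#'   "depend";
#' * a leading dollar sign defines an exclusion: `"$hypersplenism"` removes
#'   any hit whose description contains "hypersplenism";
#' * code stubs are matched exactly as inputted, as case-sensitive prefixes
#'   of the code field: `"H33"` matches `H331.11` but not `8H33.00`.
#'
#' There is no escape syntax: `"$"` is only legal at position 0 of a word
#' term, and `"+"`/`"_"` are structural in word terms. In code terms all
#' characters are literal.
#'
#' @param raw The term as written, one per line in a term file.
#' @param kind_hint `"word"` for description searching, `"code"` for code
#'   prefix searching.
#' @return A `search_term`: list with `kind` (`"code_stub"`, `"word_query"`
#'   or `"exclusion"`), `stubs` (character vector of phrases that must all
#'   occur; a single element for code stubs and exclusions) and `raw`.
#' @export
parse_term <- function(raw, kind_hint = c("word", "code")) {
  kind_hint <- match.arg(kind_hint)
  trimmed <- trimws(raw)
  if (length(trimmed) != 1L || is.na(trimmed) || trimmed == "") {
    stop("empty search term", call. = FALSE)
  }
  if (kind_hint == "code") {
    return(new_search_term("code_stub", trimmed, trimmed))
  }
  if (startsWith(trimmed, "$")) {
    stub <- substring(trimmed, 2L)
    if (grepl("[$+]", stub)) {
      stop("invalid exclusion term (\"$\" and \"+\" only legal once, leading): ",
           trimmed, call. = FALSE)
    }
    stub <- gsub("_", " ", stub, fixed = TRUE)
    if (trimws(stub) == "") stop("exclusion term reduces to an empty stub: ",
                                 raw, call. = FALSE)
    return(new_search_term("exclusion", stub, trimmed))
  }
  if (grepl("$", trimmed, fixed = TRUE)) {
    stop("\"$\" is only legal at the start of a word term: ", trimmed,
         call. = FALSE)
  }
  parts <- strsplit(trimmed, "+", fixed = TRUE)[[1]]
  stubs <- gsub("_", " ", parts, fixed = TRUE)
  if (length(stubs) == 0L || any(trimws(stubs) == "")) {
    stop("word term reduces to an empty stub: ", raw, call. = FALSE)
  }
  new_search_term("word_query", stubs, trimmed)
}

new_search_term <- function(kind, stubs, raw) {
  structure(list(kind = kind, stubs = unname(stubs), raw = raw),
            class = "search_term")
}

#' @export
print.search_term <- function(x, ...) {
  cat(sprintf("<search_term:%s> %s -> [%s]\n", x$kind, x$raw,
              paste(x$stubs, collapse = " & ")))
  invisible(x)
}

#' Assemble a search query
#'
#' @param word_terms Character vector of word terms (stub syntax; `$`-terms
#'   become exclusions).
#' @param code_terms Character vector of code-prefix terms.
#' @return A `search_query` with elements `includes` and `excludes`, each a
#'   list of `search_term`.
#' @export
search_query <- function(word_terms = character(), code_terms = character()) {
  words <- lapply(word_terms, parse_term, kind_hint = "word")
  codes <- lapply(code_terms, parse_term, kind_hint = "code")
  includes <- c(codes, Filter(function(t) t$kind != "exclusion", words))
  excludes <- Filter(function(t) t$kind == "exclusion", words)
  if (length(includes) == 0L) {
    stop("no inclusion terms: a query of only exclusions is invalid",
         call. = FALSE)
  }
  structure(list(includes = includes, excludes = excludes),
            class = "search_query")
}

#' @export
print.search_query <- function(x, ...) {
  cat(sprintf("<search_query> %d include term(s), %d exclusion(s)\n",
              length(x$includes), length(x$excludes)))
  for (t in x$includes) cat("  + ", t$raw, " [", t$kind, "]\n", sep = "")
  for (t in x$excludes) cat("  - ", t$raw, "\n", sep = "")
  invisible(x)
}

#' Read a term file into a search query
#'
#' Plain text, one term per line; blank lines and lines starting `#` are
#' ignored. Word terms and code stubs live in separate files (mirroring the
#' usual split into code stubs lifted from QOF business rules and word stubs
#' suggested by clinicians).
#'
#' @param word_file,code_file Paths; either may be `NULL`.
#' @return A `search_query`.
#' @export
read_terms <- function(word_file = NULL, code_file = NULL) {
  read_one <- function(path) {
    if (is.null(path)) return(character())
    if (!file.exists(path)) stop("term file not found: ", path, call. = FALSE)
    lines <- trimws(readLines(path, warn = FALSE))
    lines[lines != "" & !startsWith(lines, "#")]
  }
  search_query(word_terms = read_one(word_file), code_terms = read_one(code_file))
}

#' Does a term match a description?
#'
#' A `word_query` matches iff every stub occurs as a contiguous substring of
#' the description; an `exclusion` matches iff its single stub occurs.
#' Matching is case-insensitive by default (the inclusive, sensitivity-first
#' intent of stub searching argues against missing case variants); set
#' `case_sensitive = TRUE` for exact-case matching. No other normalisation
#' is applied: hyphens, apostrophes and internal whitespace are compared
#' literally, which is why `"angin"` matches "Head-banging".
#'
#' @param term A `search_term` of kind `word_query` or `exclusion`.
#' @param description Character vector of descriptions.
#' @param case_sensitive Logical flag.
#' @return Logical vector, one element per description.
#' @export
match_description <- function(term, description, case_sensitive = FALSE) {
  stopifnot(inherits(term, "search_term"), term$kind != "code_stub")
  hay <- if (case_sensitive) description else tolower(description)
  out <- rep(TRUE, length(description))
  for (stub in term$stubs) {
    needle <- if (case_sensitive) stub else tolower(stub)
    out <- out & grepl(needle, hay, fixed = TRUE)
  }
  out & !is.na(description)
}

#' Does a code stub match a code?
#'
#' Code stubs are matched exactly as inputted, at the start of the code
#' field, case-sensitively and with no wildcard expansion — the prefix
#' semantics of a hierarchical coding system, where a prefix search is a
#' subtree search. `"H33"` matches `H331.11` (Late onset asthma) but not
#' `8H33.00` (Day hospital care).
#'
#' @param stub Non-empty code prefix.
#' @param code Character vector of codes.
#' @return Logical vector.
#' @export
match_code_prefix <- function(stub, code) {
  stopifnot(is.character(stub), length(stub) == 1L, nzchar(stub))
  startsWith(code, stub)
}

term_matches <- function(term, table, case_sensitive) {
  if (term$kind == "code_stub") {
    match_code_prefix(term$stubs[[1]], table$code)
  } else {
    match_description(term, table$description, case_sensitive = case_sensitive)
  }
}

#' Run a search query against a lookup table
#'
#' Hits are the entries matched by at least one inclusion term, minus every
#' entry whose description contains any exclusion stub. Exclusions apply to
#' the whole hit set, including hits found via code stubs: exclusions exist
#' to cut false positives from the list put in front of reviewers, so they
#' are applied last. Hits are sorted by (code, description, row_id) for
#' reproducible diffs between runs.
#'
#' @param query A `search_query`.
#' @param table A `lookup_table`.
#' @param case_sensitive Case sensitivity for description matching
#'   (default insensitive; code matching is always case-sensitive).
#' @return A `search_result`: tibble with the hit rows (`row_id`, `code`,
#'   `description`, `source`) plus `matched_terms`, a list-column holding
#'   the raw strings of the inclusion terms each hit matched. Attributes
#'   `query`, `lookup_source` and `case_sensitive` record provenance.
#' @examples
#' tab <- lookup_table(c("J083300", "E273100"),
#'                     c("Ludwig's angina", "Head-banging"))
#' run_search(search_query("angin"), tab)
#' @export
run_search <- function(query, table, case_sensitive = FALSE) {
  stopifnot(inherits(query, "search_query"), inherits(table, "lookup_table"))
  if (length(query$includes) == 0L) stop("no inclusion terms", call. = FALSE)
  inc <- vapply(query$includes, term_matches, logical(nrow(table)),
                table = table, case_sensitive = case_sensitive)
  inc <- matrix(inc, nrow = nrow(table))
  hit <- rowSums(inc) > 0
  for (term in query$excludes) {
    hit <- hit & !match_description(term, table$description,
                                    case_sensitive = case_sensitive)
  }
  res <- tibble::as_tibble(table)[hit, , drop = FALSE]
  raws <- vapply(query$includes, function(t) t$raw, character(1))
  res$matched_terms <- lapply(which(hit), function(i) raws[inc[i, ]])
  ord <- order(res$code, res$description, res$row_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  structure(res, class = c("search_result", class(tibble::tibble())),
            query = query, lookup_source = attr(table, "source"),
            case_sensitive = case_sensitive)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d hit(s) from the %s table\n",
              nrow(x), attr(x, "lookup_source") %||% "?"))
  show <- tibble::as_tibble(x)
  show$matched_terms <- vapply(show$matched_terms, paste, character(1),
                               collapse = ";")
  print(show, ...)
  invisible(x)
}

#' Write search hits to delimited text
#'
#' Columns: code, description, source, matched_terms (semicolon-joined).
#'
#' @param result A `search_result`.
#' @param path Output path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_search_result <- function(result, path, delimiter = c("comma", "tab")) {
  stopifnot(inherits(result, "search_result"))
  delimiter <- match.arg(delimiter)
  out <- tibble::tibble(
    code = result$code, description = result$description,
    source = result$source,
    matched_terms = vapply(result$matched_terms, paste, character(1),
                           collapse = ";"))
  readr::write_delim(out, path, delim = if (delimiter == "comma") "," else "\t")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
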