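# Category vocabulary for expert review. Fixed so that typos in hand-edited
# review files are rejected at ingest rather than silently dropped.
REVIEW_CATEGORIES <- c("diagnosis", "management_or_symptom", "drug",
                       "complication", "screening", "history_or_resolved",
                       "other", "not_relevant")

CODELIST_TIERS <- c("qof", "conservative", "speculative")

#' Build a review template from search hits
#'
#' The inclusive hit list from a stub search is deliberately high-
#' sensitivity and carries many false positives (searching for "stroke"
#' also returns "sunstroke"); an expert panel reviews it and assigns each
#' row a category. This function exports that review sheet: one row per hit
#' with an empty `category` and `reviewer_note` to fill in.
#'
#' @param result A non-empty `search_result`.
#' @return A `review_template` tibble with columns `code`, `description`,
#'   `source`, `matched_terms` (semicolon-joined), `category`,
#'   `reviewer_note`, in the result's (code, description, row_id) order.
#' @export
make_review_template <- function(result) {
  stopifnot(inherits(result, "search_result"))
  if (nrow(result) == 0L) {
    stop("search returned no hits; broaden the query before review",
         call. = FALSE)
  }
  out <- tibble::tibble(
    code = result$code,
    description = result$description,
    source = result$source,
    matched_terms = vapply(result$matched_terms, paste, character(1),
                           collapse = ";"),
    category = "",
    reviewer_note = "")
  structure(out, class = c("review_template", class(tibble::tibble())))
}

#' Write or read a review template
#'
#' Delimited text with header (code, description, source, matched_terms,
#' category, reviewer_note) — the layout a code-list repository deposit
#' expects. Export then ingest with no edits reproduces the template
#' exactly, and re-export after partial labelling preserves existing
#' labels.
#'
#' @param template A `review_template` (possibly partially labelled).
#' @param path File path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return `path` invisibly for the writer; a `review_template` for the reader.
#' @export
write_review_template <- function(template, path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  stopifnot(all(c("code", "description", "source", "matched_terms",
                  "category", "reviewer_note") %in% names(template)))
  readr::write_delim(tibble::as_tibble(template)[, c(
    "code", "description", "source", "matched_terms", "category",
    "reviewer_note")], path, delim = if (delimiter == "comma") "," else "\t")
  invisible(path)
}

#' @rdname write_review_template
#' @export
read_review_template <- function(path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("review file not found: ", path, call. = FALSE)
  df <- readr::read_delim(I(read_text_utf8(path)),
                          delim = if (delimiter == "comma") "," else "\t",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  need <- c("code", "description", "source", "matched_terms", "category",
            "reviewer_note")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("review file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  for (col in need) df[[col]][is.na(df[[col]])] <- ""
  bad <- setdiff(unique(df$category), c("", REVIEW_CATEGORIES))
  if (length(bad) > 0) {
    stop("unknown review categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "),
         "\n  allowed: ", paste(REVIEW_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  structure(df, class = c("review_template", class(tibble::tibble())))
}

#' Build a tiered code list from reviewed rows
#'
#' Keeps the rows whose category the tier's policy admits; every row must
#' carry a category (an unreviewed sheet is an error, listing the offending
#' codes). Rows labelled `not_relevant` are never included regardless of
#' policy. Duplicate codes are collapsed to their first-seen category and
#' each conflict is reported via a warning.
#'
#' The conservative tier admits only `diagnosis` by default: each code on a
#' conservative list must indicate the condition of interest and that
#' alone. The admitted set is configurable because some conditions have
#' definitive non-diagnosis codes — a product prescribed exclusively for
#' one condition (insulin for diabetes, say) can be promoted.
#'
#' @param rows A reviewed `review_template` (every `category` non-empty).
#' @param tier `"qof"`, `"conservative"` or `"speculative"`.
#' @param category_policy Categories admitted to this tier.
#' @param name List name, recorded in the result.
#' @param provenance Optional named list of free-text metadata (term-file
#'   hash, lookup identity, date); recorded verbatim to keep the list
#'   replicable.
#' @return A `codelist`: tibble of unique (`code`, `category`) pairs with
#'   attributes `name`, `tier`, `provenance`.
#' @export
build_codelist <- function(rows, tier = c("conservative", "qof", "speculative"),
                           category_policy = "diagnosis",
                           name = "codelist", provenance = list()) {
  tier <- match.arg(tier)
  stopifnot(all(c("code", "category") %in% names(rows)))
  unreviewed <- rows$code[is.na(rows$category) | rows$category == ""]
  if (length(unreviewed) > 0) {
    stop("unreviewed rows (empty category) for code(s): ",
         paste(unique(unreviewed), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(rows$category), REVIEW_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  category_policy <- setdiff(category_policy, "not_relevant")
  keep <- rows[rows$category %in% category_policy, c("code", "category")]
  conflict <- unique(keep$code[duplicated(keep$code) &
                                 !duplicated(paste0(keep$code, "\r", keep$category))])
  dup_conflicts <- keep$code %in% conflict
  if (any(dup_conflicts)) {
    warning("code(s) labelled with conflicting categories; first label kept: ",
            paste(unique(keep$code[dup_conflicts]), collapse = ", "),
            call. = FALSE)
  }
  entries <- keep[!duplicated(keep$code), , drop = FALSE]
  if (nrow(entries) == 0L) {
    warning("no reviewed rows fall within the admitted categories (",
            paste(category_policy, collapse = ", "), "); code list '", name,
            "' is empty", call. = FALSE)
  }
  new_codelist(entries, name = name, tier = tier, provenance = provenance)
}

new_codelist <- function(entries, name, tier, provenance = list()) {
  stopifnot(tier %in% CODELIST_TIERS,
            all(c("code", "category") %in% names(entries)))
  if (anyDuplicated(entries$code)) stop("codes must be unique within a code list")
  provenance$built_at <- provenance$built_at %||% format(Sys.time(), "%Y-%m-%d")
  structure(tibble::as_tibble(entries[, c("code", "category")]),
            class = c("codelist", class(tibble::tibble())),
            name = name, tier = tier, provenance = provenance)
}

#' Construct a code list directly from codes
#'
#' Convenience constructor for lists whose categories are already known
#' (e.g. a QOF business-rules list, where every code is definitional).
#'
#' @param code Character vector of unique codes.
#' @param category Single category or vector matching `code`.
#' @inheritParams build_codelist
#' @export
codelist <- function(code, category = "diagnosis", name = "codelist",
                     tier = c("conservative", "qof", "speculative"),
                     provenance = list()) {
  tier <- match.arg(tier)
  new_codelist(tibble::tibble(code = as.character(code),
                              category = rep_len(category, length(code))),
               name = name, tier = tier, provenance = provenance)
}

#' @export
print.codelist <- function(x, ...) {
  cat(sprintf("<codelist> '%s' (%s tier): %d codes\n",
              attr(x, "name"), attr(x, "tier"), nrow(x)))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Codes carried by a code list
#' @param x A `codelist`.
#' @return Character vector of codes.
#' @export
codelist_codes <- function(x) {
  stopifnot(inherits(x, "codelist"))
  x$code
}

#' Check the tier superset relations
#'
#' A conservative code list should be a superset of the matching QOF list —
#' except for QOF exception-reporting codes, which mark a patient as
#' unsuitable for the quality indicators rather than as having the
#' condition — and a speculative (sensitivity) list should be a superset of
#' the conservative one. Supersets are non-strict; violations are report
#' content, not exceptions, because the relations are normative rather than
#' mechanical.
#'
#' @param qof,conservative,speculative `codelist`s (QOF may be `NULL` when
#'   no QOF register exists for the condition).
#' @param qof_exception_codes Codes excused from the QOF ⊆ conservative
#'   check. How exception codes are flagged inside business-rule files
#'   varies, so they are taken as an explicit set.
#' @return A `superset_report`: list with `pass` (logical),
#'   `missing_from_conservative` and `missing_from_speculative`
#'   (sorted character vectors of violating codes).
#' @export
check_supersets <- function(qof = NULL, conservative, speculative,
                            qof_exception_codes = character()) {
  stopifnot(inherits(conservative, "codelist"), inherits(speculative, "codelist"))
  miss_cons <- character()
  if (!is.null(qof)) {
    stopifnot(inherits(qof, "codelist"))
    miss_cons <- sort(setdiff(setdiff(qof$code, qof_exception_codes),
                              conservative$code))
  }
  miss_spec <- sort(setdiff(conservative$code, speculative$code))
  structure(list(pass = length(miss_cons) == 0L && length(miss_spec) == 0L,
                 missing_from_conservative = miss_cons,
                 missing_from_speculative = miss_spec),
            class = "superset_report")
}

#' @export
print.superset_report <- function(x, ...) {
  cat("<superset_report> ", if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  if (length(x$missing_from_conservative))
    cat("  QOF codes missing from conservative list: ",
        paste(x$missing_from_conservative, collapse = ", "), "\n", sep = "")
  if (length(x$missing_from_speculative))
    cat("  conservative codes missing from speculative list: ",
        paste(x$missing_from_speculative, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Merge code lists
#'
#' Union of entries; where the same code carries different categories the
#' first list's label wins and the conflict is warned about, as in
#' [build_codelist()]. Provenance is concatenated.
#'
#' @param lists A list of `codelist` objects (at least one).
#' @param name,tier Name and tier for the merged list.
#' @return A `codelist`.
#' @export
merge_codelists <- function(lists, name = "merged",
                            tier = c("speculative", "conservative", "qof")) {
  tier <- match.arg(tier)
  stopifnot(length(lists) >= 1L,
            all(vapply(lists, inherits, logical(1), "codelist")))
  all_entries <- do.call(rbind, lapply(lists, tibble::as_tibble))
  conflict <- all_entries$code[duplicated(all_entries$code) &
                                 !duplicated(paste0(all_entries$code, "\r",
                                                    all_entries$category))]
  if (length(conflict) > 0) {
    warning("conflicting categories on merge; first-seen kept: ",
            paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  entries <- all_entries[!duplicated(all_entries$code), , drop = FALSE]
  prov <- list(merged_from = vapply(lists, attr, character(1), "name"))
  new_codelist(entries, name = name, tier = tier, provenance = prov)
}

#' Write or read a code list
#'
#' Delimited text with header (code, category).
#'
#' @param x A `codelist`.
#' @param path File path.
#' @param delimiter `"comma"` or `"tab"`.
#' @inheritParams codelist
#' @export
write_codelist <- function(x, path, delimiter = c("comma", "tab")) {
  stopifnot(inherits(x, "codelist"))
  delimiter <- match.arg(delimiter)
  readr::write_delim(tibble::as_tibble(x), path,
                     delim = if (delimiter == "comma") "," else "\t")
  invisible(path)
}

#' @rdname write_codelist
#' @export
read_codelist <- function(path, name = basename(path),
                          tier = c("conservative", "qof", "speculative"),
                          delimiter = c("comma", "tab")) {
  tier <- match.arg(tier)
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("code list file not found: ", path, call. = FALSE)
  df <- readr::read_delim(I(read_text_utf8(path)),
                          delim = if (delimiter == "comma") "," else "\t",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  if (!all(c("code", "category") %in% names(df))) {
    stop("code list file needs columns code, category: ", path, call. = FALSE)
  }
  new_codelist(df[, c("code", "category")], name = name, tier = tier)
}
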