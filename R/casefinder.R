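#' Read a patient event table
#'
#' Delimited text with header columns `patient_id`, `event_date` (ISO-8601),
#' `code` and optionally `table` (`"clinical"` or `"referral"`; defaults to
#' clinical). Clinical and referral extracts are concatenated before case
#' finding, so both may be read and row-bound. Unparseable dates are
#' rejected at read time, never silently dropped.
#'
#' @param path File path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return A tibble (`patient_id`, `event_date` as `Date`, `code`, `table`).
#' @export
read_events <- function(path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  df <- readr::read_delim(I(read_text_utf8(path)),
                          delim = if (delimiter == "comma") "," else "\t",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  need <- c("patient_id", "event_date", "code")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("event file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"table" %in% names(df)) df$table <- "clinical"
  patient_events(df$patient_id, df$event_date, df$code, df$table)
}

#' Construct a patient event table from vectors
#'
#' @param patient_id Character vector (non-empty strings).
#' @param event_date `Date` vector or ISO-8601 strings.
#' @param code Character vector of clinical/product codes.
#' @param table `"clinical"` or `"referral"`, recycled.
#' @return A tibble of events.
#' @export
patient_events <- function(patient_id, event_date, code, table = "clinical") {
  patient_id <- as.character(patient_id)
  if (any(is.na(patient_id) | patient_id == "")) {
    stop("patient_id must be non-empty", call. = FALSE)
  }
  dates <- parse_iso_date(event_date, what = "event_date")
  table <- rep_len(as.character(table), length(patient_id))
  bad_tab <- setdiff(unique(table), c("clinical", "referral"))
  if (length(bad_tab) > 0) {
    stop("unknown event table type(s): ", paste(bad_tab, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(patient_id = patient_id, event_date = dates,
                 code = as.character(code), table = table)
}

parse_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & x != "")
  if (length(bad) > 0) {
    stop("unparseable ", what, " value(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (expected ISO-8601 YYYY-MM-DD)", call. = FALSE)
  }
  d
}

#' Flag cases in patient event data with a code list
#'
#' A patient is a case iff their events carry at least `min_codes` codes
#' from the list. One qualifying code is enough by default, since a patient
#' with a chronic condition typically accrues many such codes; requiring
#' two or more is a stricter criterion that protects against misdiagnoses
#' and recording errors. Occurrences are counted per event row, so the same
#' code on different dates counts separately; set `distinct_dates = TRUE`
#' to count distinct event dates instead, which guards against same-day
#' duplicate entries.
#'
#' Matching between event codes and the list is exact string equality —
#' prefix logic belongs to dictionary searching, not case finding. Events
#' whose codes appear in no dictionary are permitted and simply never
#' match. Onset is dated to the first qualifying event.
#'
#' @param events Event tibble from [read_events()] / [patient_events()]
#'   (clinical and referral rows may be row-bound).
#' @param list A non-empty `codelist`.
#' @param min_codes Minimum number of qualifying events (>= 1).
#' @param distinct_dates Count distinct event dates rather than occurrences.
#' @return A `case_records` tibble sorted by `patient_id`:
#'   `patient_id`, `first_event_date`, `n_matching_events`,
#'   `matched_codes` (list-column of the distinct codes seen).
#' @export
find_cases <- function(events, list, min_codes = 1L, distinct_dates = FALSE) {
  stopifnot(inherits(list, "codelist"))
  if (nrow(list) == 0L) stop("empty code list", call. = FALSE)
  if (!is.numeric(min_codes) || min_codes < 1) {
    stop("min_codes must be a positive integer", call. = FALSE)
  }
  need <- c("patient_id", "event_date", "code")
  stopifnot(all(need %in% names(events)))
  if (nrow(events) == 0L) return(empty_case_records(min_codes))
  m <- events[events$code %in% list$code, need]
  if (nrow(m) == 0L) return(empty_case_records(min_codes))
  grp <- split(m, m$patient_id)
  recs <- lapply(grp, function(g) {
    n <- if (distinct_dates) length(unique(g$event_date)) else nrow(g)
    tibble::tibble(patient_id = g$patient_id[[1]],
                   first_event_date = min(g$event_date),
                   n_matching_events = n,
                   matched_codes = list(sort(unique(g$code))))
  })
  out <- do.call(rbind, recs)
  out <- out[out$n_matching_events >= min_codes, , drop = FALSE]
  out <- out[order(out$patient_id, method = "radix"), , drop = FALSE]
  structure(out, class = c("case_records", class(tibble::tibble())),
            min_codes = as.integer(min_codes))
}

empty_case_records <- function(min_codes) {
  structure(tibble::tibble(patient_id = character(),
                           first_event_date = as.Date(character()),
                           n_matching_events = integer(),
                           matched_codes = list()),
            class = c("case_records", class(tibble::tibble())),
            min_codes = as.integer(min_codes))
}

#' @export
print.case_records <- function(x, ...) {
  cat(sprintf("<case_records> %d case(s) (min_codes = %d)\n", nrow(x),
              attr(x, "min_codes") %||% 1L))
  show <- tibble::as_tibble(x)
  show$matched_codes <- vapply(show$matched_codes, paste, character(1),
                               collapse = ";")
  print(show, ...)
  invisible(x)
}

#' Write case records to delimited text
#'
#' Columns: patient_id, first_event_date, n_matching_events,
#' matched_codes (semicolon-joined).
#'
#' @param cases A `case_records` tibble.
#' @param path Output path.
#' @param delimiter `"comma"` or `"tab"`.
#' @export
write_cases <- function(cases, path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  out <- tibble::tibble(
    patient_id = cases$patient_id,
    first_event_date = format(cases$first_event_date, "%Y-%m-%d"),
    n_matching_events = cases$n_matching_events,
    matched_codes = vapply(cases$matched_codes, paste, character(1),
                           collapse = ";"))
  readr::write_delim(out, path, delim = if (delimiter == "comma") "," else "\t")
  invisible(path)
}

#' Read case records written by [write_cases()]
#'
#' @param path File path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return A `case_records` tibble.
#' @export
read_cases <- function(path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  df <- readr::read_delim(I(read_text_utf8(path)),
                          delim = if (delimiter == "comma") "," else "\t",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  need <- c("patient_id", "first_event_date", "n_matching_events",
            "matched_codes")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("case file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = df$patient_id,
    first_event_date = parse_iso_date(df$first_event_date, "first_event_date"),
    n_matching_events = as.integer(df$n_matching_events),
    matched_codes = strsplit(df$matched_codes, ";", fixed = TRUE))
  structure(out, class = c("case_records", class(tibble::tibble())),
            min_codes = NA_integer_)
}

#' Compare two case sets built from the same event table
#'
#' Summarises how two case definitions (say, a QOF register versus a
#' conservative code list) disagree: counts of patients flagged by A only,
#' by B only, and by both, plus the difference in onset dates for shared
#' patients.
#'
#' @param cases_a,cases_b `case_records` built against the same events.
#' @return A `case_comparison`: list with `n_a_only`, `n_b_only`, `n_both`
#'   and `onset_diff_days`, a tibble (`patient_id`, `diff_days` =
#'   A's onset minus B's onset, in days) over the shared patients.
#' @export
compare_case_sets <- function(cases_a, cases_b) {
  a <- cases_a$patient_id
  b <- cases_b$patient_id
  shared <- intersect(a, b)
  ia <- match(shared, a)
  ib <- match(shared, b)
  diffs <- tibble::tibble(
    patient_id = shared,
    diff_days = as.numeric(cases_a$first_event_date[ia] -
                             cases_b$first_event_date[ib]))
  structure(list(n_a_only = length(setdiff(a, b)),
                 n_b_only = length(setdiff(b, a)),
                 n_both = length(shared),
                 onset_diff_days = diffs),
            class = "case_comparison")
}

#' @export
print.case_comparison <- function(x, ...) {
  cat(sprintf("<case_comparison> A only: %d | B only: %d | both: %d\n",
              x$n_a_only, x$n_b_only, x$n_both))
  if (nrow(x$onset_diff_days) > 0) {
    cat(sprintf("  onset difference (A - B), days: median %.0f, range [%d, %d]\n",
                stats::median(x$onset_diff_days$diff_days),
                min(x$onset_diff_days$diff_days),
                max(x$onset_diff_days$diff_days)))
  }
  invisible(x)
}
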