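#' Read a clinical or product lookup table
#'
#' Reads a delimited-text dictionary of clinical codes or products (e.g. a
#' CPRD medical or product dictionary export) into a `lookup_table`. The
#' logical fields `code` and `description` are mapped onto input columns by
#' name, so any two-column-or-wider layout works.
#'
#' Codes are trimmed of surrounding whitespace but never case-folded or
#' otherwise normalised: Read codes are case-significant and prefix-
#' significant. Descriptions are kept verbatim; matching semantics live
#' entirely in the query functions.
#'
#' Files are decoded as UTF-8; if any line is not valid UTF-8 the whole file
#' is re-decoded as Latin-1 (legacy dictionary exports) and a message is
#' emitted. The delimiter is explicit, never sniffed.
#'
#' @param path Path to a delimited text file with a header row.
#' @param source Either `"clinical"` or `"product"`.
#' @param column_map Named character vector mapping the logical fields to
#'   input column names, e.g. `c(code = "readcode", description = "desc")`.
#'   Must name both `code` and `description`.
#' @param delimiter `"comma"` or `"tab"`.
#' @return A `lookup_table`: a tibble with columns `row_id` (integer
#'   surrogate key in file order), `code`, `description` and `source`, plus
#'   attributes `source` and `column_map`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("readcode,desc",
#'              "H331.11,Late onset asthma",
#'              "8H33.00,Day hospital care"), f)
#' read_lookup(f, "clinical", c(code = "readcode", description = "desc"))
#' @export
read_lookup <- function(path, source = c("clinical", "product"),
                        column_map = c(code = "code", description = "description"),
                        delimiter = c("comma", "tab")) {
  source <- match.arg(source)
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) {
    stop("lookup file not found: ", path, call. = FALSE)
  }
  if (!all(c("code", "description") %in% names(column_map))) {
    stop("column_map must name both 'code' and 'description'", call. = FALSE)
  }
  txt <- read_text_utf8(path)
  delim <- if (delimiter == "comma") "," else "\t"
  raw <- readr::read_delim(I(txt), delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(column_map[c("code", "description")]), names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    stop("lookup file has zero data rows: ", path, call. = FALSE)
  }
  code <- trimws(raw[[column_map[["code"]]]])
  desc <- raw[[column_map[["description"]]]]
  desc[is.na(desc)] <- ""
  code[is.na(code)] <- ""
  if (any(code == "")) {
    stop("empty code(s) at data row(s): ",
         paste(utils::head(which(code == ""), 5L), collapse = ", "), call. = FALSE)
  }
  new_lookup_table(
    tibble::tibble(row_id = seq_along(code), code = code,
                   description = desc, source = source),
    source = source, column_map = column_map
  )
}

new_lookup_table <- function(df, source, column_map = NULL) {
  stopifnot(all(c("row_id", "code", "description", "source") %in% names(df)))
  if (anyDuplicated(df$row_id)) stop("row_id must be unique within a lookup table")
  structure(df, class = c("lookup_table", class(tibble::as_tibble(df))),
            source = source, column_map = column_map)
}

#' Construct a lookup table from vectors
#'
#' In-memory constructor used by the synthetic-data generator and by tests;
#' applies the same trimming rules as [read_lookup()].
#'
#' @param code Character vector of codes.
#' @param description Character vector of descriptions (recycled empty string
#'   for `NA`).
#' @param source `"clinical"` or `"product"`.
#' @return A `lookup_table`.
#' @export
lookup_table <- function(code, description, source = c("clinical", "product")) {
  source <- match.arg(source)
  code <- trimws(as.character(code))
  description <- as.character(description)
  description[is.na(description)] <- ""
  if (any(is.na(code) | code == "")) stop("codes must be non-empty", call. = FALSE)
  new_lookup_table(
    tibble::tibble(row_id = seq_along(code), code = code,
                   description = description, source = source),
    source = source
  )
}

#' @export
print.lookup_table <- function(x, ...) {
  cat(sprintf("<lookup_table> %d %s codes\n", nrow(x), attr(x, "source")))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Validate a lookup table
#'
#' Purely informational checks: counts of empty descriptions, duplicate
#' codes, duplicate (code, description) pairs and codes that required
#' whitespace trimming at read time cannot be detected post hoc, so the
#' report covers what the table itself can show. Never mutates the table.
#'
#' @param table A `lookup_table`.
#' @return A list of class `lookup_validation` with counts
#'   `n_rows`, `n_empty_description`, `n_duplicate_codes` (rows beyond the
#'   first occurrence of each code) and `n_duplicate_pairs` (rows duplicating
#'   an earlier (code, description) pair), plus `anomalies`, their total.
#' @export
validate_lookup <- function(table) {
  stopifnot(inherits(table, "lookup_table"))
  dup_codes <- sum(duplicated(table$code))
  dup_pairs <- sum(duplicated(paste0(table$code, "\r", table$description)))
  rep <- list(
    n_rows = nrow(table),
    n_empty_description = sum(table$description == ""),
    n_duplicate_codes = dup_codes,
    n_duplicate_pairs = dup_pairs
  )
  rep$anomalies <- rep$n_empty_description + dup_codes + dup_pairs
  structure(rep, class = "lookup_validation")
}

#' @export
print.lookup_validation <- function(x, ...) {
  cat(sprintf(
    "<lookup_validation> %d rows | empty descriptions: %d | duplicate codes: %d | duplicate (code, description) pairs: %d\n",
    x$n_rows, x$n_empty_description, x$n_duplicate_codes, x$n_duplicate_pairs))
  invisible(x)
}

#' Write a lookup table back to delimited text
#'
#' Round-trip companion to [read_lookup()]: writing then re-reading
#' reproduces (code, description, source) exactly.
#'
#' @param table A `lookup_table`.
#' @param path Output file path.
#' @param delimiter `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_lookup <- function(table, path, delimiter = c("comma", "tab")) {
  stopifnot(inherits(table, "lookup_table"))
  delimiter <- match.arg(delimiter)
  out <- tibble::tibble(code = table$code, description = table$description)
  readr::write_delim(out, path, delim = if (delimiter == "comma") "," else "\t")
  invisible(path)
}

# Decode a file as UTF-8, falling back to Latin-1 when any line carries
# invalid UTF-8 bytes (legacy exports). Returns a single string.
read_text_utf8 <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "bytes")
  if (!all(validUTF8(lines))) {
    message("file is not valid UTF-8; falling back to Latin-1: ", path)
    lines <- iconv(lines, from = "latin1", to = "UTF-8")
  } else {
    Encoding(lines) <- "UTF-8"
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
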