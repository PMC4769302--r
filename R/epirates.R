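#' UK financial year of a date
#'
#' QOF registers and primary-care rate reporting run on the UK financial
#' year, 1 April through 31 March. Dates from 1 April of year Y through
#' 31 March of year Y+1 map to the label `"Y/Y+1"` in its two-digit form,
#' e.g. `2000-04-01` and `2001-03-31` both map to `"2000/01"`.
#'
#' @param d A `Date` vector (or ISO-8601 strings).
#' @return Character vector of labels like `"2000/01"`.
#' @export
financial_year <- function(d) {
  d <- parse_iso_date(d)
  y <- as.integer(format(d, "%Y"))
  m <- as.integer(format(d, "%m"))
  start <- ifelse(m >= 4L, y, y - 1L)
  financial_year_label(start)
}

financial_year_label <- function(start_year) {
  sprintf("%d/%02d", start_year, (start_year + 1L) %% 100L)
}

fy_start <- function(start_year) as.Date(sprintf("%d-04-01", start_year))
fy_end <- function(start_year) as.Date(sprintf("%d-03-31", start_year + 1L))

#' Read or construct a registration table
#'
#' One registration interval per patient (multi-spell registration is out
#' of scope); `reg_end` may be blank/`NA` for patients still registered.
#'
#' @param path Delimited text with header columns `patient_id`, `sex`
#'   (`male`/`female`/`unknown`), `reg_start`, `reg_end` (ISO-8601;
#'   `reg_end` blank means open).
#' @param delimiter `"comma"` or `"tab"`.
#' @return A tibble (`patient_id`, `sex`, `reg_start`, `reg_end`).
#' @export
read_registrations <- function(path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("registration file not found: ", path, call. = FALSE)
  df <- readr::read_delim(I(read_text_utf8(path)),
                          delim = if (delimiter == "comma") "," else "\t",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  need <- c("patient_id", "sex", "reg_start", "reg_end")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("registration file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  registrations(df$patient_id, df$sex, df$reg_start, df$reg_end)
}

#' @rdname read_registrations
#' @param patient_id,sex,reg_start,reg_end Vectors, one element per patient.
#' @export
registrations <- function(patient_id, sex, reg_start, reg_end = NA) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) {
    stop("one registration interval per patient; duplicated patient_id(s): ",
         paste(utils::head(unique(patient_id[duplicated(patient_id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  sex <- as.character(sex)
  bad_sex <- setdiff(unique(sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    stop("sex must be male/female/unknown; got: ",
         paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  start <- parse_iso_date(reg_start, "reg_start")
  end <- parse_iso_date(ifelse(is.na(reg_end) | reg_end == "", NA, as.character(reg_end)),
                        "reg_end")
  if (any(!is.na(end) & end < start)) {
    stop("reg_end precedes reg_start for patient(s): ",
         paste(utils::head(patient_id[!is.na(end) & end < start], 5L),
               collapse = ", "), call. = FALSE)
  }
  tibble::tibble(patient_id = patient_id, sex = sex,
                 reg_start = start, reg_end = end)
}

# registration interval overlaps the financial year [start, end]
reg_overlaps <- function(regs, year_start, year_end) {
  regs$reg_start <= year_end & (is.na(regs$reg_end) | regs$reg_end >= year_start)
}

rate_strata <- function(regs, by_sex) {
  if (by_sex) c("all", intersect(c("male", "female", "unknown"),
                                 unique(regs$sex))) else "all"
}

#' Annual prevalence by financial year
#'
#' For each financial year the denominator is the count of patients whose
#' registration interval overlaps the year; the numerator counts those who
#' are cases with a first qualifying event on or before the last day of the
#' year. The rate is the exact ratio; a zero denominator yields an `NA`
#' rate, never a silent zero. The any-overlap denominator is the simplest
#' defensible population definition — a person-years alternative is a noted
#' extension point, not implemented here.
#'
#' @param cases A `case_records` tibble (see [find_cases()]).
#' @param regs A registration tibble (see [registrations()]). Every case
#'   patient must be present, or an error lists the missing ids.
#' @param years Integer vector of financial-year start years, e.g.
#'   `2000:2011` for 2000/01 through 2011/12.
#' @param by_sex Also compute male/female/unknown strata.
#' @return A `rate_table`: tibble with `financial_year`, `stratum`,
#'   `numerator`, `denominator`, `rate` (proportion; `NA` when the
#'   denominator is zero) and attribute `measure`.
#' @export
prevalence <- function(cases, regs, years, by_sex = FALSE) {
  check_cases_registered(cases, regs)
  first_event <- case_first_event(cases, regs)
  rows <- lapply(sort(unique(as.integer(years))), function(y) {
    ys <- fy_start(y); ye <- fy_end(y)
    in_denom <- reg_overlaps(regs, ys, ye)
    in_numer <- in_denom & !is.na(first_event) & first_event <= ye
    stratum_rows(regs, in_numer, in_denom, y, by_sex)
  })
  new_rate_table(do.call(rbind, rows), measure = "prevalence")
}

#' Annual incidence by financial year
#'
#' For each financial year the numerator counts patients whose first
#' qualifying event falls inside the year and whose registration overlaps
#' it; the denominator counts patients registered during the year who had
#' no first event before the year starts (the population still at risk).
#' A case whose first event predates their registration interval entirely
#' never enters a numerator; such patients are reported via a message so
#' they are excluded visibly, not silently.
#'
#' @inheritParams prevalence
#' @return A `rate_table` with attribute `measure = "incidence"`.
#' @export
incidence <- function(cases, regs, years, by_sex = FALSE) {
  check_cases_registered(cases, regs)
  first_event <- case_first_event(cases, regs)
  years <- sort(unique(as.integer(years)))
  rows <- lapply(years, function(y) {
    ys <- fy_start(y); ye <- fy_end(y)
    reg_y <- reg_overlaps(regs, ys, ye)
    at_risk <- reg_y & (is.na(first_event) | first_event >= ys)
    incident <- reg_y & !is.na(first_event) & first_event >= ys & first_event <= ye
    stratum_rows(regs, incident, at_risk, y, by_sex)
  })
  # a case not registered during their onset year never enters a numerator;
  # report such exclusions rather than dropping them silently
  is_case <- !is.na(first_event)
  if (any(is_case)) {
    ev_y <- as.integer(format(first_event[is_case], "%Y")) -
      (as.integer(format(first_event[is_case], "%m")) < 4L)
    in_window <- ev_y %in% years
    no_overlap <- regs$reg_start[is_case] > fy_end(ev_y) |
      (!is.na(regs$reg_end[is_case]) & regs$reg_end[is_case] < fy_start(ev_y))
    dropped <- regs$patient_id[is_case][in_window & no_overlap]
    if (length(dropped) > 0) {
      message(length(dropped),
              " case(s) not registered during their onset year; ",
              "excluded from incidence numerators: ",
              paste(utils::head(dropped, 5L), collapse = ", "))
    }
  }
  new_rate_table(do.call(rbind, rows), measure = "incidence")
}

check_cases_registered <- function(cases, regs) {
  missing <- setdiff(cases$patient_id, regs$patient_id)
  if (length(missing) > 0) {
    stop("case patient(s) absent from the registration table: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  }
}

# first qualifying event date aligned to the registration table's rows
case_first_event <- function(cases, regs) {
  idx <- match(regs$patient_id, cases$patient_id)
  cases$first_event_date[idx]
}

stratum_rows <- function(regs, in_numer, in_denom, year, by_sex) {
  strata <- rate_strata(regs, by_sex)
  do.call(rbind, lapply(strata, function(s) {
    sel <- if (s == "all") rep(TRUE, nrow(regs)) else regs$sex == s
    num <- sum(in_numer & sel)
    den <- sum(in_denom & sel)
    tibble::tibble(financial_year = financial_year_label(year), stratum = s,
                   numerator = num, denominator = den,
                   rate = if (den > 0) num / den else NA_real_)
  }))
}

new_rate_table <- function(df, measure) {
  stopifnot(all(df$numerator <= df$denominator))
  structure(df, class = c("rate_table", class(tibble::tibble())),
            measure = measure)
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %s over %d year(s)\n",
              attr(x, "measure") %||% "rates",
              length(unique(x$financial_year))))
  show <- tibble::as_tibble(x)
  show$rate_percent <- sprintf("%.4f", 100 * show$rate)
  print(show, ...)
  invisible(x)
}

#' Write a rate table to delimited text
#'
#' Columns: financial_year, stratum, numerator, denominator, rate_percent
#' (rate as a percentage, 4 decimal places; internally rates stay exact
#' ratios).
#'
#' @param x A `rate_table`.
#' @param path Output path.
#' @param delimiter `"comma"` or `"tab"`.
#' @export
write_rates <- function(x, path, delimiter = c("comma", "tab")) {
  delimiter <- match.arg(delimiter)
  out <- tibble::as_tibble(x)
  out$rate_percent <- ifelse(is.na(out$rate), "",
                             sprintf("%.4f", 100 * out$rate))
  out$rate <- NULL
  readr::write_delim(out, path, delim = if (delimiter == "comma") "," else "\t")
  invisible(path)
}

#' Read a rate table written by [write_rates()]
#'
#' Rates are reconstructed as exact numerator/denominator ratios, not from
#' the rounded percentage column.
#'
#' @param path File path.
#' @param measure `"prevalence"` or `"incidence"`.
#' @param delimiter `"comma"` or `"tab"`.
#' @return A `rate_table`.
#' @export
read_rates <- function(path, measure = c("prevalence", "incidence"),
                       delimiter = c("comma", "tab")) {
  measure <- match.arg(measure)
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop("rate file not found: ", path, call. = FALSE)
  df <- readr::read_delim(I(read_text_utf8(path)),
                          delim = if (delimiter == "comma") "," else "\t",
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  need <- c("financial_year", "stratum", "numerator", "denominator")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("rate file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num <- as.integer(df$numerator)
  den <- as.integer(df$denominator)
  new_rate_table(tibble::tibble(
    financial_year = df$financial_year, stratum = df$stratum,
    numerator = num, denominator = den,
    rate = ifelse(den > 0, num / den, NA_real_)), measure = measure)
}

#' Difference between two rate tables
#'
#' Elementwise `rate_a - rate_b` on an identical (financial_year, stratum)
#' grid — the comparison that shows how much a broader case definition
#' raises prevalence or incidence over a narrower one. Also reports, per
#' stratum, the year(s) where the absolute difference peaks.
#'
#' @param a,b `rate_table`s over identical year/stratum grids.
#' @return A `rate_comparison`: tibble (`financial_year`, `stratum`,
#'   `rate_a`, `rate_b`, `diff`) with attribute `argmax`, a tibble of the
#'   peak-difference rows per stratum.
#' @export
compare_rates <- function(a, b) {
  key_a <- paste0(a$financial_year, "\r", a$stratum)
  key_b <- paste0(b$financial_year, "\r", b$stratum)
  if (length(key_a) != length(key_b) || any(sort(key_a) != sort(key_b))) {
    stop("rate tables cover different (financial_year, stratum) grids",
         call. = FALSE)
  }
  bb <- b[match(key_a, key_b), ]
  out <- tibble::tibble(financial_year = a$financial_year,
                        stratum = a$stratum,
                        rate_a = a$rate, rate_b = bb$rate,
                        diff = a$rate - bb$rate)
  argmax <- do.call(rbind, lapply(split(out, out$stratum), function(g) {
    if (all(is.na(g$diff))) return(g[0, ])
    g[which(abs(g$diff) == max(abs(g$diff), na.rm = TRUE)), ]
  }))
  structure(out, class = c("rate_comparison", class(tibble::tibble())),
            argmax = argmax)
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat("<rate_comparison>\n")
  print(tibble::as_tibble(x), ...)
  am <- attr(x, "argmax")
  if (!is.null(am) && nrow(am) > 0) {
    cat("peak differences:\n")
    for (i in seq_len(nrow(am))) {
      cat(sprintf("  %s, %s: %.4f%%\n", am$stratum[i], am$financial_year[i],
                  100 * am$diff[i]))
    }
  }
  invisible(x)
}

#' Plot two rate curves over financial years
#'
#' Line plot of the same measure under two case definitions, optionally
#' faceted by sex stratum. Requires ggplot2.
#'
#' @param a,b `rate_table`s (same measure, same grid).
#' @param labels Length-2 character vector naming the two definitions.
#' @return A ggplot object.
#' @export
plot_rates <- function(a, b, labels = c("conservative", "QOF")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rates requires the ggplot2 package", call. = FALSE)
  }
  df <- rbind(
    cbind(tibble::as_tibble(a), definition = labels[[1]]),
    cbind(tibble::as_tibble(b), definition = labels[[2]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$financial_year, y = 100 * .data$rate,
    colour = .data$definition, group = .data$definition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "financial year",
                  y = paste0(attr(a, "measure") %||% "rate", " (%)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (length(unique(df$stratum)) > 1) {
    p <- p + ggplot2::facet_wrap(~stratum)
  }
  p
}
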