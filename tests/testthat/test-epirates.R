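test_that("financial_year maps 1 April - 31 March to the Y/Y+1 label", {
  expect_equal(financial_year(as.Date("2000-04-01")), "2000/01")
  expect_equal(financial_year(as.Date("2001-03-31")), "2000/01")
  expect_equal(financial_year(as.Date("2001-04-01")), "2001/02")
  expect_equal(financial_year(as.Date("1999-12-31")), "1999/00")
})

test_that("labels change exactly once over a year of consecutive days", {
  days <- as.Date("2000-10-01") + 0:365
  labs <- financial_year(days)
  expect_equal(sum(labs[-1] != labs[-length(labs)]), 1L)
  expect_equal(unique(labs), c("2000/01", "2001/02"))
  expect_equal(days[which(labs == "2001/02")[1]], as.Date("2001-04-01"))
})

toy_cohort <- function() {
  regs <- registrations(
    patient_id = c("p1", "p2", "p3", "p4"),
    sex = c("female", "male", "female", "unknown"),
    reg_start = c("1999-01-01", "1999-06-01", "2001-09-01", "1999-01-01"),
    reg_end = c(NA, "2002-03-31", NA, NA))
  cases <- structure(tibble::tibble(
    patient_id = c("p1", "p3"),
    first_event_date = as.Date(c("2001-06-01", "2002-02-01")),
    n_matching_events = c(2L, 1L),
    matched_codes = list("X1", "X1")),
    class = c("case_records", class(tibble::tibble())), min_codes = 1L)
  list(regs = regs, cases = cases)
}

test_that("prevalence counts overlap denominators and cumulative numerators", {
  tc <- toy_cohort()
  pr <- prevalence(tc$cases, tc$regs, 2000:2003)
  expect_equal(pr$denominator, c(3L, 4L, 3L, 3L))
  # p1 prevalent from 2001/02 onward, not 2000/01
  expect_equal(pr$numerator, c(0L, 2L, 2L, 2L))
  expect_equal(pr$rate, pr$numerator / pr$denominator)

  none <- tc$cases[0, ]
  pr0 <- prevalence(none, tc$regs, 2000:2003)
  expect_true(all(pr0$numerator == 0L))
})

test_that("incidence numerators land in the onset year only, at-risk denominators", {
  tc <- toy_cohort()
  inc <- incidence(tc$cases, tc$regs, 2000:2003)
  # p1 incident 2001/02, p3 incident 2001/02 (2002-02-01 is in FY 2001/02)
  expect_equal(inc$numerator, c(0L, 2L, 0L, 0L))
  # 2002/03: p2 deregistered 2002-03-31 still overlaps? reg_end 2002-03-31
  # is the last day of 2001/02, so p2 is out from 2002/03; p1 and p3 are
  # already cases, leaving p4 at risk.
  expect_equal(inc$denominator, c(3L, 4L, 1L, 1L))
})

test_that("a case is never counted twice and onset before registration is excluded", {
  regs <- registrations(c("a", "b"), c("male", "female"),
                        c("2000-01-01", "2003-04-01"), c(NA, NA))
  cases <- structure(tibble::tibble(
    patient_id = c("a", "b"),
    first_event_date = as.Date(c("2001-05-05", "2001-05-05")),
    n_matching_events = 1L, matched_codes = list("X", "X")),
    class = c("case_records", class(tibble::tibble())), min_codes = 1L)
  expect_message(inc <- incidence(cases, regs, 2000:2004), "excluded")
  # patient a counts once, in 2001/02; patient b was not registered in
  # 2001/02 and never enters a numerator
  expect_equal(sum(inc$numerator), 1L)
  expect_equal(inc$numerator[inc$financial_year == "2001/02"], 1L)
})

test_that("hand-built orderings of (reg_start, event, reg_end) match hand counts", {
  # event inside registration; event before reg_start but same FY; event
  # after reg_end; event before reg entirely
  regs <- registrations(
    c("in", "sameyr", "after", "before"),
    rep("male", 4),
    c("2000-01-01", "2001-10-01", "2000-01-01", "2003-01-01"),
    c(NA, NA, "2001-03-31", NA))
  mk_cases <- function(ids, dates) {
    structure(tibble::tibble(
      patient_id = ids, first_event_date = as.Date(dates),
      n_matching_events = 1L,
      matched_codes = rep(list("X"), length(ids))),
      class = c("case_records", class(tibble::tibble())), min_codes = 1L)
  }
  cases <- mk_cases(c("in", "sameyr", "after", "before"),
                    c("2001-06-01", "2001-06-01", "2001-06-01", "2001-06-01"))
  inc <- suppressMessages(incidence(cases, regs, 2000:2003))
  # "in" and "sameyr" (reg starts later in the same FY → overlap) count in
  # 2001/02; "after" (deregistered before the FY) and "before" never count
  expect_equal(inc$numerator[inc$financial_year == "2001/02"], 2L)
  expect_equal(sum(inc$numerator), 2L)
})

test_that("case patients missing from the registration table are an error", {
  tc <- toy_cohort()
  bad <- tc$cases
  bad$patient_id[[1]] <- "ghost"
  expect_error(prevalence(bad, tc$regs, 2000:2001), "ghost")
  expect_error(incidence(bad, tc$regs, 2000:2001), "ghost")
})

test_that("sex strata add up to the all stratum", {
  cl <- codelist(c("X1..00", "X2..00"))
  pop <- generate_population(3000, cl, prevalence = 0.05,
                             annual_incidence = 0.01, years = 2000:2004,
                             seed = 12)
  cases <- find_cases(pop$events, cl)
  for (tabfun in list(prevalence, incidence)) {
    rt <- tabfun(cases, pop$registrations, 2000:2004, by_sex = TRUE)
    for (fy in unique(rt$financial_year)) {
      sub <- rt[rt$financial_year == fy, ]
      expect_equal(sub$numerator[sub$stratum == "all"],
                   sum(sub$numerator[sub$stratum != "all"]))
      expect_equal(sub$denominator[sub$stratum == "all"],
                   sum(sub$denominator[sub$stratum != "all"]))
    }
  }
})

test_that("prevalence never decreases in a closed cohort with open registrations", {
  cl <- codelist("X1..00")
  pop <- generate_population(2000, cl, prevalence = 0.05,
                             annual_incidence = 0.005, years = 2000:2006,
                             seed = 9)
  cases <- find_cases(pop$events, cl)
  pr <- prevalence(cases, pop$registrations, 2000:2006)
  expect_true(all(diff(pr$rate) >= -1e-12))
})

test_that("zero denominators yield NA rates, never zero", {
  regs <- registrations("p1", "male", "2005-04-01", NA)
  cases <- structure(tibble::tibble(
    patient_id = character(), first_event_date = as.Date(character()),
    n_matching_events = integer(), matched_codes = list()),
    class = c("case_records", class(tibble::tibble())), min_codes = 1L)
  pr <- prevalence(cases, regs, 2000:2001)
  expect_true(all(is.na(pr$rate)))
  expect_true(all(pr$denominator == 0L))
})

test_that("compare_rates differences match hand arithmetic and find the peak", {
  mk <- function(nums, dens, measure) {
    codesifter:::new_rate_table(tibble::tibble(
      financial_year = financial_year(as.Date(c("2000-06-01", "2001-06-01",
                                                "2002-06-01"))),
      stratum = "all", numerator = nums, denominator = dens,
      rate = nums / dens), measure)
  }
  a <- mk(c(10L, 20L, 30L), c(1000L, 1000L, 1000L), "prevalence")
  b <- mk(c(8L, 10L, 29L), c(1000L, 1000L, 1000L), "prevalence")
  cmp <- compare_rates(a, b)
  expect_equal(cmp$diff, c(0.002, 0.010, 0.001))
  am <- attr(cmp, "argmax")
  expect_equal(am$financial_year, "2001/02")

  expect_equal(compare_rates(a, a)$diff, rep(0, 3))

  shifted <- mk(c(1L, 2L, 3L), c(10L, 10L, 10L), "prevalence")
  shifted$financial_year <- c("1990/91", "1991/92", "1992/93")
  expect_error(compare_rates(a, shifted), "grids")
})

test_that("rate tables round-trip through delimited text with exact ratios", {
  tc <- toy_cohort()
  pr <- prevalence(tc$cases, tc$regs, 2000:2002, by_sex = TRUE)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rates(pr, f)
  back <- read_rates(f, "prevalence")
  expect_equal(back$rate, pr$rate)
  expect_equal(back$numerator, pr$numerator)
})
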