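# Packaged description corpus for lookup generation. Deliberately generic
# clinical-flavoured words; at generation time any word containing a query
# stub is filtered out, so the remainder can pad descriptions that must
# match nothing.
SYNTH_WORDS <- c(
  "acute", "chronic", "mild", "severe", "recurrent", "bilateral", "left",
  "right", "upper", "lower", "primary", "secondary", "benign", "malignant",
  "unspecified", "history", "screening", "review", "referral", "follow",
  "assessment", "examination", "monitoring", "advice", "therapy",
  "treatment", "injection", "vaccination", "immunisation", "procedure",
  "operation", "fracture", "sprain", "laceration", "contusion", "swelling",
  "pain", "ache", "fever", "cough", "rash", "nausea", "fatigue", "insomnia",
  "headache", "dizziness", "palpitation", "weakness", "numbness", "tremor",
  "joint", "muscle", "tendon", "ligament", "cartilage", "vertebra", "rib",
  "femur", "tibia", "radius", "ulna", "clavicle", "scapula", "pelvis",
  "kidney", "liver", "spleen", "pancreas", "gallbladder", "stomach",
  "intestine", "colon", "rectum", "bladder", "prostate", "uterus", "ovary",
  "thyroid", "adrenal", "pituitary", "lymph", "node", "gland", "vessel",
  "artery", "vein", "capillary", "nerve", "cortex", "membrane", "tissue",
  "lesion", "ulcer", "cyst", "polyp", "nodule", "tumour", "abscess",
  "infection", "inflammation", "disorder", "disease", "syndrome",
  "deficiency", "excess", "intolerance", "allergy", "reaction", "exposure",
  "injury", "wound", "burn", "bite", "sting", "poisoning", "overdose",
  "withdrawal", "dependence", "misuse", "cessation", "counselling",
  "education", "certificate", "letter", "report", "result", "normal",
  "abnormal", "borderline", "elevated", "reduced", "absent", "present",
  "suspected", "confirmed", "excluded", "resolved", "ongoing", "improving",
  "worsening", "stable", "annual", "routine", "urgent", "emergency",
  "domiciliary", "telephone", "clinic", "hospital", "ward", "theatre",
  "practice", "nurse", "doctor", "specialist", "consultant", "midwife")

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

random_codes <- function(n, forbidden_prefixes = character()) {
  alphabet <- c(LETTERS, 0:9)
  draw <- function(k) {
    paste0(apply(matrix(sample(alphabet, 5L * k, replace = TRUE), ncol = 5L),
                 1L, paste, collapse = ""), ".00")
  }
  codes <- character(0)
  while (length(codes) < n) {
    cand <- unique(draw(n - length(codes) + 16L))
    if (length(forbidden_prefixes) > 0) {
      bad <- Reduce(`|`, lapply(forbidden_prefixes, startsWith, x = cand))
      cand <- cand[!bad]
    }
    codes <- unique(c(codes, cand))
  }
  codes[seq_len(n)]
}

#' Generate a synthetic lookup table with planted ground truth
#'
#' Manufactures a code dictionary in which a known subset of rows should be
#' found by a given query (planted true positives), a second subset is a
#' deliberate false-positive trap — descriptions embedding an inclusion
#' stub strictly inside a longer word, the "sunstroke"-for-"stroke"
#' phenomenon that makes expert review necessary — and the remaining rows
#' match nothing.
#'
#' @param n_rows Total rows; must cover the planted sets.
#' @param term_set A `search_query` to plant against.
#' @param relevant_fraction,trap_fraction Proportions of rows planted as
#'   true positives and as traps.
#' @param seed Integer seed; generation is reproducible and leaves the
#'   caller's RNG state untouched.
#' @param source Lookup source tag.
#' @return A `lookup_truth`: list with `table` (a `lookup_table`),
#'   `relevant_row_ids`, `trap_row_ids`, `query` and `seed`.
#' @export
generate_lookup <- function(n_rows, term_set, relevant_fraction = 0.1,
                            trap_fraction = 0.05, seed = 1L,
                            source = c("clinical", "product")) {
  source <- match.arg(source)
  stopifnot(inherits(term_set, "search_query"),
            trap_fraction >= 0, trap_fraction <= 1,
            relevant_fraction >= 0, relevant_fraction <= 1)
  n_relevant <- round(relevant_fraction * n_rows)
  n_trap <- round(trap_fraction * n_rows)
  if (n_relevant + n_trap > n_rows) {
    stop("planted sets exceed n_rows", call. = FALSE)
  }
  word_terms <- Filter(function(t) t$kind == "word_query", term_set$includes)
  code_terms <- Filter(function(t) t$kind == "code_stub", term_set$includes)
  excl_stubs <- tolower(vapply(term_set$excludes, function(t) t$stubs[[1]],
                               character(1)))
  all_stubs <- tolower(unlist(lapply(c(word_terms, term_set$excludes),
                                     function(t) t$stubs)))
  max_desc <- 60L
  if (any(nchar(all_stubs) > max_desc)) {
    stop("stub(s) longer than the maximum description length (", max_desc,
         " characters) cannot be embedded", call. = FALSE)
  }
  contains_any <- function(x, stubs) {
    if (length(stubs) == 0) return(rep(FALSE, length(x)))
    Reduce(`|`, lapply(stubs, function(s) grepl(s, x, fixed = TRUE)))
  }
  # drop corpus words containing any stub, and any word of a phrase stub, so
  # padding words can never assemble a phrase match by adjacency
  stub_tokens <- unique(unlist(strsplit(all_stubs, " ", fixed = TRUE)))
  safe_words <- SYNTH_WORDS[!contains_any(tolower(SYNTH_WORDS),
                                          unique(c(all_stubs, stub_tokens)))]
  if (length(safe_words) < 10L) {
    stop("query stubs cover too much of the description corpus", call. = FALSE)
  }
  # a word term is plantable only if its stubs avoid every exclusion stub
  plantable_words <- Filter(function(t) {
    !any(contains_any(tolower(t$stubs), excl_stubs))
  }, word_terms)
  plantable <- c(plantable_words, code_terms)
  if (n_relevant > 0 && length(plantable) == 0L) {
    stop("no inclusion term can be planted without tripping an exclusion",
         call. = FALSE)
  }
  # traps need a stub embeddable inside a longer word: glueing letters on
  # must not create an exclusion match
  trap_stubs <- unique(unlist(lapply(plantable_words, function(t) t$stubs)))
  trap_stubs <- trap_stubs[!vapply(trap_stubs, function(s) {
    any(contains_any(tolower(s), excl_stubs))
  }, logical(1))]
  if (n_trap > 0 && length(trap_stubs) == 0L) {
    stop("no word stub available for trap planting", call. = FALSE)
  }

  with_seed(seed, {
    pad <- function(k) sample(safe_words, k, replace = TRUE)
    desc_relevant <- function(term) {
      words <- pad(sample(2:4, 1L))
      paste(sample(c(words, term$stubs)), collapse = " ")
    }
    desc_trap <- function() {
      stub <- sample(trap_stubs, 1L)
      glued <- paste0(paste(sample(letters, 2L), collapse = ""), stub,
                      paste(sample(letters, 2L), collapse = ""))
      paste(sample(c(pad(sample(2:4, 1L)), glued)), collapse = " ")
    }
    desc_noise <- function() paste(pad(sample(3:6, 1L)), collapse = " ")

    n_noise <- n_rows - n_relevant - n_trap
    code_prefixes <- vapply(code_terms, function(t) t$stubs[[1]], character(1))
    codes <- random_codes(n_rows, forbidden_prefixes = code_prefixes)

    descriptions <- character(n_rows)
    rel_ids <- seq_len(n_relevant)
    trap_ids <- seq_len(n_trap) + n_relevant
    noise_ids <- setdiff(seq_len(n_rows), c(rel_ids, trap_ids))
    for (i in rel_ids) {
      term <- plantable[[((i - 1L) %% length(plantable)) + 1L]]
      if (term$kind == "code_stub") {
        codes[i] <- paste0(term$stubs[[1]],
                           paste(sample(c(LETTERS, 0:9), 3L), collapse = ""))
        descriptions[i] <- desc_noise()
      } else {
        descriptions[i] <- desc_relevant(term)
      }
    }
    for (i in trap_ids) descriptions[i] <- desc_trap()
    for (i in noise_ids) descriptions[i] <- desc_noise()

    ord <- sample(n_rows)
    table <- lookup_table(codes[ord], descriptions[ord], source = source)
    structure(list(table = table,
                   relevant_row_ids = match(rel_ids, ord),
                   trap_row_ids = match(trap_ids, ord),
                   query = term_set, seed = as.integer(seed)),
              class = "lookup_truth")
  })
}

#' @export
print.lookup_truth <- function(x, ...) {
  cat(sprintf(
    "<lookup_truth> %d rows: %d planted relevant, %d traps (seed %d)\n",
    nrow(x$table), length(x$relevant_row_ids), length(x$trap_row_ids), x$seed))
  invisible(x)
}

#' Generate a synthetic patient population with planted rates
#'
#' Builds a registration table and event stream with known ground truth:
#' baseline-prevalent cases have onset before the first financial year;
#' each subsequent year, every patient not yet a case becomes incident with
#' the planted annual probability, with onset uniform in the year. Every
#' case's first list-code event falls exactly on their onset date, further
#' list-code events follow later, and non-cases receive only noise-code
#' events — so the generator's labels are themselves a valid case-finding
#' oracle. All patients register before the study window and stay
#' registered (a closed, fully observed cohort), keeping the planted rates
#' identifiable from the any-overlap denominators.
#'
#' @param n_patients Cohort size.
#' @param codelist A non-empty `codelist`; case events draw codes uniformly
#'   from it.
#' @param prevalence Baseline prevalence at the start of the first year.
#' @param annual_incidence Per-year probability that an at-risk patient
#'   becomes a case.
#' @param years Integer vector of financial-year start years.
#' @param noise_codes Codes outside the list, given to all patients.
#' @param events_per_case Function `n -> integer vector` of list-code event
#'   counts per case, all >= 1. Default `1 + rpois(n, 2)`.
#' @param seed Integer seed.
#' @return A `population_truth`: list with `registrations`, `events`,
#'   `true_cases` (tibble of `patient_id`, `onset`), `planted` parameters
#'   and `seed`.
#' @export
generate_population <- function(n_patients, codelist, prevalence = 0.008,
                                annual_incidence = 0.0005,
                                years = 2000:2011,
                                noise_codes = paste0("ZN", 1:5, "..00"),
                                events_per_case = function(n) 1L + stats::rpois(n, 2),
                                seed = 1L) {
  stopifnot(inherits(codelist, "codelist"), nrow(codelist) > 0,
            prevalence >= 0, prevalence <= 1,
            annual_incidence >= 0, annual_incidence <= 1)
  years <- sort(unique(as.integer(years)))
  if (prevalence + length(years) * annual_incidence > 1) {
    stop("infeasible: prevalence + cumulative incidence exceeds 1",
         call. = FALSE)
  }
  overlap <- intersect(noise_codes, codelist$code)
  if (length(overlap) > 0) {
    stop("noise_codes must be disjoint from the code list: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  window_start <- fy_start(years[[1]])
  window_end <- fy_end(years[[length(years)]])

  with_seed(seed, {
    ids <- sprintf("P%06d", seq_len(n_patients))
    sex <- sample(c("male", "female", "unknown"), n_patients, replace = TRUE,
                  prob = c(0.49, 0.49, 0.02))
    reg_start <- window_start - sample.int(5L * 365L, n_patients, replace = TRUE)
    regs <- registrations(ids, sex, reg_start, NA)

    onset <- rep(as.Date(NA), n_patients)
    baseline <- stats::runif(n_patients) < prevalence
    n_base <- sum(baseline)
    if (n_base > 0) {
      # onset uniform between registration start and the day before window
      span <- as.integer(window_start - reg_start[baseline])
      onset[baseline] <- reg_start[baseline] +
        floor(stats::runif(n_base) * span)
    }
    at_risk <- !baseline
    for (y in years) {
      ys <- fy_start(y)
      n_days <- as.integer(fy_end(y) - ys) + 1L
      incident <- at_risk & stats::runif(n_patients) < annual_incidence
      n_inc <- sum(incident)
      if (n_inc > 0) {
        onset[incident] <- ys + floor(stats::runif(n_inc) * n_days)
      }
      at_risk <- at_risk & !incident
    }
    is_case <- !is.na(onset)

    # list-code events: first on onset, the rest uniform to window end
    case_idx <- which(is_case)
    n_ev <- if (length(case_idx) > 0) events_per_case(length(case_idx)) else integer()
    if (any(n_ev < 1)) {
      stop("events_per_case must return counts >= 1", call. = FALSE)
    }
    case_events <- if (length(case_idx) > 0) {
      pid <- rep(ids[case_idx], n_ev)
      first <- unlist(lapply(seq_along(case_idx), function(j) {
        c(TRUE, rep(FALSE, n_ev[[j]] - 1L))
      }))
      onset_rep <- rep(onset[case_idx], n_ev)
      span <- pmax(as.integer(window_end - onset_rep), 0L)
      dates <- onset_rep + ifelse(first, 0L, floor(stats::runif(length(pid)) *
                                                     (span + 1L)))
      tibble::tibble(patient_id = pid, event_date = dates,
                     code = sample(codelist$code, length(pid), replace = TRUE),
                     table = sample(c("clinical", "referral"), length(pid),
                                    replace = TRUE, prob = c(0.9, 0.1)))
    } else {
      patient_events(character(), as.Date(character()), character())[0, ]
    }
    # noise events for everyone
    n_noise_ev <- sample(1:3, n_patients, replace = TRUE)
    pid_n <- rep(ids, n_noise_ev)
    rs_n <- rep(reg_start, n_noise_ev)
    span_n <- as.integer(window_end - rs_n)
    noise_events <- tibble::tibble(
      patient_id = pid_n,
      event_date = rs_n + floor(stats::runif(length(pid_n)) * (span_n + 1L)),
      code = sample(noise_codes, length(pid_n), replace = TRUE),
      table = "clinical")
    events <- rbind(case_events, noise_events)
    events <- events[order(events$patient_id, events$event_date, events$code,
                           method = "radix"), ]

    structure(list(
      registrations = regs,
      events = events,
      true_cases = tibble::tibble(patient_id = ids[is_case],
                                  onset = onset[is_case]),
      planted = list(prevalence = prevalence,
                     annual_incidence = annual_incidence,
                     years = years),
      seed = as.integer(seed)),
      class = "population_truth")
  })
}

#' @export
print.population_truth <- function(x, ...) {
  cat(sprintf(
    "<population_truth> %d patients, %d true cases, %d events (seed %d)\n",
    nrow(x$registrations), nrow(x$true_cases), nrow(x$events), x$seed))
  cat(sprintf("  planted prevalence %.4g, annual incidence %.4g over %s-%s\n",
              x$planted$prevalence, x$planted$annual_incidence,
              financial_year_label(x$planted$years[[1]]),
              financial_year_label(utils::tail(x$planted$years, 1L))))
  invisible(x)
}

#' Write a synthetic population to a directory
#'
#' Emits `events.csv` and `registrations.csv` in the formats the case
#' finder and rate functions read, plus `truth.json`, a sidecar with the
#' planted parameters, true case labels and seed. Output is byte-identical
#' across runs for a fixed generator seed.
#'
#' @param pop A `population_truth`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  stopifnot(inherits(pop, "population_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- pop$events
  ev$event_date <- format(ev$event_date, "%Y-%m-%d")
  readr::write_csv(ev, file.path(dir, "events.csv"))
  rg <- pop$registrations
  rg$reg_start <- format(rg$reg_start, "%Y-%m-%d")
  rg$reg_end <- ifelse(is.na(rg$reg_end), "", format(rg$reg_end, "%Y-%m-%d"))
  readr::write_csv(rg, file.path(dir, "registrations.csv"))
  truth <- list(
    seed = pop$seed,
    planted = pop$planted,
    true_cases = list(patient_id = pop$true_cases$patient_id,
                      onset = format(pop$true_cases$onset, "%Y-%m-%d")))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
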