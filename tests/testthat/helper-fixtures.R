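# Shared fixtures and independent oracles.

# Dictionary fixture carrying the classic worked-example codes: prefix
# search, substring false positives, phrase and conjunction terms, and the
# exclusion demonstration.
demo_lookup <- function() {
  lookup_table(
    code = c("H331.11", "8H33.00", "J083300", "E273100", "13HV400",
             "G61X.00", "14A7.00", "E250.00", "136T.00", "G554000",
             "D731.00", "D737.00", "7J36000"),
    description = c("Late onset asthma", "Day hospital care",
                    "Ludwig's angina", "Head-banging",
                    "Seven year itch - marital", "Stroke NOS",
                    "H/O: sunstroke", "Alcohol dependence syndrome",
                    "Alcohol intake above recommended sensible limits",
                    "Ischemic cardiomyopathy", "Splenomegaly",
                    "Hypersplenism", "Splenectomy"),
    source = "clinical")
}

five_row_lookup <- function() {
  lookup_table(
    code = c("H331.11", "8H33.00", "J083300", "E273100", "13HV400"),
    description = c("Late onset asthma", "Day hospital care",
                    "Ludwig's angina", "Head-banging",
                    "Seven year itch - marital"))
}

# ---------------------------------------------------------------------------
# Independent search oracle: a naive per-entry scan that shares no code with
# run_search(). Description matching goes through escaped regular
# expressions with ignore.case, code prefixes through character comparison.

regex_escape <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

oracle_prefix <- function(stub, code) {
  nchar(code) >= nchar(stub) && substr(code, 1L, nchar(stub)) == stub
}

oracle_word_match <- function(stubs, description, case_sensitive = FALSE) {
  all(vapply(stubs, function(s) {
    grepl(regex_escape(s), description, ignore.case = !case_sensitive)
  }, logical(1)))
}

# includes: list of list(type = "code"|"word", stubs = character)
# excludes: character vector of single stubs
oracle_search <- function(includes, excludes, table, case_sensitive = FALSE) {
  hit <- vapply(seq_len(nrow(table)), function(i) {
    matched <- any(vapply(includes, function(term) {
      if (term$type == "code") {
        oracle_prefix(term$stubs[[1]], table$code[[i]])
      } else {
        oracle_word_match(term$stubs, table$description[[i]], case_sensitive)
      }
    }, logical(1)))
    excluded <- any(vapply(excludes, function(s) {
      grepl(regex_escape(s), table$description[[i]],
            ignore.case = !case_sensitive)
    }, logical(1)))
    matched && !excluded
  }, logical(1))
  sort(table$row_id[hit])
}

# ---------------------------------------------------------------------------
# Random instance generator for oracle-equivalence and property tests.

random_lookup <- function(n_rows) {
  vocab <- c("asthma", "angina", "stroke", "fracture", "diabetes", "annual",
             "review", "screening", "history", "acute", "chronic", "severe",
             "bilateral", "referral", "therapy", "banging", "marital",
             "dependence", "intake", "splenomegaly", "cardiomyopathy",
             "sunstroke", "injection", "advice", "letter")
  desc <- vapply(seq_len(n_rows), function(i) {
    paste(sample(vocab, sample(2:5, 1L), replace = TRUE), collapse = " ")
  }, character(1))
  codes <- vapply(seq_len(n_rows), function(i) {
    paste0(paste(sample(c(LETTERS, 0:9), 5L, replace = TRUE), collapse = ""),
           ".00")
  }, character(1))
  lookup_table(codes, desc)
}

# random substring of a random description, cleaned so it parses as a word
# term (no structural characters, non-empty after trimming)
random_word_stub <- function(table) {
  for (i in 1:50) {
    d <- sample(table$description, 1L)
    if (nchar(d) < 3) next
    a <- sample.int(nchar(d) - 2L, 1L)
    len <- sample(3:8, 1L)
    stub <- trimws(substr(d, a, min(nchar(d), a + len - 1L)))
    if (nchar(stub) >= 2 && !grepl("[+$_]", stub)) return(stub)
  }
  "asthma"
}

random_query_instance <- function(table, n_terms) {
  includes <- list()
  raw_word <- character()
  raw_code <- character()
  excludes <- character()
  for (k in seq_len(n_terms)) {
    kind <- sample(c("word", "phrase", "conj", "code", "excl"), 1L,
                   prob = c(0.35, 0.15, 0.15, 0.2, 0.15))
    if (kind == "code") {
      code <- sample(table$code, 1L)
      stub <- substr(code, 1L, sample(1:4, 1L))
      includes <- c(includes, list(list(type = "code", stubs = stub)))
      raw_code <- c(raw_code, stub)
    } else if (kind == "excl") {
      stub <- random_word_stub(table)
      excludes <- c(excludes, stub)
      raw_word <- c(raw_word, paste0("$", gsub(" ", "_", stub)))
    } else if (kind == "conj") {
      stubs <- c(random_word_stub(table), random_word_stub(table))
      stubs <- vapply(strsplit(stubs, " ", fixed = TRUE),
                      function(p) p[[1]], character(1))
      includes <- c(includes, list(list(type = "word", stubs = stubs)))
      raw_word <- c(raw_word, paste(stubs, collapse = "+"))
    } else {
      stub <- random_word_stub(table)
      includes <- c(includes, list(list(type = "word", stubs = stub)))
      raw_word <- c(raw_word, gsub(" ", "_", stub))
    }
  }
  if (length(includes) == 0L) {
    includes <- list(list(type = "word", stubs = "asthma"))
    raw_word <- c(raw_word, "asthma")
  }
  list(query = search_query(word_terms = raw_word, code_terms = raw_code),
       includes = includes, excludes = excludes)
}

# ---------------------------------------------------------------------------
# Small reviewed-template builder for codelist tests.

reviewed_template <- function(codes, categories) {
  structure(tibble::tibble(
    code = codes, description = paste("desc", codes), source = "clinical",
    matched_terms = "t", category = categories, reviewer_note = ""),
    class = c("review_template", class(tibble::tibble())))
}
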