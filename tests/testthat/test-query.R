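test_that("parse_term handles stubs, phrases, conjunctions and exclusions", {
  t1 <- parse_term("alcohol+depend", "word")
  expect_equal(t1$kind, "word_query")
  expect_equal(t1$stubs, c("alcohol", "depend"))

  t2 <- parse_term("ischemic_cardiomyopathy", "word")
  expect_equal(t2$stubs, "ischemic cardiomyopathy")

  t3 <- parse_term("$hypersplenism", "word")
  expect_equal(t3$kind, "exclusion")
  expect_equal(t3$stubs, "hypersplenism")

  t4 <- parse_term("a_b+c_d", "word")
  expect_equal(t4$stubs, c("a b", "c d"))

  # code terms are fully literal
  t5 <- parse_term("H33$+_", "code")
  expect_equal(t5$kind, "code_stub")
  expect_equal(t5$stubs, "H33$+_")
})

test_that("parse_term rejects empty and malformed terms", {
  expect_error(parse_term("", "word"), "empty")
  expect_error(parse_term("   ", "word"), "empty")
  expect_error(parse_term("+", "word"), "empty stub")
  expect_error(parse_term("$", "word"), "empty stub")
  expect_error(parse_term("a++b", "word"), "empty stub")
  expect_error(parse_term("foo$bar", "word"), "only legal at the start")
  expect_error(parse_term("$a+b", "word"), "invalid exclusion")
})

test_that("a query of only exclusions is invalid", {
  expect_error(search_query("$hypersplenism"), "no inclusion terms")
})

test_that("match_description follows substring semantics", {
  angin <- parse_term("angin", "word")
  expect_true(match_description(angin, "Ludwig's angina"))
  expect_true(match_description(angin, "Head-banging"))
  expect_false(match_description(angin, ""))

  both <- parse_term("alcohol+depend", "word")
  expect_true(match_description(both, "Alcohol dependence syndrome"))
  expect_false(match_description(both, "Alcohol intake"))

  stroke <- parse_term("stroke", "word")
  expect_true(match_description(stroke, "sunstroke"))

  phrase <- parse_term("ischemic_cardiomyopathy", "word")
  expect_true(match_description(phrase, "Ischemic cardiomyopathy"))
  expect_false(match_description(phrase, "ischemic dilated cardiomyopathy"))
})

test_that("description matching is case-insensitive by default, flag restores", {
  term <- parse_term("Asthma", "word")
  expect_true(match_description(term, "late onset asthma"))
  expect_false(match_description(term, "late onset asthma",
                                 case_sensitive = TRUE))
  expect_true(match_description(term, "Asthma", case_sensitive = TRUE))
})

test_that("match_code_prefix is a case-sensitive prefix test", {
  expect_true(match_code_prefix("H33", "H331.11"))
  expect_false(match_code_prefix("H33", "8H33.00"))
  expect_true(match_code_prefix("H331.11", "H331.11"))
  expect_false(match_code_prefix("h33", "H331.11"))
  # exhaustive check against a character-by-character comparator
  tab <- demo_lookup()
  for (stub in c("H", "H33", "h33", "13", "D73", "7J36000", "E2")) {
    for (code in tab$code) {
      expect_identical(match_code_prefix(stub, code),
                       oracle_prefix(stub, code),
                       info = paste(stub, code))
    }
  }
})

test_that("run_search applies inclusion union, exclusions, and sorted output", {
  tab <- demo_lookup()

  r <- run_search(search_query(c("splen", "$hypersplenism")), tab)
  expect_setequal(r$description, c("Splenomegaly", "Splenectomy"))

  r2 <- run_search(search_query(character(), "H33"), tab)
  expect_equal(r2$code, "H331.11")
  expect_equal(r2$matched_terms[[1]], "H33")

  r3 <- run_search(search_query("zzz-absent-stub"), tab)
  expect_equal(nrow(r3), 0L)

  # ordering by (code, description, row_id)
  r4 <- run_search(search_query("a"), tab)
  ord <- order(r4$code, r4$description, r4$row_id, method = "radix")
  expect_equal(ord, seq_len(nrow(r4)))
})

test_that("exclusions also suppress hits found via code stubs", {
  tab <- demo_lookup()
  r <- run_search(search_query("$asthma", code_terms = "H33"), tab)
  expect_equal(nrow(r), 0L)
})

test_that("matched_by reports every include term each hit matched", {
  tab <- demo_lookup()
  r <- run_search(search_query(c("splen", "spleno")), tab)
  splenomegaly <- r$matched_terms[[match("Splenomegaly", r$description)]]
  expect_setequal(splenomegaly, c("splen", "spleno"))
  splenectomy <- r$matched_terms[[match("Splenectomy", r$description)]]
  expect_equal(splenectomy, "splen")
  expect_true(all(lengths(r$matched_terms) >= 1L))
})

test_that("run_search equals the naive per-entry oracle on random instances", {
  set.seed(42)
  for (i in 1:25) {
    tab <- random_lookup(sample(50:400, 1L))
    inst <- random_query_instance(tab, sample(1:8, 1L))
    got <- sort(run_search(inst$query, tab)$row_id)
    want <- oracle_search(inst$includes, inst$excludes, tab)
    expect_identical(got, want, info = paste("instance", i))
  }
})

test_that("inclusion and exclusion monotonicity and conjunction law hold", {
  set.seed(7)
  for (i in 1:10) {
    tab <- random_lookup(200)
    a <- random_word_stub(tab)
    b <- random_word_stub(tab)
    base <- run_search(search_query(gsub(" ", "_", a)), tab)$row_id
    wider <- run_search(search_query(gsub(" ", "_", c(a, b))), tab)$row_id
    expect_true(all(base %in% wider))

    narrowed <- run_search(
      search_query(c(gsub(" ", "_", a), paste0("$", gsub(" ", "_", b)))),
      tab)$row_id
    expect_true(all(narrowed %in% base))

    # conjunction = intersection of single-stub hit sets
    a1 <- vapply(strsplit(a, " "), `[[`, character(1), 1L)
    b1 <- vapply(strsplit(b, " "), `[[`, character(1), 1L)
    conj <- run_search(search_query(paste(a1, b1, sep = "+")), tab)$row_id
    ha <- run_search(search_query(a1), tab)$row_id
    hb <- run_search(search_query(b1), tab)$row_id
    expect_setequal(conj, intersect(ha, hb))
  }
})

test_that("substring dominance: longer stubs hit subsets of their substrings", {
  set.seed(11)
  for (i in 1:10) {
    tab <- random_lookup(200)
    long <- random_word_stub(tab)
    if (nchar(long) < 3) next
    short <- substr(long, 1L, nchar(long) - 1L)
    if (grepl("[+$_]", short) || trimws(short) == "") next
    h_long <- run_search(search_query(gsub(" ", "_", long)), tab)$row_id
    h_short <- run_search(search_query(gsub(" ", "_", trimws(short))), tab)$row_id
    expect_true(all(h_long %in% h_short))
  }
})

test_that("term files parse with comments and drive the same search", {
  words <- withr::local_tempfile(fileext = ".txt")
  codes <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# clinician suggestions", "splen", "", "$hypersplenism"), words)
  writeLines(c("# from business rules", "H33"), codes)
  q <- read_terms(words, codes)
  expect_length(q$includes, 2L)
  expect_length(q$excludes, 1L)
  r <- run_search(q, demo_lookup())
  expect_setequal(r$code, c("D731.00", "7J36000", "H331.11"))
})
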