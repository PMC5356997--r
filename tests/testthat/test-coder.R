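test_that("SDL loader validates codes, uniqueness and tokenizes entries", {
  path <- system.file("extdata", "table1_sdl.tsv", package = "lcscoder")
  sdl <- load_sdl(path, hep_config())
  expect_equal(nrow(sdl$entries), 4)
  expect_equal(sdl$entries$code, sprintf("B15.00%d", 0:3))
  # filtered token counts: "YA JI XING" is a single lexicon word, so the
  # last two entries both have 5 tokens
  expect_equal(sdl$entries$lb, c(3, 4, 5, 5))
  expect_equal(sdl$entries$tokens[[1]],
               c("jia xing", "bing du xing gan yan", "gan hun mi"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("some name\t15B.000", bad)
  expect_error(load_sdl(bad), "line 1.*15B\\.000")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name one\tB15.000", "name two\tB15.000"), dup)
  expect_error(load_sdl(dup), "duplicate")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_warning(load_sdl(empty), "empty")
})

test_that("code validation pattern accepts 6-character ICD-10 codes only", {
  expect_true(all(is_valid_icd10(c("B15.000", "O99.100", "A00.999"))))
  expect_false(any(is_valid_icd10(c("15B.000", "B15000", "b15.000", "B15.00", ""))))
})

test_that("exact Table-1 query self-matches at confidence 1 and auto-outputs", {
  fx <- paper_fixtures()
  r <- assign_code(fx$query_exact, fx$sdl, fx$ontology, measure = "wlcs")
  top <- glance(r)
  expect_equal(top$code, "B15.000")
  expect_equal(top$confidence, 1)
  expect_equal(top$decision, "auto_output")
})

test_that("abbreviated query resolves through the ontology to B15.000", {
  fx <- paper_fixtures()
  for (m in c("wlcs", "tlcs", "lcs")) {
    r <- glance(assign_code(fx$query_abbrev, fx$sdl, fx$ontology, measure = m))
    expect_equal(r$code, "B15.000")
  }
  # without the ontology the abbreviation still finds B15.000 via "gan hun mi"
  # but at much lower confidence
  r0 <- glance(assign_code(fx$query_abbrev, fx$sdl, NULL, measure = "wlcs"))
  r1 <- glance(assign_code(fx$query_abbrev, fx$sdl, fx$ontology, measure = "wlcs"))
  expect_gt(r1$confidence, r0$confidence)
})

test_that("queries sharing nothing with the library go to manual review", {
  fx <- paper_fixtures()
  r <- assign_code("wu guan ci liao", fx$sdl, fx$ontology)
  expect_true(all(r$candidates$confidence == 0))
  expect_equal(r$decision, "manual_review")
})

test_that("a query of only stop words is an empty-query error", {
  fx <- paper_fixtures()
  expect_error(assign_code("BAN", fx$sdl), "zero tokens")
})

test_that("confidence policy routes strictly above the threshold", {
  fx <- paper_fixtures()
  r <- assign_code(fx$query_abbrev, fx$sdl, fx$ontology) # confidence 6/7
  expect_equal(apply_confidence_policy(r, 0.803)$decision, "auto_output")
  expect_equal(apply_confidence_policy(r, 0.9)$decision, "manual_review")
  expect_equal(apply_confidence_policy(r, 6 / 7)$decision, "manual_review") # strict
  expect_equal(apply_confidence_policy(r, 0)$decision, "auto_output")
})

test_that("every library entry retrieves itself at confidence 1 (all measures)", {
  bm <- generate_benchmark(n_codes = 30, n_queries = 1, vocab_size = 30, seed = 9)
  for (m in c("lcs", "tlcs", "wlcs", "word", "bigram")) {
    coded <- code_diagnoses(bm$sdl$entries$name, bm$sdl, bm$ontology, measure = m)
    expect_equal(coded$code, bm$sdl$entries$code)
    expect_true(all(coded$confidence == 1))
  }
})

test_that("rankings are deterministic with total tie-breaking", {
  fx <- paper_fixtures()
  r1 <- tidy(assign_code(fx$query_abbrev, fx$sdl, fx$ontology, top_k = 4))
  r2 <- tidy(assign_code(fx$query_abbrev, fx$sdl, fx$ontology, top_k = 4))
  expect_identical(r1, r2)
  expect_true(all(diff(r1$confidence) <= 0))
  # equal-confidence candidates sort by code
  sdl <- sdl_library(tibble::tibble(
    name = c("x y ZZ", "x y AA"),
    code = c("Z99.000", "A00.000")
  ))
  r <- tidy(assign_code("x y", sdl, measure = "wlcs", top_k = 2))
  expect_equal(r$confidence[1], r$confidence[2])
  expect_equal(r$code, c("A00.000", "Z99.000"))
})

test_that("code_diagnoses is data-frame-first and preserves extra columns", {
  fx <- paper_fixtures()
  df <- tibble::tibble(query = c(fx$query_exact, fx$query_abbrev),
                       id = c("q1", "q2"))
  out <- df |> code_diagnoses(fx$sdl, fx$ontology)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$id, c("q1", "q2"))
  expect_equal(out$code, c("B15.000", "B15.000"))
})
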