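test_that("classic LCS matches hand-enumerated and trivial cases", {
  x <- c("jia xing", "gan", "gan hun mi")
  y <- c("jia xing", "bing du xing gan yan", "gan hun mi")
  expect_equal(classic_lcs(x, y)$length, 2)
  expect_equal(classic_lcs(x, x)$length, 3)
  expect_equal(classic_lcs(x, character(0))$length, 0)
  expect_equal(classic_lcs(character(0), character(0))$length, 0)
})

test_that("DP matrix satisfies its structural invariants", {
  withr::with_seed(21, {
    for (i in 1:30) {
      x <- random_tokens(sample(0:6, 1))
      y <- random_tokens(sample(0:6, 1))
      r <- classic_lcs(x, y)
      cm <- r$matrix
      expect_true(all(cm[1, ] == 0) && all(cm[, 1] == 0))
      if (nrow(cm) > 1) expect_true(all(diff(cm) >= 0))        # rows
      if (ncol(cm) > 1) expect_true(all(t(diff(t(cm))) >= 0))  # cols
      if (nrow(cm) > 1 && ncol(cm) > 1) {
        diag_step <- cm[-1, -1] - cm[-nrow(cm), -ncol(cm)]
        expect_true(all(diag_step %in% c(0, 1)))
      }
      expect_equal(r$length, cm[nrow(cm), ncol(cm)])
      expect_lte(r$length, min(length(x), length(y)))
      # matched pairs lie on one optimal path
      expect_equal(nrow(r$matched_pairs), r$length)
      if (nrow(r$matched_pairs) > 1) {
        expect_true(all(diff(r$matched_pairs$i) > 0))
        expect_true(all(diff(r$matched_pairs$j) > 0))
      }
      if (nrow(r$matched_pairs) > 0) {
        expect_true(all(x[r$matched_pairs$i] == y[r$matched_pairs$j]))
      }
    }
  })
})

test_that("classic LCS equals the brute-force oracle on random pairs", {
  withr::with_seed(42, {
    for (i in 1:150) {
      x <- random_tokens(sample(0:8, 1), letters[1:3])
      y <- random_tokens(sample(0:8, 1), letters[1:3])
      expect_equal(classic_lcs(x, y)$length, brute_force_lcs(x, y))
    }
  })
})

test_that("semantic LCS equals the oracle under the thresholded predicate", {
  withr::with_seed(43, {
    for (i in 1:150) {
      onto <- random_ontology(letters[1:5], fallback = runif(1) < 0.3)
      eps <- runif(1)
      x <- random_tokens(sample(0:8, 1))
      y <- random_tokens(sample(0:8, 1))
      pred <- function(a, b) token_similarity(a, b, onto) > eps
      expect_equal(semantic_lcs(x, y, onto, eps)$length,
                   brute_force_lcs(x, y, pred))
    }
  })
})

test_that("semantic LCS reproduces the abbreviated-diagnosis match", {
  onto <- term_ontology(synonym_group("abbr", c("jia gan", "jia xing bing du xing gan yan"), 0.9))
  r <- semantic_lcs(c("jia gan", "gan hun mi"),
                    c("jia xing bing du xing gan yan", "gan hun mi"),
                    onto, epsilon = 0.8)
  expect_equal(r$length, 2)
})

test_that("epsilon behaves as a strict threshold with an inclusive option", {
  onto <- term_ontology(synonym_group("g", c("a", "b"), 0.8))
  # sim = 0.8 is NOT > 0.8
  expect_equal(semantic_lcs("a", "b", onto, epsilon = 0.8)$length, 0)
  expect_equal(semantic_lcs("a", "b", onto, epsilon = 0.8, inclusive = TRUE)$length, 1)
  # epsilon = 1: nothing exceeds 1, even identical tokens
  expect_equal(semantic_lcs(c("a", "b"), c("a", "b"), onto, epsilon = 1)$length, 0)
})

test_that("LCS length is non-increasing in epsilon and classic in the limit", {
  withr::with_seed(44, {
    for (i in 1:40) {
      onto <- random_ontology()
      x <- random_tokens(sample(1:7, 1))
      y <- random_tokens(sample(1:7, 1))
      eps_grid <- c(0, 0.25, 0.5, 0.75, 0.95)
      lens <- vapply(eps_grid, function(e) semantic_lcs(x, y, onto, e)$length, numeric(1))
      expect_true(all(diff(lens) <= 0))
      # empty ontology, fallback off, eps just below 1 -> classic
      expect_equal(semantic_lcs(x, y, NULL, 0.999)$length, classic_lcs(x, y)$length)
    }
  })
})

test_that("brute-force oracle handles trivial cases and refuses long input", {
  x <- random_tokens(5)
  expect_equal(brute_force_lcs(x, x), 5)
  expect_equal(brute_force_lcs(c("a", "b"), c("x", "y")), 0)
  expect_error(brute_force_lcs(letters[1:13], letters[1:3]), "12")
})

test_that("tidy and glance expose matched pairs and lengths", {
  r <- classic_lcs(c("a", "b", "c"), c("a", "c"))
  expect_equal(glance(r)$lcsl, 2)
  expect_equal(glance(r)$la, 3)
  expect_equal(tidy(r)$j, c(1, 2))
})
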