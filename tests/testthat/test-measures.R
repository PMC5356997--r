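test_that("printed similarity table reproduces for L(A) 1..4 (all 60 cells)", {
  fx <- paper_fixtures()
  t3 <- fx$table3[fx$table3$la <= 4, ]
  expect_equal(nrow(t3), 20)
  expect_equal(round_half_up(lcs_similarity(t3$lcsl, t3$la, t3$lb), 2), t3$lcs)
  expect_equal(round_half_up(tlcs_similarity(t3$lcsl, t3$la, t3$lb), 2), t3$tlcs)
  expect_equal(round_half_up(wlcs_similarity(t3$lcsl, t3$la, t3$lb), 2), t3$wlcs)
})

test_that("spot values match the printed table", {
  expect_equal(round_half_up(lcs_similarity(1, 1, 5), 2), 0.20)
  expect_equal(round_half_up(lcs_similarity(3, 3, 7), 2), 0.43)
  expect_equal(lcs_similarity(0, 2, 3), 0)
  expect_equal(round_half_up(tlcs_similarity(2, 2, 6), 2), 0.50)
  expect_equal(round_half_up(tlcs_similarity(4, 4, 7), 2), 0.73)
  expect_equal(tlcs_similarity(3, 3, 3), 1)
  expect_equal(wlcs_similarity(2, 2, 3), 6 / 7)
  expect_equal(wlcs_similarity(4, 4, 8), 20 / 24)
  expect_equal(wlcs_similarity(4, 4, 4), 1)
  expect_equal(wlcs_similarity(0, 2, 3), 0)
})

test_that("degenerate lengths raise undefined-similarity errors", {
  expect_error(lcs_similarity(0, 0, 0), "undefined")
  expect_error(tlcs_similarity(0, 0, 0), "undefined")
  expect_error(wlcs_similarity(0, 0, 0), "undefined")
  expect_error(lcs_similarity(3, 2, 2), "lcsl")
})

test_that("W-LCS >= T-LCS >= LCS-ratio over all admissible triples to 12", {
  grid <- expand.grid(lcsl = 1:12, la = 1:12, lb = 1:12)
  grid <- grid[grid$lcsl <= grid$la & grid$la <= grid$lb, ]
  w <- wlcs_similarity(grid$lcsl, grid$la, grid$lb)
  t <- tlcs_similarity(grid$lcsl, grid$la, grid$lb)
  l <- lcs_similarity(grid$lcsl, grid$la, grid$lb)
  expect_true(all(w >= t - 1e-12))
  expect_true(all(t >= l - 1e-12))
  expect_true(all(w <= 1 & l >= 0))
  # all three are 1 iff lcsl = la = lb, 0 iff lcsl = 0
  full <- grid$lcsl == grid$la & grid$la == grid$lb
  expect_true(all((w == 1) == full))
  expect_true(all((l == 1) == full))
  expect_true(all(w > 0 & t > 0 & l > 0)) # lcsl >= 1 in the grid
})

test_that("measures are symmetric under swapping the operand lengths", {
  withr::with_seed(5, {
    for (i in 1:30) {
      la <- sample(1:10, 1)
      lb <- sample(1:10, 1)
      k <- sample(0:min(la, lb), 1)
      expect_equal(lcs_similarity(k, la, lb), lcs_similarity(k, lb, la))
      expect_equal(tlcs_similarity(k, la, lb), tlcs_similarity(k, lb, la))
      expect_equal(wlcs_similarity(k, la, lb), wlcs_similarity(k, lb, la))
    }
  })
})

test_that("word-matching baseline is the all-or-nothing indicator", {
  expect_equal(word_match_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(word_match_similarity(c("a", "b"), c("a", "c")), 0)
  expect_equal(word_match_similarity(c("a", "b"), c("b", "a")), 0)
  expect_equal(word_match_similarity(c("a", "b"), c("a", "b", "c")), 0)
  expect_equal(word_match_similarity(character(0), character(0)), 1)
})

test_that("bigram baseline is Dice over boundary-padded token bigrams", {
  expect_equal(bigram_similarity(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(bigram_similarity(c("a", "b"), c("x", "y")), 0)
  # [a,b,c] vs [a,b,d]: padded bigrams {^a, ab, bc, c$} vs {^a, ab, bd, d$}
  # -> 2 shared of 4 + 4
  expect_equal(bigram_similarity(c("a", "b", "c"), c("a", "b", "d")), 0.5)
  # single token and empty sequences are well defined through padding
  expect_equal(bigram_similarity("a", "a"), 1)
  expect_equal(bigram_similarity(character(0), character(0)), 1)
  expect_lt(bigram_similarity("a", c("a", "b")), 1)
})

test_that("sequence_similarity dispatches measures and records lengths", {
  onto <- term_ontology(synonym_group("g", c("b", "bb"), 0.9))
  s <- sequence_similarity(c("a", "b"), c("a", "bb", "c"), "wlcs", onto)
  expect_equal(s$lcsl, 2)
  expect_equal(s$la, 2)
  expect_equal(s$lb, 3)
  expect_equal(s$value, 6 / 7)
  expect_equal(sequence_similarity(c("a", "b"), c("a", "b"), "word-match")$value, 1)
  expect_error(sequence_similarity("a", "b", "xyz"), "unknown measure")
})

test_that("half-up rounding matches table formatting", {
  expect_equal(round_half_up(0.805, 2), 0.81)
  expect_equal(round_half_up(0.5714286, 2), 0.57)
  expect_equal(round_half_up(6 / 7, 2), 0.86)
  expect_equal(round_half_up(0.425, 2), 0.43) # base round() would give 0.42
})
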