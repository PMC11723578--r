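test_that("classify_encoding maps all nine label pairs correctly", {
  lv <- c("excited", "inhibited", "not_significant")
  grid <- expand.grid(a = lv, b = lv, stringsAsFactors = FALSE)
  got <- classify_encoding(grid$a, grid$b)
  expected <- ifelse(grid$a == "not_significant" & grid$b == "not_significant",
                     "not_significant",
                     ifelse(grid$a == grid$b, "salience", "valence"))
  expect_equal(got$category, expected)
  # specific cells: both-excited is salience; opposite responses are valence
  expect_equal(classify_encoding("excited", "excited")$category, "salience")
  expect_equal(classify_encoding("excited", "excited")$subtype, "excited:excited")
  expect_equal(classify_encoding("inhibited", "excited")$category, "valence")
  expect_equal(classify_encoding("not_significant", "not_significant")$category,
               "not_significant")
  expect_error(classify_encoding("up", "excited"), "label_a")
})

test_that("classify_encoding category is symmetric under label swap", {
  lv <- c("excited", "inhibited", "not_significant")
  for (a in lv) for (b in lv) {
    expect_equal(classify_encoding(a, b)$category,
                 classify_encoding(b, a)$category)
  }
})

fake_results <- function(ids, labels, stimulus = "food") {
  data.frame(neuron_id = ids, stimulus = stimulus, label = labels,
             stringsAsFactors = FALSE)
}

test_that("build_encoding_table joins across the registration map", {
  ra <- fake_results(c("a1", "a2", "a3"),
                     c("excited", "not_significant", "inhibited"))
  rb <- fake_results(c("b1", "b2", "b3"),
                     c("excited", "not_significant", "excited"), "shock")
  reg <- registration_map(c("a3", "a1"), c("b2", "b1"))
  tab <- build_encoding_table(ra, rb, reg)
  expect_equal(nrow(tab), 2)
  # row order follows the registration map
  expect_equal(tab$label_a, c("inhibited", "excited"))
  expect_equal(tab$label_b, c("not_significant", "excited"))
  expect_equal(tab$category, c("valence", "salience"))
  # unresolved pair errors with the offending ID
  bad <- registration_map("a9", "b1")
  expect_error(build_encoding_table(ra, rb, bad), "a9")
  # empty registration -> empty table
  empty <- build_encoding_table(ra, rb, registration_map(character(0), character(0)))
  expect_equal(nrow(empty), 0)
})

test_that("category counts partition the registered neurons", {
  labels_a <- rep(c("excited", "inhibited", "not_significant"), c(5, 3, 4))
  labels_b <- rep(c("excited", "not_significant", "not_significant"), c(5, 3, 4))
  ra <- fake_results(sprintf("a%d", 1:12), labels_a)
  rb <- fake_results(sprintf("b%d", 1:12), labels_b, "shock")
  tab <- build_encoding_table(ra, rb, registration_map(ra$neuron_id, rb$neuron_id))
  cc <- category_counts(tab)
  expect_equal(sum(cc), 12)
  expect_equal(unname(cc[1, ]), c(5, 3, 4))
  cs <- category_counts(tab, by = "subtype")
  expect_equal(sum(cs), 12)
  expect_equal(ncol(cs), 9)
})

test_that("percentages use round-half-away-from-zero on exact counts", {
  mk <- function(counts) {
    df <- data.frame(category = rep(c("salience", "valence", "not_significant"),
                                    counts),
                     subtype = "x", stringsAsFactors = FALSE)
    class(df) <- c("encoding_table", "data.frame")
    df
  }
  pct <- attr(category_counts(mk(c(46, 198, 59))), "percent")
  expect_equal(unname(pct[1, ]), c(15, 65, 19))
  pct <- attr(category_counts(mk(c(7, 57, 239))), "percent")
  expect_equal(unname(pct[1, ]), c(2, 19, 79))
  # single-neuron table
  one <- category_counts(mk(c(1, 0, 0)))
  expect_equal(unname(one[1, ]), c(1, 0, 0))
})

test_that("chi_square_independence matches the closed-form Pearson statistic", {
  pearson <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(14)
  for (r in 1:10) {
    m <- matrix(rpois(6, 40) + 1, nrow = 2)
    got <- chi_square_independence(m)
    expect_equal(got$statistic, pearson(m), tolerance = 1e-9)
    expect_equal(got$df, 2)
    # invariance under row/column permutation
    expect_equal(chi_square_independence(m[2:1, c(2, 3, 1)])$statistic,
                 got$statistic, tolerance = 1e-9)
  }
  expect_equal(chi_square_independence(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square_independence(matrix(c(10, 10, 10, 10), 2))$p, 1)
  # diagonal table, expectation 2.5 in every cell
  got <- chi_square_independence(matrix(c(5, 0, 0, 5), 2))
  expect_equal(got$statistic, 10)
  expect_equal(got$df, 1)
  expect_error(chi_square_independence(matrix(c(1, 2), 1)), "2 x 2")
  expect_error(chi_square_independence(matrix(c(0, 0, 1, 2), 2)), "positive")
})

test_that("compare_order_groups builds 2 x 3 tables and tests them", {
  labels_a <- rep(c("excited", "excited", "not_significant"), times = 4)
  labels_b <- rep(c("excited", "not_significant", "not_significant"), times = 4)
  ra <- fake_results(sprintf("a%d", 1:12), labels_a)
  rb <- fake_results(sprintf("b%d", 1:12), labels_b, "shock")
  tab <- build_encoding_table(ra, rb, registration_map(ra$neuron_id, rb$neuron_id))
  grp <- rep(c("appetitive_first", "fear_first"), each = 6)
  out <- compare_order_groups(tab, grp)
  expect_equal(dim(out$table), c(2, 3))
  expect_equal(sum(out$table), 12)
  # identical groups -> statistic 0
  expect_equal(out$chi_square$statistic, 0)
  expect_error(compare_order_groups(tab, grp[1:3]), "one entry per")
  expect_error(compare_order_groups(tab, rep("x", 12)), "appetitive_first")
})
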