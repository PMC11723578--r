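test_that("circular_shift matches its definition and boundary cases", {
  expect_equal(circular_shift(c(1, 2, 3, 4, 5), 2), c(3, 4, 5, 1, 2))
  expect_equal(circular_shift(c(1, 2, 3, 4, 5), 5), c(1, 2, 3, 4, 5))
  expect_error(circular_shift(1:5, 0), "in \\[1, 5\\]")
  expect_error(circular_shift(1:5, 6), "in \\[1, 5\\]")
})

test_that("circular_shift composes modularly and preserves the multiset", {
  for (n in 2:8) {
    x <- rnorm(n)
    for (s1 in 1:n) {
      expect_identical(sort(circular_shift(x, s1)), sort(x))
      for (s2 in 1:n) {
        expect_equal(circular_shift(circular_shift(x, s1), s2),
                     circular_shift(x, ((s1 + s2 - 1) %% n) + 1))
      }
    }
  }
})

test_that("wrst_statistic is the midrank sum of the post samples", {
  expect_equal(wrst_statistic(c(1, 2, 3), c(4, 5, 6)), 15)
  expect_equal(wrst_statistic(c(4, 5, 6), c(1, 2, 3)), 6)
  expect_equal(wrst_statistic(c(1, 1), c(1, 1)), 5)
  expect_error(wrst_statistic(numeric(0), 1), "non-empty")
})

test_that("wrst_statistic conserves ranks and ignores monotone transforms", {
  set.seed(31)
  for (r in 1:20) {
    pre <- sample(rnorm(8), sample(2:8, 1), replace = TRUE)
    post <- sample(c(pre, rnorm(5)), sample(2:8, 1), replace = TRUE)
    tt <- length(pre) + length(post)
    expect_equal(wrst_statistic(pre, post) + wrst_statistic(post, pre),
                 tt * (tt + 1) / 2)
    mono <- function(x) exp(2 * x) - 3
    expect_equal(wrst_statistic(mono(pre), mono(post)),
                 wrst_statistic(pre, post))
    # agreement with the standard Mann-Whitney statistic:
    # W (wilcox.test) = ranksum - n_post (n_post + 1) / 2 with post as x
    w <- suppressWarnings(stats::wilcox.test(post, pre)$statistic)
    expect_equal(wrst_statistic(pre, post),
                 unname(w) + length(post) * (length(post) + 1) / 2)
  }
})

test_that("observed_statistic sums per-trial statistics over trials", {
  # constant neuron: every pooled sample ties, post midrank sum is
  # n_post (n_pre + n_post + 1) / 2 per trial
  s <- make_session(make_traces(1, 4, 100, function(i, j, k) 2))
  w <- compact_windows()  # pre 20 samples, post 20 samples
  expect_equal(observed_statistic(s, "n01", w), 4 * 20 * (20 + 20 + 1) / 2)
  # single-trial session reduces to wrst_statistic on the windows
  set.seed(8)
  tr <- rnorm(100)
  s1 <- make_session(array(tr, dim = c(1, 1, 100)))
  # iso [-5,5) = samples 1..100; pre [-2,0) = 31..50; post [0,2) = 51..70
  expect_equal(observed_statistic(s1, "n01", w),
               wrst_statistic(tr[31:50], tr[51:70]))
  expect_error(observed_statistic(s1, "zzz", w), "not present")
})

test_that("observed_statistic equals a naive per-trial recomputation", {
  set.seed(9)
  s <- make_noise_session(5, 6, seed = 9)
  w <- analysis_windows("cs")
  for (id in s$neuron_ids) {
    brute <- 0
    for (j in 1:6) {
      y <- s$traces[match(id, s$neuron_ids), j, 1:400]  # iso [-30, 10)
      brute <- brute + naive_wrst(y[101:300], y[301:400])
    }
    expect_identical(observed_statistic(s, id, w), brute)
  }
})

test_that("the null repository is deterministic and degenerate under ties", {
  s <- make_session(make_traces(3, 2, 100, function(i, j, k) 1))
  w <- compact_windows()
  repo <- build_null_repository(s, w, B = 25, seed = 4)
  expect_length(repo$stats, 25)
  expect_true(all(repo$stats == 20 * (41) / 2 * 2))
  repo2 <- build_null_repository(s, w, B = 25, seed = 4)
  expect_identical(repo$stats, repo2$stats)
  expect_false(identical(repo$stats,
                         build_null_repository(make_noise_session(3, 2), w,
                                               B = 25, seed = 5)$stats))
  expect_error(build_null_repository(s, w, B = 0), "B must be")
})

test_that("empirical_pvalue implements the add-one formulas", {
  repo <- structure(list(stats = c(rep(0, 490), rep(100, 10)), B = 500,
                         windows = NULL, session_id = "x", rng_seed = 1),
                    class = "null_repository")
  p <- empirical_pvalue(50, repo)  # 10 nulls >= 50
  expect_equal(p$p_plus, 11 / 501)
  expect_equal(p$p_minus, 491 / 501)
  expect_equal(p$p_two_sided, 22 / 501)
  expect_equal(p$direction, "excited")
  # observed above every null
  p2 <- empirical_pvalue(1e9, repo)
  expect_equal(p2$p_plus, 1 / 501)
  expect_equal(p2$p_two_sided, 2 / 501)
  # tie double-counting bound
  set.seed(2)
  for (r in 1:20) {
    repo$stats <- sample(0:5, 500, replace = TRUE)
    p <- empirical_pvalue(sample(0:5, 1), repo)
    expect_gte(p$p_plus + p$p_minus, 502 / 501)
  }
})

test_that("an all-constant session is never called responsive", {
  s <- make_session(make_traces(3, 2, 100, function(i, j, k) 7))
  res <- test_population(s, compact_windows(), B = 50, seed = 3)
  expect_true(all(res$label == "not_significant"))
  expect_true(all(res$p_two_sided == 1))
})

test_that("pipeline determinism: seed fixes every p-value", {
  s <- make_noise_session(4, 3, seed = 21)
  w <- compact_windows()
  r1 <- test_population(s, w, B = 60, seed = 17)
  r2 <- test_population(s, w, B = 60, seed = 17)
  expect_identical(r1$p_two_sided, r2$p_two_sided)
  expect_identical(r1$label, r2$label)
})

test_that("null p-values are stochastically no smaller than uniform", {
  s <- simulate_null_session(60, 8, seed = 5)
  res <- test_population(s, analysis_windows("cs"), B = 150, seed = 6)
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    # allow binomial slack at n = 60
    expect_lte(mean(res$p_two_sided <= q), q + 3 * sqrt(q * (1 - q) / 60))
  }
})

test_that("strong injected excitation is labelled excited by both methods", {
  spec <- population_spec(n_registered = 6, effect_size = 10, seed = 31)
  truth <- data.frame(label_food = rep("excited", 6),
                      label_shock = rep("not_significant", 6),
                      label_cs_food = rep("not_significant", 6),
                      label_cs_shock = rep("not_significant", 6))
  sim <- simulate_paired_sessions(spec, truth = truth)
  w <- analysis_windows("food")
  circ <- test_population(sim$appetitive, w, B = 200, seed = 32)
  expect_true(all(circ$label == "excited"))
  sr <- signrank_responsiveness(sim$appetitive, w)
  expect_true(all(sr$label == "excited"))
})

test_that("sign-rank cutoff defaults to the binomial-tail construction", {
  s <- make_session(make_traces(1, 20, 100, function(i, j, k) 1))
  r <- signrank_responsiveness(s, compact_windows())
  # smallest k with P(Binom(20, 0.025) >= k) <= 0.05 is 3
  expect_equal(r$cutoff, 3L)
  expect_equal(r$label, "not_significant")
  s10 <- make_session(make_traces(1, 10, 100, function(i, j, k) 1))
  expect_equal(signrank_responsiveness(s10, compact_windows())$cutoff, 2L)
})
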