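test_that("simulation is deterministic and substream-stable", {
  spec <- population_spec(n_registered = 4, seed = 123)
  s1 <- simulate_paired_sessions(spec)
  s2 <- simulate_paired_sessions(spec)
  expect_identical(s1$appetitive$traces, s2$appetitive$traces)
  expect_identical(s1$fear$traces, s2$fear$traces)
  expect_identical(s1$ground_truth, s2$ground_truth)
  # adding neurons must not perturb existing ones
  s6 <- simulate_paired_sessions(population_spec(n_registered = 6, seed = 123))
  expect_identical(s6$appetitive$traces[1:4, , ], s1$appetitive$traces[1:4, , ])
  expect_identical(s6$ground_truth[1:4, ], s1$ground_truth[1:4, ])
})

test_that("simulated sessions carry the paradigm trial structure", {
  sim <- simulate_paired_sessions(population_spec(n_registered = 3, seed = 5))
  expect_equal(dim(sim$appetitive), c(3, 20, 600))
  expect_equal(dim(sim$fear), c(3, 10, 600))
  expect_equal(sim$appetitive$sampling_rate, 10)
  expect_equal(sim$appetitive$events$us_onset_s, 13)
  he <- sim$appetitive$events$head_entry_s
  expect_length(he, 20)
  expect_true(all(he > 13))
  expect_null(sim$fear$events$head_entry_s)
  expect_identical(sim$registration$neuron_id_session_a,
                   sim$appetitive$neuron_ids)
})

test_that("ground-truth categories are consistent with classify_encoding", {
  sim <- simulate_paired_sessions(population_spec(n_registered = 40, seed = 8))
  gt <- sim$ground_truth
  us <- classify_encoding(gt$label_food, gt$label_shock)
  cs <- classify_encoding(gt$label_cs_food, gt$label_cs_shock)
  expect_equal(gt$us_category, us$category)
  expect_equal(gt$us_subtype, us$subtype)
  expect_equal(gt$cs_category, cs$category)
  expect_equal(gt$cs_subtype, cs$subtype)
})

test_that("category frequencies follow the joint distribution", {
  # all mass on one cell -> every neuron gets that label pair
  p <- matrix(0, 3, 3); p[1, 2] <- 1  # food excited, shock inhibited
  spec <- population_spec(n_registered = 25, joint_category_probabilities = p,
                          cs_response_given_us = 0, seed = 9)
  gt <- simulate_paired_sessions(spec)$ground_truth
  expect_true(all(gt$label_food == "excited"))
  expect_true(all(gt$label_shock == "inhibited"))
  expect_true(all(gt$label_cs_food == "not_significant"))
  # multinomial draw at n = 400: observed cell frequencies within an exact
  # 99.9% binomial band of the target probabilities
  spec <- population_spec(n_registered = 400, seed = 10)
  gt <- simulate_paired_sessions(spec)$ground_truth
  probs <- spec$joint_category_probabilities
  for (f in rownames(probs)) for (s in colnames(probs)) {
    n_obs <- sum(gt$label_food == f & gt$label_shock == s)
    band <- qbinom(c(0.0005, 0.9995), 400, probs[f, s])
    expect_gte(n_obs, band[1])
    expect_lte(n_obs, band[2])
  }
})

test_that("population_spec validates its probability inputs", {
  p <- default_joint_probabilities()
  expect_equal(sum(p), 1)
  p_bad <- p; p_bad[1, 1] <- p_bad[1, 1] + 0.01
  expect_error(population_spec(joint_category_probabilities = p_bad), "sum to 1")
  expect_error(population_spec(cs_response_given_us = 1.2), "\\[0, 1\\]")
  expect_error(population_spec(effect_size = -1), "effect_size")
  expect_error(transient_model(kernel_rise_s = 2, kernel_decay_s = 1), "rise")
})

test_that("excited response margin grows with effect size", {
  margins <- sapply(c(0, 3, 8), function(es) {
    spec <- population_spec(n_registered = 4, effect_size = es, seed = 77)
    truth <- data.frame(label_food = rep("excited", 4),
                        label_shock = rep("not_significant", 4),
                        label_cs_food = rep("not_significant", 4),
                        label_cs_shock = rep("not_significant", 4))
    sim <- simulate_paired_sessions(spec, truth = truth)
    pre <- extract_window(sim$appetitive, "cs_onset", c(-5, 13))
    post <- extract_window(sim$appetitive, "cs_onset", c(13, 28))
    mean(apply(post, 1, mean) - apply(pre, 1, mean))
  })
  expect_true(all(diff(margins) > 0))
})

test_that("null sessions are stimulus-independent and deterministic", {
  s1 <- simulate_null_session(5, 6, seed = 3)
  s2 <- simulate_null_session(5, 6, seed = 3)
  expect_identical(s1$traces, s2$traces)
  expect_equal(dim(s1), c(5, 6, 600))
  s0 <- simulate_null_session(0, 6, seed = 3)
  expect_equal(dim(s0)[1], 0)
  # no event-locked modulation: pre/post means match within noise
  big <- simulate_null_session(40, 10, seed = 4)
  pre <- extract_window(big, "cs_onset", c(-5, 13))
  post <- extract_window(big, "cs_onset", c(13, 30))
  expect_lt(abs(mean(post) - mean(pre)), 0.05)
})
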