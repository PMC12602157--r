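test_that("discovery prior follows inverse-squared distance, row-normalized", {
  # three collinear nodes: d(A,B) = 1, d(A,C) = 2
  env <- new_bee_env(rbind(c(1, 0), c(2, 0)))  # nest A at origin
  p_d <- discovery_probabilities(env)
  expect_equal(p_d[1, 2], 0.8)   # (1/1) / (1/1 + 1/4)
  expect_equal(p_d[1, 3], 0.2)
  expect_equal(diag(p_d), rep(0, 3))

  # equidistant destinations split evenly
  env <- new_bee_env(rbind(c(3, 0), c(0, 3)))
  p_d <- discovery_probabilities(env)
  expect_equal(p_d[1, 2], p_d[1, 3])

  # every row sums to 1 in a generic random environment
  p_d <- discovery_probabilities(toy_env(20))
  expect_equal(rowSums(p_d), rep(1, 21), tolerance = 1e-12)
})

test_that("Q-table initialization is half of n_max discounted by the prior", {
  env <- new_bee_env(rbind(c(1, 0), c(2, 0)), n_max = 20)
  p_d <- discovery_probabilities(env)
  q0 <- init_q(env, p_d)
  expect_equal(q0[1, 2], 0.5 * 20 * 0.8)  # 8.0
  expect_equal(q0[1, 3], 2.0)
  expect_equal(rowSums(q0), rep(0.5 * 20, 3))
  expect_true(all(diag(q0) == 0))
})

test_that("perceived value multiplies arrival nectar by the discovery prior", {
  expect_equal(perceived_value(0, 0.7), 0)
  expect_equal(perceived_value(8, 1), 8)
  expect_equal(perceived_value(10, 0.2), 2)
})

test_that("Q update is a convex combination bounded by its inputs", {
  expect_equal(update_q(2, 0.5, 4), 3)
  expect_identical(update_q(1.2345, 0, 99), 1.2345)  # alpha = 0: untouched
  expect_equal(update_q(1.2345, 1, 99), 99)          # alpha = 1: replaced
  expect_error(update_q(1, 1.5, 1), "alpha")
  # property: stays within [0, n_max] when v does
  set.seed(1)
  q <- runif(1, 0, 8)
  for (i in 1:200) {
    q <- update_q(q, runif(1), runif(1, 0, 8))
    expect_gte(q, 0); expect_lte(q, 8)
  }
})

test_that("softmax probabilities are exact, normalized, and shift-invariant", {
  expect_equal(softmax_probabilities(c(3, 1, 2, 0), beta = 0), rep(0.25, 4))
  expect_equal(softmax_probabilities(c(5, 5), beta = 7), c(0.5, 0.5))
  pr <- softmax_probabilities(c(1, 0), beta = 10)
  expect_equal(pr, c(exp(10) / (exp(10) + 1), 1 / (exp(10) + 1)), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:20) {
    q <- runif(5, 0, 8)
    p1 <- softmax_probabilities(q, beta = 3)
    expect_equal(sum(p1), 1, tolerance = 1e-12)
    expect_equal(p1, softmax_probabilities(q + 123.4, beta = 3), tolerance = 1e-12)
    # stable at extreme magnitudes (beta * Q of several hundred)
    expect_false(any(is.nan(softmax_probabilities(q * 100, beta = 20))))
  }
})

test_that("raising a Q value never decreases its choice probability", {
  set.seed(3)
  for (i in 1:50) {
    q <- runif(6, 0, 8)
    bump <- q; bump[4] <- bump[4] + runif(1, 0, 2)
    expect_gte(softmax_probabilities(bump, 10)[4], softmax_probabilities(q, 10)[4])
  }
})

test_that("choose_destination matches softmax frequencies", {
  set.seed(4)
  draws <- replicate(4000, choose_destination(c(11L, 22L), c(0.3, 0.0), beta = 5))
  p_hat <- mean(draws == 11L)
  expect_equal(p_hat, softmax_probabilities(c(0.3, 0), 5)[1], tolerance = 0.03)
  expect_identical(choose_destination(7L, 1.0, 10), 7L)
  expect_error(choose_destination(integer(0), numeric(0), 10), "no allowed")
})

test_that("working memory excludes plants visited within the span", {
  last <- c(100, 100, -Inf)
  expect_identical(working_memory_filter(last, now = 150, wm_span = 60),
                   c(TRUE, TRUE, FALSE))   # 50 s ago: excluded
  expect_identical(working_memory_filter(last, now = 161, wm_span = 60),
                   c(FALSE, FALSE, FALSE)) # 61 s ago: available again
  expect_identical(working_memory_filter(last, now = 160, wm_span = 60),
                   c(FALSE, FALSE, FALSE)) # exactly the span: available
  expect_identical(working_memory_filter(last, now = 100, wm_span = 0),
                   c(FALSE, FALSE, FALSE)) # span 0 excludes nothing
})

test_that("bouts end on a full crop or on the distance cap", {
  expect_true(should_end_bout(40, 40, 0, 10, 3000))
  expect_false(should_end_bout(0, 40, 0, 10, 3000))
  expect_true(should_end_bout(0, 40, 2995, 10, 3000))
  expect_false(should_end_bout(0, 40, 2990, 10, 3000))
  # five full-plant harvests fill a 5-load crop exactly
  crop <- 0
  for (k in 1:5) crop <- crop + harvest(8, 5 * 8 - crop)$collected
  expect_true(should_end_bout(crop, 5 * 8, 0, 1, Inf))
})
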