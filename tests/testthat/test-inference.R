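test_that("Bayes posterior matches the four-term hand computation", {
  b <- new_belief()
  # uninformative likelihood column: posterior equals prior
  bu <- new_belief(likelihood = matrix(0.25, 4, 4))
  expect_equal(bayes_posterior(bu, 0), bu$prior)
  # hand example: uniform prior, column (0.7, 0.1, 0.1, 0.1), normalizer 0.25
  expect_equal(bayes_posterior(b, 0), c(0.7, 0.1, 0.1, 0.1))
  # degenerate prior is absorbing
  bd <- new_belief(prior = c(1, 0, 0, 0))
  expect_equal(bayes_posterior(bd, 2), c(1, 0, 0, 0))
  # oracle equivalence on random beliefs
  set.seed(11)
  for (i in 1:100) {
    pr <- as.vector(rmultinom(1, 60, rep(0.25, 4))) / 60
    lik <- t(apply(matrix(rexp(16), 4), 1, function(r) r / sum(r)))
    bb <- new_belief(pr, lik)
    d <- sample(0:3, 1)
    num <- vapply(1:4, function(h) lik[h, d + 1] * pr[h], numeric(1))
    expect_equal(bayes_posterior(bb, d), num / sum(num), tolerance = 1e-12)
    expect_equal(sum(bayes_posterior(bb, d)), 1, tolerance = 1e-9)
  }
})

test_that("zero normalizer passes the prior through unchanged", {
  lik <- default_likelihood()
  lik[, 1] <- 0          # nobody predicts d = 0
  lik <- lik / rowSums(lik)
  b <- new_belief(likelihood = lik)
  expect_equal(bayes_posterior(b, 0), b$prior)
})

test_that("roulette selection implements the min-cumulative rule", {
  w <- c(0.2, 0.1, 0.4, 0.3)  # cumulative 0.2 0.3 0.7 1.0
  expect_identical(roulette_select(w, r = 0.5), 2L)
  expect_identical(roulette_select(w, r = 0.2), 0L)
  expect_identical(roulette_select(c(1, 0, 0, 0), r = 0.7), 0L)
  expect_error(roulette_select(c(0, 0, 0, 0)), "zero")
})

test_that("inverse-roulette favors low-probability hypotheses per the EP rule", {
  post <- c(0.2, 0.1, 0.4, 0.3)  # EP = 0.8 1.7 2.3 3.0
  expect_identical(select_inverse_target(post, r = 1.0), 1L)
  expect_identical(select_inverse_target(post, r = 0.5), 0L)
  expect_identical(select_inverse_target(post, r = 2.0), 2L)
  expect_identical(select_inverse_target(post, r = 3.0), 3L)
})

test_that("roulette empirical frequencies match their selection probabilities", {
  set.seed(5)
  w <- c(0.2, 0.1, 0.4, 0.3)
  n <- 1e5
  draws <- vapply(runif(n, 0, 1), function(r) roulette_select(w, r),
                  integer(1))
  expect_gt(chisq.test(tabulate(draws + 1, 4), p = w)$p.value, 0.01)
  post <- c(0.2, 0.1, 0.4, 0.3)
  inv <- vapply(runif(n, 0, 3), function(r) select_inverse_target(post, r),
                integer(1))
  expect_gt(chisq.test(tabulate(inv + 1, 4), p = (1 - post) / 3)$p.value,
            0.01)
  # uniform posterior: each target equally likely
  invu <- vapply(runif(n, 0, 3),
                 function(r) select_inverse_target(rep(0.25, 4), r),
                 integer(1))
  expect_gt(chisq.test(tabulate(invu + 1, 4))$p.value, 0.01)
})

test_that("window probability is the normalized symbol frequency", {
  expect_equal(window_probability(c(0, 0, 2, 1)), c(0.5, 0.25, 0.25, 0))
  expect_equal(window_probability(c(2, 2, 2)), c(0, 0, 1, 0))
  expect_error(window_probability(integer(0)), "empty")
  set.seed(3)
  buf <- sample(0:3, 40, replace = TRUE)
  counts <- vapply(0:3, function(s) sum(buf == s), numeric(1))
  expect_equal(window_probability(buf), counts / 40)
})

test_that("inverse Bayes replaces exactly one likelihood row", {
  b <- new_belief()
  wp <- c(0.5, 0.25, 0.25, 0)
  b2 <- apply_inverse_bayes(b, f = 1, wp = wp)
  expect_equal(b2$likelihood[2, ], wp)
  expect_equal(b2$likelihood[-2, ], b$likelihood[-2, ])
  expect_equal(b2$prior, b$prior)
  expect_equal(rowSums(b2$likelihood), rep(1, 4))
  # replacing a row with itself is a no-op
  b3 <- apply_inverse_bayes(b2, 1, wp)
  expect_identical(b3, b2)
})

test_that("inference step preserves normalization and BO freezes the table", {
  set.seed(21)
  agent <- list(belief = new_belief(), d = 2L, h = 0L, window = integer(0))
  lik0 <- agent$belief$likelihood
  for (i in 1:200) {
    agent <- inference_step(agent, "BO")
    expect_equal(sum(agent$belief$prior), 1, tolerance = 1e-9)
    expect_true(agent$d %in% 0:3 && agent$h %in% 0:3)
  }
  expect_identical(agent$belief$likelihood, lik0)

  # BIB with a pure window forces a pure likelihood row
  agent <- list(belief = new_belief(), d = 0L, h = 0L,
                window = c(0L, 0L, 0L, 0L))
  set.seed(2)
  a2 <- inference_step(agent, "BIB", m = 10)
  expect_true(any(apply(a2$belief$likelihood, 1,
                        function(r) identical(r, c(1, 0, 0, 0)))))
  # rows stay stochastic over many BIB steps
  set.seed(22)
  agent <- list(belief = new_belief(), d = 1L, h = 2L, window = integer(0))
  for (i in 1:200) {
    agent <- inference_step(agent, "BIB", m = 5)
    expect_equal(rowSums(agent$belief$likelihood), rep(1, 4),
                 tolerance = 1e-9)
    expect_equal(sum(agent$belief$prior), 1, tolerance = 1e-9)
  }
})
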