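test_that("mean turn matches brute-force recomputation", {
  tr <- circle_track(40, pi / 20)
  expect_equal(mean_turn(tr[, 1], tr[, 2], t = 20, W = 10), pi / 20,
               tolerance = 1e-9)
  bl <- ballistic_track(40)
  expect_equal(mean_turn(bl[, 1], bl[, 2], t = 20, W = 10), 0)
  expect_true(is.na(mean_turn(tr[, 1], tr[, 2], t = 11, W = 10)))
  set.seed(51)
  zz <- zigzag_track(60, 0.3)
  for (t in c(13, 25, 40)) {
    angles <- vapply(3:nrow(zz), function(s)
      bending_angle(zz[s - 2, ], zz[s - 1, ], zz[s, ], v = 5), numeric(1))
    oracle <- mean(angles[(t - 10 - 1):(t - 2) - 0])
    expect_equal(mean_turn(zz[, 1], zz[, 2], t = t, W = 10), oracle,
                 tolerance = 1e-9)
  }
})

test_that("tornado, translation and splash counts follow their thresholds", {
  n_steps <- 40
  # 6 agents circling at pi/20 per step (between pi/30 and pi/10)
  circles <- lapply(1:6, function(k) circle_track(n_steps, pi / 20) +
                      200 * k)
  traj_c <- make_traj(lapply(circles, `[`, , 1),
                      lapply(circles, `[`, , 2))
  expect_equal(tornado_count(traj_c, 30), 6)
  expect_equal(translation_count(traj_c, 30), 0)

  # ballistic swarm: all translation, no tornado
  lines <- lapply(1:6, function(k) ballistic_track(n_steps,
                                                   origin = c(0, 30 * k)))
  traj_l <- make_traj(lapply(lines, `[`, , 1), lapply(lines, `[`, , 2))
  expect_equal(translation_count(traj_l, 30), 6)
  expect_equal(tornado_count(traj_l, 30), 0)

  # turning faster than the upper bound is not a tornado
  fast <- lapply(1:4, function(k) circle_track(n_steps, pi / 5) + 100 * k)
  traj_f <- make_traj(lapply(fast, `[`, , 1), lapply(fast, `[`, , 2))
  expect_equal(tornado_count(traj_f, 30), 0)

  # mixed population is counted exactly
  mixed <- make_traj(c(lapply(circles[1:3], `[`, , 1),
                       lapply(lines[1:3], `[`, , 1)),
                     c(lapply(circles[1:3], `[`, , 2),
                       lapply(lines[1:3], `[`, , 2)))
  expect_equal(tornado_count(mixed, 30), 3)
  expect_equal(translation_count(mixed, 30), 3)

  # static-distance swarm never splashes; two departing agents both do
  expect_equal(splash_count(traj_l, 30), 0)
  dep <- make_traj(list(ballistic_track(n_steps, theta = 0)[, 1],
                        ballistic_track(n_steps, theta = pi)[, 1]),
                   list(ballistic_track(n_steps, theta = 0)[, 2],
                        ballistic_track(n_steps, theta = pi)[, 2]))
  expect_equal(splash_count(dep, 30), 2)  # growth 100 > 8 over T = 10
})

test_that("splash count equals a brute-force nearest-neighbor oracle", {
  set.seed(52)
  n <- 30; T_total <- 25
  xs <- lapply(1:n, function(k) cumsum(c(runif(1, 0, 100),
                                         5 * cos(runif(T_total, 0, 2 * pi)))))
  ys <- lapply(1:n, function(k) cumsum(c(runif(1, 0, 100),
                                         5 * sin(runif(T_total, 0, 2 * pi)))))
  traj <- make_traj(xs, ys)
  par <- index_params(T_spl = 10, W = 10)
  rmin_or <- function(t) {
    p <- cbind(traj$x[t, ], traj$y[t, ])
    vapply(1:n, function(k)
      min(sqrt((p[k, 1] - p[-k, 1])^2 + (p[k, 2] - p[-k, 2])^2)),
      numeric(1))
  }
  for (t in c(15, 20, 25)) {
    oracle <- sum(rmin_or(t) - rmin_or(t - 10) > 8)
    expect_equal(splash_count(traj, t, par), oracle)
  }
})

test_that("index series covers admissible steps and bounds counts by N", {
  set.seed(53)
  traj <- simulate_swarm(swarm_config("SPP", n = 25, steps = 60,
                                      epsilon = 0.15, boundary = "periodic",
                                      init = "uniform", seed = 3))
  ser <- index_series(traj)
  expect_equal(ser$t, 12:60)
  expect_true(all(ser$tornado >= 0 & ser$tornado <= 25))
  expect_true(all(ser$splash >= 0 & ser$splash <= 25))
  expect_true(all(ser$translation >= 0 & ser$translation <= 25))
  t_mid <- 30
  expect_equal(ser$tornado[ser$t == t_mid], tornado_count(traj, t_mid))
  expect_equal(ser$splash[ser$t == t_mid], splash_count(traj, t_mid))
})

test_that("ratio summaries use the six standard statistics and skip zeros", {
  ser <- data.frame(t = 1:3, tornado = c(10, 10, 10),
                    splash = c(5, 5, 5), translation = c(20, 20, 20))
  class(ser) <- c("index_series", "data.frame")
  s <- ratio_summary(ser)
  expect_true(all(s$tornado_translation == 0.5))
  expect_true(all(s$splash_translation == 0.25))
  expect_equal(s$skipped, 0)

  ser2 <- data.frame(t = 1:4, tornado = c(2, 4, 9, 1),
                     splash = c(1, 0, 3, 2), translation = c(4, 8, 6, 0))
  class(ser2) <- c("index_series", "data.frame")
  rs <- ratio_series(ser2)
  expect_equal(nrow(rs), 3)
  expect_equal(attr(rs, "skipped"), 1)
  s2 <- ratio_summary(ser2)
  tt <- c(0.5, 0.5, 1.5)
  expect_equal(unname(s2$tornado_translation),
               c(min(tt), unname(quantile(tt, 0.25)), median(tt), mean(tt),
                 unname(quantile(tt, 0.75)), max(tt)))

  ser3 <- ser2; ser3$translation <- 0
  expect_error(ratio_summary(ser3), "zero")
})

test_that("nonparametric comparisons behave on known inputs", {
  set.seed(54)
  a <- rnorm(500)
  ident <- compare_models(a = a, b = a)
  expect_gt(ident$wilcoxon, 0.9)
  # Shapiro-Wilk accepts normal data at n = 500
  expect_gt(ident$shapiro[["a"]], 0.05)
  # disjoint support: decisive rank-sum rejection
  disj <- compare_models(runif(50), 10 + runif(50))
  expect_lt(disj$wilcoxon, 0.001)
  # three groups trigger Kruskal-Wallis
  kw <- compare_models(runif(50), runif(50), 5 + runif(50))
  expect_lt(kw$kruskal, 0.001)
  expect_true(is.na(kw$wilcoxon))
  # degenerate all-tied series: not computable, reported as NA
  deg <- compare_models(rep(1, 10), rep(1, 10))
  expect_true(is.na(deg$shapiro[[1]]))
})
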