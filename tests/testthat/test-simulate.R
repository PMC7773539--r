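test_that("initialization respects placement, bounds and determinism", {
  cfg <- swarm_config("BIB", n = 1000, steps = 10, epsilon = 0.1,
                      init = "central", central_side = 50, seed = 9)
  set.seed(9); st <- init_swarm(cfg)
  expect_true(all(abs(st$pos) <= 25))
  a <- agent_state(st, 17)
  expect_s3_class(a$belief, "belief")
  expect_equal(sum(a$belief$prior), 1)
  expect_equal(rowSums(a$belief$likelihood), rep(1, 4))
  # virtual previous position is V behind along the initial heading
  expect_equal(sqrt(sum((a$pos - a$prev_pos)^2)), 5, tolerance = 1e-12)
  set.seed(9); st2 <- init_swarm(cfg)
  expect_identical(st, st2)

  one <- swarm_config("SPP", n = 1, steps = 5, epsilon = 0, seed = 1)
  set.seed(1)
  expect_silent(st1 <- init_swarm(one))
  expect_error(swarm_config("BIB", n = 10, steps = 5, epsilon = 0.1,
                            init = "central", central_side = -1),
               "central_side")
})

test_that("trajectories are deterministic in (config, seed) and exactly V-paced", {
  cfg <- swarm_config("BIB", n = 30, steps = 80, epsilon = 0.2, seed = 5)
  t1 <- simulate_swarm(cfg)
  t2 <- simulate_swarm(cfg)
  expect_identical(t1, t2)
  t3 <- simulate_swarm(swarm_config("BIB", n = 30, steps = 80,
                                    epsilon = 0.2, seed = 6))
  expect_false(identical(t1$x, t3$x))
  # every displacement of every agent has magnitude exactly V
  for (traj in list(t1, simulate_swarm(swarm_config("SPP", n = 20,
                                                    steps = 50,
                                                    epsilon = 0.3,
                                                    seed = 2)))) {
    sp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    expect_equal(max(abs(sp - traj$config$v)), 0, tolerance = 1e-9)
  }
})

test_that("a lone noise-free SPP agent is ballistic", {
  traj <- simulate_swarm(swarm_config("SPP", n = 1, steps = 40,
                                      epsilon = 0, seed = 3))
  d1 <- c(traj$x[2, 1] - traj$x[1, 1], traj$y[2, 1] - traj$y[1, 1])
  disp <- c(traj$x[40, 1] - traj$x[1, 1], traj$y[40, 1] - traj$y[1, 1])
  # net displacement V * (T - 1) along the initial heading
  expect_equal(sqrt(sum(disp^2)), 5 * 39, tolerance = 1e-9)
  expect_equal(disp / 39, d1, tolerance = 1e-9)
})

test_that("low-noise periodic SPP coalesces into an aligned swarm", {
  traj <- simulate_swarm(swarm_config("SPP", n = 60, steps = 400,
                                      epsilon = 0.001,
                                      boundary = "periodic", L = 100,
                                      init = "uniform", seed = 4))
  T_total <- nrow(traj$x)
  vx <- traj$x[T_total, ] - traj$x[T_total - 1, ]
  vy <- traj$y[T_total, ] - traj$y[T_total - 1, ]
  polarization <- sqrt(sum(vx)^2 + sum(vy)^2) / (60 * 5)
  expect_gt(polarization, 0.9)
})

test_that("engine inference agrees with the scalar per-agent operations", {
  # one agent, shared RNG stream: the vectorized engine must reproduce the
  # composition of the exported scalar operations draw for draw
  cfg <- swarm_config("BIB", n = 1, steps = 60, epsilon = 0.25, m = 7,
                      seed = 31)
  traj <- simulate_swarm(cfg)

  set.seed(31)
  st <- init_swarm(cfg)
  a <- agent_state(st, 1)
  agent <- list(belief = a$belief, d = a$d, h = a$h, window = integer(0))
  pos <- a$pos; prev <- a$prev_pos; theta_prev <- a$theta
  xs <- numeric(60); ys <- numeric(60); ds <- integer(60)
  xs[1] <- pos[1]; ys[1] <- pos[2]; ds[1] <- agent$d
  for (t in 2:60) {
    th <- mean_heading(1L, rbind(pos), rbind(prev))
    if (is.na(th)) th <- theta_prev
    newpos <- move_agent(pos, th, agent$d, cfg$epsilon, cfg$v)
    prev <- pos; pos <- newpos; theta_prev <- th
    agent <- inference_step(agent, "BIB", m = cfg$m,
                            prior_leak = cfg$prior_leak,
                            response_floor = cfg$response_floor)
    xs[t] <- pos[1]; ys[t] <- pos[2]; ds[t] <- agent$d
  }
  expect_equal(traj$x[, 1], xs, tolerance = 1e-12)
  expect_equal(traj$y[, 1], ys, tolerance = 1e-12)
  expect_identical(as.integer(traj$d[, 1]), ds)
})

test_that("recorded beliefs stay normalized along a BIB run", {
  cfg <- swarm_config("BIB", n = 40, steps = 120, epsilon = 0.1, seed = 8)
  set.seed(8)
  st <- init_swarm(cfg)
  for (t in 1:120) {
    st <- bibswarm:::.move_all(st, cfg)
    st <- bibswarm:::.infer_all(st, cfg)
    expect_equal(max(abs(rowSums(st$prior) - 1)), 0, tolerance = 1e-9)
  }
  for (k in c(1, 20, 40)) {
    b <- agent_state(st, k)$belief
    expect_equal(rowSums(b$likelihood), rep(1, 4), tolerance = 1e-9)
  }
})
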