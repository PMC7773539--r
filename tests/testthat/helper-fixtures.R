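# Shared fixtures and independent oracles used across the test files.

# brute-force O(N^2) neighbor oracle, minimum image under periodic boundary
brute_neighbors <- function(positions, R, boundary = "open", L = NULL) {
  n <- nrow(positions)
  lapply(seq_len(n), function(k) {
    dx <- positions[, 1] - positions[k, 1]
    dy <- positions[, 2] - positions[k, 2]
    if (boundary == "periodic") {
      dx <- dx - L * round(dx / L)
      dy <- dy - L * round(dy / L)
    }
    which(dx * dx + dy * dy <= R * R)
  })
}

# track builders (unwrapped coordinates, speed v per step)
ballistic_track <- function(n_steps, v = 5, theta = 0, origin = c(0, 0)) {
  t <- 0:n_steps
  cbind(x = origin[1] + v * t * cos(theta),
        y = origin[2] + v * t * sin(theta))
}

# constant-curvature track turning `beta` radians per step
circle_track <- function(n_steps, beta, v = 5) {
  headings <- cumsum(c(0, rep(beta, n_steps - 1)))
  x <- cumsum(c(0, v * cos(headings)))
  y <- cumsum(c(0, v * sin(headings)))
  cbind(x = x, y = y)
}

# zigzag: turning angle alternates +beta, -beta every step
zigzag_track <- function(n_steps, beta, v = 5) {
  headings <- cumsum(c(0, rep(c(beta, -beta), length.out = n_steps - 1)))
  x <- cumsum(c(0, v * cos(headings)))
  y <- cumsum(c(0, v * sin(headings)))
  cbind(x = x, y = y)
}

# wrap a bare coordinate matrix list into a minimal swarm_trajectory
make_traj <- function(xs, ys, model = "SPP", epsilon = 0, v = 5,
                      boundary = "open") {
  x <- do.call(cbind, xs); y <- do.call(cbind, ys)
  cfg <- swarm_config(model, n = ncol(x), steps = nrow(x),
                      epsilon = epsilon, v = v, boundary = boundary,
                      seed = 1)
  structure(list(x = x, y = y,
                 d = matrix(0L, nrow(x), ncol(x)),
                 h = matrix(0L, nrow(x), ncol(x)), config = cfg),
            class = "swarm_trajectory")
}
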