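# Time-stepping orchestration: initialize a swarm, advance all agents
# synchronously, record trajectories.
#
# The engine keeps the whole swarm in flat matrices (positions N x 2,
# prior N x 4, likelihood N x 4 x 4 indexed [agent, h, d]) and advances all
# agents with vectorized operations; per-agent semantics are identical to
# the scalar operations in inference.R (tested by a one-agent equivalence
# run on a shared RNG stream).

#' Initialize a swarm state
#'
#' Places `n` agents per `config$init`, gives each a random initial heading
#' `theta0 ~ Uniform[0, 2 pi)` with a virtual previous position
#' `pos - v (cos theta0, sin theta0)` (so the first heading computation has
#' a well-defined displacement), and initializes beliefs: uniform prior,
#' likelihood `P(d|h) = 0.7` if `d == h` else `0.1`, initial data symbol
#' uniform on `0:3`, initial hypothesis sampled from the prior.
#'
#' @param config a [swarm_config()]. The caller controls the RNG (use
#'   `set.seed()`; [simulate_swarm()] does this from `config$seed`).
#' @return A `swarm_state` list with matrices `pos`, `prev` (`n x 2`),
#'   vectors `theta`, `d`, `h`, matrix `prior` (`n x 4`), array `lik`
#'   (`n x 4 x 4`, `[agent, h, d]`), and the data window buffer.
#' @seealso [agent_state()] to extract one agent in per-agent form.
#' @export
init_swarm <- function(config) {
  validate_swarm_config(config)
  n <- config$n
  if (config$init == "central") {
    ctr <- if (config$boundary == "periodic") config$L / 2 else 0
    half <- config$central_side / 2
    pos <- cbind(runif(n, ctr - half, ctr + half),
                 runif(n, ctr - half, ctr + half))
  } else {
    pos <- cbind(runif(n, 0, config$L), runif(n, 0, config$L))
  }
  theta0 <- runif(n, 0, 2 * pi)
  prev <- pos - config$v * cbind(cos(theta0), sin(theta0))
  st <- list(pos = pos, prev = prev, theta = theta0,
             d = integer(n), h = integer(n),
             prior = NULL, lik = NULL, win = NULL, win_n = 0L)
  if (config$model != "SPP") {
    st$d <- sample(0:3, n, replace = TRUE)
    st$h <- sample(0:3, n, replace = TRUE)  # drawn from the uniform prior
    st$prior <- matrix(0.25, n, 4)
    lik0 <- default_likelihood()
    st$lik <- array(rep(lik0, each = n), dim = c(n, 4, 4))
    if (config$model == "BIB")
      st$win <- matrix(NA_integer_, n, config$m)
  }
  structure(st, class = "swarm_state")
}

#' Extract one agent from a swarm state
#'
#' @param state a `swarm_state` from [init_swarm()].
#' @param k agent index.
#' @return List with `pos`, `prev_pos`, `theta`, `d`, `h`, and (for BO/BIB
#'   states) `belief` and `window`.
#' @export
agent_state <- function(state, k) {
  out <- list(pos = state$pos[k, ], prev_pos = state$prev[k, ],
              theta = state$theta[k], d = state$d[k], h = state$h[k])
  if (!is.null(state$prior)) {
    lik <- matrix(state$lik[k, , ], 4, 4)
    out$belief <- new_belief(state$prior[k, ], lik)
    if (!is.null(state$win))
      out$window <- state$win[k, seq_len(state$win_n)]
  }
  out
}

# one synchronous kinematic step: headings from the (t-1, t) configurations,
# then every agent moves distance v
.move_all <- function(st, cfg) {
  n <- cfg$n
  ref <- if (cfg$boundary == "periodic") st$prev %% cfg$L else st$prev
  d2 <- .dist2_matrix(ref, cfg$boundary, cfg$L)
  adj <- d2 <= cfg$r^2
  disp <- st$pos - st$prev
  sx <- adj %*% disp[, 1]
  sy <- adj %*% disp[, 2]
  theta <- atan2(sy, sx)
  und <- abs(sx) < 1e-12 & abs(sy) < 1e-12
  theta[und] <- st$theta[und]
  u <- runif(n, 0, cfg$epsilon)
  sgn <- c(1, -1)[1L + (runif(n) < 0.5)]
  phi <- as.numeric(theta) + sgn * u + st$d * (pi / 2)
  st$prev <- st$pos
  st$pos <- st$pos + cfg$v * cbind(cos(phi), sin(phi))
  st$theta <- as.numeric(theta)
  st
}

# vectorized inference step for all agents (BO / BIB)
.infer_all <- function(st, cfg) {
  n <- cfg$n
  ii <- rep(seq_len(n), 4L)
  jj <- rep(1:4, each = n)
  # Bayes: posterior over h given the current data symbol
  likcol <- matrix(st$lik[ii + (jj - 1L) * n + st$d[ii] * (4L * n)], n, 4)
  if (cfg$likelihood_floor > 0)
    likcol <- pmax(likcol, cfg$likelihood_floor)
  num <- likcol * st$prior
  z <- rowSums(num)
  post <- num / z
  bad <- which(!(z > 0))
  if (length(bad)) post[bad, ] <- st$prior[bad, , drop = FALSE]
  if (cfg$prior_leak > 0)
    post <- (1 - cfg$prior_leak) * post + cfg$prior_leak / 4
  st$prior <- post
  if (cfg$model == "BIB") {
    # push the newest datum, then windowed empirical data frequency
    if (st$win_n < cfg$m) {
      st$win_n <- st$win_n + 1L
      st$win[, st$win_n] <- st$d
    } else {
      st$win <- cbind(st$win[, -1L, drop = FALSE], st$d)
    }
    w <- st$win[, seq_len(st$win_n), drop = FALSE]
    wp <- vapply(0:3, function(s) rowSums(w == s), numeric(n)) / st$win_n
    # inverse roulette: low-probability hypotheses picked preferentially
    q <- 1 - post
    ep1 <- q[, 1]; ep2 <- ep1 + q[, 2]; ep3 <- ep2 + q[, 3]
    rf <- runif(n, 0, 3)
    f <- (rf > ep1 + 1e-12) + (rf > ep2 + 1e-12) + (rf > ep3 + 1e-12)
    st$lik[ii + f[ii] * n + (jj - 1L) * (4L * n)] <- as.vector(wp)
  }
  # roulette-sample the new hypothesis from the posterior
  cp1 <- post[, 1]; cp2 <- cp1 + post[, 2]; cp3 <- cp2 + post[, 3]
  rh <- runif(n)
  h <- (rh > cp1 + 1e-12) + (rh > cp2 + 1e-12) + (rh > cp3 + 1e-12)
  st$h <- as.integer(pmin(h, 3))
  # roulette-sample the new data symbol from that hypothesis's row
  rowlik <- matrix(st$lik[ii + st$h[ii] * n + (jj - 1L) * (4L * n)], n, 4)
  if (cfg$response_floor > 0) {
    rowlik <- pmax(rowlik, cfg$response_floor)
    rowlik <- rowlik / rowSums(rowlik)
  }
  dp1 <- rowlik[, 1]; dp2 <- dp1 + rowlik[, 2]; dp3 <- dp2 + rowlik[, 3]
  rd <- runif(n)
  dn <- (rd > dp1 + 1e-12) + (rd > dp2 + 1e-12) + (rd > dp3 + 1e-12)
  st$d <- as.integer(pmin(dn, 3))
  st
}

#' Run a swarm simulation
#'
#' Advances the swarm synchronously for `config$steps` time steps: at each
#' step all headings are computed from the previous two configurations
#' (neighborhoods of radius `r` around the previous positions,
#' minimum-image under a periodic boundary), then all agents move distance
#' `v`, then (BO/BIB) all agents run one inference step. The trajectory is
#' a pure function of the configuration: the same `config` (including
#' `seed`) reproduces it bit for bit.
#'
#' @param config a [swarm_config()] or [swarm_preset()].
#' @return An object of class `swarm_trajectory`: list with `steps x n`
#'   matrices `x`, `y` (unwrapped coordinates), `d`, `h` (symbols in force
#'   at each time step), and the `config`.
#' @examples
#' traj <- simulate_swarm(swarm_config("SPP", n = 20, steps = 50,
#'                                     epsilon = 0.01, seed = 1))
#' traj
#' @export
simulate_swarm <- function(config) {
  validate_swarm_config(config)
  set.seed(config$seed)
  n <- config$n
  T_total <- config$steps
  st <- init_swarm(config)
  x <- matrix(NA_real_, T_total, n)
  y <- matrix(NA_real_, T_total, n)
  dmat <- matrix(NA_integer_, T_total, n)
  hmat <- matrix(NA_integer_, T_total, n)
  x[1, ] <- st$pos[, 1]; y[1, ] <- st$pos[, 2]
  dmat[1, ] <- st$d; hmat[1, ] <- st$h
  if (T_total > 1) for (t in 2:T_total) {
    st <- .move_all(st, config)
    if (config$model != "SPP") st <- .infer_all(st, config)
    x[t, ] <- st$pos[, 1]; y[t, ] <- st$pos[, 2]
    dmat[t, ] <- st$d; hmat[t, ] <- st$h
  }
  structure(list(x = x, y = y, d = dmat, h = hmat, config = config),
            class = "swarm_trajectory")
}

#' @export
print.swarm_trajectory <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Swarm trajectory: %s model, %d agents, %d time steps\n",
              cfg$model, cfg$n, nrow(x$x)))
  cat(sprintf("  boundary %s, epsilon = %g, seed = %d\n",
              cfg$boundary, cfg$epsilon, cfg$seed))
  ext <- c(range(x$x), range(x$y))
  cat(sprintf("  extent: x [%.1f, %.1f], y [%.1f, %.1f] (unwrapped)\n",
              ext[1], ext[2], ext[3], ext[4]))
  invisible(x)
}

#' @describeIn simulate_swarm long-format view: one row per `(t, agent)`
#'   with columns `t, agent, x, y, d, h`.
#' @param x,row.names,optional,... standard [as.data.frame()] arguments.
#' @export
as.data.frame.swarm_trajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  T_total <- nrow(x$x); n <- ncol(x$x)
  data.frame(t = rep(seq_len(T_total), n),
             agent = rep(seq_len(n), each = T_total),
             x = as.vector(x$x), y = as.vector(x$y),
             d = as.vector(x$d), h = as.vector(x$h))
}

#' Plot agent trajectories
#'
#' Draws the unwrapped paths of a subset of agents.
#'
#' @param x a `swarm_trajectory`.
#' @param agents indices of agents to draw (default: up to 50).
#' @param ... passed to [matplot()].
#' @return Invisibly, `x`.
#' @export
plot.swarm_trajectory <- function(x, agents = seq_len(min(50, ncol(x$x))),
                                  ...) {
  matplot(x$x[, agents, drop = FALSE], x$y[, agents, drop = FALSE],
          type = "l", lty = 1, col = adjustcolor(seq_along(agents), 0.6),
          xlab = "x", ylab = "y",
          main = sprintf("%s trajectories", x$config$model), asp = 1, ...)
  invisible(x)
}
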