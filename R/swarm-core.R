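# Kinematics of the self-propelled particles: neighborhoods under open or
# periodic boundaries, mean heading of a neighborhood, and the movement rule.

# minimum-image wrap of coordinate differences into [-L/2, L/2)
.min_image <- function(delta, L) delta - L * round(delta / L)

# N x N squared-distance matrix, minimum image under periodic boundary
.dist2_matrix <- function(positions, boundary = "open", L = NULL) {
  dx <- outer(positions[, 1], positions[, 1], "-")
  dy <- outer(positions[, 2], positions[, 2], "-")
  if (boundary == "periodic") {
    dx <- .min_image(dx, L)
    dy <- .min_image(dy, L)
  }
  dx * dx + dy * dy
}

#' Neighbors of one agent
#'
#' All agents within radius `R` of agent `k` (agent `k` itself included:
#' its distance to itself is 0). Under a periodic boundary distances follow
#' the minimum-image convention.
#'
#' @param k agent index (1-based).
#' @param positions numeric `N x 2` matrix of coordinates.
#' @param R neighborhood radius (> 0).
#' @param boundary `"open"` or `"periodic"`.
#' @param L box side, required when `boundary = "periodic"`.
#' @return Integer vector of neighbor indices (always contains `k`).
#' @examples
#' pos <- rbind(c(0, 0), c(10, 0), c(100, 0))
#' neighbors_of(1, pos, R = 20)
#' @export
neighbors_of <- function(k, positions, R, boundary = c("open", "periodic"),
                         L = NULL) {
  boundary <- match.arg(boundary)
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  stopifnot(R > 0, k >= 1, k <= nrow(positions))
  dx <- positions[, 1] - positions[k, 1]
  dy <- positions[, 2] - positions[k, 2]
  if (boundary == "periodic") {
    dx <- .min_image(dx, L)
    dy <- .min_image(dy, L)
  }
  which(dx * dx + dy * dy <= R * R)
}

#' Neighbor lists for all agents
#'
#' Neighbor sets for every agent at once. `method = "grid"` bins agents into
#' cells of side `R` and only scans the 3x3 cell neighborhood, giving
#' near-linear scaling; `method = "brute"` is the direct all-pairs scan. The
#' two are exactly equivalent (the grid method is oracle-tested against the
#' brute force).
#'
#' @inheritParams neighbors_of
#' @param method `"grid"` or `"brute"`.
#' @return List of integer vectors, one per agent, each sorted and
#'   containing the agent itself.
#' @export
neighbor_lists <- function(positions, R, boundary = c("open", "periodic"),
                           L = NULL, method = c("grid", "brute")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  stopifnot(R > 0)
  n <- nrow(positions)
  if (method == "brute" || n < 32) {
    d2 <- .dist2_matrix(positions, boundary, L)
    return(lapply(seq_len(n), function(k) which(d2[k, ] <= R * R)))
  }
  .neighbor_lists_grid(positions, R, boundary, L)
}

.neighbor_lists_grid <- function(positions, R, boundary, L) {
  n <- nrow(positions)
  if (boundary == "periodic") {
    pw <- positions %% L
    ncell <- max(1L, floor(L / R))
    cell_side <- L / ncell
    cx <- pmin(floor(pw[, 1] / cell_side), ncell - 1)
    cy <- pmin(floor(pw[, 2] / cell_side), ncell - 1)
  } else {
    xmin <- min(positions[, 1]); ymin <- min(positions[, 2])
    cx <- floor((positions[, 1] - xmin) / R)
    cy <- floor((positions[, 2] - ymin) / R)
    ncell <- NULL
  }
  key <- paste(cx, cy)
  bins <- split(seq_len(n), key)
  out <- vector("list", n)
  R2 <- R * R
  for (k in seq_len(n)) {
    # candidate agents from the 3x3 cell block around k's cell
    cand <- integer(0)
    for (ox in -1:1) for (oy in -1:1) {
      gx <- cx[k] + ox; gy <- cy[k] + oy
      if (boundary == "periodic") { gx <- gx %% ncell; gy <- gy %% ncell }
      b <- bins[[paste(gx, gy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- unique(cand)
    dx <- positions[cand, 1] - positions[k, 1]
    dy <- positions[cand, 2] - positions[k, 2]
    if (boundary == "periodic") {
      dx <- .min_image(dx, L)
      dy <- .min_image(dy, L)
    }
    out[[k]] <- sort(cand[dx * dx + dy * dy <= R2])
  }
  out
}

#' Mean heading of a neighborhood
#'
#' Angle of the summed displacement vector of the agents in `nbrs` between
#' two consecutive configurations, computed with the two-argument
#' arctangent so the full `[-pi, pi)` range is covered. When the summed
#' displacement is the zero vector the heading is undefined and `NA` is
#' returned (the caller keeps the previous heading).
#'
#' @param nbrs integer vector of neighbor indices (nonempty; an agent is
#'   always its own neighbor).
#' @param positions_t,positions_tm1 `N x 2` coordinate matrices at the
#'   current and previous time step (unwrapped).
#' @return Heading angle in radians, or `NA` when undefined.
#' @examples
#' p0 <- rbind(c(0, 0), c(1, 0))
#' p1 <- rbind(c(1, 0), c(1, 1))
#' mean_heading(1:2, p1, p0)  # atan2(1, 1) = pi/4
#' @export
mean_heading <- function(nbrs, positions_t, positions_tm1) {
  if (length(nbrs) == 0) stop("empty neighbor set")
  sx <- sum(positions_t[nbrs, 1] - positions_tm1[nbrs, 1])
  sy <- sum(positions_t[nbrs, 2] - positions_tm1[nbrs, 2])
  if (abs(sx) < 1e-12 && abs(sy) < 1e-12) return(NA_real_)
  atan2(sy, sx)
}

#' Move one agent
#'
#' One application of the movement rule: the new position is
#' `pos + V (cos phi, sin phi)` with
#' `phi = theta + s * u + d * pi/2`, where `u ~ Uniform[0, epsilon]` and
#' `s` is a fair sign, both drawn fresh. The offset symbol `d` rotates the
#' agent against the matched velocity in quarter turns; `d = 2` sends it
#' straight back through its flock mates.
#'
#' @param pos length-2 numeric position.
#' @param theta heading (radian).
#' @param d offset symbol in `0:3`.
#' @param epsilon maximum perturbation (radian).
#' @param v speed.
#' @return New length-2 position; the displacement magnitude is exactly `v`.
#' @examples
#' move_agent(c(0, 0), theta = 0, d = 2, epsilon = 0, v = 5)  # (-5, 0)
#' @export
move_agent <- function(pos, theta, d, epsilon, v = 5) {
  stopifnot(is.finite(theta), d %in% 0:3, epsilon >= 0)
  u <- runif(1, 0, epsilon)
  s <- if (runif(1) < 0.5) -1 else 1
  phi <- theta + s * u + d * pi / 2
  pos + v * c(cos(phi), sin(phi))
}
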