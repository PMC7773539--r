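# Bending-angle segmentation of trajectories into steps: a step ends
# wherever the turning angle exceeds alpha_max (default 2*pi/9), and its
# length is the Euclidean distance between consecutive bending points.

#' Bending angle at a triple of positions
#'
#' Angle in `[0, pi]` between the displacement `p0 -> p1` and `p1 -> p2`:
#' `acos` of their dot product divided by `V^2` (displacements always have
#' magnitude `V`), the argument clamped to `[-1, 1]` against rounding.
#'
#' @param p0,p1,p2 length-2 positions at three consecutive time steps.
#' @param v speed (displacement magnitude).
#' @return Bending angle in radians, in `[0, pi]`.
#' @examples
#' bending_angle(c(0, 0), c(5, 0), c(5, 5), v = 5)  # pi/2
#' @export
bending_angle <- function(p0, p1, p2, v = 5) {
  a <- p1 - p0
  b <- p2 - p1
  if (sum(a * a) < 1e-18 || sum(b * b) < 1e-18)
    stop("zero displacement in bending-angle computation")
  acos(max(-1, min(1, sum(a * b) / v^2)))
}

# bending-angle series for a whole track: element i is the angle at time
# i + 2, i.e. between displacements (i -> i+1) and (i+1 -> i+2)
.bending_series <- function(x, y, v) {
  dx <- diff(x); dy <- diff(y)
  m <- length(dx)
  if (m < 2) return(numeric(0))
  dot <- dx[-1] * dx[-m] + dy[-1] * dy[-m]
  acos(pmax(-1, pmin(1, dot / v^2)))
}

#' Extract step lengths from a single track
#'
#' Scans the track from its third position; whenever the bending angle at
#' time `t` strictly exceeds `alpha_max` the current step ends at position
#' `t - 1`, its length being the Euclidean distance from the previous
#' bending point to that position; the bending point then advances. The
#' track's first position is the initial bending point. The incomplete
#' trailing segment is discarded unless `emit_tail = TRUE`.
#'
#' Coordinates must be unwrapped (periodic runs store unwrapped positions,
#' so wrap jumps never fabricate bending points).
#'
#' @param x,y numeric coordinate vectors of one agent's track.
#' @param alpha_max turn threshold in radians (default `2 pi / 9` = 40
#'   degrees).
#' @param v speed.
#' @param emit_tail also emit the final (unterminated) segment.
#' @return Data frame with columns `start_t`, `end_t`, `length` (possibly
#'   zero rows).
#' @examples
#' # 5 steps east, a right-angle turn, 5 steps north: one 25-long step
#' x <- c(0:5 * 5, rep(25, 5)); y <- c(rep(0, 6), 1:5 * 5)
#' extract_steps(x, y, v = 5)
#' @export
extract_steps <- function(x, y, alpha_max = 2 * pi / 9, v = 5,
                          emit_tail = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n)
  empty <- data.frame(start_t = integer(0), end_t = integer(0),
                      length = numeric(0))
  if (n < 3) return(empty)
  alpha <- .bending_series(x, y, v)
  bend <- c(1L, which(alpha > alpha_max) + 1L)  # positions, 1-based times
  if (emit_tail) bend <- c(bend, n)
  bend <- unique(bend)
  if (length(bend) < 2) return(empty)
  from <- bend[-length(bend)]
  to <- bend[-1]
  data.frame(start_t = from, end_t = to,
             length = sqrt((x[to] - x[from])^2 + (y[to] - y[from])^2))
}

#' Pool step lengths over all agents of a trajectory
#'
#' Runs [extract_steps()] on every agent and concatenates the results with
#' agent provenance.
#'
#' @param traj a `swarm_trajectory` from [simulate_swarm()].
#' @param alpha_max turn threshold in radians.
#' @param emit_tail passed to [extract_steps()].
#' @return A `step_table`: data frame with columns `agent`, `start_t`,
#'   `end_t`, `length`.
#' @export
pool_steps <- function(traj, alpha_max = 2 * pi / 9, emit_tail = FALSE) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  v <- traj$config$v
  per <- lapply(seq_len(ncol(traj$x)), function(k) {
    s <- extract_steps(traj$x[, k], traj$y[, k], alpha_max, v, emit_tail)
    if (nrow(s)) cbind(agent = k, s) else NULL
  })
  out <- do.call(rbind, per)
  if (is.null(out))
    out <- data.frame(agent = integer(0), start_t = integer(0),
                      end_t = integer(0), length = numeric(0))
  class(out) <- c("step_table", "data.frame")
  out
}
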