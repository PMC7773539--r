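# Tornado / splash / translation behavior indexes: per-time-step counts of
# agents whose windowed mean turning angle lies in (alpha_tor, alpha_tor_hi)
# (tornado), is below alpha_trans (translation), or whose nearest-neighbor
# distance grew by more than r_spl over the last T_spl steps (splash). The
# indexes are not mutually exclusive.

#' Behavior-index parameters
#'
#' Thresholds for the three indexes. Defaults follow the study conditions:
#' `alpha_tor = alpha_trans = pi/30`, `alpha_tor_hi = pi/10`,
#' `r_spl = 8.0`. The turning window `W` and splash interval `T_spl`
#' (both 10 steps) set the averaging scales; with speed 5 a mean turn in
#' `(pi/30, pi/10)` corresponds to circling at radii of roughly 8 to 48
#' length units.
#'
#' @param alpha_tor lower tornado threshold (radian per step).
#' @param alpha_tor_hi upper tornado threshold (radian per step).
#' @param alpha_trans translation threshold (radian per step).
#' @param r_spl nearest-neighbor growth threshold (length units).
#' @param T_spl splash comparison interval (steps).
#' @param W trailing window for the mean turning angle (steps).
#' @return A validated list of class `index_params`.
#' @export
index_params <- function(alpha_tor = pi / 30, alpha_tor_hi = pi / 10,
                         alpha_trans = pi / 30, r_spl = 8,
                         T_spl = 10, W = 10) {
  stopifnot(alpha_tor > 0, alpha_tor_hi > alpha_tor, alpha_trans > 0,
            r_spl > 0, T_spl >= 1, W >= 1)
  structure(list(alpha_tor = alpha_tor, alpha_tor_hi = alpha_tor_hi,
                 alpha_trans = alpha_trans, r_spl = r_spl,
                 T_spl = as.integer(T_spl), W = as.integer(W)),
            class = "index_params")
}

# matrix of windowed mean turning angles: row t, column agent; NA before
# the warm-up t >= W + 2
.mean_turn_matrix <- function(traj, W) {
  v <- traj$config$v
  T_total <- nrow(traj$x)
  n <- ncol(traj$x)
  out <- matrix(NA_real_, T_total, n)
  if (T_total < W + 2) return(out)
  dx <- diff(traj$x); dy <- diff(traj$y)
  m <- T_total - 1
  arg <- (dx[-1, , drop = FALSE] * dx[-m, , drop = FALSE] +
            dy[-1, , drop = FALSE] * dy[-m, , drop = FALSE]) / v^2
  arg[arg > 1] <- 1
  arg[arg < -1] <- -1
  alpha <- acos(arg)   # row i: angle at time i+2
  cs <- apply(alpha, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = n)
  for (t in (W + 2):T_total) {
    hi <- t - 2
    lo <- t - W - 2
    prev <- if (lo == 0) 0 else cs[lo, ]
    out[t, ] <- (cs[hi, ] - prev) / W
  }
  out
}

#' Windowed mean turning angle of one agent
#'
#' Arithmetic mean of the bending angles over the trailing window
#' `t - W + 1, ..., t`.
#'
#' @param x,y one agent's coordinate vectors (unwrapped).
#' @param t time step (requires `t >= W + 2`).
#' @param W window length (steps).
#' @param v speed.
#' @return Mean turning angle in radians, or `NA` when the history is too
#'   short.
#' @export
mean_turn <- function(x, y, t, W = 10, v = 5) {
  if (t < W + 2 || t > length(x)) return(NA_real_)
  alpha <- .bending_series(x, y, v)
  mean(alpha[(t - W - 1):(t - 2)])
}

# nearest-neighbor distance of every agent at one time step
.rmin_at <- function(traj, t) {
  cfg <- traj$config
  pos <- cbind(traj$x[t, ], traj$y[t, ])
  if (cfg$boundary == "periodic") pos <- pos %% cfg$L
  d2 <- .dist2_matrix(pos, cfg$boundary, cfg$L)
  diag(d2) <- Inf
  sqrt(apply(d2, 1, min))
}

#' Per-time-step behavior-index counts
#'
#' For every admissible time step, the number of agents in tornado mode
#' (mean turn strictly between `alpha_tor` and `alpha_tor_hi`), splash mode
#' (nearest-neighbor distance grew by more than `r_spl` since `t - T_spl`),
#' and translation mode (mean turn below `alpha_trans`). Admissible steps
#' start at `max(W + 2, T_spl + 1)` so every agent has full history; the
#' three conditions are not mutually exclusive.
#'
#' @param traj a `swarm_trajectory`.
#' @param params an [index_params()].
#' @return An `index_series`: data frame with columns `t`, `tornado`,
#'   `splash`, `translation`.
#' @export
index_series <- function(traj, params = index_params()) {
  stopifnot(inherits(traj, "swarm_trajectory"))
  T_total <- nrow(traj$x)
  n <- ncol(traj$x)
  t0 <- max(params$W + 2, params$T_spl + 1)
  if (T_total < t0) stop("trajectory shorter than the index warm-up")
  mt <- .mean_turn_matrix(traj, params$W)
  rmin <- if (n >= 2) {
    vapply(seq_len(T_total), function(t) .rmin_at(traj, t), numeric(n))
  } else NULL  # single agent: no neighbor, splash count is 0
  ts <- t0:T_total
  tor <- integer(length(ts)); spl <- integer(length(ts))
  trs <- integer(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    m <- mt[t, ]
    tor[i] <- sum(m > params$alpha_tor & m < params$alpha_tor_hi,
                  na.rm = TRUE)
    trs[i] <- sum(m < params$alpha_trans, na.rm = TRUE)
    if (!is.null(rmin))
      spl[i] <- sum(rmin[, t] - rmin[, t - params$T_spl] > params$r_spl)
  }
  out <- data.frame(t = ts, tornado = tor, splash = spl, translation = trs)
  class(out) <- c("index_series", "data.frame")
  out
}

#' @rdname index_series
#' @param t single time step.
#' @export
tornado_count <- function(traj, t, params = index_params()) {
  m <- .mean_turn_matrix(traj, params$W)[t, ]
  sum(m > params$alpha_tor & m < params$alpha_tor_hi, na.rm = TRUE)
}

#' @rdname index_series
#' @export
translation_count <- function(traj, t, params = index_params()) {
  m <- .mean_turn_matrix(traj, params$W)[t, ]
  sum(m < params$alpha_trans, na.rm = TRUE)
}

#' @rdname index_series
#' @export
splash_count <- function(traj, t, params = index_params()) {
  if (ncol(traj$x) < 2) return(0L)
  if (t <= params$T_spl) stop("t must exceed the splash interval")
  sum(.rmin_at(traj, t) - .rmin_at(traj, t - params$T_spl) > params$r_spl)
}

#' Ratio series and summary of behavior indexes
#'
#' `ratio_series()` forms the per-time-step ratios tornado/translation and
#' splash/translation, skipping steps with a zero translation count.
#' `ratio_summary()` reduces each ratio series to the six standard summary
#' statistics (minimum, first quartile, median, mean, third quartile,
#' maximum, default quantile convention).
#'
#' @param series an [index_series()].
#' @return For `ratio_series()`, a data frame with columns `t`,
#'   `tornado_translation`, `splash_translation` and attribute `skipped`
#'   (number of zero-translation steps dropped). For `ratio_summary()`, a
#'   list with the two six-number summaries and the skip count.
#' @export
ratio_series <- function(series) {
  stopifnot(nrow(series) > 0)
  keep <- series$translation > 0
  out <- data.frame(
    t = series$t[keep],
    tornado_translation = series$tornado[keep] / series$translation[keep],
    splash_translation = series$splash[keep] / series$translation[keep])
  attr(out, "skipped") <- sum(!keep)
  out
}

#' @rdname ratio_series
#' @export
ratio_summary <- function(series) {
  rs <- ratio_series(series)
  if (nrow(rs) == 0) stop("translation count is zero at every time step")
  six <- function(v) {
    q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    setNames(c(q[1], q[2], q[3], mean(v), q[4], q[5]),
             c("Min.", "1st Qu.", "Median", "Mean", "3rd Qu.", "Max."))
  }
  list(tornado_translation = six(rs$tornado_translation),
       splash_translation = six(rs$splash_translation),
       skipped = attr(rs, "skipped"))
}

#' Nonparametric comparison of ratio series
#'
#' Standard published tests on two or more series of behavior ratios:
#' Shapiro-Wilk normality per series (on an evenly spaced subsample of at
#' most 5000 values, the test's size limit), a two-sided Wilcoxon rank-sum
#' test for two series, and a Kruskal-Wallis rank-sum test when three or
#' more series are supplied. Degenerate inputs (all values tied) yield `NA`
#' for the affected test.
#'
#' @param ... two or more numeric vectors (each of length >= 3), optionally
#'   named.
#' @return List with elements `shapiro` (named p-value vector),
#'   `wilcoxon` (p-value, two-series case) and `kruskal` (p-value, three or
#'   more series).
#' @export
compare_models <- function(...) {
  series <- list(...)
  if (length(series) == 1 && is.list(series[[1]]) &&
      !is.numeric(series[[1]]))
    series <- series[[1]]
  stopifnot(length(series) >= 2, all(vapply(series, length, 1L) >= 3))
  if (is.null(names(series)) || any(names(series) == ""))
    names(series) <- paste0("series", seq_along(series))
  safe_p <- function(expr) tryCatch(suppressWarnings(expr$p.value),
                                    error = function(e) NA_real_)
  shapiro <- vapply(series, function(v) {
    if (length(v) > 5000)
      v <- v[round(seq(1, length(v), length.out = 5000))]
    safe_p(shapiro.test(v))
  }, numeric(1))
  out <- list(shapiro = shapiro, wilcoxon = NA_real_, kruskal = NA_real_)
  if (length(series) == 2)
    out$wilcoxon <- safe_p(wilcox.test(series[[1]], series[[2]],
                                       alternative = "two.sided"))
  if (length(series) >= 3)
    out$kruskal <- safe_p(kruskal.test(series))
  out
}
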